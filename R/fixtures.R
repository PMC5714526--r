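#' Load a packaged reference fixture
#'
#' The package ships the published reference dataset for the M42-type seed
#' as machine-readable fixtures: the polar dose-rate table (`"table1"`, 19
#' angles x 11 radii = 209 cells, cGy/h/mCi), the radial dose function with
#' its independent-code comparison column (`"table2"`, 11 radii), the 2D
#' anisotropy function (`"table3"`, 209 cells), and the scalar constants
#' (`"constants"`: dose-rate constant, air-kerma strength, polynomial
#' coefficients). The numeric values are stored exactly as printed; a
#' checksum in each file header guards against corruption.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"constants"`.
#' @return `"table1"`: a [polar_dose_table()]; `"table2"`: a data.frame
#'   with columns `r_cm`, `g_fluka`, `g_mcnp5`, `difference_pct`;
#'   `"table3"`: a data.frame `r_cm`, `theta_deg`, `F`; `"constants"`: a
#'   named list.
#' @examples
#' t1 <- load_fixture("table1")
#' subset(t1, r_cm == 0.5 & theta_deg == 0)$dose_rate  # 4.544
#' @export
load_fixture <- function(name = c("table1", "table2", "table3",
                                  "constants")) {
  name <- match.arg(name)
  dir <- .ybdosim_extdata("tables")
  if (name == "constants") {
    return(jsonlite::fromJSON(file.path(dir, "constants.json")))
  }
  path <- file.path(dir, switch(name,
    table1 = "table1_dose_rate.csv",
    table2 = "table2_radial_dose.csv",
    table3 = "table3_anisotropy.csv"))
  parse_fixture_table(path, name)
}

# parse a fixture CSV, verifying the header checksum (guards the packaged
# data against corruption); kept separate from path resolution for testing
parse_fixture_table <- function(path, name) {
  lines <- readLines(path)
  stated <- as.numeric(sub("^# checksum:\\s*", "",
                           grep("^# checksum:", lines, value = TRUE)))
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(textConnection(body), check.names = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (name == "table2") vals <- as.matrix(tab[, c("g_fluka", "g_mcnp5")])
  if (abs(sum(vals) - stated) > 5e-7 * length(vals)) {
    stop("fixture '", name, "' failed its checksum: corrupted packaged data")
  }
  if (name == "table2") {
    names(tab)[1L] <- "r_cm"
    return(tab)
  }
  r <- as.numeric(colnames(tab)[-1L])
  long <- data.frame(
    r_cm = rep(r, each = nrow(tab)),
    theta_deg = rep(tab[[1L]], times = length(r)),
    value = as.vector(vals))
  if (name == "table1") {
    polar_dose_table(long$r_cm, long$theta_deg, long$value,
                     meta = list(source = "published reference table 1"))
  } else {
    out <- data.frame(r_cm = long$r_cm, theta_deg = long$theta_deg,
                      F = long$value)
    out[order(out$r_cm, out$theta_deg), ]
  }
}
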