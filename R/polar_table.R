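#' Polar dose-rate table
#'
#' A long-format table of dose rates on the polar grid around the source:
#' one row per (r, theta) cell with the dose rate in cGy/h/mCi and the
#' per-cell relative statistical uncertainty (NA where undefined, e.g. for
#' fixture tables or zero-score bins).
#'
#' @param r_cm radial distance of each cell, cm.
#' @param theta_deg polar angle of each cell, degrees from the seed tip
#'   (cable side at 180).
#' @param dose_rate dose rate in cGy/h/mCi; must be finite.
#' @param rel_err relative (1 sigma) statistical uncertainty, or NA.
#' @param meta optional named list of provenance metadata (seed, histories,
#'   mode, ...), stored as an attribute and echoed by the CSV writer.
#' @return A data.frame of class `polar_dose_table`.
#' @export
polar_dose_table <- function(r_cm, theta_deg, dose_rate,
                             rel_err = NA_real_, meta = list()) {
  stopifnot(length(r_cm) == length(theta_deg),
            length(r_cm) == length(dose_rate))
  if (any(!is.finite(dose_rate))) stop("non-finite dose rate")
  out <- data.frame(r_cm = r_cm, theta_deg = theta_deg,
                    dose_rate = dose_rate,
                    rel_err = rep_len(rel_err, length(r_cm)))
  structure(out, meta = meta, class = c("polar_dose_table", "data.frame"))
}

#' @export
print.polar_dose_table <- function(x, ...) {
  cat("<polar_dose_table>", nrow(x), "cells, r in [",
      min(x$r_cm), ",", max(x$r_cm), "] cm\n")
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  meta:", paste(names(meta), unlist(lapply(meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Read and write polar dose tables as CSV
#'
#' The CSV layout is long format with columns `r_cm`, `theta_deg`,
#' `dose_rate_cGy_per_h_per_mCi`, `rel_err`, preceded by `#` metadata header
#' lines (`# key: value`). The reader restores the metadata.
#'
#' @param table a [polar_dose_table()].
#' @param path file path.
#' @return `read_polar_dose_table()` returns a [polar_dose_table()];
#'   `write_polar_dose_table()` returns `path` invisibly.
#' @export
write_polar_dose_table <- function(table, path) {
  stopifnot(inherits(table, "polar_dose_table"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(table, "meta")
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
  writeLines("r_cm,theta_deg,dose_rate_cGy_per_h_per_mCi,rel_err", con)
  writeLines(sprintf("%.10g,%.10g,%.10g,%.6g", table$r_cm, table$theta_deg,
                     table$dose_rate, table$rel_err), con)
  invisible(path)
}

#' @rdname write_polar_dose_table
#' @export
read_polar_dose_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  polar_dose_table(tab[[1L]], tab[[2L]], tab[[3L]],
                   suppressWarnings(as.numeric(tab[[4L]])), meta = meta)
}

#' Merge duplicate cells by uncertainty-weighted averaging
#'
#' Cells that share the same (r, theta) coordinates (for example azimuthal
#' duplicates from cylindrical re-binning) are merged by inverse-variance
#' weighting of their absolute uncertainties; with equal or undefined
#' uncertainties the plain mean is used. Mirror cells across the transverse
#' plane (theta vs 180 - theta) are deliberately NOT averaged: the source
#' assembly is asymmetric about that plane because of the cable.
#'
#' @param table a [polar_dose_table()].
#' @return A [polar_dose_table()] with one row per unique (r, theta).
#' @examples
#' t <- polar_dose_table(c(1, 1), c(90, 90), c(2, 4), c(0.5, 0.5))
#' average_symmetric_bins(t)$dose_rate  # inverse-variance weighted
#' @export
average_symmetric_bins <- function(table) {
  stopifnot(inherits(table, "polar_dose_table"))
  key <- paste(signif(table$r_cm, 12), signif(table$theta_deg, 12))
  if (!anyDuplicated(key)) return(table)
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(groups, function(idx) {
    d <- table$dose_rate[idx]
    re <- table$rel_err[idx]
    sig <- re * d
    if (length(idx) == 1L) {
      w <- 1
    } else if (any(!is.finite(sig)) || any(sig <= 0)) {
      w <- rep(1, length(idx))
    } else {
      w <- 1 / sig^2
    }
    dm <- sum(w * d) / sum(w)
    rem <- if (all(is.finite(sig)) && all(sig > 0)) {
      sqrt(1 / sum(1 / sig^2)) / dm
    } else {
      NA_real_
    }
    c(table$r_cm[idx[1L]], table$theta_deg[idx[1L]], dm, rem)
  })
  m <- do.call(rbind, rows)
  o <- order(m[, 1L], m[, 2L])
  polar_dose_table(m[o, 1L], m[o, 2L], m[o, 3L], m[o, 4L],
                   meta = attr(table, "meta"))
}

# dose matrix (theta rows x r columns) from a long table; errors if the
# table is not a complete grid
dose_matrix <- function(table) {
  r <- sort(unique(table$r_cm))
  th <- sort(unique(table$theta_deg))
  m <- matrix(NA_real_, length(th), length(r),
              dimnames = list(theta = th, r = r))
  m[cbind(match(table$theta_deg, th), match(table$r_cm, r))] <-
    table$dose_rate
  if (any(is.na(m))) stop("polar table is not a complete (r, theta) grid")
  m
}
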