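#' Define a material by density and elemental mass fractions
#'
#' A material is a named density (g/cm^3) plus an elemental composition given
#' as mass fractions. Photon interaction coefficients for the material are
#' assembled from the packaged per-element tables with the standard mixture
#' rule (mass-fraction weighted sum of elemental mass coefficients).
#'
#' @param name character scalar, label for the material.
#' @param density mass density in g/cm^3, must be positive.
#' @param composition named numeric vector of elemental mass fractions
#'   (names are element symbols present in the packaged data); must sum to 1
#'   within 1e-6.
#' @return An object of class `material_spec`.
#' @examples
#' water <- material_spec("water", 0.998, c(H = 0.111894, O = 0.888106))
#' @export
material_spec <- function(name, density, composition) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("material '", name, "': density must be a positive number")
  }
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("material '", name, "': composition must be a named vector")
  }
  if (any(composition < 0)) {
    stop("material '", name, "': negative mass fraction")
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("material '", name, "': mass fractions sum to ", sum(composition),
         ", not 1")
  }
  unknown <- setdiff(names(composition), known_elements())
  if (length(unknown)) {
    stop("material '", name, "': no packaged data for element(s) ",
         paste(unknown, collapse = ", "))
  }
  structure(list(name = name, density = density,
                 composition = composition[composition > 0]),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat("<material_spec> ", x$name, " (", format(x$density), " g/cm^3)\n",
      sep = "")
  comp <- paste0(names(x$composition), "=",
                 format(x$composition, digits = 5, trim = TRUE))
  cat("  composition:", paste(comp, collapse = ", "), "\n")
  invisible(x)
}

known_elements <- function() {
  files <- list.files(.ybdosim_extdata("xsec"), pattern = "^[A-Z][a-z]?\\.txt$")
  sub("\\.txt$", "", files)
}

#' Built-in materials
#'
#' Materials used by the default source model and phantoms: liquid water
#' (0.998 g/cm^3), dry air near sea level (1.20479e-3 g/cm^3), ytterbium oxide
#' (7.1 g/cm^3), titanium (4.51 g/cm^3) and stainless steel 304 (7.80 g/cm^3,
#' 16% Cr, 10% Ni, 0.03% S, 0.75% Si, 0.08% C, 2% Mn, 0.045% P, 69.095% Fe,
#' 2% Mo by mass).
#'
#' @param name one of `"water"`, `"air"`, `"yb2o3"`, `"titanium"`, `"ss304"`.
#' @return A [material_spec()].
#' @examples
#' builtin_material("ss304")
#' @export
builtin_material <- function(name = c("water", "air", "yb2o3", "titanium",
                                      "ss304")) {
  name <- match.arg(name)
  switch(name,
    water = material_spec("water", 0.998, c(H = 0.111894, O = 0.888106)),
    air = material_spec("air", 1.20479e-3,
                        c(C = 0.000124, N = 0.755267, O = 0.231781,
                          Ar = 0.012828)),
    # Yb2O3: 2*173.045 / (2*173.045 + 3*15.999) ytterbium by mass
    yb2o3 = material_spec("yb2o3", 7.1, c(Yb = 0.8782097, O = 0.1217903)),
    titanium = material_spec("titanium", 4.51, c(Ti = 1)),
    ss304 = material_spec("ss304", 7.80,
                          c(Cr = 0.16, Ni = 0.10, S = 0.0003, Si = 0.0075,
                            C = 0.0008, Mn = 0.02, P = 0.00045, Fe = 0.69095,
                            Mo = 0.02)))
}
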