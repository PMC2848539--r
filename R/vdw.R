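#' Van der Waals radius table
#'
#' Element-wise van der Waals radii (Bondi-style) used by the interface
#' distance criterion: two atoms are "in contact" when their distance is
#' strictly less than the sum of their radii plus the diameter of a water
#' molecule (default 2.8 Angstrom).
#'
#' @param radii named numeric vector of radii in Angstrom, names are element
#'   symbols (upper case). Defaults cover the heavy atoms found in protein
#'   chains: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80.
#' @param water_diameter diameter of a water molecule in Angstrom added to
#'   the radius sum (default 2.8).
#' @param fallback_radius radius used for elements absent from `radii`;
#'   `NA` (default) makes unknown elements an error in
#'   [assign_interface()].
#' @return an object of class `vdw_table`.
#' @examples
#' vdw_table()
#' vdw_table(water_diameter = 0)  # raw vdW contact
#' @export
vdw_table <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80),
                      water_diameter = 2.8,
                      fallback_radius = NA_real_) {
  if (any(radii <= 0)) stop("all vdW radii must be > 0", call. = FALSE)
  if (water_diameter < 0) stop("water_diameter must be >= 0", call. = FALSE)
  names(radii) <- toupper(names(radii))
  structure(list(radii = radii, water_diameter = water_diameter,
                 fallback_radius = fallback_radius),
            class = "vdw_table")
}

# Resolve per-atom radii; error on unknown element unless fallback set.
vdw_radii_for <- function(vdw, elements) {
  r <- vdw$radii[toupper(elements)]
  bad <- is.na(r)
  if (any(bad)) {
    if (is.na(vdw$fallback_radius))
      stop("unknown element(s) with no fallback radius: ",
           paste(unique(elements[bad]), collapse = ", "), call. = FALSE)
    r[bad] <- vdw$fallback_radius
  }
  unname(r)
}

#' @export
print.vdw_table <- function(x, ...) {
  cat("vdW table:", paste(names(x$radii), x$radii, sep = "=", collapse = " "),
      "| water diameter", x$water_diameter, "A\n")
  invisible(x)
}
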