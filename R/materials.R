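#' Define a stack material
#'
#' A material is an elemental composition (mass fractions) plus a bulk
#' density. Stopping powers for compounds and mixtures are obtained by Bragg
#' additivity over the elemental constituents, so no compound mean excitation
#' energy is needed.
#'
#' @param name Character label.
#' @param composition Named numeric vector of elemental mass fractions; names
#'   must be element symbols known to the package (`H`, `C`, `N`, `O`, `Al`,
#'   `Ar`, `Ti`, `Ti48`, `Ni`). Must sum to 1 within `1e-6`.
#' @param density_g_cm3 Bulk density in g/cm^3; must be positive.
#' @return An object of class `material`.
#' @examples
#' material("titanium", c(Ti = 1), 4.506)
#' @export
material <- function(name, composition, density_g_cm3) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named numeric vector of mass fractions")
  unknown <- setdiff(names(composition), .elements$symbol)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", format(sum(composition)), ")")
  if (!is.numeric(density_g_cm3) || density_g_cm3 <= 0)
    stop("density must be positive")
  structure(list(name = name,
                 composition = composition,
                 density_g_cm3 = density_g_cm3),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, " density", x$density_g_cm3, "g/cm^3\n")
  comp <- paste0(names(x$composition), "=", signif(x$composition, 5))
  cat("  mass fractions:", paste(comp, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in stack materials
#'
#' Materials used in a typical stacked target: the target deposit
#' (isotopically pure Ti-48 or natural Ti), aluminium degraders/backings and
#' recoil catchers, natural nickel monitor foils, the Kapton beam-exit window
#' and dry air for the window-to-stack gap.
#'
#' @param name One of `"Ti"`, `"Ti48"`, `"Al"`, `"Ni"`, `"kapton"`, `"air"`.
#' @return A [material] object.
#' @examples
#' builtin_material("kapton")
#' @export
builtin_material <- function(name = c("Ti", "Ti48", "Al", "Ni", "kapton", "air")) {
  name <- match.arg(name)
  switch(name,
    Ti   = material("Ti",   c(Ti = 1),   4.506),
    Ti48 = material("Ti48", c(Ti48 = 1), 4.506),
    Al   = material("Al",   c(Al = 1),   2.699),
    Ni   = material("Ni",   c(Ni = 1),   8.902),
    # Kapton C22H10N2O5, molar mass 382.35 g/mol
    kapton = material("kapton",
                      c(C = 0.691130, H = 0.026362, N = 0.073270, O = 0.209238) /
                        sum(c(0.691130, 0.026362, 0.073270, 0.209238)),
                      1.42),
    air = material("air",
                   c(C = 0.000124, N = 0.755268, O = 0.231781, Ar = 0.012827) /
                     sum(c(0.000124, 0.755268, 0.231781, 0.012827)),
                   1.20479e-3))
}

.resolve_material <- function(m) {
  if (inherits(m, "material")) return(m)
  if (is.character(m) && length(m) == 1) return(builtin_material(m))
  stop("expected a material object or a built-in material name")
}
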