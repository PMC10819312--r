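# Decay-data registry: half-lives and gamma lines of the product nuclides
# (Sc-47, Sc-46, Sc-44m, Sc-44g, Sc-43, V-48) and of the Ni-57 monitor
# product, plus quantification-line selection. The Sc-46 1120 keV line is
# flagged unusable (interference with background Bi-214 from the natural
# U-238 chain); for Sc-46 only the 889 keV line quantifies. The Sc-44m
# 1157 keV branch is unusable because it coincides with the strong Sc-44g
# 1157 keV line.

.unit_to_hours <- c(s = 1 / 3600, m = 1 / 60, h = 1, d = 24)

#' Decay constant from a half-life
#'
#' @param half_life Half-life value (positive).
#' @param unit Time unit of `half_life`: `"s"`, `"m"`, `"h"` or `"d"`.
#' @return Decay constant lambda = ln(2)/t1/2 in 1/hour.
#' @examples
#' decay_constant(3.3492, "d")   # Sc-47
#' decay_constant(log(2), "h")   # 1 per hour
#' @export
decay_constant <- function(half_life, unit = "h") {
  unit <- match.arg(unit, names(.unit_to_hours))
  if (!is.numeric(half_life) || any(!is.finite(half_life)) || any(half_life <= 0))
    stop("half-life must be positive")
  log(2) / (half_life * .unit_to_hours[[unit]])
}

.validate_nuclide_df <- function(df, path = "<data>") {
  req <- c("nuclide", "half_life_value", "half_life_unit", "half_life_unc",
           "gamma_energy_kev", "gamma_intensity", "intensity_unc", "usable")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("nuclide table ", path, " is missing mandatory field(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop("nuclide table ", path, " has no rows")
  if (any(!is.finite(df$half_life_value)) || any(df$half_life_value <= 0))
    stop("half-life must be positive for every nuclide")
  if (any(!df$half_life_unit %in% names(.unit_to_hours)))
    stop("half-life unit must be one of s, m, h, d")
  if (any(!is.finite(df$gamma_energy_kev)) || any(df$gamma_energy_kev <= 0))
    stop("gamma-line energies must be positive")
  ok_int <- is.finite(df$gamma_intensity) &
    df$gamma_intensity > 0 & df$gamma_intensity <= 1
  if (any(!ok_int))
    stop("gamma intensities must lie in (0, 1]")
  invisible(df)
}

#' Load a nuclide decay-data table
#'
#' Reads a CSV with one row per gamma line (columns `nuclide`,
#' `half_life_value`, `half_life_unit`, `half_life_unc`, `gamma_energy_kev`,
#' `gamma_intensity`, `intensity_unc`, `usable`) and builds a registry of
#' nuclides and gamma lines. Half-lives are converted to hours internally;
#' intensities are fractions in (0, 1].
#'
#' @param path Path to the CSV file. Defaults to the decay data shipped with
#'   the package.
#' @return An object of class `nuclide_registry`: list with `nuclides` (one
#'   row per nuclide, half-life in native unit and in hours, decay constant
#'   per hour) and `lines` (one row per gamma line).
#' @export
load_nuclide_table <- function(path = system.file("extdata", "nuclide_table.csv",
                                                  package = "sc47yield")) {
  if (!file.exists(path)) stop("nuclide table not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse nuclide table ", path, ": ",
                             conditionMessage(e)))
  .validate_nuclide_df(df, path)
  df$nuclide <- as.character(df$nuclide)
  df$half_life_unit <- as.character(df$half_life_unit)
  df$usable <- as.logical(df$usable)
  nuc <- unique(df[, c("nuclide", "half_life_value", "half_life_unit",
                       "half_life_unc")])
  if (anyDuplicated(nuc$nuclide))
    stop("inconsistent half-life entries for: ",
         paste(nuc$nuclide[duplicated(nuc$nuclide)], collapse = ", "))
  nuc$half_life_h <- nuc$half_life_value *
    .unit_to_hours[nuc$half_life_unit]
  nuc$lambda_h <- log(2) / nuc$half_life_h
  rownames(nuc) <- NULL
  lines <- df[, c("nuclide", "gamma_energy_kev", "gamma_intensity",
                  "intensity_unc", "usable")]
  rownames(lines) <- NULL
  structure(list(nuclides = nuc, lines = lines), class = "nuclide_registry")
}

#' Write a nuclide registry back to CSV
#'
#' Inverse of [load_nuclide_table()]; writing then re-reading reproduces the
#' registry exactly.
#'
#' @param registry A `nuclide_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclide_table <- function(registry, path) {
  stopifnot(inherits(registry, "nuclide_registry"))
  df <- merge(registry$lines,
              registry$nuclides[, c("nuclide", "half_life_value",
                                    "half_life_unit", "half_life_unc")],
              by = "nuclide", sort = FALSE)
  df <- df[, c("nuclide", "half_life_value", "half_life_unit", "half_life_unc",
               "gamma_energy_kev", "gamma_intensity", "intensity_unc", "usable")]
  ord <- order(match(df$nuclide, registry$nuclides$nuclide), df$gamma_energy_kev)
  utils::write.csv(df[ord, ], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default decay data shipped with the package
#'
#' Cached registry of the seven nuclides used in the analysis.
#' @return A `nuclide_registry`.
#' @export
default_nuclides <- function() {
  if (is.null(.pkg_cache$nuclides))
    .pkg_cache$nuclides <- load_nuclide_table()
  .pkg_cache$nuclides
}

#' @export
print.nuclide_registry <- function(x, ...) {
  cat("<nuclide_registry>", nrow(x$nuclides), "nuclides,",
      nrow(x$lines), "gamma lines\n")
  print(x$nuclides[, c("nuclide", "half_life_value", "half_life_unit",
                       "lambda_h")], row.names = FALSE)
  invisible(x)
}

.nuclide_row <- function(registry, nuclide) {
  i <- match(nuclide, registry$nuclides$nuclide)
  if (is.na(i)) stop("unknown nuclide: ", nuclide)
  registry$nuclides[i, ]
}

#' Half-life (hours) and decay constant (1/hour) of a registry nuclide
#'
#' @param registry A `nuclide_registry`.
#' @param nuclide Nuclide symbol, e.g. `"Sc-47"`.
#' @return Numeric scalar.
#' @export
half_life_hours <- function(registry, nuclide) .nuclide_row(registry, nuclide)$half_life_h

#' @rdname half_life_hours
#' @export
lambda_per_hour <- function(registry, nuclide) .nuclide_row(registry, nuclide)$lambda_h

#' Gamma lines usable for quantification
#'
#' Returns the gamma lines of a nuclide flagged as usable for activity
#' quantification (lines with known interferences are excluded).
#'
#' @inheritParams half_life_hours
#' @return Data frame of usable lines (`gamma_energy_kev`, `gamma_intensity`,
#'   `intensity_unc`).
#' @export
quantification_lines <- function(registry, nuclide) {
  .nuclide_row(registry, nuclide)  # errors on unknown nuclide
  out <- registry$lines[registry$lines$nuclide == nuclide & registry$lines$usable, ]
  rownames(out) <- NULL
  out
}

#' Gamma-line intensity lookup
#'
#' Finds the registry line of a nuclide closest to a measured line energy
#' (within `tol_kev`) and returns its intensity and uncertainty.
#'
#' @inheritParams half_life_hours
#' @param energy_kev Measured line energy.
#' @param tol_kev Matching tolerance (keV).
#' @return List with `gamma_energy_kev`, `gamma_intensity`, `intensity_unc`,
#'   `usable`.
#' @export
match_gamma_line <- function(registry, nuclide, energy_kev, tol_kev = 1) {
  ln <- registry$lines[registry$lines$nuclide == nuclide, ]
  if (!nrow(ln)) stop("unknown nuclide: ", nuclide)
  i <- which.min(abs(ln$gamma_energy_kev - energy_kev))
  if (abs(ln$gamma_energy_kev[i] - energy_kev) > tol_kev)
    stop("no ", nuclide, " gamma line within ", tol_kev, " keV of ",
         energy_kev, " keV")
  as.list(ln[i, c("gamma_energy_kev", "gamma_intensity", "intensity_unc",
                  "usable")])
}

#' Reaction thresholds for products of proton-irradiated Ti-48
#'
#' Laboratory-frame threshold energies computed from atomic mass excesses for
#' the lowest-threshold channel that emits only nucleons and alpha particles
#' (light-cluster emission channels are neglected): (p,2p) for Sc-47,
#' (p,2pn) for Sc-46, (p,alpha n) for Sc-44 (+ the 271 keV isomer excitation
#' for Sc-44m), (p,alpha 2n) for Sc-43 and (p,n) for V-48. Used as the zero
#' anchors of excitation-function fits; override via the `thresholds`
#' argument of the fitting functions if desired.
#'
#' @return Named numeric vector of threshold energies in MeV.
#' @export
reaction_thresholds <- function() {
  me <- .mass_excess_mev
  q <- c(
    "Sc-47"  = me[["Ti-48"]] - me[["Sc-47"]] - me[["p"]],
    "Sc-46"  = me[["Ti-48"]] - me[["Sc-46"]] - me[["p"]] - me[["n"]],
    "Sc-44g" = me[["Ti-48"]] + me[["p"]] - me[["Sc-44"]] - me[["alpha"]] - me[["n"]],
    "Sc-44m" = me[["Ti-48"]] + me[["p"]] - me[["Sc-44"]] - me[["alpha"]] - me[["n"]] -
      .sc44m_excitation_mev,
    "Sc-43"  = me[["Ti-48"]] + me[["p"]] - me[["Sc-43"]] - me[["alpha"]] - 2 * me[["n"]],
    "V-48"   = me[["Ti-48"]] + me[["p"]] - me[["V-48"]] - me[["n"]]
  )
  -q * (.u_target_ti48 + .u_proton) / .u_target_ti48
}

#' Default isomeric-transition branching of Sc-44m to Sc-44g
#'
#' Fraction of Sc-44m decays proceeding by isomeric transition to the ground
#' state (standard evaluated value; the remainder is direct electron
#' capture). Configurable wherever the decay chain is evolved; the purity
#' results are insensitive at the percent level.
#'
#' @return Numeric scalar, 0.988.
#' @export
it_branching_sc44 <- function() 0.988
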