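# Excitation-function fitting and the thick-target activation integral.

#' Fit an excitation function through measured cross-section points
#'
#' Builds a shape-preserving (Fritsch-Carlson monotone-segment cubic)
#' interpolant through the measured points plus a zero anchor at the
#' reaction threshold. The fit is exact at the data points, never negative,
#' zero below threshold, and extrapolates as a constant above the last
#' measured energy (flagged on prediction).
#'
#' @param energy_mev Measured proton energies (MeV), distinct.
#' @param sigma_mb Measured cross-sections (mb, non-negative).
#' @param threshold_mev Reaction threshold used as the `(threshold, 0)`
#'   anchor; must lie below the lowest data point.
#' @param product Optional product nuclide label (e.g. `"Sc-47"`).
#' @param sigma_unc_mb Optional point uncertainties (stored, not used by the
#'   interpolant).
#' @return An object of class `excitation_fit` with `predict`, `print`,
#'   `plot` and `coef` methods.
#' @examples
#' xs <- fit_excitation(c(20, 30), c(10, 20), threshold_mev = 10)
#' predict(xs, 25)
#' @export
fit_excitation <- function(energy_mev, sigma_mb, threshold_mev,
                           product = NULL, sigma_unc_mb = NULL) {
  if (length(energy_mev) < 2) stop("need at least two cross-section points")
  if (length(energy_mev) != length(sigma_mb)) stop("energy/sigma length mismatch")
  if (anyDuplicated(energy_mev)) stop("duplicate energies in cross-section points")
  if (any(sigma_mb < 0)) stop("cross-sections must be non-negative")
  ord <- order(energy_mev)
  e <- energy_mev[ord]; s <- sigma_mb[ord]
  if (threshold_mev >= e[1])
    stop("threshold (", threshold_mev, " MeV) must lie below the first data point (",
         e[1], " MeV)")
  x <- c(threshold_mev, e); y <- c(0, s)
  structure(list(product = product,
                 energy_mev = e, sigma_mb = s,
                 sigma_unc_mb = if (is.null(sigma_unc_mb)) rep(NA_real_, length(s))
                                else sigma_unc_mb[ord],
                 threshold_mev = threshold_mev,
                 e_max = max(e),
                 fun = stats::splinefun(x, y, method = "monoH.FC")),
            class = "excitation_fit")
}

#' Evaluate a fitted excitation function
#'
#' @param object An `excitation_fit`.
#' @param energy_mev Energies at which to evaluate (MeV).
#' @param warn_extrapolation Warn when evaluating above the last data point
#'   (where the curve continues as a constant).
#' @param ... Unused.
#' @return Cross-sections in mb (zero below threshold, never negative).
#' @export
predict.excitation_fit <- function(object, energy_mev,
                                   warn_extrapolation = TRUE, ...) {
  out <- numeric(length(energy_mev))
  above <- energy_mev > object$e_max
  if (any(above) && warn_extrapolation)
    warning("extrapolating above the last measured point (",
            object$e_max, " MeV) as a constant")
  inside <- energy_mev >= object$threshold_mev & !above
  out[inside] <- pmax(0, object$fun(energy_mev[inside]))
  out[above] <- pmax(0, object$fun(object$e_max))
  out
}

#' @export
print.excitation_fit <- function(x, ...) {
  cat("<excitation_fit>", if (!is.null(x$product)) x$product else "",
      "\n  ", length(x$energy_mev), " points, ",
      sprintf("%.2f", min(x$energy_mev)), "-", sprintf("%.2f", max(x$energy_mev)),
      " MeV, threshold anchor at ", sprintf("%.2f", x$threshold_mev), " MeV\n",
      sep = "")
  invisible(x)
}

#' @export
coef.excitation_fit <- function(object, ...) {
  data.frame(energy_mev = c(object$threshold_mev, object$energy_mev),
             sigma_mb = c(0, object$sigma_mb),
             sigma_unc_mb = c(0, object$sigma_unc_mb))
}

#' @export
plot.excitation_fit <- function(x, n = 300, ...) {
  e <- seq(x$threshold_mev, x$e_max, length.out = n)
  s <- predict(x, e, warn_extrapolation = FALSE)
  graphics::plot(e, s, type = "l", xlab = "Proton energy (MeV)",
                 ylab = expression(sigma ~ "(mb)"),
                 main = x$product %||% "excitation function", ...)
  graphics::points(x$energy_mev, x$sigma_mb, pch = 19)
  if (!all(is.na(x$sigma_unc_mb)))
    graphics::arrows(x$energy_mev, x$sigma_mb - x$sigma_unc_mb,
                     x$energy_mev, x$sigma_mb + x$sigma_unc_mb,
                     angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Shipped measured Ti-48(p,x) cross-section table
#'
#' The measured excitation data for the six products (Sc-47, cumulative
#' Sc-46, Sc-44g, Sc-44m, Sc-43, V-48) over 18-70 MeV, referred to a 100
#' percent enriched Ti-48 target. Blank cells mark energies with no measured
#' value (below the effective onset or not observed).
#'
#' @return Data frame in the package cross-section schema (see
#'   [read_xs_table()]).
#' @export
measured_cross_sections <- function() {
  if (is.null(.pkg_cache$xs))
    .pkg_cache$xs <- read_xs_table(system.file("extdata", "ti48_cross_sections.csv",
                                               package = "sc47yield"))
  .pkg_cache$xs
}

.xs_column <- c("Sc-47" = "sc47", "Sc-46" = "sc46c", "Sc-44g" = "sc44g",
                "Sc-44m" = "sc44m", "Sc-43" = "sc43", "V-48" = "v48")

#' Excitation fits for all products from a cross-section table
#'
#' @param xs Cross-section table in the package schema; defaults to the
#'   shipped measured data.
#' @param products Product nuclides to fit.
#' @param thresholds Named threshold vector; defaults to
#'   [reaction_thresholds()].
#' @return Named list of [fit_excitation()] objects.
#' @export
excitation_fits <- function(xs = measured_cross_sections(),
                            products = names(.xs_column),
                            thresholds = reaction_thresholds()) {
  out <- list()
  for (p in products) {
    col <- .xs_column[[p]]
    keep <- !is.na(xs[[paste0(col, "_mb")]])
    if (sum(keep) < 2) next
    out[[p]] <- fit_excitation(xs$energy_mev[keep],
                               xs[[paste0(col, "_mb")]][keep],
                               threshold_mev = thresholds[[p]],
                               product = p,
                               sigma_unc_mb = xs[[paste0(col, "_unc_mb")]][keep])
  }
  out
}

#' Saturation factor
#'
#' Fraction of the asymptotic activity reached after irradiating for
#' `t_irr_h`: `1 - exp(-lambda * t_irr)`.
#'
#' @param lambda_h Decay constant (1/h, positive).
#' @param t_irr_h Irradiation time (h, non-negative).
#' @return Fraction in `[0, 1)`.
#' @export
saturation_factor <- function(lambda_h, t_irr_h) {
  if (any(lambda_h <= 0)) stop("lambda must be positive")
  if (any(t_irr_h < 0)) stop("irradiation time must be non-negative")
  1 - exp(-lambda_h * t_irr_h)
}

#' Irradiation scenario
#'
#' @param e_entry_mev Proton energy entering the target (MeV).
#' @param t_irr_h Irradiation duration (h, positive).
#' @param e_exit_mev Energy at which the beam leaves the target; the default
#'   0 means the target is thick enough to degrade below every reaction
#'   threshold (the integral truncates at each product's threshold).
#' @param current_ua Beam current (uA).
#' @param name Optional label (e.g. `"E<30"`).
#' @return Object of class `scenario`.
#' @export
scenario <- function(e_entry_mev, t_irr_h, e_exit_mev = 0, current_ua = 1,
                     name = NULL) {
  if (e_entry_mev <= e_exit_mev) stop("entry energy must exceed exit energy")
  if (e_exit_mev < 0) stop("exit energy must be non-negative")
  if (t_irr_h <= 0) stop("irradiation time must be positive")
  structure(list(e_entry_mev = e_entry_mev, e_exit_mev = e_exit_mev,
                 t_irr_h = t_irr_h, current_ua = current_ua,
                 name = name %||% sprintf("E<%g/%gh", e_entry_mev, t_irr_h)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %.1f -> %.1f MeV, %g h, %g uA\n",
              x$name, x$e_entry_mev, x$e_exit_mev, x$t_irr_h, x$current_ua))
  invisible(x)
}

#' Thick-target end-of-bombardment activity
#'
#' Standard activation integral for a target degrading the beam from the
#' scenario entry energy down to its exit energy (truncated at the reaction
#' threshold):
#' \deqn{A = \frac{I}{e}\,\frac{N_A}{M}\,(1-e^{-\lambda t_{irr}})
#'   \int_{E_{exit}}^{E_{entry}} \frac{\sigma(E)}{S_m(E)}\,dE}
#' with \eqn{\sigma} in cm^2 and \eqn{S_m} the mass stopping power of the
#' target material (trapezoidal quadrature on a fixed energy step).
#'
#' @param xs An [fit_excitation] object.
#' @param sc A [scenario].
#' @param lambda_h Product decay constant (1/h).
#' @param target_material Target [material]; defaults to isotopically pure
#'   Ti-48.
#' @param molar_mass_g Target molar mass (g/mol).
#' @param step_mev Trapezoid energy step (MeV).
#' @return EOB activity in MBq (for the scenario current).
#' @export
thick_target_eob_activity <- function(xs, sc, lambda_h,
                                      target_material = builtin_material("Ti48"),
                                      molar_mass_g = .u_target_ti48,
                                      step_mev = 0.02) {
  stopifnot(inherits(xs, "excitation_fit"), inherits(sc, "scenario"))
  lo <- max(sc$e_exit_mev, xs$threshold_mev)
  hi <- sc$e_entry_mev
  if (hi <= lo) return(0)
  if (hi > xs$e_max)
    warning("scenario entry energy ", hi,
            " MeV is above the measured range; constant extrapolation used")
  n <- max(2L, ceiling((hi - lo) / step_mev) + 1L)
  e <- seq(lo, hi, length.out = n)
  integrand <- predict(xs, e, warn_extrapolation = FALSE) * .const$mb_to_cm2 /
    (mass_stopping_power(e, target_material) * 1000)  # sigma/S, S in MeV cm^2/g
  h <- e[2] - e[1]
  integral <- h * (sum(integrand) - (integrand[1] + integrand[n]) / 2)
  rate <- protons_per_second(sc$current_ua) *
    (.const$n_avogadro / molar_mass_g) * integral      # atoms/s
  rate * saturation_factor(lambda_h, sc$t_irr_h) / 1e6 # MBq
}

#' Yield table over products and scenarios
#'
#' Computes the thick-target EOB activity of every product for every
#' scenario. A cell is reported as `NA` (blank) when the excitation data
#' offer no measured point below the scenario entry energy: without
#' measured support the product is treated as not produced in that energy
#' window, matching how scenario tables leave such entries blank.
#'
#' @param fits Named list of [fit_excitation] objects (names = nuclides).
#' @param scenarios List of [scenario] objects.
#' @param registry Decay data.
#' @param ... Passed to [thick_target_eob_activity()].
#' @return Data frame: one row per scenario x product with `scenario`,
#'   `e_entry_mev`, `t_irr_h`, `nuclide`, `activity_mbq`, `activity_mci`
#'   (`= MBq / 37`).
#' @export
yield_table <- function(fits, scenarios, registry = default_nuclides(), ...) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (sc in scenarios) {
    for (nuc in names(fits)) {
      xs <- fits[[nuc]]
      supported <- min(xs$energy_mev) < sc$e_entry_mev
      a <- if (supported)
        thick_target_eob_activity(xs, sc, lambda_per_hour(registry, nuc), ...)
      else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc$name, e_entry_mev = sc$e_entry_mev, t_irr_h = sc$t_irr_h,
        current_ua = sc$current_ua, nuclide = nuc,
        activity_mbq = a, activity_mci = a / 37,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
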