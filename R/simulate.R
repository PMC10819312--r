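# Forward simulator: a complete synthetic stacked-foil campaign with known
# ground truth (true excitation functions, true flux, Poisson counting),
# emitting the same measurement schema the inverse pipeline consumes. Used
# to validate the count -> activity -> flux -> cross-section chain.

# Default per-line counting plan: HPGe at fixed 19 cm geometry; efficiencies
# fall with line energy; short-lived products are counted early, the rest
# overnight. Dead time ~2 percent.
.default_schedule <- function() {
  data.frame(
    nuclide  = c("Sc-47", "Sc-46", "Sc-44g", "Sc-44m", "Sc-43", "Ni-57"),
    line_kev = c(159.381, 889.277, 1157.022, 271.251, 372.9, 1377.63),
    eff      = c(0.0040, 0.0015, 0.0012, 0.0035, 0.0030, 0.0010),
    eff_unc_rel = 0.02,
    t_cool_h = c(24, 24, 3, 24, 3, 24),
    t_real_h = c(3, 8, 1, 3, 1, 3),
    stringsAsFactors = FALSE)
}

# Default synthetic stack: Kapton window, 12 cm air gap, then four target
# units [Ti-48 deposit / Al backing / Ni monitor / Al catcher / Al
# degraders] spanning roughly 36 -> 24 MeV, the region of the Sc-47 peak.
.default_synthetic_stack <- function() {
  unit <- function(k, degraders_um) {
    c(list(
      foil_spec("Ti48", areal_density_ug_cm2 = 500, role = "target",
                id = sprintf("Ti48-S%02d", k), areal_unc_ug_cm2 = 25),
      foil_spec("Al", thickness_um = 25, role = "degrader",
                id = sprintf("backing-%02d", k)),
      foil_spec("Ni", thickness_um = 25, role = "monitor",
                id = sprintf("Ni-S%02d", k)),
      foil_spec("Al", thickness_um = 10, role = "catcher",
                id = sprintf("cat-S%02d", k))),
      lapply(seq_along(degraders_um), function(j)
        foil_spec("Al", thickness_um = degraders_um[j], role = "degrader",
                  id = sprintf("deg-%02d-%d", k, j))))
  }
  c(list(foil_spec("kapton", thickness_um = 75, role = "window", id = "window"),
         foil_spec("air", thickness_cm = 12, role = "air_gap", id = "air")),
    unit(1, c(500, 500)), unit(2, c(500, 500)), unit(3, c(500, 250)),
    unit(4, integer(0)))
}

.stack_foil_table <- function(layers) {
  keep <- vapply(layers, function(f) f$role %in% c("target", "monitor", "catcher"),
                 logical(1))
  grp <- 0L
  rows <- lapply(layers[keep], function(f) {
    if (f$role == "target") grp <<- grp + 1L
    data.frame(foil_id = f$id, role = f$role, group = grp,
               areal_density_ug_cm2 = f$areal_density_ug_cm2,
               areal_unc_ug_cm2 = f$areal_unc_ug_cm2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ground-truth model for a synthetic campaign
#'
#' Bundles everything that defines a campaign: true excitation functions
#' (default: the shape-preserving fits through the shipped measured data, so
#' synthetic campaigns resemble the real one), the true proton flux, the
#' stack design, irradiation time, counting schedule and the Ni-57 recoil
#' fraction. Poisson counting noise is the only stochastic element;
#' areal-density and efficiency uncertainties enter the budget as fixed
#' systematic terms, mirroring the quadrature treatment of the analysis.
#'
#' @param fits Named list of true excitation functions
#'   ([fit_excitation] objects); default [excitation_fits()] for the five Sc
#'   products.
#' @param flux_pps True proton flux (default 100 nA).
#' @param layers Stack layer list; default: four Ti-48/Ni/Al units spanning
#'   about 36 to 24 MeV.
#' @param e0_mev,e0_unc_kev Cyclotron extraction energy and uncertainty.
#' @param t_irr_h Irradiation duration (h).
#' @param schedule Counting plan (see source for schema).
#' @param enrichment Ti-48 enrichment of the deposits.
#' @param recoil_fraction Fraction of Ni-57 activity recoiling into the
#'   catcher foil.
#' @param registry Decay data.
#' @return Object of class `true_model` (with per-foil mid energies and
#'   true cross-sections precomputed).
#' @export
true_model <- function(fits = excitation_fits(products = c("Sc-47", "Sc-46",
                                                           "Sc-44g", "Sc-44m",
                                                           "Sc-43")),
                       flux_pps = protons_per_second(0.1),
                       layers = .default_synthetic_stack(),
                       e0_mev = 36, e0_unc_kev = 500, t_irr_h = 1.5,
                       schedule = .default_schedule(),
                       enrichment = 0.9932, recoil_fraction = 0.01,
                       registry = default_nuclides()) {
  energies <- propagate_stack(beam_state(e0_mev, e0_unc_kev), layers)
  foils <- .stack_foil_table(layers)
  truth <- list()
  for (fid in foils$foil_id[foils$role == "target"]) {
    e <- energies$e_mid_mev[match(fid, energies$id)]
    sig <- vapply(fits, function(xs) predict(xs, e, warn_extrapolation = FALSE),
                  numeric(1))
    truth[[fid]] <- sig[sig > 1e-3]  # products with effective support at this depth
  }
  structure(list(fits = fits, flux_pps = flux_pps, layers = layers,
                 foils = foils, energies = energies, t_irr_h = t_irr_h,
                 schedule = schedule, enrichment = enrichment,
                 recoil_fraction = recoil_fraction, registry = registry,
                 true_sigma = truth),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  tg <- x$energies[x$energies$role == "target", ]
  cat("<true_model>", nrow(tg), "target foils,",
      sprintf("%.1f", max(tg$e_mid_mev)), "-",
      sprintf("%.1f", min(tg$e_mid_mev)), "MeV, flux",
      format(x$flux_pps, digits = 3), "p/s, t_irr", x$t_irr_h, "h\n")
  invisible(x)
}

#' True EOB activity of one foil
#'
#' Deterministic forward physics `A = phi * f * N_t * sigma(E_mid) * (1 -
#' exp(-lambda t_irr))` for every product with support at the foil's depth.
#'
#' @param model A [true_model].
#' @param foil_id Target foil identifier.
#' @return Named vector of EOB activities (Bq) per product.
#' @export
simulate_foil_activity <- function(model, foil_id) {
  i <- match(foil_id, model$foils$foil_id)
  if (is.na(i) || model$foils$role[i] != "target")
    stop("unknown target foil: ", foil_id)
  sig <- model$true_sigma[[foil_id]]
  n_t <- areal_atoms_cm2(model$foils$areal_density_ug_cm2[i], .u_target_ti48) *
    model$enrichment
  vapply(names(sig), function(nuc) {
    lam <- lambda_per_hour(model$registry, nuc)
    model$flux_pps * n_t * sig[[nuc]] * .const$mb_to_cm2 *
      saturation_factor(lam, model$t_irr_h)
  }, numeric(1))
}

#' Expected and realised peak counts for an activity
#'
#' Forward counting model: expected counts
#' `A * 3600 / lambda * eff * I * exp(-lambda t_c) * (1 - exp(-lambda t_real))
#'  * (t_live / t_real)`; realised counts are Poisson-distributed around the
#' expectation (or exactly equal to it with `noise = FALSE`).
#'
#' @param activity_bq EOB activity (Bq).
#' @param lambda_h Decay constant (1/h).
#' @param t_cool_h,t_real_h,t_live_h Counting times (h).
#' @param efficiency,intensity Detection efficiency and line intensity.
#' @param noise Draw Poisson counts (uses the current RNG stream).
#' @return List with `counts` and `expected`.
#' @export
simulate_counts <- function(activity_bq, lambda_h, t_cool_h, t_real_h,
                            t_live_h, efficiency, intensity, noise = TRUE) {
  expected <- activity_bq * 3600 / lambda_h * efficiency * intensity *
    exp(-lambda_h * t_cool_h) * (1 - exp(-lambda_h * t_real_h)) *
    (t_live_h / t_real_h)
  counts <- if (noise) stats::rpois(1, expected) else expected
  list(counts = counts, expected = expected)
}

# Build the full measurement table for one campaign realisation.
.campaign_measurements <- function(model, noise) {
  sched <- model$schedule
  rows <- list()
  add_meas <- function(fid, nuc, activity_bq) {
    s <- sched[sched$nuclide == nuc, ]
    cnt <- simulate_counts(activity_bq, lambda_per_hour(model$registry, nuc),
                           s$t_cool_h, s$t_real_h, 0.98 * s$t_real_h,
                           s$eff, match_gamma_line(model$registry, nuc,
                                                   s$line_kev)$gamma_intensity,
                           noise = noise)
    rows[[length(rows) + 1]] <<- data.frame(
      foil_id = fid, nuclide = nuc, line_kev = s$line_kev,
      counts = cnt$counts, counts_unc = sqrt(cnt$counts),
      t_cool_h = s$t_cool_h, t_real_h = s$t_real_h,
      t_live_h = 0.98 * s$t_real_h,
      eff = s$eff, eff_unc = s$eff * s$eff_unc_rel,
      stringsAsFactors = FALSE)
  }
  lam57 <- lambda_per_hour(model$registry, "Ni-57")
  for (g in unique(model$foils$group[model$foils$role == "target"])) {
    grp <- model$foils[model$foils$group == g, ]
    tgt <- grp$foil_id[grp$role == "target"]
    mon <- grp[grp$role == "monitor", ]
    cat_id <- grp$foil_id[grp$role == "catcher"]
    # monitor: Ni-57 with ~1% recoil transferred to the catcher
    e_mon <- model$energies$e_mid_mev[match(mon$foil_id, model$energies$id)]
    a57 <- model$flux_pps *
      areal_atoms_cm2(mon$areal_density_ug_cm2, 58.6934) *
      monitor_sigma(e_mon)$sigma_mb * .const$mb_to_cm2 *
      saturation_factor(lam57, model$t_irr_h)
    add_meas(mon$foil_id, "Ni-57", a57 * (1 - model$recoil_fraction))
    if (length(cat_id)) add_meas(cat_id[1], "Ni-57", a57 * model$recoil_fraction)
    acts <- simulate_foil_activity(model, tgt)
    for (nuc in names(acts)) add_meas(tgt, nuc, acts[[nuc]])
  }
  do.call(rbind, rows)
}

#' Generate a synthetic stacked-foil campaign
#'
#' @param model A [true_model].
#' @param seed RNG seed; fixes the whole realisation.
#' @param noise Poisson counting noise on/off.
#' @return List with `measurements` (inverse-pipeline schema), `foils`,
#'   `energies`, `t_irr_h` and `truth` (per-foil true cross-sections and the
#'   true flux).
#' @export
synthetic_campaign <- function(model = true_model(), seed = 1, noise = TRUE) {
  set.seed(seed)
  list(measurements = .campaign_measurements(model, noise),
       foils = model$foils,
       energies = data.frame(foil_id = model$energies$id,
                             e_mid_mev = model$energies$e_mid_mev,
                             unc_mid_kev = model$energies$unc_mid_kev,
                             stringsAsFactors = FALSE),
       t_irr_h = model$t_irr_h,
       truth = list(sigma_mb = model$true_sigma, flux_pps = model$flux_pps))
}

#' Parameter-recovery experiment
#'
#' Repeats the full forward-then-inverse chain: simulate Poisson counts,
#' extract cross-sections and flux, and compare with the ground truth in
#' units of the reported combined standard uncertainty. Reports pooled 1
#' and 3 sigma coverage, the mean relative bias of the cross-sections, and
#' the flux recovery bias in standard errors.
#'
#' @param model A [true_model].
#' @param replicates Number of campaign realisations (>= 100 advised).
#' @param seed RNG seed.
#' @return Object of class `recovery_report`: list with `n_cells`,
#'   `coverage_1s`, `coverage_3s`, `mean_rel_bias`, `flux_bias_se`,
#'   `replicates`.
#' @export
run_recovery_experiment <- function(model = true_model(), replicates = 500,
                                    seed = 1) {
  set.seed(seed)
  energies <- data.frame(foil_id = model$energies$id,
                         e_mid_mev = model$energies$e_mid_mev,
                         unc_mid_kev = model$energies$unc_mid_kev,
                         stringsAsFactors = FALSE)
  z <- c(); relerr <- c(); flux_rel <- c()
  for (r in seq_len(replicates)) {
    meas <- .campaign_measurements(model, noise = TRUE)
    xs <- extract_cross_sections(meas, model$foils, energies, model$t_irr_h,
                                 registry = model$registry,
                                 enrichment = model$enrichment)
    truth <- mapply(function(fid, nuc) model$true_sigma[[fid]][[nuc]],
                    xs$foil_id, xs$nuclide)
    z <- c(z, (xs$sigma_mb - truth) / xs$unc_mb)
    relerr <- c(relerr, xs$sigma_mb / truth - 1)
    flux_rel <- c(flux_rel, unique(xs$flux_pps) / model$flux_pps - 1)
  }
  structure(list(n_cells = length(z),
                 coverage_1s = mean(abs(z) <= 1),
                 coverage_3s = mean(abs(z) <= 3),
                 mean_rel_bias = mean(relerr),
                 flux_bias_se = mean(flux_rel) /
                   (stats::sd(flux_rel) / sqrt(length(flux_rel))),
                 replicates = replicates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$replicates, "replicates,", x$n_cells,
      "cross-section cells\n")
  cat(sprintf("  coverage: %.1f%% within 1 sigma, %.2f%% within 3 sigma\n",
              100 * x$coverage_1s, 100 * x$coverage_3s))
  cat(sprintf("  mean relative bias: %+.3f%%; flux bias: %+.2f standard errors\n",
              100 * x$mean_rel_bias, x$flux_bias_se))
  invisible(x)
}
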