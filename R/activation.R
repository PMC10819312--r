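# Inverse pipeline: gamma-peak counts -> end-of-bombardment activities ->
# beam flux (natNi(p,x)57Ni monitor) -> production cross-sections with the
# standard quadrature uncertainty budget.

#' End-of-bombardment activity from a counted gamma peak
#'
#' Converts a net peak area to the activity at the end of bombardment,
#' correcting for decay during cooling, decay during the acquisition (real
#' time in the saturation-like factor) and dead time (live/real ratio as a
#' multiplicative correction, valid for the <10 percent dead times enforced
#' here):
#' \deqn{A_{EOB} = \frac{C\,\lambda\,(t_{real}/t_{live})}
#'   {3600\,\varepsilon\,I_\gamma\,e^{-\lambda t_c}(1-e^{-\lambda t_{real}})}}
#' with \eqn{\lambda} in 1/h and times in hours (the 3600 converts decays per
#' hour to Bq).
#'
#' @param counts Net peak counts (non-negative).
#' @param lambda_h Decay constant (1/h, positive).
#' @param t_cool_h Cooling time from EOB to acquisition start (h).
#' @param t_real_h Acquisition real time (h).
#' @param t_live_h Acquisition live time (h); must satisfy
#'   `t_live_h <= t_real_h` and dead time `< 10` percent.
#' @param efficiency Full-energy peak detection efficiency at the counting
#'   geometry (fraction, positive).
#' @param intensity Gamma emission intensity of the line (fraction, positive).
#' @param counts_unc,efficiency_unc,intensity_unc 1-sigma absolute
#'   uncertainties; counting defaults to `sqrt(counts)`.
#' @return List with `activity_bq` and `unc_bq` (quadrature of the counting,
#'   efficiency and intensity relative uncertainties).
#' @export
eob_activity <- function(counts, lambda_h, t_cool_h, t_real_h, t_live_h,
                         efficiency, intensity,
                         counts_unc = sqrt(counts), efficiency_unc = 0,
                         intensity_unc = 0) {
  if (lambda_h <= 0) stop("decay constant must be positive")
  if (counts < 0) stop("counts must be non-negative")
  if (t_live_h > t_real_h) stop("live time cannot exceed real time")
  if ((t_real_h - t_live_h) / t_real_h >= 0.10)
    stop("dead time of ", signif(100 * (t_real_h - t_live_h) / t_real_h, 3),
         "% exceeds the 10% validity bound")
  if (efficiency <= 0 || intensity <= 0)
    stop("efficiency and gamma intensity must be positive")
  denom <- 3600 * efficiency * intensity * exp(-lambda_h * t_cool_h) *
    (1 - exp(-lambda_h * t_real_h))
  a <- counts * lambda_h * (t_real_h / t_live_h) / denom
  rel <- sqrt((if (counts > 0) (counts_unc / counts)^2 else 0) +
                (efficiency_unc / efficiency)^2 +
                (intensity_unc / intensity)^2)
  list(activity_bq = a, unc_bq = a * rel)
}

#' Shipped natNi(p,x)57Ni monitor cross-section table
#'
#' IAEA-recommended monitor reaction values on the 22.4-67.9 MeV grid used
#' for flux normalisation.
#'
#' @return Data frame with `energy_mev`, `sigma_mb`, `unc_mb`.
#' @export
monitor_cross_sections <- function() {
  if (is.null(.pkg_cache$monitor)) {
    p <- system.file("extdata", "monitor_ni57.csv", package = "sc47yield")
    .pkg_cache$monitor <- utils::read.csv(p)
  }
  .pkg_cache$monitor
}

#' Interpolated monitor cross-section
#'
#' Shape-preserving piecewise-cubic (Fritsch-Carlson) interpolation of the
#' recommended natNi(p,x)57Ni cross-section; the relative uncertainty is
#' interpolated linearly alongside.
#'
#' @param energy_mev Proton energy (MeV); must lie within the recommended
#'   grid (22.4 to 67.9 MeV).
#' @param table Monitor table; defaults to [monitor_cross_sections()].
#' @return List with `sigma_mb` and `unc_mb`.
#' @export
monitor_sigma <- function(energy_mev, table = monitor_cross_sections()) {
  rng <- range(table$energy_mev)
  if (any(energy_mev < rng[1]) || any(energy_mev > rng[2]))
    stop("monitor energy outside the recommended range [", rng[1], ", ",
         rng[2], "] MeV")
  f <- stats::splinefun(table$energy_mev, table$sigma_mb, method = "monoH.FC")
  rel <- stats::approx(table$energy_mev, table$unc_mb / table$sigma_mb,
                       xout = energy_mev)$y
  s <- f(energy_mev)
  list(sigma_mb = s, unc_mb = s * rel)
}

#' Combine monitor and recoil-catcher activities
#'
#' Recoil Ni-57 atoms leaving the monitor foil are collected in a thin
#' catcher foil; the true monitor activity is the sum of the two. Also
#' reports the recoil fraction (about 1 percent in practice).
#'
#' @param a_monitor_bq,a_catcher_bq Activities (Bq, non-negative).
#' @return List with `activity_bq` and `recoil_fraction`.
#' @export
add_recoil <- function(a_monitor_bq, a_catcher_bq) {
  if (a_monitor_bq < 0 || a_catcher_bq < 0) stop("activities must be non-negative")
  tot <- a_monitor_bq + a_catcher_bq
  list(activity_bq = tot,
       recoil_fraction = if (tot > 0) a_catcher_bq / tot else 0)
}

#' Average proton flux from the monitor foil
#'
#' \deqn{\phi = A_{EOB} / (N_t\,\sigma\,(1 - e^{-\lambda t_{irr}}))}
#' with the monitor cross-section converted to cm^2.
#'
#' @param a57_eob_bq Ni-57 EOB activity (Bq).
#' @param a57_unc_bq Its 1-sigma uncertainty.
#' @param n_t_atoms_cm2 Nickel areal atom density (atoms/cm^2).
#' @param sigma_mb,sigma_unc_mb Monitor cross-section and uncertainty (mb).
#' @param lambda_h Ni-57 decay constant (1/h).
#' @param t_irr_h Irradiation duration (h, positive).
#' @return List with `flux_pps` (protons/s) and `rel_unc` (quadrature of the
#'   activity and monitor cross-section relative uncertainties).
#' @export
average_flux <- function(a57_eob_bq, n_t_atoms_cm2, sigma_mb, lambda_h, t_irr_h,
                         a57_unc_bq = 0, sigma_unc_mb = 0) {
  if (t_irr_h <= 0) stop("irradiation time must be positive")
  if (any(c(a57_eob_bq, n_t_atoms_cm2, sigma_mb, lambda_h) <= 0))
    stop("activity, atom density, cross-section and lambda must be positive")
  sat <- 1 - exp(-lambda_h * t_irr_h)
  phi <- a57_eob_bq / (n_t_atoms_cm2 * sigma_mb * .const$mb_to_cm2 * sat)
  rel <- sqrt((a57_unc_bq / a57_eob_bq)^2 + (sigma_unc_mb / sigma_mb)^2)
  list(flux_pps = phi, rel_unc = rel)
}

#' Beam current to proton flux
#'
#' @param current_ua Beam current in microampere.
#' @return Protons per second (`current / e`).
#' @export
protons_per_second <- function(current_ua) current_ua * 1e-6 / .const$e_coulomb

#' Areal atom density of a foil
#'
#' @param areal_density_ug_cm2 Mass areal density (ug/cm^2).
#' @param molar_mass_g Molar mass (g/mol).
#' @return Atoms per cm^2.
#' @export
areal_atoms_cm2 <- function(areal_density_ug_cm2, molar_mass_g) {
  areal_density_ug_cm2 * 1e-6 / molar_mass_g * .const$n_avogadro
}

#' Production cross-section from an EOB activity
#'
#' \deqn{\sigma = A_{EOB} / (\phi\,f\,N_t\,(1 - e^{-\lambda t_{irr}})) }
#' where \eqn{N_t} is the total titanium areal atom density and `f` the
#' Ti-48 enrichment, so the result refers to a 100 percent enriched target.
#' The uncertainty combines, in quadrature, the activity, flux and areal
#' density relative uncertainties.
#'
#' @param a_eob_bq Product EOB activity (Bq) and `a_unc_bq` its uncertainty.
#' @param flux_pps Proton flux (protons/s), `flux_rel_unc` its relative
#'   uncertainty (from the monitor analysis).
#' @param areal_density_ug_cm2 Titanium areal density of the target deposit,
#'   `areal_unc_ug_cm2` its uncertainty.
#' @param lambda_h Product decay constant (1/h).
#' @param t_irr_h Irradiation duration (h).
#' @param enrichment Ti-48 atom fraction of the target material (0.9932 for
#'   the enriched powder considered here).
#' @param molar_mass_g Molar mass of the target material (g/mol).
#' @param a_unc_bq,flux_rel_unc,areal_unc_ug_cm2 Uncertainty inputs.
#' @return List with `sigma_mb` and `unc_mb`.
#' @export
production_cross_section <- function(a_eob_bq, flux_pps, areal_density_ug_cm2,
                                     lambda_h, t_irr_h,
                                     a_unc_bq = 0, flux_rel_unc = 0,
                                     areal_unc_ug_cm2 = 0,
                                     enrichment = 0.9932,
                                     molar_mass_g = .u_target_ti48) {
  if (t_irr_h <= 0) stop("irradiation time must be positive")
  if (enrichment <= 0 || enrichment > 1) stop("enrichment must be in (0, 1]")
  if (areal_density_ug_cm2 <= 0) stop("areal density must be positive")
  n_t <- areal_atoms_cm2(areal_density_ug_cm2, molar_mass_g)
  sat <- 1 - exp(-lambda_h * t_irr_h)
  sigma_cm2 <- a_eob_bq / (flux_pps * enrichment * n_t * sat)
  rel <- sqrt((if (a_eob_bq > 0) (a_unc_bq / a_eob_bq)^2 else 0) +
                flux_rel_unc^2 +
                (areal_unc_ug_cm2 / areal_density_ug_cm2)^2)
  s <- sigma_cm2 / .const$mb_to_cm2
  list(sigma_mb = s, unc_mb = s * rel)
}

#' Quadrature uncertainty budget
#'
#' @param components Named numeric vector of relative uncertainty
#'   contributions (all non-negative).
#' @return List with `total` (quadrature sum) and `contributions` (sorted,
#'   decreasing).
#' @export
uncertainty_budget <- function(components) {
  if (any(components < 0)) stop("uncertainty components must be non-negative")
  list(total = sqrt(sum(components^2)),
       contributions = sort(components, decreasing = TRUE))
}

#' Inverse-variance weighted mean of repeated activity determinations
#'
#' Repeated counts of the same foil/product (after individual EOB decay
#' correction) are combined by an inverse-variance weighted mean; zero-
#' uncertainty inputs fall back to the plain mean.
#'
#' @param values Activity values.
#' @param uncs Their 1-sigma uncertainties.
#' @return List with `value` and `unc`.
#' @export
combine_activities <- function(values, uncs) {
  stopifnot(length(values) == length(uncs))
  if (length(values) == 1) return(list(value = values, unc = uncs))
  if (any(uncs <= 0)) return(list(value = mean(values), unc = 0))
  w <- 1 / uncs^2
  list(value = sum(w * values) / sum(w), unc = sqrt(1 / sum(w)))
}

#' Extract cross-sections from a measured campaign
#'
#' Runs the full inverse pipeline for one irradiation run: for every target
#' position (group), the Ni-57 monitor (+ recoil catcher) measurements give
#' the effective proton flux, and each product measured on the Ti-48 foil
#' yields one cross-section point at the foil's mid energy.
#'
#' @param measurements Data frame with columns `foil_id`, `nuclide`,
#'   `line_kev`, `counts`, `counts_unc`, `t_cool_h`, `t_real_h`, `t_live_h`,
#'   `eff`, `eff_unc`.
#' @param foils Data frame with columns `foil_id`, `role` (`target`,
#'   `monitor`, `catcher`), `group` (integer pairing a target with its
#'   monitor/catcher), `areal_density_ug_cm2`, `areal_unc_ug_cm2`.
#' @param energies Data frame with `foil_id`, `e_mid_mev`, `unc_mid_kev`
#'   (typically the `target`/`monitor` rows of [propagate_stack()] output).
#' @param t_irr_h Irradiation duration (h).
#' @param registry Decay data ([default_nuclides()]).
#' @param enrichment Ti-48 enrichment of the targets.
#' @return Data frame of cross-section points: `foil_id`, `nuclide`,
#'   `energy_mev`, `energy_unc_mev`, `sigma_mb`, `unc_mb`, `flux_pps`.
#' @export
extract_cross_sections <- function(measurements, foils, energies, t_irr_h,
                                   registry = default_nuclides(),
                                   enrichment = 0.9932) {
  req <- c("foil_id", "nuclide", "line_kev", "counts", "counts_unc",
           "t_cool_h", "t_real_h", "t_live_h", "eff", "eff_unc")
  if (length(miss <- setdiff(req, names(measurements))))
    stop("measurements table missing column(s): ", paste(miss, collapse = ", "))

  eob_for <- function(rows, nuclide) {
    lam <- lambda_per_hour(registry, nuclide)
    acts <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      ln <- match_gamma_line(registry, nuclide, r$line_kev)
      eob_activity(r$counts, lam, r$t_cool_h, r$t_real_h, r$t_live_h,
                   r$eff, ln$gamma_intensity,
                   counts_unc = r$counts_unc, efficiency_unc = r$eff_unc,
                   intensity_unc = if (is.na(ln$intensity_unc)) 0 else ln$intensity_unc)
    })
    combine_activities(vapply(acts, `[[`, 0, "activity_bq"),
                       vapply(acts, `[[`, 0, "unc_bq"))
  }
  foil_energy <- function(fid) {
    i <- match(fid, energies$foil_id)
    if (is.na(i)) stop("no propagated energy for foil ", fid)
    energies[i, ]
  }

  out <- list()
  lam57 <- lambda_per_hour(registry, "Ni-57")
  for (g in sort(unique(foils$group[foils$role == "target"]))) {
    grp <- foils[foils$group == g, ]
    tgt <- grp[grp$role == "target", ]
    mon <- grp[grp$role == "monitor", ]
    if (nrow(tgt) != 1 || nrow(mon) != 1)
      stop("group ", g, " must contain exactly one target and one monitor foil")
    cat_f <- grp[grp$role == "catcher", ]

    m_mon <- measurements[measurements$foil_id == mon$foil_id &
                            measurements$nuclide == "Ni-57", ]
    if (!nrow(m_mon)) stop("no Ni-57 monitor measurement for group ", g)
    a_mon <- eob_for(m_mon, "Ni-57")
    a_cat <- list(value = 0, unc = 0)
    if (nrow(cat_f)) {
      m_cat <- measurements[measurements$foil_id %in% cat_f$foil_id &
                              measurements$nuclide == "Ni-57", ]
      if (nrow(m_cat)) a_cat <- eob_for(m_cat, "Ni-57")
    }
    a57 <- add_recoil(a_mon$value, a_cat$value)
    a57_unc <- sqrt(a_mon$unc^2 + a_cat$unc^2)

    emon <- foil_energy(mon$foil_id)
    smon <- monitor_sigma(emon$e_mid_mev)
    n_ni <- areal_atoms_cm2(mon$areal_density_ug_cm2, 58.6934)
    flux <- average_flux(a57$activity_bq, n_ni, smon$sigma_mb, lam57, t_irr_h,
                         a57_unc_bq = a57_unc, sigma_unc_mb = smon$unc_mb)

    etgt <- foil_energy(tgt$foil_id)
    m_tgt <- measurements[measurements$foil_id == tgt$foil_id, ]
    for (nuc in unique(m_tgt$nuclide)) {
      a_prod <- eob_for(m_tgt[m_tgt$nuclide == nuc, ], nuc)
      xs <- production_cross_section(
        a_prod$value, flux$flux_pps, tgt$areal_density_ug_cm2,
        lambda_per_hour(registry, nuc), t_irr_h,
        a_unc_bq = a_prod$unc, flux_rel_unc = flux$rel_unc,
        areal_unc_ug_cm2 = tgt$areal_unc_ug_cm2, enrichment = enrichment)
      out[[length(out) + 1]] <- data.frame(
        foil_id = tgt$foil_id, nuclide = nuc,
        energy_mev = etgt$e_mid_mev, energy_unc_mev = etgt$unc_mid_kev / 1000,
        sigma_mb = xs$sigma_mb, unc_mb = xs$unc_mb,
        flux_pps = flux$flux_pps, flux_rel_unc = flux$rel_unc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no target-foil measurements found")
  do.call(rbind, out)
}
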