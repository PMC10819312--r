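# Proton energy loss and straggling through the stacked target.
#
# The analysis only needs stopping powers for protons between a few MeV and
# 70 MeV in light/medium-Z foils, where the plain Bethe formula (no shell or
# Barkas corrections, Tmax ~ 2 me c^2 beta^2 gamma^2) is good to a few
# percent. Straggling uses the relativistic Bohr formula.

.beta2_gamma <- function(energy_mev) {
  gamma <- 1 + energy_mev / .const$mp_c2_mev
  list(beta2 = 1 - 1 / gamma^2, gamma = gamma)
}

# Elemental mass stopping power, MeV cm^2/g.
.element_stopping_g <- function(energy_mev, Z, A, I_ev) {
  bg <- .beta2_gamma(energy_mev)
  arg <- 2 * .const$me_c2_mev * bg$beta2 * bg$gamma^2 / (I_ev * 1e-6)
  .const$bethe_k * (Z / A) / bg$beta2 * (log(arg) - bg$beta2)
}

# Material mass stopping power in MeV cm^2/g (internal working unit).
.stopping_g <- function(energy_mev, mat) {
  idx <- match(names(mat$composition), .elements$symbol)
  s <- 0
  for (k in seq_along(idx)) {
    e <- .elements[idx[k], ]
    s <- s + mat$composition[[k]] * .element_stopping_g(energy_mev, e$Z, e$A, e$I_ev)
  }
  s
}

#' Proton mass stopping power
#'
#' Bethe-model mass stopping power of a material for protons, with Bragg-rule
#' additivity over the elemental constituents for compounds and mixtures.
#'
#' @param energy_mev Proton kinetic energy (MeV); vectorised. Valid for
#'   energies of at least 1 MeV (the model's validity floor here).
#' @param mat A [material] object or built-in material name.
#' @return Mass stopping power in MeV cm^2/mg.
#' @examples
#' mass_stopping_power(30, "Ti")
#' @export
mass_stopping_power <- function(energy_mev, mat) {
  mat <- .resolve_material(mat)
  if (any(!is.finite(energy_mev)) || any(energy_mev < .const$e_floor_mev))
    stop("energy below the ", .const$e_floor_mev,
         " MeV validity floor of the stopping-power model")
  vapply(energy_mev, function(e) .stopping_g(e, mat) / 1000, numeric(1))
}

#' Beam state: energy and its combined uncertainty
#'
#' @param energy_mev Proton kinetic energy in MeV (non-negative).
#' @param unc_kev Combined 1-sigma energy uncertainty in keV. At stack entry
#'   this is the cyclotron extraction uncertainty (500 keV); straggling is
#'   added in quadrature as the beam penetrates the stack.
#' @return An object of class `beam_state`.
#' @export
beam_state <- function(energy_mev, unc_kev = 500) {
  if (energy_mev < 0) stop("beam energy must be non-negative")
  if (unc_kev < 0) stop("energy uncertainty must be non-negative")
  structure(list(energy_mev = energy_mev, unc_kev = unc_kev),
            class = "beam_state")
}

#' @export
print.beam_state <- function(x, ...) {
  cat(sprintf("<beam_state> %.3f MeV +/- %.0f keV\n", x$energy_mev, x$unc_kev))
  invisible(x)
}

#' Foil specification
#'
#' One layer of the stacked target. Thickness may be given directly as an
#' areal density or as a linear thickness (converted using the material
#' density); air gaps are conveniently specified in cm.
#'
#' @param mat [material] or built-in material name.
#' @param areal_density_ug_cm2 Areal density in ug/cm^2 (preferred).
#' @param thickness_um Linear thickness in um (alternative).
#' @param thickness_cm Linear thickness in cm (alternative, for air gaps).
#' @param role One of `"target"`, `"monitor"`, `"catcher"`, `"degrader"`,
#'   `"window"`, `"air_gap"`.
#' @param id Optional foil identifier.
#' @param areal_unc_ug_cm2 1-sigma uncertainty on the areal density.
#' @return An object of class `foil_spec`.
#' @export
foil_spec <- function(mat, areal_density_ug_cm2 = NULL, thickness_um = NULL,
                      thickness_cm = NULL, role = "degrader", id = NULL,
                      areal_unc_ug_cm2 = 0) {
  mat <- .resolve_material(mat)
  role <- match.arg(role,
                    c("target", "monitor", "catcher", "degrader", "window", "air_gap"))
  if (is.null(areal_density_ug_cm2)) {
    if (!is.null(thickness_um)) {
      areal_density_ug_cm2 <- thickness_um * 1e-4 * mat$density_g_cm3 * 1e6
    } else if (!is.null(thickness_cm)) {
      areal_density_ug_cm2 <- thickness_cm * mat$density_g_cm3 * 1e6
    } else stop("give areal_density_ug_cm2 or thickness_um/thickness_cm")
  }
  if (areal_density_ug_cm2 < 0) stop("areal density must be non-negative")
  structure(list(material = mat,
                 areal_density_ug_cm2 = areal_density_ug_cm2,
                 areal_unc_ug_cm2 = areal_unc_ug_cm2,
                 role = role, id = id),
            class = "foil_spec")
}

#' @export
print.foil_spec <- function(x, ...) {
  cat(sprintf("<foil_spec> %s [%s] %.1f ug/cm^2%s\n", x$material$name, x$role,
              x$areal_density_ug_cm2,
              if (!is.null(x$id)) paste0("  id=", x$id) else ""))
  invisible(x)
}

# RK4 step of dE/dxi = -S(E), xi in mg/cm^2, S in MeV cm^2/mg.
.rk4_step <- function(e, h, mat) {
  f <- function(x) -.stopping_g(x, mat) / 1000
  k1 <- f(e)
  k2 <- f(e + h / 2 * k1)
  k3 <- f(e + h / 2 * k2)
  k4 <- f(e + h * k3)
  e + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Integrate energy loss across an areal density xi (mg/cm^2); returns energy.
.degrade_energy <- function(e0, xi_mg, mat, n_steps) {
  if (xi_mg <= 0) return(e0)
  h <- xi_mg / n_steps
  e <- e0
  for (i in seq_len(n_steps)) {
    e <- .rk4_step(e, h, mat)
    if (!is.finite(e) || e < .const$e_floor_mev)
      stop("ranged-out: beam energy fell below ", .const$e_floor_mev,
           " MeV inside the foil")
  }
  e
}

.n_steps_for <- function(xi_mg, n_min = 100, step_mg = 1) {
  max(n_min, ceiling(xi_mg / step_mg))
}

#' Degrade the beam through one foil
#'
#' Integrates the proton energy loss over the foil areal density (RK4 over a
#' fixed quadrature grid: a 1 mg/cm^2 step or 100 steps per foil, whichever
#' is finer) and propagates the energy uncertainty by adding the Bohr
#' straggling of the traversed matter in quadrature.
#'
#' @param beam Entry [beam_state].
#' @param foil [foil_spec].
#' @param n_min Minimum number of integration steps per foil.
#' @return List with `mid` and `exit` [beam_state]s: the beam at the foil
#'   midpoint (in areal density) and at the exit face.
#' @export
degrade <- function(beam, foil, n_min = 100) {
  xi <- foil$areal_density_ug_cm2 / 1000  # mg/cm^2
  if (xi <= 0) return(list(mid = beam, exit = beam))
  n <- .n_steps_for(xi, n_min)
  if (n %% 2 == 1) n <- n + 1
  e_mid <- tryCatch(.degrade_energy(beam$energy_mev, xi / 2, foil$material, n / 2),
                    error = function(e) stop("foil ", foil$id %||% foil$material$name,
                                             ": ", conditionMessage(e)))
  e_exit <- tryCatch(.degrade_energy(e_mid, xi / 2, foil$material, n / 2),
                     error = function(e) stop("foil ", foil$id %||% foil$material$name,
                                              ": ", conditionMessage(e)))
  s_mid <- straggling(foil, beam$energy_mev, fraction = 0.5)
  s_exit <- straggling(foil, beam$energy_mev, fraction = 1)
  list(mid = beam_state(e_mid, sqrt(beam$unc_kev^2 + s_mid^2)),
       exit = beam_state(e_exit, sqrt(beam$unc_kev^2 + s_exit^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bohr energy straggling through a foil
#'
#' Relativistic Bohr straggling (1 sigma) accumulated over a foil, evaluated
#' with the kinematic factor at the entry energy.
#'
#' @param foil [foil_spec].
#' @param entry_energy_mev Proton energy entering the foil (MeV).
#' @param fraction Fraction of the foil areal density traversed (default 1).
#' @return Straggling standard deviation in keV.
#' @export
straggling <- function(foil, entry_energy_mev, fraction = 1) {
  xi_g <- foil$areal_density_ug_cm2 * 1e-6 * fraction  # g/cm^2
  if (xi_g <= 0) return(0)
  if (entry_energy_mev < .const$e_floor_mev)
    stop("energy below the stopping-power validity floor")
  idx <- match(names(foil$material$composition), .elements$symbol)
  zoa <- sum(foil$material$composition *
               .elements$Z[idx] / .elements$A[idx])
  bg <- .beta2_gamma(entry_energy_mev)
  rel <- (1 - bg$beta2 / 2) / (1 - bg$beta2)
  omega2_mev2 <- .const$bohr_k_mev2 * zoa * xi_g * rel
  sqrt(omega2_mev2) * 1000
}

#' Propagate the beam through a whole stack
#'
#' Applies [degrade()] layer by layer, recording the mid-foil beam state of
#' every layer. Straggling variances accumulate in quadrature with the entry
#' uncertainty.
#'
#' @param beam Entry [beam_state] (cyclotron extraction energy, typically
#'   +/- 500 keV).
#' @param layers List of [foil_spec]s, in beam order (window and air gap
#'   first for an in-air stack).
#' @return A data frame with one row per layer: `id`, `role`, `material`,
#'   `areal_density_ug_cm2`, `e_entry_mev`, `e_mid_mev`, `e_exit_mev`,
#'   `unc_mid_kev`, `unc_exit_kev`.
#' @export
propagate_stack <- function(beam, layers) {
  if (!length(layers)) stop("layer list must be non-empty")
  rows <- vector("list", length(layers))
  cur <- beam
  for (i in seq_along(layers)) {
    f <- layers[[i]]
    d <- tryCatch(degrade(cur, f),
                  error = function(e) stop("layer ", i, ": ", conditionMessage(e)))
    rows[[i]] <- data.frame(
      id = f$id %||% paste0("layer-", i),
      role = f$role,
      material = f$material$name,
      areal_density_ug_cm2 = f$areal_density_ug_cm2,
      e_entry_mev = cur$energy_mev,
      e_mid_mev = d$mid$energy_mev,
      e_exit_mev = d$exit$energy_mev,
      unc_mid_kev = d$mid$unc_kev,
      unc_exit_kev = d$exit$unc_kev,
      stringsAsFactors = FALSE)
    cur <- d$exit
  }
  do.call(rbind, rows)
}
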