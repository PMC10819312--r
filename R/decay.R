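# Post-EOB activity evolution and radionuclidic purity (RNP).
#
# All products decay independently except Sc-44g, which is fed by the
# isomeric transition of Sc-44m (branch b ~ 0.988); the pair follows the
# two-member Bateman solution.

#' Activity set at a time point
#'
#' @param activities Named numeric vector of activities (MBq, non-negative);
#'   names are nuclide symbols (`"Sc-47"`, `"Sc-44m"`, ...).
#' @param time_h Time offset from EOB (h).
#' @return Object of class `activity_set`.
#' @examples
#' activity_set(c("Sc-47" = 198, "Sc-44g" = 1792, "Sc-44m" = 154))
#' @export
activity_set <- function(activities, time_h = 0) {
  if (is.null(names(activities)) || any(!nzchar(names(activities))))
    stop("activities must be a named vector of nuclide activities")
  if (any(activities < 0)) stop("activities must be non-negative")
  structure(list(activities = activities, time_h = time_h),
            class = "activity_set")
}

#' @export
print.activity_set <- function(x, ...) {
  cat(sprintf("<activity_set> t = %.1f h after EOB\n", x$time_h))
  df <- data.frame(nuclide = names(x$activities),
                   activity_mbq = as.numeric(x$activities))
  print(df, row.names = FALSE)
  invisible(x)
}

# Vectorised decay over a vector of elapsed times; returns a matrix
# (nuclide x time). Handles the Sc-44m -> Sc-44g feeding pair.
.decay_matrix <- function(a, dt_h, registry, it_branch) {
  acts <- a$activities
  nucs <- names(acts)
  lam <- vapply(nucs, function(n) lambda_per_hour(registry, n), numeric(1))
  m <- outer(lam, dt_h, function(l, t) exp(-l * t)) * acts
  rownames(m) <- nucs
  if ("Sc-44g" %in% nucs && "Sc-44m" %in% nucs && acts[["Sc-44m"]] > 0) {
    lg <- lam[["Sc-44g"]]; lm <- lam[["Sc-44m"]]
    am0 <- acts[["Sc-44m"]]
    feed <- if (abs(lg - lm) < 1e-12 * lg) {
      # degenerate limit lambda_g -> lambda_m
      it_branch * lg * am0 * dt_h * exp(-lg * dt_h)
    } else {
      it_branch * (lg / (lg - lm)) * am0 * (exp(-lm * dt_h) - exp(-lg * dt_h))
    }
    m["Sc-44g", ] <- m["Sc-44g", ] + feed
  }
  m
}

#' Decay an activity set forward in time
#'
#' Each nuclide decays exponentially; Sc-44g additionally receives the
#' Bateman feeding term from the isomeric transition of Sc-44m:
#' \deqn{A_g(t) = A_g(0)e^{-\lambda_g t} + b\frac{\lambda_g}{\lambda_g-\lambda_m}
#'   A_m(0)\left(e^{-\lambda_m t} - e^{-\lambda_g t}\right)}
#' (with the limiting form when the two decay constants coincide).
#'
#' @param a An [activity_set].
#' @param dt_h Elapsed time (h, non-negative scalar).
#' @param registry Decay data.
#' @param it_branch Isomeric-transition branching fraction of Sc-44m
#'   (default [it_branching_sc44()]).
#' @return The decayed [activity_set] (time stamp advanced by `dt_h`).
#' @export
decay_activities <- function(a, dt_h, registry = default_nuclides(),
                             it_branch = it_branching_sc44()) {
  stopifnot(inherits(a, "activity_set"))
  if (dt_h < 0) stop("elapsed time must be non-negative")
  m <- .decay_matrix(a, dt_h, registry, it_branch)
  activity_set(stats::setNames(m[, 1], rownames(m)), time_h = a$time_h + dt_h)
}

#' Radionuclidic purity of Sc-47
#'
#' Activity fraction of Sc-47 among all scandium isotopes in the set;
#' non-scandium nuclides (e.g. V-48, which is removed chemically with the
#' titanium) are excluded from the denominator.
#'
#' @param a An [activity_set].
#' @return Fraction in `[0, 1]`.
#' @export
rnp <- function(a) {
  stopifnot(inherits(a, "activity_set"))
  sc <- a$activities[grepl("^Sc-", names(a$activities))]
  tot <- sum(sc)
  if (tot <= 0) stop("total scandium activity is zero; RNP undefined")
  unname(if ("Sc-47" %in% names(sc)) sc[["Sc-47"]] / tot else 0)
}

.rnp_on_grid <- function(a0, times, registry, it_branch) {
  m <- .decay_matrix(a0, times, registry, it_branch)
  sc <- grepl("^Sc-", rownames(m))
  tot <- colSums(m[sc, , drop = FALSE])
  a47 <- if ("Sc-47" %in% rownames(m)) m["Sc-47", ] else 0 * tot
  ifelse(tot > 0, a47 / tot, NA_real_)
}

#' RNP evolution curve
#'
#' @param a0 EOB [activity_set].
#' @param times_h Times after EOB at which to evaluate (h).
#' @inheritParams decay_activities
#' @return Data frame with `t_h` and `rnp`.
#' @export
rnp_curve <- function(a0, times_h = seq(0, 2000, by = 10),
                      registry = default_nuclides(),
                      it_branch = it_branching_sc44()) {
  data.frame(t_h = times_h,
             rnp = .rnp_on_grid(a0, times_h, registry, it_branch))
}

#' Time after EOB to reach a target RNP
#'
#' Scans an hourly grid for the first crossing of the target purity, then
#' refines by root bisection within the bracketing interval. When the
#' target is never reached on the horizon (the long-lived Sc-46 term caps
#' the achievable purity), `Inf` is returned.
#'
#' @param a0 EOB [activity_set].
#' @param target Target purity in (0, 1), e.g. 0.99.
#' @param horizon_h Search horizon (h).
#' @inheritParams decay_activities
#' @return Smallest time (h) with RNP >= target; 0 if already above; `Inf`
#'   if unreachable within the horizon.
#' @export
time_to_rnp <- function(a0, target, horizon_h = 5000,
                        registry = default_nuclides(),
                        it_branch = it_branching_sc44()) {
  if (target <= 0 || target >= 1) stop("target purity must be in (0, 1)")
  grid <- seq(0, horizon_h, by = 1)
  r <- .rnp_on_grid(a0, grid, registry, it_branch)
  if (r[1] >= target) return(0)
  idx <- which(r >= target)
  if (!length(idx)) return(Inf)
  i <- idx[1]
  f <- function(t) .rnp_on_grid(a0, t, registry, it_branch) - target
  stats::uniroot(f, lower = grid[i - 1], upper = grid[i], tol = 1e-4)$root
}

#' Maximum achievable RNP
#'
#' Hourly grid search over the horizon refined by local optimisation. For
#' sets without impurities outliving Sc-47 the purity grows monotonically;
#' the horizon end is then returned with `monotone = TRUE`.
#'
#' @inheritParams time_to_rnp
#' @return List with `t_h` (argmax), `rnp` (maximum) and `monotone`.
#' @export
max_rnp <- function(a0, horizon_h = 5000, registry = default_nuclides(),
                    it_branch = it_branching_sc44()) {
  grid <- seq(0, horizon_h, by = 1)
  r <- .rnp_on_grid(a0, grid, registry, it_branch)
  i <- which.max(r)
  if (i == length(grid)) {
    return(list(t_h = horizon_h, rnp = r[i], monotone = TRUE))
  }
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(t) .rnp_on_grid(a0, t, registry, it_branch),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
  list(t_h = opt$maximum, rnp = opt$objective, monotone = FALSE)
}

#' Shipped reference scenario yields
#'
#' Reference thick-target EOB activities for the eight irradiation
#' scenarios (entry energies 25-40 MeV, 24 h and 80 h at 1 uA), as
#' calculated from the full body of experimental excitation data. Used as
#' printed starting activities for purity-evolution studies.
#'
#' @return Data frame with `scenario`, `e_entry_mev`, `t_irr_h`, `nuclide`,
#'   `activity_mbq`.
#' @export
reference_yields <- function() {
  if (is.null(.pkg_cache$ref_yields)) {
    p <- system.file("extdata", "reference_yields.csv", package = "sc47yield")
    .pkg_cache$ref_yields <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  .pkg_cache$ref_yields
}

#' EOB activity set of a reference scenario
#'
#' @param e_entry_mev Scenario entry energy (25, 30, 35 or 40).
#' @param t_irr_h Irradiation time (24 or 80).
#' @return An [activity_set] with the scenario's Sc activities.
#' @export
reference_activity_set <- function(e_entry_mev, t_irr_h) {
  y <- reference_yields()
  sel <- y[y$e_entry_mev == e_entry_mev & y$t_irr_h == t_irr_h, ]
  if (!nrow(sel)) stop("no reference scenario with entry energy ",
                       e_entry_mev, " MeV and t_irr ", t_irr_h, " h")
  activity_set(stats::setNames(sel$activity_mbq, sel$nuclide))
}
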