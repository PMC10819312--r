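# Tabular and JSON I/O plus the end-to-end pipeline driver.

.xs_schema <- c("target_id", "energy_mev", "energy_unc_mev",
                "sc47_mb", "sc47_unc_mb", "sc46c_mb", "sc46c_unc_mb",
                "sc44g_mb", "sc44g_unc_mb", "sc44m_mb", "sc44m_unc_mb",
                "sc43_mb", "sc43_unc_mb", "v48_mb", "v48_unc_mb")

#' Read a cross-section table
#'
#' CSV in the package cross-section schema: one row per target foil, one
#' `<product>_mb` / `<product>_unc_mb` column pair per product. Blank cells
#' mean "no measured value" (below onset / not observed) and are kept as
#' `NA`, never coerced to zero.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_xs_table <- function(path) {
  if (!file.exists(path)) stop("cross-section table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (length(miss <- setdiff(.xs_schema, names(raw))))
    stop("cross-section table missing column(s): ", paste(miss, collapse = ", "))
  df <- raw
  for (col in setdiff(.xs_schema, "target_id")) {
    v <- trimws(raw[[col]])
    v[v == "" | v == "-"] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("malformed numeric in column ", col, ", row ", bad[1],
           ": '", v[bad[1]], "'")
    df[[col]] <- num
  }
  if (any(!is.finite(df$energy_mev)))
    stop("every row needs a proton energy")
  sig_cols <- grep("_mb$", names(df), value = TRUE)
  sig_cols <- sig_cols[!grepl("_unc_mb$", sig_cols)]
  for (col in sig_cols)
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative cross-section in column ", col, ", row ",
           which(df[[col]] < 0)[1])
  df
}

#' Write a cross-section table
#'
#' Inverse of [read_xs_table()]; `NA` cells serialize as empty strings so
#' that "not measured" round-trips losslessly and is never written as 0.
#'
#' @param df Data frame in the cross-section schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_xs_table <- function(df, path) {
  if (length(miss <- setdiff(.xs_schema, names(df))))
    stop("cross-section table missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(df[, .xs_schema], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a stack description from JSON
#'
#' Schema: `{"e0_mev": .., "e0_unc_kev": .., "layers": [{"material": ..,
#' "role": .., "id": .., "areal_density_ug_cm2" | "thickness_um" |
#' "thickness_cm": .., "areal_unc_ug_cm2": ..}, ...]}`.
#'
#' @param path JSON file path.
#' @return List with `beam` ([beam_state]), `layers` (list of [foil_spec])
#'   and `foils` (target/monitor/catcher table with pairing groups).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$e0_mev) || is.null(j$layers) || !length(j$layers))
    stop("stack file needs e0_mev and a non-empty layers array")
  layers <- lapply(seq_along(j$layers), function(i) {
    l <- j$layers[[i]]
    if (is.null(l$material) || is.null(l$role))
      stop("stack layer ", i, " needs material and role")
    foil_spec(l$material,
              areal_density_ug_cm2 = l$areal_density_ug_cm2,
              thickness_um = l$thickness_um, thickness_cm = l$thickness_cm,
              role = l$role, id = l$id %||% paste0("layer-", i),
              areal_unc_ug_cm2 = l$areal_unc_ug_cm2 %||% 0)
  })
  list(beam = beam_state(j$e0_mev, j$e0_unc_kev %||% 500),
       layers = layers,
       foils = .stack_foil_table(layers))
}

#' Read irradiation scenarios from JSON
#'
#' Array of objects with `e_entry_mev`, `t_irr_h` and optional `e_exit_mev`,
#' `current_ua`, `name`.
#'
#' @param path JSON file path.
#' @return List of [scenario] objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(j), function(i) {
    s <- j[[i]]
    if (is.null(s$e_entry_mev) || is.null(s$t_irr_h))
      stop("scenario ", i, " needs e_entry_mev and t_irr_h")
    scenario(s$e_entry_mev, s$t_irr_h, s$e_exit_mev %||% 0,
             s$current_ua %||% 1, s$name %||% NULL)
  })
}

#' Read measurement records
#'
#' @param path CSV with columns `foil_id`, `nuclide`, `line_kev`, `counts`,
#'   `counts_unc`, `t_cool_h`, `t_real_h`, `t_live_h`, `eff`, `eff_unc`.
#' @return Data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurements file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("foil_id", "nuclide", "line_kev", "counts", "counts_unc",
           "t_cool_h", "t_real_h", "t_live_h", "eff", "eff_unc")
  if (length(miss <- setdiff(req, names(df))))
    stop("measurements file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Run the full analysis pipeline from a config file
#'
#' The config is a JSON object with paths (relative to the config file) and
#' options:
#' \itemize{
#'   \item `stack`: stack JSON (optional; enables energy bookkeeping and,
#'     with `measurements`, cross-section extraction);
#'   \item `measurements`: measurement CSV (optional);
#'   \item `xs_table`: cross-section CSV used for yield planning (default:
#'     the shipped measured table);
#'   \item `scenarios`: scenario JSON (optional; enables yield and purity
#'     planning);
#'   \item `t_irr_h`, `enrichment`, `it_branch`, `rnp_target`, `horizon_h`,
#'     `step_mev`, `seed`: options with documented defaults.
#' }
#' Outputs written to `out_dir`: `stack_energies.csv`, `cross_sections.csv`,
#' `yields.csv`, `rnp_curves.csv`, `rnp_solutions.csv` (as applicable) and a
#' `provenance.json` recording input hashes, the seed and all defaults
#' actually used. Outputs are deterministic given config + seed.
#'
#' @param config Path to the JSON config, or an equivalent named list.
#' @param out_dir Output directory (created if needed); overrides the config
#'   entry.
#' @return Invisible character vector of the files written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(normalizePath(config))
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  out_dir <- out_dir %||% resolve(config$out_dir) %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  opts <- list(t_irr_h = config$t_irr_h %||% 1.5,
               enrichment = config$enrichment %||% 0.9932,
               it_branch = config$it_branch %||% it_branching_sc44(),
               rnp_target = config$rnp_target %||% 0.99,
               horizon_h = config$horizon_h %||% 5000,
               step_mev = config$step_mev %||% 0.02,
               seed = config$seed %||% 1)
  set.seed(opts$seed)
  registry <- if (!is.null(config$nuclide_table))
    load_nuclide_table(resolve(config$nuclide_table)) else default_nuclides()

  written <- character(0)
  inputs <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }

  xs_df <- NULL
  if (!is.null(config$stack)) {
    sp <- resolve(config$stack); inputs$stack <- sp
    stk <- read_stack(sp)
    energies <- propagate_stack(stk$beam, stk$layers)
    emit(energies, "stack_energies.csv")
    if (!is.null(config$measurements)) {
      mp <- resolve(config$measurements); inputs$measurements <- mp
      meas <- read_measurements(mp)
      en <- data.frame(foil_id = energies$id, e_mid_mev = energies$e_mid_mev,
                       unc_mid_kev = energies$unc_mid_kev)
      xs_df <- extract_cross_sections(meas, stk$foils, en,
                                      t_irr_h = opts$t_irr_h,
                                      registry = registry,
                                      enrichment = opts$enrichment)
      emit(xs_df, "cross_sections.csv")
    }
  }

  xs_path <- resolve(config$xs_table) %||%
    system.file("extdata", "ti48_cross_sections.csv", package = "sc47yield")
  inputs$xs_table <- xs_path
  fits <- excitation_fits(read_xs_table(xs_path),
                          products = c("Sc-47", "Sc-46", "Sc-44g",
                                       "Sc-44m", "Sc-43"))

  if (!is.null(config$scenarios)) {
    scp <- resolve(config$scenarios); inputs$scenarios <- scp
    scens <- read_scenarios(scp)
    yt <- yield_table(fits, scens, registry = registry,
                      step_mev = opts$step_mev)
    emit(yt, "yields.csv")

    curves <- list(); sols <- list()
    for (sc in scens) {
      ys <- yt[yt$scenario == sc$name & !is.na(yt$activity_mbq), ]
      a0 <- activity_set(stats::setNames(ys$activity_mbq, ys$nuclide))
      cur <- rnp_curve(a0, seq(0, opts$horizon_h, by = 10),
                       registry = registry, it_branch = opts$it_branch)
      cur$scenario <- sc$name
      curves[[sc$name]] <- cur
      t99 <- time_to_rnp(a0, opts$rnp_target, horizon_h = opts$horizon_h,
                         registry = registry, it_branch = opts$it_branch)
      mx <- max_rnp(a0, horizon_h = opts$horizon_h, registry = registry,
                    it_branch = opts$it_branch)
      sols[[sc$name]] <- data.frame(scenario = sc$name,
                                    rnp_target = opts$rnp_target,
                                    t_to_target_h = t99,
                                    t_max_h = mx$t_h, rnp_max = mx$rnp,
                                    monotone = mx$monotone)
    }
    emit(do.call(rbind, curves), "rnp_curves.csv")
    emit(do.call(rbind, sols), "rnp_solutions.csv")
  }

  prov <- list(
    package = "sc47yield",
    version = as.character(utils::packageVersion("sc47yield")),
    seed = opts$seed,
    options = opts[names(opts) != "seed"],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(written))
  pp <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, pp)
  invisible(written)
}
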