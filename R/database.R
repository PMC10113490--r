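#' Run a simulation campaign
#'
#' Crosses a geometry grid with a material grid and computes the
#' deformation features of every combination, producing the
#' feature/target table used for regression analysis and network
#' training. Backends: `"surrogate"` (calibrated layered-cylinder
#' map, suitable for desk-scale campaigns) or `"fe"` (full finite
#' element solve per case). Failed cases are retained as rows with a
#' status flag rather than silently dropped; the campaign aborts if
#' more than 1% of cases fail.
#'
#' @param geometry_grid Data frame with columns `SR`, `cap_thk`,
#'   `core_thk` (e.g. [enumerate_idealized_grid()]).
#' @param material_grid A [enumerate_material_grid()] object.
#' @param backend `"surrogate"` or `"fe"`.
#' @param subsample `NULL` for the full factorial, a fraction in
#'   (0, 1), or a list `list(geometries =, E_core =, E_plaque =)` of
#'   stratified counts to scale the factorial down while preserving
#'   its structure.
#' @param seed Seed controlling subsampling.
#' @param calibration Surrogate calibration (surrogate backend).
#' @param protocol,config Forward-model settings.
#' @param h Mesh size for the FE backend.
#' @param verbose Print progress every 1000 cases.
#' @return A tibble of class `dataset_table` with one row per case:
#'   ids, geometry parameters, targets (`E_core`, `E_plaque`, kPa),
#'   features, and `status`; provenance is attached as attribute
#'   `provenance`.
#' @export
run_campaign <- function(geometry_grid, material_grid,
                         backend = c("surrogate", "fe"),
                         subsample = NULL, seed = 1L,
                         calibration = NULL, protocol = load_protocol(),
                         config = solver_config(), h = 0.2, verbose = FALSE) {
  backend <- match.arg(backend)
  stopifnot(all(c("SR", "cap_thk", "core_thk") %in% names(geometry_grid)))
  geometry_grid <- dplyr::mutate(geometry_grid,
                                 geometry_id = dplyr::row_number())

  E_core <- material_grid$E_core
  E_plaque <- material_grid$E_plaque

  if (is.list(subsample) && !is.null(subsample$geometries)) {
    set.seed(seed)
    geometry_grid <- stratified_rows(geometry_grid, "SR", subsample$geometries)
    E_core <- stratified_values(E_core, subsample$E_core)
    E_plaque <- stratified_values(E_plaque, subsample$E_plaque)
  }

  cases <- tidyr::expand_grid(
    geometry_id = geometry_grid$geometry_id,
    E_core = E_core, E_plaque = E_plaque
  ) |>
    dplyr::left_join(geometry_grid, by = "geometry_id")

  if (is.numeric(subsample) && length(subsample) == 1) {
    set.seed(seed)
    keep <- sort(sample(nrow(cases), max(1, round(subsample * nrow(cases)))))
    cases <- cases[keep, ]
  }
  cases <- dplyr::mutate(cases, case_id = sprintf("C%07d", dplyr::row_number()),
                         .before = 1)

  if (backend == "surrogate") {
    calibration <- calibration %||% load_surrogate_calibration()
    feats <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
      if (verbose && i %% 1000 == 0) message("case ", i, "/", nrow(cases))
      out <- tryCatch(
        surrogate_forward_params(cases$SR[i], cases$cap_thk[i], cases$E_core[i],
                                 cases$E_plaque[i], calibration = calibration,
                                 protocol = protocol),
        error = function(e) NULL)
      if (is.null(out)) tibble::tibble(status = "failed")
      else dplyr::mutate(out[, feature_columns()], status = "ok")
    })
  } else {
    feats <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
      if (verbose) message("FE case ", i, "/", nrow(cases))
      out <- tryCatch(
        fe_case_features(cases$SR[i], cases$cap_thk[i], cases$core_thk[i],
                         cases$E_core[i], cases$E_plaque[i], h = h,
                         protocol = protocol),
        error = function(e) NULL)
      if (is.null(out)) tibble::tibble(status = "failed")
      else tibble::tibble(
        eps1 = out$eps1, eps2 = out$eps2, eps_core = out$eps_core,
        eps_cap = out$eps_cap, eps_theta = out$eps_theta,
        eps_core_sq = out$eps_core^2, eps_cap_sq = out$eps_cap^2,
        eps_theta_sq = out$eps_theta^2, status = "ok")
    })
  }

  tbl <- dplyr::bind_cols(cases, feats)
  fail_rate <- mean(tbl$status != "ok")
  if (fail_rate > 0.01) {
    ath_abort(sprintf("campaign aborted: %.1f%% of cases failed to solve",
                      100 * fail_rate), "atheromech_campaign_error")
  }
  as_dataset_table(tbl, provenance = list(
    backend = backend, seed = seed, n_cases = nrow(tbl),
    n_geometries = nrow(geometry_grid),
    n_E_core = length(E_core), n_E_plaque = length(E_plaque),
    protocol = list(end_kPa = protocol$end_kPa, n_inc = protocol$n_inc),
    package_version = as.character(utils::packageVersion("atheromech"))
  ))
}

feature_columns <- function() {
  c("eps1", "eps2", "eps_core", "eps_cap", "eps_theta",
    "eps_core_sq", "eps_cap_sq", "eps_theta_sq")
}

dataset_schema <- function() {
  c("case_id", "geometry_id", "E_core", "E_plaque", "SR", "cap_thk",
    "core_thk", feature_columns(), "status")
}

as_dataset_table <- function(tbl, provenance = list()) {
  missing <- setdiff(dataset_schema(), names(tbl))
  if (length(missing)) {
    ath_abort(paste0("dataset is missing column(s): ",
                     paste(missing, collapse = ", ")), "atheromech_schema_error")
  }
  if (anyDuplicated(tbl$case_id)) {
    ath_abort("dataset case ids must be unique", "atheromech_schema_error")
  }
  tbl <- tbl[, c(dataset_schema(), setdiff(names(tbl), dataset_schema()))]
  attr(tbl, "provenance") <- provenance
  class(tbl) <- c("dataset_table", class(tbl))
  tbl
}

# stratified subsample helpers: pick n rows/values spread over strata
stratified_rows <- function(grid, strat_col, n) {
  if (n >= nrow(grid)) return(grid)
  split_idx <- split(seq_len(nrow(grid)), grid[[strat_col]])
  per <- ceiling(n / length(split_idx))
  take <- unlist(lapply(split_idx, function(ix) sample(ix, min(per, length(ix)))))
  grid[sort(sample(take, min(n, length(take)))), ]
}

stratified_values <- function(values, n) {
  if (n >= length(values)) return(values)
  values[unique(round(seq(1, length(values), length.out = n)))]
}

#' Scaled-down default campaign design
#'
#' The full factorial (540 geometries x 300 x 10 materials) is
#' cluster-scale; the default desk-scale campaign keeps the factorial
#' structure with 60 geometries (stratified over stenosis ratio),
#' 50 log-spaced core moduli and 5 fibrotic moduli: 15,000 cases.
#'
#' @param n_geometries,n_E_core,n_E_plaque Stratified counts.
#' @return A list passable as `subsample` to [run_campaign()].
#' @export
default_subsample <- function(n_geometries = 60, n_E_core = 50, n_E_plaque = 5) {
  list(geometries = n_geometries, E_core = n_E_core, E_plaque = n_E_plaque)
}

#' Save and load dataset tables
#'
#' The table is written as plain CSV with a JSON provenance sidecar
#' (`<path>.provenance.json`); a load after a save restores every
#' field (12 significant digits for reals).
#'
#' @param table A `dataset_table`.
#' @param path CSV file path.
#' @return `save_dataset()` returns `path` invisibly; `load_dataset()`
#'   the restored `dataset_table`.
#' @export
save_dataset <- function(table, path) {
  stopifnot(inherits(table, "dataset_table"))
  readr::write_csv(table, path)
  jsonlite::write_json(attr(table, "provenance"),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    case_id = readr::col_character(), status = readr::col_character(),
    geometry_id = readr::col_integer(),
    .default = readr::col_double()))
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else list()
  as_dataset_table(tbl, provenance = prov)
}

#' Realistic-family feature dataset
#'
#' Evaluates the surrogate (with per-geometry shape modulation) for
#' every case of a [generate_realistic_family()] object, yielding a
#' `dataset_table` with the same schema as the idealized campaigns.
#'
#' @param family A `realistic_family`.
#' @param calibration Surrogate calibration.
#' @param protocol Load protocol.
#' @param verbose Print progress.
#' @return A `dataset_table`.
#' @export
realistic_dataset <- function(family, calibration = NULL,
                              protocol = load_protocol(), verbose = FALSE) {
  stopifnot(inherits(family, "realistic_family"))
  calibration <- calibration %||% load_surrogate_calibration()
  mods <- lapply(family$geometries, shape_modulation)
  core_thk <- mm_to_um(family$geometries[[1]]$shape$core)

  cases <- family$cases
  feats <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    if (verbose && i %% 1000 == 0) message("case ", i, "/", nrow(cases))
    surrogate_forward_params(cases$SR[i], cases$cap_thk[i], cases$E_core[i],
                             cases$E_plaque[i], calibration = calibration,
                             protocol = protocol,
                             shape_mod = mods[[cases$geometry_id[i]]])[, feature_columns()]
  })
  tbl <- dplyr::bind_cols(
    dplyr::transmute(cases, case_id = .data$case_id,
                     geometry_id = as.integer(.data$geometry_id),
                     E_core = .data$E_core, E_plaque = .data$E_plaque,
                     SR = .data$SR, cap_thk = .data$cap_thk,
                     core_thk = core_thk),
    feats, tibble::tibble(status = rep("ok", nrow(cases))))
  as_dataset_table(tbl, provenance = list(
    backend = "surrogate-realistic", seed = family$seed,
    amp_frac = family$amp_frac, n_cases = nrow(tbl),
    n_geometries = length(family$geometries),
    package_version = as.character(utils::packageVersion("atheromech"))
  ))
}
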