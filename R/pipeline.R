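#' Pipeline configuration
#'
#' One structured configuration drives the end-to-end workflow
#' (database, feature selection, training, realistic family,
#' transfer, case study). Every stochastic stage has an explicit
#' seed derived from the master `seed`. Serializable to/from YAML.
#'
#' @param seed Master seed.
#' @param backend `"surrogate"` or `"fe"` for the idealized campaign.
#' @param subsample Campaign scaling, see [run_campaign()]; default
#'   [default_subsample()] (15,000 cases).
#' @param n_realistic_cap Cap variants in the realistic family.
#' @param realistic_materials Counts `c(n_E_core, n_E_plaque)` for the
#'   realistic material grid.
#' @param hidden_width,batch_size,epochs Network/training settings
#'   forwarded to [mlp_spec()] / [train_config()].
#' @param alpha,vif_cap Feature-selection settings.
#' @param finetune A [finetune_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, backend = "surrogate",
                            subsample = default_subsample(),
                            n_realistic_cap = 20L,
                            realistic_materials = c(20L, 5L),
                            hidden_width = 24L, batch_size = 256L,
                            epochs = 7000L,
                            alpha = 0.05, vif_cap = 10,
                            finetune = finetune_config(seed = seed)) {
  structure(list(seed = as.integer(seed), backend = backend,
                 subsample = subsample, n_realistic_cap = n_realistic_cap,
                 realistic_materials = realistic_materials,
                 hidden_width = hidden_width, batch_size = batch_size,
                 epochs = as.integer(epochs),
                 alpha = alpha, vif_cap = vif_cap, finetune = finetune),
            class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' build-db, select-features, train, build-realistic, finetune and
#' case-study in sequence, writing every artifact (CSV datasets, JSON
#' reports, model checkpoint, training curves, manifest with hashes
#' and seeds) into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if missing).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory artifacts (`dataset`,
#'   `selection`, `model`, `realistic`, `case_study`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "atheromech-run",
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  t_start <- Sys.time()

  say("stage build-db (", config$backend, " backend)")
  dataset <- run_campaign(enumerate_idealized_grid(), enumerate_material_grid(),
                          backend = config$backend,
                          subsample = config$subsample, seed = config$seed)
  save_dataset(dataset, file.path(out_dir, "idealized_dataset.csv"))

  say("stage select-features")
  selection <- select_ann_inputs(dataset, alpha = config$alpha,
                                 vif_cap = config$vif_cap)
  jsonlite::write_json(list(inputs = selection$inputs,
                            data_driven = selection$selection$selected,
                            log = selection$selection$log),
                       file.path(out_dir, "feature_selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("stage train (", config$epochs, " epochs)")
  model <- train_stiffness_model(
    dataset, inputs = selection$inputs,
    spec = mlp_spec(n_in = length(selection$inputs),
                    hidden = rep(config$hidden_width, 12)),
    config = train_config(epochs = config$epochs,
                          batch_size = config$batch_size, seed = config$seed))
  write_model(model, file.path(out_dir, "model.json"))
  readr::write_csv(model$history, file.path(out_dir, "training_curves.csv"))

  say("stage build-realistic")
  family <- generate_realistic_family(
    n_cap = config$n_realistic_cap,
    material_grid = enumerate_material_grid(config$realistic_materials[1],
                                            config$realistic_materials[2]),
    seed = config$seed)
  realistic <- realistic_dataset(family)
  save_dataset(realistic, file.path(out_dir, "realistic_dataset.csv"))

  say("stage case-study (finetune + three-case evaluation)")
  cs <- run_case_study(model, dataset, realistic, config$finetune)
  write_case_study(cs, file.path(out_dir, "case_study.json"))
  write_model(cs$finetuned, file.path(out_dir, "model_finetuned.json"))

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    elapsed_min = round(as.numeric(difftime(Sys.time(), t_start, units = "mins")), 2),
    seed = config$seed,
    config = unclass_deep(config),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(files) + 1, " artifacts in ", out_dir)

  invisible(list(dataset = dataset, selection = selection, model = model,
                 realistic = realistic, case_study = cs, manifest = manifest))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Read and write pipeline configurations as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    ath_abort("the yaml package is required for YAML configs", "atheromech_domain_error")
  }
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    ath_abort("the yaml package is required for YAML configs", "atheromech_domain_error")
  }
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  known <- names(base)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    ath_abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
              "atheromech_config_error")
  }
  merged <- modifyList(unclass(base), raw)
  if (!is.null(raw$finetune)) {
    merged$finetune <- do.call(finetune_config, raw$finetune)
  }
  out <- do.call(pipeline_config, merged[setdiff(names(merged), character())])
  out
}
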