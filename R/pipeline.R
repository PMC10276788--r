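## Pipeline orchestration: simulate -> filter -> energies -> fit ->
## predict behind one structured config (YAML or list). Every tabular
## artifact carries a provenance comment header (package version, stage,
## config hash); logging goes to stderr with timestamps.

.log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

.provenance <- function(stage, hash) {
  c(paste0("liece ", as.character(utils::packageVersion("liece"))),
    paste0("stage: ", stage),
    paste0("config: ", hash))
}

#' Validate a pipeline configuration
#'
#' Collects every violation (unknown stages, missing referenced files,
#' invalid model variants) and errors with the full list.
#'
#' @param config list, or path to a YAML file.
#' @return the validated config (invisibly errors otherwise).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  known <- c("simulate", "filter", "energies", "fit", "predict")
  stages <- config$stages
  if (is.null(stages)) problems <- c(problems, "no `stages` listed")
  bad <- setdiff(stages, known)
  if (length(bad))
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad, collapse = ", ")))
  if (is.null(config$out_dir)) problems <- c(problems, "no `out_dir`")
  for (field in c("energies", "model")) {
    for (stage in c("fit", "predict")) {
      p <- config[[stage]][[field]]
      ## paths produced by an earlier stage of the same run are allowed
      if (!is.null(p) && !file.exists(p) &&
          !identical(dirname(p), config$out_dir))
        problems <- c(problems,
                      paste0(stage, "$", field, ": file not found: ", p))
    }
  }
  v <- config$fit$variants
  if (!is.null(v) && length(setdiff(v, .VARIANTS)))
    problems <- c(problems, paste0("unknown variant(s): ",
                                   paste(setdiff(v, .VARIANTS),
                                         collapse = ", ")))
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  config
}

#' Run the LIECE pipeline
#'
#' Executes the configured stages in order: `simulate` (synthetic energy
#' table), `filter` (toy poses and decoys through [filter_poses()]),
#' `energies` ([interaction_terms()] on the toy complex), `fit`
#' ([fit_liece()] plus [loo_cv()] per variant, model written as JSON) and
#' `predict` (external evaluation of a stored model). Any stage failure
#' aborts with a stage-named error. Reruns with an identical config and
#' seed produce identical outputs.
#'
#' @param config list or YAML path; see `validate_config()`. Main fields:
#'   `stages`, `out_dir`, `seed`, and per-stage blocks `simulate`
#'   (passed to [table_spec()]), `filter`/`energies` (passed to
#'   [complex_spec()]), `fit` (`energies` path, `subset`, `variants`,
#'   `loo`), `predict` (`model`, `energies`).
#' @return list with `status` (0 on success) and `manifest` data.frame
#'   (stage, artifact, path).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  hash <- .config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- data.frame(stage = character(), artifact = character(),
                         path = character())
  add <- function(stage, artifact, path) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, artifact = artifact,
                                  path = path))
  }
  run_stage <- function(stage, fn) {
    .log("stage %s: start", stage)
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .log("stage %s: done", stage)
  }

  for (stage in config$stages) switch(stage,
    simulate = run_stage("simulate", function() {
      args <- config$simulate
      args$seed <- if (is.null(args$seed)) seed else args$seed
      spec <- do.call(table_spec, args)
      tab <- gen_energy_table(spec)
      path <- file.path(config$out_dir, "energy_table.csv")
      write_energy_table(tab, path, comments = .provenance("simulate", hash))
      add("simulate", "energy_table", path)
    }),
    filter = run_stage("filter", function() {
      args <- config$filter
      args$seed <- if (is.null(args$seed)) seed else args$seed
      toy <- gen_toy_complex(do.call(complex_spec, args))
      poses <- list(toy$ligand,
                    gen_decoy_pose(toy$ligand, "flip"),
                    gen_decoy_pose(toy$ligand, "strand_donor"),
                    gen_decoy_pose(toy$ligand, "expose_apolar"))
      res <- filter_poses(poses, toy$protein)
      path <- file.path(config$out_dir, "pose_decisions.csv")
      con <- file(path, "w")
      writeLines(paste0("# ", .provenance("filter", hash)), con)
      utils::write.csv(res$decisions, con, row.names = FALSE)
      close(con)
      add("filter", "pose_decisions", path)
    }),
    energies = run_stage("energies", function() {
      args <- config$energies
      args$seed <- if (is.null(args$seed)) seed else args$seed
      toy <- gen_toy_complex(do.call(complex_spec, args))
      it <- interaction_terms(toy$complex_structure, toy$protein,
                              toy$ligand)
      tab <- data.frame(ligand_id = "toy", dE_vdw = it$terms["dE_vdw"],
                        dE_coul = it$terms["dE_coul"],
                        dG_solv = it$terms["dG_solv"], dg_exp = NA,
                        dataset_label = "toy",
                        docking_program = "generated",
                        receptor_model = "toy")
      path <- file.path(config$out_dir, "energy_terms.csv")
      con <- file(path, "w")
      writeLines(paste0("# ", .provenance("energies", hash)), con)
      utils::write.csv(tab, con, row.names = FALSE)
      close(con)
      add("energies", "energy_terms", path)
    }),
    fit = run_stage("fit", function() {
      fc <- config$fit
      rows <- read_energy_table(fc$energies)
      if (!is.null(fc$subset))
        rows <- do.call(subset_energy_table, c(list(rows), fc$subset))
      variants <- if (is.null(fc$variants)) "full_int" else fc$variants
      models <- lapply(variants, function(v) {
        m <- fit_liece(rows, v)
        if (isTRUE(fc$loo) || is.null(fc$loo))
          m$loo <- loo_cv(rows, v, full_model = m)
        m
      })
      names(models) <- variants
      path <- file.path(config$out_dir, "model.json")
      write_model(models, path, provenance = .provenance("fit", hash))
      add("fit", "models", path)
    }),
    predict = run_stage("predict", function() {
      pc <- config$predict
      models <- read_model(pc$model)
      rows <- read_energy_table(pc$energies)
      out <- NULL
      for (v in names(models)) {
        pred <- predict_dg(models[[v]], rows)
        st <- if (all(is.finite(rows$dg_exp)))
          fit_statistics(pred, rows$dg_exp) else list(r2 = NA, rmse = NA)
        out <- rbind(out, data.frame(
          variant = v, ligand_id = rows$ligand_id, dg_pred = pred,
          dg_exp = rows$dg_exp, r2 = st$r2, rmse = st$rmse))
      }
      path <- file.path(config$out_dir, "predictions.csv")
      con <- file(path, "w")
      writeLines(paste0("# ", .provenance("predict", hash)), con)
      utils::write.csv(out, con, row.names = FALSE)
      close(con)
      add("predict", "predictions", path)
    }),
    stop("unknown stage: ", stage)
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, dataframe = "rows", pretty = TRUE)
  list(status = 0L, manifest = manifest)
}

#' Write fitted models to JSON
#'
#' @param models a `liece_model` or named list of them.
#' @param path output JSON file.
#' @param provenance optional character vector stored under `$provenance`.
#' @return `path`, invisibly.
#' @export
write_model <- function(models, path, provenance = NULL) {
  if (inherits(models, "liece_model")) models <- list(model = models)
  ser <- lapply(models, function(m) list(
    variant = m$variant,
    coefficients = as.list(m$coefficients),
    n_train = m$n_train,
    fit = m$fit,
    loo = if (!is.null(m$loo)) list(
      coef_std = as.list(m$loo$coef_std),
      mean_ddg = m$loo$mean_ddg,
      ddg_mode = m$loo$ddg_mode
    )
  ))
  jsonlite::write_json(list(provenance = provenance, models = ser), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read fitted models from JSON
#'
#' @param path JSON file written by [write_model()].
#' @return named list of `liece_model` objects.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path)
  lapply(j$models, function(m) {
    structure(list(
      coefficients = unlist(m$coefficients),
      variant = m$variant, n_train = m$n_train,
      fit = m$fit,
      loo = if (!is.null(m$loo)) list(
        coef_std = unlist(m$loo$coef_std),
        mean_ddg = m$loo$mean_ddg, ddg_mode = m$loo$ddg_mode
      )
    ), class = "liece_model")
  })
}
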