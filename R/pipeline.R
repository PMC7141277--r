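#' Pipeline configuration
#'
#' A single declarative configuration drives the four stages
#' simulate -> reconstruct -> featurize -> classify. It can be built from
#' a YAML file or an equivalent nested list; keys mirror the argument
#' names of [cohort_spec()], [gqi_config()], [ae_config()] and
#' [classifier_spec()]. The `cohort` block is mandatory. `geometry`
#' selects the grid: `"small"` keeps the cohort's grid (default 24^3,
#' already divisible by 8), `"template"` uses the full (91, 109, 91)
#' template grid, whose index maps are pruned to (88, 104, 88) before the
#' autoencoder.
#'
#' @param config path to a YAML file, or a nested list.
#' @param outdir,seed,geometry optional overrides of the config values.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(config, outdir = NULL, seed = NULL,
                            geometry = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_invalid("config must be a list or a YAML path")
  if (is.null(config$cohort))
    stop_invalid("config validation failed: missing 'cohort' block")
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(geometry)) config$geometry <- geometry
  if (is.null(config$outdir)) stop_invalid("config needs an 'outdir'")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$geometry <- match.arg(config$geometry %||% "small",
                               c("small", "template"))

  co <- config$cohort
  if (!is.null(co$group_sizes)) co$group_sizes <- unlist(co$group_sizes)
  if (identical(config$geometry, "template")) co$grid_shape <- c(91, 109, 91)
  if (is.null(co$seed)) co$seed <- derive_seed(config$seed, 1L)
  spec <- do.call(cohort_spec, co)

  gq <- do.call(gqi_config, config$gqi %||% list())

  ae <- config$ae %||% list()
  ae$input_shape <- ae_input_shape_for(spec$grid_shape)
  if (is.null(ae$seed)) ae$seed <- derive_seed(config$seed, 2L)
  aecfg <- do.call(ae_config, ae)

  cl <- config$classifier %||% list()
  cls <- list(kinds = cl$kinds %||% c("xgb", "lr"),
              max_depth = cl$max_depth %||% 5,
              n_estimators = cl$n_estimators %||% 1000,
              scale_pos_weight = cl$scale_pos_weight,
              n_iterations = cl$n_iterations %||% 10,
              cv_folds = cl$cv_folds %||% 5)

  structure(list(cohort = spec, gqi = gq, ae = aecfg, classifier = cls,
                 outdir = config$outdir, seed = config$seed,
                 geometry = config$geometry),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The grid the autoencoder sees: template grids are pruned first.
ae_input_shape_for <- function(grid_shape) {
  if (identical(as.integer(grid_shape), c(91L, 109L, 91L)))
    return(c(88L, 104L, 88L))
  if (any(grid_shape %% 8 != 0))
    stop_invalid("grid %s is not divisible by 8 and has no pruning rule",
                 paste(grid_shape, collapse = "x"))
  as.integer(grid_shape)
}

#' Run the simulate / reconstruct / featurize / classify pipeline
#'
#' Executes the requested stages in order, writing standard-format
#' artifacts under the config's output directory: 4D DWI volumes with
#' bval/bvec files, per-subject GFA/ISO/NQA NIfTI maps, per-index feature
#' CSVs, averaged and best-iteration metric tables, and per-configuration
#' ROC points. Fully deterministic for a fixed config and seed. A stage
#' failure aborts with the stage name; outputs of completed stages are
#' retained together with a `FAILED_<stage>.txt` marker.
#'
#' @param config a [pipeline_config()] (or something coercible to one).
#' @param stages subset of `c("simulate", "reconstruct", "featurize",
#'   "classify")`, in pipeline order; later stages read the files earlier
#'   stages (or earlier runs) left in `outdir`.
#' @return a `run_manifest` data.frame (stage, key, path) of every file
#'   written, invisibly also saved as `run_manifest.csv`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "reconstruct", "featurize",
                                    "classify")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), key = character(),
                         path = character(), stringsAsFactors = FALSE)
  add <- function(stage, key, path) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, key = key, path = path,
                                  stringsAsFactors = FALSE))
  }
  run_stage <- function(name, fun) {
    message(sprintf("[gqidl] stage %s: start (seed %d)", name, config$seed))
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e) {
      marker <- file.path(config$outdir, sprintf("FAILED_%s.txt", name))
      writeLines(conditionMessage(e), marker)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[gqidl] stage %s: done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if ("simulate" %in% stages)
    run_stage("simulate", function() stage_simulate(config, add))
  if ("reconstruct" %in% stages)
    run_stage("reconstruct", function() stage_reconstruct(config, add))
  if ("featurize" %in% stages)
    run_stage("featurize", function() stage_featurize(config, add))
  if ("classify" %in% stages)
    run_stage("classify", function() stage_classify(config, add))

  mpath <- file.path(config$outdir, "run_manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  class(manifest) <- c("run_manifest", "data.frame")
  manifest
}

stage_simulate <- function(config, add) {
  spec <- config$cohort
  man <- cohort_manifest(spec)
  gtab <- cohort_gradient_table(spec)
  dwi_dir <- file.path(config$outdir, "dwi")
  dir.create(dwi_dir, showWarnings = FALSE)
  paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    dwi <- simulate_subject(spec, gtab, man[i, ])
    paths[i] <- file.path(dwi_dir, paste0(man$subject_id[i], "_dwi.nii.gz"))
    write_dwi_nifti(dwi, paths[i])
    add("simulate", man$subject_id[i], paths[i])
  }
  man$dwi_path <- paths
  cpath <- file.path(config$outdir, "cohort_manifest.csv")
  write.csv(man, cpath, row.names = FALSE)
  add("simulate", "cohort_manifest", cpath)
}

read_cohort_manifest <- function(config) {
  cpath <- file.path(config$outdir, "cohort_manifest.csv")
  if (!file.exists(cpath))
    stop_invalid("missing %s; run the simulate stage first", cpath)
  read.csv(cpath, stringsAsFactors = FALSE)
}

stage_reconstruct <- function(config, add) {
  man <- read_cohort_manifest(config)
  map_dir <- file.path(config$outdir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  dirs <- make_direction_set(config$gqi$order)
  for (i in seq_len(nrow(man))) {
    dwi <- read_dwi_nifti(man$dwi_path[i])
    maps <- build_index_maps(dwi, config$gqi, dirs = dirs)
    for (ty in names(maps)) {
      p <- file.path(map_dir, sprintf("%s_%s.nii.gz", man$subject_id[i], ty))
      save_index_map(maps[[ty]], p)
      add("reconstruct", sprintf("%s_%s", man$subject_id[i], ty), p)
    }
  }
}

stage_featurize <- function(config, add) {
  man <- read_cohort_manifest(config)
  feat_dir <- file.path(config$outdir, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  for (ty in c("GFA", "ISO", "NQA")) {
    vols <- lapply(man$subject_id, function(sid) {
      m <- load_index_map(file.path(config$outdir, "maps",
                                    sprintf("%s_%s.nii.gz", sid, ty)))
      v <- m$data
      if (identical(as.integer(dim(v)), c(91L, 109L, 91L)))
        v <- prune_volume(v)
      normalize_intensity(v)
    })
    names(vols) <- man$subject_id
    model <- build_autoencoder(config$ae)
    trained <- train_autoencoder(model, vols)
    feats <- encode_and_flatten(trained$model, vols)
    fpath <- file.path(feat_dir, sprintf("features_%s.csv", ty))
    df <- data.frame(subject_id = rownames(feats), feats,
                     stringsAsFactors = FALSE, check.names = FALSE)
    colnames(df) <- c("subject_id", sprintf("f%05d", seq_len(ncol(feats))))
    write.csv(df, fpath, row.names = FALSE)
    add("featurize", sprintf("features_%s", ty), fpath)
    mpath <- file.path(feat_dir, sprintf("autoencoder_%s.rds", ty))
    saveRDS(list(model = trained$model, loss_history = trained$loss_history),
            mpath)
    add("featurize", sprintf("autoencoder_%s", ty), mpath)
  }
}

stage_classify <- function(config, add) {
  man <- read_cohort_manifest(config)
  met_dir <- file.path(config$outdir, "metrics")
  dir.create(met_dir, showWarnings = FALSE)
  cl <- config$classifier
  halves <- split_nonideation_halves(man[man$group %in% c("HC", "NS"),
                                         c("subject_id", "group")],
                                     seed = derive_seed(config$seed, 3L))
  si_ids <- man$subject_id[man$group == "SI"]
  avg_rows <- list()
  best_rows <- list()
  for (ty in c("GFA", "ISO", "NQA")) {
    fdf <- read.csv(file.path(config$outdir, "features",
                              sprintf("features_%s.csv", ty)),
                    stringsAsFactors = FALSE)
    feats <- as.matrix(fdf[, -1])
    rownames(feats) <- fdf$subject_id
    for (h in 1:2) {
      non_ids <- halves[[h]]$subject_id
      ids <- c(non_ids, si_ids)
      labels <- c(rep(0L, length(non_ids)), rep(1L, length(si_ids)))
      names(labels) <- ids
      for (kind in cl$kinds) {
        spec <- classifier_spec(kind, max_depth = cl$max_depth,
                                n_estimators = cl$n_estimators,
                                scale_pos_weight = cl$scale_pos_weight)
        res <- run_iterated_classification(
          feats[ids, , drop = FALSE], labels, spec,
          random_states = seq_len(cl$n_iterations) - 1L,
          n_folds = cl$cv_folds, index_type = ty, half_id = h)
        avg_rows[[length(avg_rows) + 1]] <- report_row(res$averaged)
        best_rows[[length(best_rows) + 1]] <- report_row(res$best)
        rpath <- file.path(met_dir, sprintf("roc_%s_%s_%d.csv", kind, ty, h))
        write.csv(res$best$roc, rpath, row.names = FALSE)
        add("classify", sprintf("roc_%s_%s_%d", kind, ty, h), rpath)
      }
    }
  }
  for (nm in c("averaged", "best")) {
    rows <- if (nm == "averaged") avg_rows else best_rows
    tab <- do.call(rbind, rows)
    p <- file.path(met_dir, sprintf("metrics_%s.csv", nm))
    write.csv(tab, p, row.names = FALSE)
    add("classify", sprintf("metrics_%s", nm), p)
  }
}

report_row <- function(r) {
  data.frame(model = r$model, index = r$index_type, half = r$half_id,
             cv_acc = r$cv$acc, cv_sen = r$cv$sen, cv_spe = r$cv$spe,
             cv_auc = r$cv$auc,
             test_acc = r$test$acc, test_sen = r$test$sen,
             test_spe = r$test$spe, test_auc = r$test$auc,
             random_state = r$random_state,
             stringsAsFactors = FALSE)
}
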