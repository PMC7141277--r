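#' End-to-end signal-recovery study on a synthetic cohort
#'
#' Runs the full analysis in memory for one index type: simulate every
#' subject of the cohort spec, reconstruct the index map by generalized
#' q-sampling, train the autoencoder on all subjects' normalized maps,
#' extract bottleneck features, and classify ideation vs non-ideation on
#' one stratified half of the non-ideation subjects (concatenated with all
#' SI subjects) under the iterated 4:1:1 protocol. Only one diffusion
#' volume is held in memory at a time, so cohort size is disk- and
#' RAM-friendly.
#'
#' With a strong injected effect the mean test AUC over the iterations is
#' expected to be high; with `effect_delta = 0` the cohort carries no
#' class signal and the mean test AUC calibrates around 0.5.
#'
#' @param spec a [cohort_spec()]; its `effect_delta` defines the injected
#'   group difference.
#' @param gqi a [gqi_config()].
#' @param ae an [ae_config()] whose `input_shape` matches the spec's grid
#'   (built automatically when `NULL`).
#' @param classifier a [classifier_spec()] (default: gradient-boosted
#'   trees with max_depth 5, n_estimators 1000).
#' @param index_type which index map feeds the autoencoder.
#' @param half which non-ideation half to classify (1 or 2).
#' @param random_states split seeds for the iterated evaluation.
#' @param n_folds CV folds.
#' @return list with `mean_test_auc`, `averaged`, `best`, `reports`,
#'   `features`, `labels`, `loss_history`.
#' @export
signal_recovery_study <- function(spec = cohort_spec(),
                                  gqi = gqi_config(),
                                  ae = NULL,
                                  classifier = classifier_spec("xgb"),
                                  index_type = c("GFA", "ISO", "NQA"),
                                  half = 1,
                                  random_states = 0:9,
                                  n_folds = 5L) {
  index_type <- match.arg(index_type)
  if (is.null(ae))
    ae <- ae_config(ae_input_shape_for(spec$grid_shape),
                    seed = derive_seed(spec$seed, 2L))
  man <- cohort_manifest(spec)
  gtab <- cohort_gradient_table(spec)
  dirs <- make_direction_set(gqi$order)

  vols <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    dwi <- simulate_subject(spec, gtab, man[i, ])
    maps <- build_index_maps(dwi, gqi, dirs = dirs)
    v <- maps[[index_type]]$data
    if (identical(as.integer(dim(v)), c(91L, 109L, 91L))) v <- prune_volume(v)
    vols[[i]] <- normalize_intensity(v)
  }
  names(vols) <- man$subject_id

  trained <- train_autoencoder(build_autoencoder(ae), vols)
  feats <- encode_and_flatten(trained$model, vols)

  halves <- split_nonideation_halves(
    man[man$group %in% c("HC", "NS"), c("subject_id", "group")],
    seed = derive_seed(spec$seed, 3L))
  non_ids <- halves[[half]]$subject_id
  si_ids <- man$subject_id[man$group == "SI"]
  ids <- c(non_ids, si_ids)
  labels <- c(rep(0L, length(non_ids)), rep(1L, length(si_ids)))
  names(labels) <- ids

  res <- run_iterated_classification(feats[ids, , drop = FALSE], labels,
                                     classifier,
                                     random_states = random_states,
                                     n_folds = n_folds,
                                     index_type = index_type,
                                     half_id = half)
  list(mean_test_auc = res$averaged$test$auc,
       averaged = res$averaged, best = res$best, reports = res$reports,
       features = feats, labels = labels,
       loss_history = trained$loss_history)
}
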