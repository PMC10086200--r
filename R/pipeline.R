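#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end study analogue: the phantom spec,
#' preprocessing, selection thresholds, the depot-level train/validation
#' split ratio and the seeds.
#'
#' @param phantom A [phantom_spec()] for the development cohort.
#' @param preprocess A [preprocess_config()].
#' @param icc_threshold,r_threshold Selection-cascade thresholds.
#' @param split_ratio Training fraction of the depot-level split (0.7).
#' @param cv_folds LASSO cross-validation folds.
#' @param seed Master seed for split / selection / model / rater-2 masks.
#' @param external Optional list of [phantom_spec()] objects for external
#'   validation cohorts (e.g. a different site seed and `site_hu_shift`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       preprocess = preprocess_config(),
                       icc_threshold = 0.80, r_threshold = 0.90,
                       split_ratio = 0.7, cv_folds = 5, seed = 1L,
                       external = NULL) {
  if (icc_threshold <= 0 || icc_threshold >= 1) stop("icc_threshold must be in (0,1)")
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0,1)")
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0,1)")
  structure(list(phantom = phantom, preprocess = preprocess,
                 icc_threshold = icc_threshold, r_threshold = r_threshold,
                 split_ratio = split_ratio, cv_folds = cv_folds,
                 seed = as.integer(seed), external = external),
            class = "run_config")
}

#' Depot-level train / validation split
#'
#' Seeded stratified split of depots into a training and an internal
#' validation set at the given ratio (7:3 by default), stratified by the
#' depot label so class proportions are preserved to within one depot.
#'
#' @param depot_ids Depot identifiers.
#' @param labels 0/1 depot labels aligned with `depot_ids`.
#' @param ratio Training fraction.
#' @param seed RNG seed.
#' @return Character vector (`"train"` / `"internal"`) named by depot id.
#' @export
split_cohorts <- function(depot_ids, labels, ratio = 0.7, seed = 1L) {
  if (length(depot_ids) < 2L) stop("too few depots to split")
  labels <- as.integer(as.logical(labels))
  set.seed(seed)
  assign <- rep("internal", length(depot_ids))
  # largest-remainder apportionment so the overall split hits the ratio
  # exactly while remaining stratified
  classes <- sort(unique(labels))
  quota <- vapply(classes, function(cl) ratio * sum(labels == cl), 0)
  n_tr_cl <- floor(quota)
  rem <- round(ratio * length(labels)) - sum(n_tr_cl)
  if (rem > 0) {
    extra <- order(quota - n_tr_cl, decreasing = TRUE)[seq_len(rem)]
    n_tr_cl[extra] <- n_tr_cl[extra] + 1
  }
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    assign[sample(idx, min(n_tr_cl[k], length(idx)))] <- "train"
  }
  setNames(assign, depot_ids)
}

evaluate_cohort_depots <- function(calls, truth_flags, level = "depot") {
  diagnostics(calls$rs, truth_flags, cutoff = NULL, level = level)
}

classify_and_evaluate <- function(model, features, truth, cutoff = model$cutoff) {
  calls <- classify_depots(model, features, cutoff)
  list(calls = calls,
       summary = diagnostics(calls$rs, truth, cutoff = cutoff, level = "depot"))
}

#' Run the end-to-end BAT radiomics study analogue
#'
#' Simulate, label, extract, select, train, diagnose, score calcium and
#' evaluate, following the study design: two-rater feature extraction on
#' the development cohort, ICC and Pearson redundancy filters, LASSO on the
#' training depots, an RBF-SVM radiomics score with a Youden cutoff fixed on
#' the training set, per-depot and per-patient diagnostics (both patient
#' criteria), and Agatston calcium comparison between the model-defined
#' BAT-RS and non-BAT-RS patient groups. Identical configuration implies an
#' identical manifest.
#'
#' @param config A [run_config()].
#' @param progress Print stage progress.
#' @return A manifest list; see the elements `selection`, `model`,
#'   `depot_diagnostics`, `patient_diagnostics`, `calcium`, `external`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  say <- function(...) if (progress) message(format(Sys.time(), "%H:%M:%S "), ...)
  say("simulating development cohort")
  cohort <- generate_cohort(config$phantom)

  say("BARCIST labeling")
  depot_labels <- label_cohort(cohort)
  truth <- cohort$truth$depots
  lab <- depot_labels$bat_flag[match(truth$depot_id, depot_labels$depot_id)]

  say("second-rater mask perturbation")
  set.seed(config$seed + 1L)
  masks2 <- list()
  for (p in cohort$patients)
    for (roi in p$depots) masks2[[roi$depot_id]] <- perturb_mask(roi$mask)

  say("feature extraction (rater 1)")
  feats1 <- extract_cohort_features(cohort, config$preprocess)
  say("feature extraction (rater 2)")
  feats2 <- extract_cohort_features(cohort, config$preprocess, masks = masks2)
  stopifnot(identical(feats1$depot_id, truth$depot_id))

  say("depot-level 7:3 split")
  split <- split_cohorts(truth$depot_id, lab, config$split_ratio, config$seed)
  tr <- split[feats1$depot_id] == "train"

  say("feature selection cascade")
  selection <- select_features(feats1, feats2, lab,
                               icc_threshold = config$icc_threshold,
                               r_threshold = config$r_threshold,
                               cv_folds = config$cv_folds, seed = config$seed,
                               train_rows = tr)

  say("SVM training")
  model <- train_depot_model(feats1[tr, , drop = FALSE], lab[tr],
                             feature_list = selection$final, seed = config$seed)

  say("depot diagnostics")
  calls_all <- classify_depots(model, feats1)
  depot_diag <- list(
    train = diagnostics(calls_all$rs[tr], lab[tr], cutoff = model$cutoff),
    internal = diagnostics(calls_all$rs[!tr], lab[!tr], cutoff = model$cutoff))

  say("patient diagnostics")
  patient_calls <- call_patients(calls_all)
  ptruth <- cohort$truth$patients
  pord <- match(patient_calls$patient_id, ptruth$patient_id)
  patient_diag <- list(
    criterion1 = diagnostics(as.numeric(patient_calls$criterion1),
                             ptruth$bat_flag[pord], level = "patient"),
    criterion2 = diagnostics(as.numeric(patient_calls$criterion2),
                             ptruth$bat_flag[pord], level = "patient"))

  say("calcium scoring")
  calcium_tab <- do.call(rbind, lapply(cohort$patients, function(p) {
    do.call(rbind, lapply(names(p$territories), function(tn) {
      res <- score_territory(p$ct, p$territories[[tn]], tn)
      data.frame(patient_id = p$patient_id, territory = tn,
                 agatston_score = res$agatston_score,
                 calcium_volume = res$calcium_volume)
    }))
  }))
  rs_group <- setNames(patient_calls$criterion2, patient_calls$patient_id)
  calcium <- lapply(split(calcium_tab, calcium_tab$territory), function(d) {
    g <- rs_group[d$patient_id]
    territory_compare(list(bat_rs = d[g, , drop = FALSE],
                           non_bat_rs = d[!g, , drop = FALSE]))
  })

  external <- NULL
  if (!is.null(config$external)) {
    external <- lapply(config$external, function(espec) {
      say("external cohort (seed ", espec$rng_seed, ")")
      eco <- generate_cohort(espec)
      elab_tab <- label_cohort(eco)
      etruth <- eco$truth$depots
      elab <- elab_tab$bat_flag[match(etruth$depot_id, elab_tab$depot_id)]
      efeats <- extract_cohort_features(eco, config$preprocess)
      ecalls <- classify_depots(model, efeats)
      epat <- call_patients(ecalls)
      eptruth <- eco$truth$patients
      epord <- match(epat$patient_id, eptruth$patient_id)
      list(depot = diagnostics(ecalls$rs, elab, cutoff = model$cutoff),
           patient_criterion1 = diagnostics(as.numeric(epat$criterion1),
                                            eptruth$bat_flag[epord], level = "patient"),
           patient_criterion2 = diagnostics(as.numeric(epat$criterion2),
                                            eptruth$bat_flag[epord], level = "patient"),
           covariates = eptruth)
    })
  }

  say("done")
  list(config = config, truth = cohort$truth, depot_labels = depot_labels,
       split = split, features = feats1, selection = selection, model = model,
       depot_calls = calls_all, depot_diagnostics = depot_diag,
       patient_calls = patient_calls, patient_diagnostics = patient_diag,
       calcium_by_patient = calcium_tab, calcium = calcium,
       external = external)
}
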