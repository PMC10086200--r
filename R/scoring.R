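#' Train the depot-level BAT classifier
#'
#' Fits an RBF-kernel support vector machine on the selected features,
#' with probability calibration (Platt-style logistic mapping fitted by
#' internal cross-validation) providing the radiomics score RS in \[0, 1\],
#' inverse-class-frequency weights for the BAT/non-BAT imbalance, and an RBF
#' bandwidth from the inverse-median-distance heuristic. The RS cutoff RS*
#' is fixed on the training scores by the Youden index.
#'
#' @param features Feature table or matrix (training depots).
#' @param labels 0/1 depot labels.
#' @param feature_list Character vector of model features (e.g. a selection
#'   report's `final`); defaults to all columns.
#' @param seed RNG seed for the probability-calibration folds.
#' @param cost SVM cost parameter.
#' @return An object of class `depot_model` with elements `svm`, `features`,
#'   `center`, `scale`, `cutoff`, `train_scores`, `seed`.
#' @export
train_depot_model <- function(features, labels, feature_list = NULL,
                              seed = 1L, cost = 1) {
  x <- if (is.data.frame(features)) feature_matrix(features)$x else as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(as.integer(as.logical(labels)), levels = c(0, 1))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (!is.null(feature_list)) {
    missing <- setdiff(feature_list, colnames(x))
    if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
    x <- x[, feature_list, drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  # inverse-median-distance heuristic for the RBF bandwidth
  sub <- xs[sample_idx(nrow(xs), 200L, seed), , drop = FALSE]
  med <- median(stats::dist(sub))
  gamma <- if (is.finite(med) && med > 0) 1 / (2 * med^2) else 1 / ncol(xs)
  cw <- length(y) / (2 * table(y))
  set.seed(seed)
  sv <- e1071::svm(xs, y, kernel = "radial", gamma = gamma, cost = cost,
                   probability = TRUE, class.weights = cw, scale = FALSE)
  pr <- attr(predict(sv, xs, probability = TRUE), "probabilities")[, "1"]
  cutoff <- youden_cutoff(pr, as.integer(as.character(y)))
  structure(list(svm = sv, features = colnames(x), center = ctr, scale = scl,
                 gamma = gamma, cost = cost, cutoff = cutoff$cutoff,
                 cutoff_info = cutoff, train_scores = pr, seed = seed),
            class = "depot_model")
}

sample_idx <- function(n, k, seed) {
  if (n <= k) return(seq_len(n))
  set.seed(seed)
  sample.int(n, k)
}

#' @export
print.depot_model <- function(x, ...) {
  cat("<depot_model> RBF SVM,", length(x$features), "features, RS* =",
      signif(x$cutoff, 3), "\n")
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed scores,
#' evaluating each candidate t with the rule "positive iff score >= t"; ties
#' in J resolve toward the higher threshold (favouring specificity). A
#' degenerate optimum (J <= 0, e.g. inverted or all-equal scores) is
#' returned with `degenerate = TRUE`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 truth.
#' @return List: `cutoff`, `J`, `sensitivity`, `specificity`, `degenerate`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  J <- vapply(cand, function(t) {
    sens <- sum(scores >= t & labels == 1) / n1
    spec <- sum(scores < t & labels == 0) / n0
    sens + spec - 1
  }, 0)
  best <- max(J)
  t <- max(cand[J == best])           # tie -> higher threshold
  sens <- sum(scores >= t & labels == 1) / n1
  spec <- sum(scores < t & labels == 0) / n0
  list(cutoff = t, J = best, sensitivity = sens, specificity = spec,
       degenerate = best <= 0)
}

#' Score and classify depots
#'
#' Computes the radiomics score RS for each depot and calls it positive iff
#' RS is strictly greater than the cutoff (RS > RS*).
#'
#' @param model A [train_depot_model()] fit.
#' @param features Feature table or matrix covering the model's features.
#' @param cutoff Cutoff override; defaults to the model's RS*.
#' @return Data frame with depot metadata (if present), `rs` and `positive`.
#' @export
classify_depots <- function(model, features, cutoff = model$cutoff) {
  if (is.data.frame(features)) {
    fm <- feature_matrix(features)
    meta <- fm$meta; x <- fm$x
  } else { meta <- NULL; x <- as.matrix(features) }
  missing <- setdiff(model$features, colnames(x))
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  xs <- scale(x[, model$features, drop = FALSE],
              model$center[model$features], model$scale[model$features])
  rs <- attr(predict(model$svm, xs, probability = TRUE), "probabilities")[, "1"]
  out <- data.frame(rs = as.numeric(rs), positive = as.numeric(rs) > cutoff)
  if (!is.null(meta)) out <- cbind(meta, out)
  out
}

#' Per-patient BAT diagnosis
#'
#' Applies the two patient-level rules to depot calls. Criterion 1: the
#' patient is BAT positive iff at least one depot is positive. Criterion 2:
#' positive iff some bilateral region (cervical, supraclavicular or
#' axillary) has both a positive left and a positive right depot, or any
#' mediastinal depot is positive. Criterion-2 positivity implies
#' criterion-1 positivity by construction.
#'
#' @param depot_calls Data frame with `patient_id`, `region`, `laterality`,
#'   `positive` (e.g. from [classify_depots()]).
#' @param criterion 1, 2, or "both" (default).
#' @return Data frame: `patient_id`, `criterion1`, `criterion2` (as
#'   requested), and supporting depot counts.
#' @export
call_patients <- function(depot_calls, criterion = "both") {
  need <- c("patient_id", "region", "laterality", "positive")
  if (!all(need %in% names(depot_calls))) stop("depot_calls must have: ", paste(need, collapse = ", "))
  bilateral <- c("cervical", "supraclavicular", "axillary")
  res <- lapply(split(depot_calls, depot_calls$patient_id), function(d) {
    for (rg in intersect(unique(d$region), bilateral)) {
      sides <- d$laterality[d$region == rg]
      if (sum(sides == "left") != sum(sides == "right"))
        stop("bilateral depot missing its partner (", d$patient_id[1], ", ", rg, ")")
    }
    c1 <- any(d$positive)
    sym <- any(vapply(bilateral, function(rg) {
      any(d$positive[d$region == rg & d$laterality == "left"]) &&
        any(d$positive[d$region == rg & d$laterality == "right"])
    }, TRUE))
    med <- any(d$positive[d$region == "mediastinal"])
    data.frame(patient_id = d$patient_id[1], criterion1 = c1,
               criterion2 = sym || med, n_positive = sum(d$positive))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (identical(criterion, 1) || identical(criterion, 1L)) out$criterion2 <- NULL
  if (identical(criterion, 2) || identical(criterion, 2L)) out$criterion1 <- NULL
  out
}
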