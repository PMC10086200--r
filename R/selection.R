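#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures — the
#' conventional form for inter-observer reproducibility. Computed from the
#' two-way ANOVA mean squares: with n targets and k raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param x Numeric matrix, targets (depots) x raters.
#' @return ICC point estimate; 1 for perfect agreement, 0-ish for noise.
#'   Zero-variance degenerate tables return 1 if the raters agree exactly,
#'   otherwise 0.
#' @export
icc_agreement <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("ICC needs at least 3 targets")
  gm <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((x - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(den) < 1e-12) return(if (SST < 1e-12) 1 else 0)
  (MSR - MSE) / den
}

#' Second-rater mask perturbation
#'
#' Emulates an independent observer's segmentation. Manual depot
#' segmentation is performed slice by slice, so the perturbation is
#' in-plane: a random 1-pixel (4-connected) in-plane dilation or erosion,
#' followed by in-plane boundary jitter (each boundary pixel flips with
#' probability `jitter`). Erosions that would empty the mask fall back to
#' dilation.
#'
#' @param mask Binary 3D array.
#' @param jitter Per-boundary-pixel flip probability.
#' @return Perturbed binary mask (never empty).
#' @export
perturb_mask <- function(mask, jitter = 0.2) {
  m <- array(as.integer(mask != 0), dim(mask))
  if (runif(1) < 0.5) {
    m2 <- morph_inplane(m, "erode")
    if (sum(m2) < 3L) m2 <- morph_inplane(m, "dilate")
  } else m2 <- morph_inplane(m, "dilate")
  dil <- morph_inplane(m2, "dilate"); er <- morph_inplane(m2, "erode")
  boundary <- which(dil != er)       # pixels whose membership is edge-determined
  flip <- boundary[runif(length(boundary)) < jitter]
  m2[flip] <- 1L - m2[flip]
  if (sum(m2) < 3L) m2 <- m
  m2
}

# in-plane (row/column) 4-connected binary morphology
morph_inplane <- function(m, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(m)
  shifted <- function(dr, dc) {
    out <- array(0L, d)
    rs <- seq_len(d[2]); cs <- seq_len(d[3])
    rd <- rs - dr; cd <- cs - dc
    okr <- rd >= 1 & rd <= d[2]; okc <- cd >= 1 & cd <= d[3]
    out[, rs[okr], cs[okc]] <- m[, rd[okr], cd[okc]]
    out
  }
  nb <- list(shifted(1, 0), shifted(-1, 0), shifted(0, 1), shifted(0, -1))
  if (op == "dilate") {
    out <- m
    for (s in nb) out <- pmax(out, s)
  } else {
    out <- m
    for (s in nb) out <- pmin(out, s)
  }
  array(as.integer(out), d)
}

#' ICC reproducibility filter
#'
#' Computes ICC(2,1) per feature across depots between two segmentations and
#' flags features with ICC below the threshold for removal.
#'
#' @param features_rater1,features_rater2 Feature tables from
#'   [extract_cohort_features()] covering the same depots.
#' @param threshold ICC threshold (default 0.80).
#' @return List: `icc` (named vector), `keep` (names), `removed`
#'   (data frame with reason `"icc"`).
#' @export
icc_filter <- function(features_rater1, features_rater2, threshold = 0.80) {
  f1 <- feature_matrix(features_rater1)
  f2 <- feature_matrix(features_rater2)
  ord <- match(f1$meta$depot_id, f2$meta$depot_id)
  if (any(is.na(ord))) stop("the two tables must cover the same depots")
  x2 <- f2$x[ord, , drop = FALSE]
  if (nrow(f1$x) < 3L) stop("ICC needs at least 3 depots")
  icc <- vapply(seq_len(ncol(f1$x)),
                function(k) icc_agreement(cbind(f1$x[, k], x2[, k])), 0)
  names(icc) <- colnames(f1$x)
  keep <- names(icc)[icc >= threshold]
  gone <- setdiff(names(icc), keep)
  removed <- data.frame(feature = gone, reason = rep("icc", length(gone)))
  list(icc = icc, keep = keep, removed = removed, threshold = threshold)
}

#' Pearson redundancy pruning
#'
#' Greedy pairwise pruning: among feature pairs with |Pearson r| above the
#' threshold (scanned in order of descending |r|, ties broken
#' lexicographically by feature names), the member with the lower
#' point-biserial correlation (|Pearson r| against the 0/1 BAT label) is
#' removed. Constant columns have correlation 0 by definition.
#'
#' @param features Feature table (or numeric matrix) after the ICC filter.
#' @param labels Logical/0-1 depot labels aligned with rows.
#' @param r_threshold Redundancy threshold (default 0.90).
#' @return List: `keep`, `removed` (reason `"redundancy"`), `n_pairs`.
#' @export
redundancy_prune <- function(features, labels, r_threshold = 0.90) {
  x <- if (is.data.frame(features)) feature_matrix(features)$x else as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels))
  safe_cor <- function(m, y = NULL) {
    s <- apply(m, 2, stats::sd)
    ok <- s > 0
    out <- if (is.null(y)) matrix(0, ncol(m), ncol(m),
                                  dimnames = list(colnames(m), colnames(m)))
           else setNames(numeric(ncol(m)), colnames(m))
    if (is.null(y)) {
      if (any(ok)) out[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
      diag(out) <- 1
    } else if (any(ok) && stats::sd(y) > 0) {
      out[ok] <- as.vector(stats::cor(m[, ok, drop = FALSE], y))
    }
    out
  }
  cm <- abs(safe_cor(x))
  lab_cor <- abs(safe_cor(x, labels))
  pairs <- which(upper.tri(cm) & cm > r_threshold, arr.ind = TRUE)
  alive <- setNames(rep(TRUE, ncol(x)), colnames(x))
  removed <- character(0)
  if (nrow(pairs) > 0) {
    fn <- colnames(x)
    o <- order(-cm[pairs], fn[pairs[, 1]], fn[pairs[, 2]])
    pairs <- pairs[o, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (!alive[a] || !alive[b]) next
      drop <- if (lab_cor[a] < lab_cor[b]) a
              else if (lab_cor[b] < lab_cor[a]) b
              else max(a, b)            # tie: drop the lexicographically later
      alive[drop] <- FALSE
      removed <- c(removed, colnames(x)[drop])
    }
  }
  list(keep = colnames(x)[alive],
       removed = if (length(removed))
         data.frame(feature = removed, reason = "redundancy")
         else data.frame(feature = character(0), reason = character(0)),
       n_pairs = nrow(pairs))
}

#' LASSO feature selection
#'
#' L1-penalized linear regression of the 0/1 depot label on standardized
#' features. The penalty is chosen by cross-validated AUROC over the glmnet
#' penalty path with seeded folds; features with nonzero coefficients at the
#' chosen penalty form the final set (ties in CV AUROC resolve toward the
#' stronger penalty).
#'
#' @param features Feature table or matrix (post-pruning).
#' @param labels 0/1 depot labels.
#' @param cv_folds Number of folds.
#' @param seed Fold-assignment seed.
#' @return List: `keep`, `lambda`, `lambda_path`, `cv_auc`, `coefficients`.
#' @export
lasso_select <- function(features, labels, cv_folds = 5, seed = 1L) {
  x <- if (is.data.frame(features)) feature_matrix(features)$x else as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  fit <- glmnet::glmnet(xs, y, family = "gaussian", standardize = FALSE)
  lambdas <- fit$lambda
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = length(y)))
  preds <- matrix(NA_real_, length(y), length(lambdas))
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    fk <- glmnet::glmnet(xs[tr, , drop = FALSE], y[tr], family = "gaussian",
                         standardize = FALSE, lambda = lambdas)
    preds[!tr, ] <- predict(fk, xs[!tr, , drop = FALSE])
  }
  cv_auc <- apply(preds, 2, function(p) {
    if (anyNA(p)) return(NA_real_)
    auroc(p, y)
  })
  best <- which(cv_auc == max(cv_auc, na.rm = TRUE))[1]   # path is decreasing in lambda
  beta <- coef(fit, s = lambdas[best])[-1, 1]
  keep <- names(beta)[beta != 0]
  if (length(keep) == 0L)
    stop("LASSO selected no features at any cross-validated penalty; ",
         "use a weaker penalty grid or stronger signal")
  list(keep = keep, lambda = lambdas[best], lambda_path = lambdas,
       cv_auc = cv_auc, coefficients = beta[beta != 0])
}

#' Three-stage feature-selection cascade
#'
#' ICC reproducibility filter, then Pearson redundancy pruning, then LASSO,
#' producing a selection report with one removal reason per excluded
#' feature.
#'
#' @param features,features_rater2 Feature tables for the two segmentations.
#' @param labels 0/1 depot labels aligned with `features` rows.
#' @param icc_threshold,r_threshold,cv_folds,seed Stage parameters.
#' @param train_rows Optional logical vector: rows used by the supervised
#'   stages (redundancy pruning and LASSO). The unsupervised ICC stage
#'   always uses all depots.
#' @return An object of class `selection_report`: `final` (feature names),
#'   `counts` (census / post-ICC / post-prune / final), `removed`, `icc`,
#'   `lasso`.
#' @export
select_features <- function(features, features_rater2, labels,
                            icc_threshold = 0.80, r_threshold = 0.90,
                            cv_folds = 5, seed = 1L, train_rows = NULL) {
  st1 <- icc_filter(features, features_rater2, icc_threshold)
  fm <- feature_matrix(features)
  if (is.null(train_rows)) train_rows <- rep(TRUE, nrow(fm$x))
  x1 <- fm$x[train_rows, st1$keep, drop = FALSE]
  labels <- labels[train_rows]
  st2 <- redundancy_prune(x1, labels, r_threshold)
  x2 <- x1[, st2$keep, drop = FALSE]
  st3 <- lasso_select(x2, labels, cv_folds, seed)
  lasso_gone <- setdiff(st2$keep, st3$keep)
  removed <- rbind(st1$removed, st2$removed,
                   data.frame(feature = lasso_gone,
                              reason = rep("lasso", length(lasso_gone))))
  stopifnot(!anyDuplicated(removed$feature))
  structure(list(final = st3$keep,
                 counts = c(census = ncol(fm$x), post_icc = length(st1$keep),
                            post_prune = length(st2$keep), final = length(st3$keep)),
                 removed = removed, icc = st1$icc, lasso = st3),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>", paste(names(x$counts), x$counts, collapse = " -> "), "\n")
  invisible(x)
}
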