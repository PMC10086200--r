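#' Rank-based AUROC
#'
#' Area under the ROC curve computed as the concordant-pair fraction
#' (Mann-Whitney statistic with midrank tie handling): ties contribute 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 truth.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement-based variance for the AUROC
delong_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  auc <- auroc(scores, labels)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), 0)
  v01 <- vapply(ys, function(y) mean(psi(xs, y)), 0)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se), se = se)
}

clopper_pearson <- function(k, n, conf = 0.95) {
  a <- 1 - conf
  lower <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Diagnostic performance summary
#'
#' Sensitivity, specificity, PPV, NPV and accuracy with exact
#' Clopper-Pearson 95% intervals, plus the rank AUROC with a DeLong interval
#' and, when a cutoff is supplied, the "AUROC-cutoff" of the binarized
#' prediction (the rank AUROC of the 0/1 calls, which equals
#' (sensitivity + specificity) / 2).
#'
#' @param scores_or_calls Numeric scores, or logical/0-1 calls.
#' @param truth 0/1 truth.
#' @param cutoff Optional threshold; calls are `score > cutoff`.
#' @param level Free-text tag (`"depot"` or `"patient"`).
#' @param conf Confidence level.
#' @return An object of class `diagnostic_summary` (a data frame of metric,
#'   estimate, lower, upper) with the confusion counts as attributes.
#' @export
diagnostics <- function(scores_or_calls, truth, cutoff = NULL,
                        level = "depot", conf = 0.95) {
  truth <- as.integer(as.logical(truth))
  s <- as.numeric(scores_or_calls)
  calls <- if (!is.null(cutoff)) as.integer(s > cutoff) else as.integer(s != 0)
  is_binary <- all(s %in% c(0, 1))
  tp <- sum(calls == 1 & truth == 1); fn <- sum(calls == 0 & truth == 1)
  tn <- sum(calls == 0 & truth == 0); fp <- sum(calls == 1 & truth == 0)
  prop <- function(k, n) {
    if (n == 0) return(c(NA, NA, NA))
    c(k / n, clopper_pearson(k, n, conf))
  }
  rows <- rbind(sensitivity = prop(tp, tp + fn),
                specificity = prop(tn, tn + fp),
                ppv = prop(tp, tp + fp),
                npv = prop(tn, tn + fn),
                accuracy = prop(tp + tn, tp + fn + tn + fp))
  both <- length(unique(truth)) == 2L
  if (both) {
    a <- auroc(s, truth); ci <- delong_ci(s, truth, conf)
    rows <- rbind(rows, auroc = c(a, ci["lower"], ci["upper"]))
    if (!is.null(cutoff) || is_binary) {
      ac <- auroc(calls, truth); cic <- delong_ci(calls, truth, conf)
      rows <- rbind(rows, auroc_cutoff = c(ac, cic["lower"], cic["upper"]))
    }
  }
  out <- data.frame(metric = rownames(rows), estimate = rows[, 1],
                    lower = rows[, 2], upper = rows[, 3], row.names = NULL)
  attr(out, "counts") <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  attr(out, "level") <- level
  class(out) <- c("diagnostic_summary", class(out))
  out
}

#' 1:1 propensity-score matching
#'
#' Logistic-regression propensity scores, then greedy nearest-neighbour
#' matching without replacement: cases are visited in a seeded random order
#' and each takes the closest unmatched control on the propensity scale,
#' provided the distance is within the caliper.
#'
#' @param cases,controls Data frames of covariates.
#' @param covariates Covariate column names.
#' @param caliper Maximum propensity distance (default 0.1).
#' @param seed Visit-order seed.
#' @return List: `pairs` (data frame of case/control row indices and
#'   distance), `propensity_model`, `unmatched_cases`, `unmatched_controls`.
#' @export
propensity_match <- function(cases, controls, covariates, caliper = 0.1, seed = 1L) {
  dat <- rbind(cbind(cases[, covariates, drop = FALSE], .case = 1),
               cbind(controls[, covariates, drop = FALSE], .case = 0))
  fit <- suppressWarnings(glm(.case ~ ., data = dat, family = binomial()))
  if (!fit$converged || any(abs(coef(fit)[-1]) > 50, na.rm = TRUE))
    stop("degenerate propensity fit (possible perfect separation); check covariates")
  ps <- predict(fit, type = "response")
  ps_case <- ps[seq_len(nrow(cases))]
  ps_ctrl <- ps[nrow(cases) + seq_len(nrow(controls))]
  set.seed(seed)
  order_cases <- sample.int(length(ps_case))
  avail <- rep(TRUE, length(ps_ctrl))
  pairs <- list()
  for (i in order_cases) {
    d <- abs(ps_ctrl - ps_case[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      avail[j] <- FALSE
      pairs[[length(pairs) + 1L]] <- data.frame(case = i, control = j, distance = d[j])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(case = integer(0), control = integer(0), distance = numeric(0))
  list(pairs = pairs, propensity_model = fit,
       propensity = list(cases = ps_case, controls = ps_ctrl),
       unmatched_cases = setdiff(seq_along(ps_case), pairs$case),
       unmatched_controls = which(avail), caliper = caliper)
}

#' Two-group comparison with automatic test routing
#'
#' Continuous data: a Kolmogorov-Smirnov normality screen on each group
#' routes to Student's t-test (both compatible with normality) or the
#' Mann-Whitney rank test. Categorical data: chi-squared when all expected
#' counts are at least 5, otherwise Fisher's exact test. Two-sided p-values.
#'
#' @param x,y The two groups: numeric vectors (continuous) or factors/
#'   character (categorical).
#' @param kind `"continuous"` or `"categorical"`.
#' @param alpha Normality-screen level.
#' @return List: `test` (name), `p_value`, `statistic`, `normal` (screen
#'   outcome, continuous only).
#' @export
group_compare <- function(x, y, kind = c("continuous", "categorical"), alpha = 0.05) {
  kind <- match.arg(kind)
  if (!length(x) || !length(y)) stop("empty group")
  if (kind == "continuous") {
    norm_p <- function(v) {
      # tiny groups cannot support a normality claim -> nonparametric route
      if (length(v) < 8L || length(unique(v)) < 3L || stats::sd(v) == 0) return(0)
      suppressWarnings(ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
    }
    normal <- norm_p(x) > alpha && norm_p(y) > alpha
    if (normal) {
      tt <- t.test(x, y)
      list(test = "t", p_value = tt$p.value, statistic = unname(tt$statistic), normal = TRUE)
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, exact = length(x) + length(y) <= 30))
      list(test = "mann-whitney", p_value = wt$p.value,
           statistic = unname(wt$statistic), normal = FALSE)
    }
  } else {
    tab <- table(group = rep(c("x", "y"), c(length(x), length(y))), value = c(x, y))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(exp_counts >= 5)) {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      list(test = "chi-squared", p_value = ct$p.value, statistic = unname(ct$statistic))
    } else {
      ft <- fisher.test(tab)
      list(test = "fisher", p_value = ft$p.value, statistic = NA_real_)
    }
  }
}
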