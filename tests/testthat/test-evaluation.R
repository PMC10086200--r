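test_that("confusion metrics match hand arithmetic", {
  # TP=2, FN=0, TN=1, FP=1
  d <- diagnostics(c(1, 1, 1, 0), c(1, 1, 0, 0))
  est <- setNames(d$estimate, d$metric)
  expect_equal(unname(est["sensitivity"]), 1.0)
  expect_equal(unname(est["specificity"]), 0.5)
  expect_equal(unname(est["accuracy"]), 0.75)
  expect_equal(unname(est["ppv"]), 2 / 3)
  expect_equal(unname(est["npv"]), 1.0)
  expect_true(all(d$lower <= d$estimate & d$estimate <= d$upper))
  expect_equal(sum(attr(d, "counts")), 4)
})

test_that("AUROC handles perfect, tied and inverted score patterns", {
  expect_equal(auroc(c(.1, .2, .8, .9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auroc(c(.9, .8, .1), c(0, 0, 1)), 0)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC equals the exhaustive concordant-pair fraction for n <= 12", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("AUROC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE)))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("label swap exchanges sensitivity/specificity and reflects AUROC", {
  set.seed(7)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  d1 <- diagnostics(scores, labels, cutoff = 0.5)
  d2 <- diagnostics(1 - scores, 1 - labels, cutoff = 1 - 0.5 - 1e-12)
  g <- function(d, m) d$estimate[d$metric == m]
  expect_equal(g(d1, "sensitivity"), g(d2, "specificity"))
  expect_equal(g(d1, "auroc"), 1 - auroc(scores, 1 - labels))
})

test_that("the binarized AUROC-cutoff equals (sens + spec) / 2", {
  set.seed(12)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  d <- diagnostics(scores, labels, cutoff = 0.4)
  g <- function(m) d$estimate[d$metric == m]
  expect_equal(g("auroc_cutoff"), (g("sensitivity") + g("specificity")) / 2)
})

test_that("single-class truth still yields proportion metrics but no AUROC", {
  d <- diagnostics(c(1, 0, 1), c(1, 1, 1))
  expect_false("auroc" %in% d$metric)
  expect_equal(d$estimate[d$metric == "sensitivity"], 2 / 3)
})

test_that("identical covariates match at distance zero; far controls never match", {
  cases <- data.frame(age = c(40, 50, 60), sex = c(0, 1, 0), weight = c(60, 70, 80))
  res <- propensity_match(cases, cases, c("age", "sex", "weight"))
  expect_equal(nrow(res$pairs), 3)
  expect_true(all(res$pairs$distance < 1e-9))

  set.seed(13)
  cs <- data.frame(age = rnorm(20, 30, 2))
  ct <- data.frame(age = rnorm(20, 80, 2))
  res2 <- propensity_match(cs, ct, "age", caliper = 0.1)
  expect_equal(nrow(res2$pairs), 0)
  expect_equal(sort(res2$unmatched_cases), 1:20)
})

test_that("greedy matching follows the stated seeded order on hand propensities", {
  set.seed(5)
  n <- 30
  cases <- data.frame(x = rnorm(n, 1), y = rnorm(n))
  controls <- data.frame(x = rnorm(2 * n, 0), y = rnorm(2 * n))
  res <- propensity_match(cases, controls, c("x", "y"), caliper = 0.1, seed = 9)
  ps_case <- res$propensity$cases
  ps_ctrl <- res$propensity$controls
  # replay the stated algorithm from the published propensities
  set.seed(9)
  ord <- sample.int(length(ps_case))
  avail <- rep(TRUE, length(ps_ctrl))
  replay <- list()
  for (i in ord) {
    d <- abs(ps_ctrl - ps_case[i]); d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= 0.1) {
      avail[j] <- FALSE
      replay[[length(replay) + 1]] <- c(i, j)
    }
  }
  replay <- do.call(rbind, replay)
  expect_equal(res$pairs$case, replay[, 1])
  expect_equal(res$pairs$control, replay[, 2])
  expect_true(all(res$pairs$distance <= 0.1))
})

test_that("group comparison routes tests by normality and expected counts", {
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40, 0.2)
  res <- group_compare(a, b)
  expect_equal(res$test, "t")
  expect_true(res$normal)

  skewed <- rlnorm(40, 0, 2); skewed2 <- rlnorm(40, 0.2, 2)
  res2 <- group_compare(skewed, skewed2)
  expect_equal(res2$test, "mann-whitney")

  # identical tiny groups: exact rank test gives p = 1
  res3 <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$test, "mann-whitney")
  expect_equal(res3$p_value, 1)

  big <- group_compare(factor(rep(c("a", "b"), c(30, 30))),
                       factor(rep(c("a", "b"), c(15, 45))), "categorical")
  expect_equal(big$test, "chi-squared")

  small <- group_compare(factor(rep(c("a", "b"), c(5, 0)), levels = c("a", "b")),
                         factor(rep(c("a", "b"), c(0, 5)), levels = c("a", "b")),
                         "categorical")
  expect_equal(small$test, "fisher")
  # hypergeometric tail of the 5/0 vs 0/5 table by enumeration
  expect_equal(small$p_value, 2 / choose(10, 5))
  expect_error(group_compare(numeric(0), 1:3), "empty")
})
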