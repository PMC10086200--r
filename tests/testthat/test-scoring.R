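test_that("Youden cutoff matches brute-force threshold enumeration", {
  yc <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yc$cutoff, 0.8)           # tie resolves to the higher threshold
  expect_equal(yc$J, 1)
  expect_false(yc$degenerate)

  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)          # duplicates on purpose
    mine <- youden_cutoff(scores, labels)
    ref <- oracle_youden(scores, labels)
    expect_equal(mine$cutoff, ref$cutoff)
    expect_equal(mine$J, ref$J)
  }
})

test_that("degenerate score patterns are flagged", {
  inv <- youden_cutoff(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_true(inv$degenerate)
  expect_equal(inv$J, 0)
  tied <- youden_cutoff(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_true(tied$degenerate)
  expect_equal(tied$J, 0)
  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("a linearly separable toy problem is learned essentially perfectly", {
  set.seed(2)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = lab * 4 + rnorm(n, sd = 0.2), f2 = rnorm(n))
  m <- train_depot_model(x, lab, seed = 7)
  calls <- classify_depots(m, x)
  expect_equal(auroc(calls$rs, lab), 1)
  # the Youden optimum sits AT the lowest positive score and depot calls are
  # strictly greater-than, so that single boundary depot may fall negative
  expect_lte(sum(as.numeric(calls$positive) != lab), 1)
  expect_true(all(calls$positive[calls$rs > m$cutoff]))
  expect_true(m$cutoff > 0 && m$cutoff < 1)
  expect_error(train_depot_model(x, rep(0, n)), "single class")
})

test_that("training is reproducible under a fixed seed", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  lab <- rbinom(50, 1, 0.5); lab[1:2] <- c(0, 1)
  m1 <- train_depot_model(x, lab, seed = 11)
  m2 <- train_depot_model(x, lab, seed = 11)
  expect_identical(m1$cutoff, m2$cutoff)
  expect_identical(classify_depots(m1, x)$rs, classify_depots(m2, x)$rs)
})

test_that("depot positivity is strict at the cutoff", {
  set.seed(2)
  n <- 40
  lab <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = lab + rnorm(n, sd = 0.3), f2 = rnorm(n))
  m <- train_depot_model(x, lab, seed = 1)
  calls <- classify_depots(m, x)
  expect_equal(calls$positive, calls$rs > m$cutoff)
  # at RS exactly equal to the cutoff the call is negative
  calls2 <- classify_depots(m, x, cutoff = calls$rs[5])
  expect_false(calls2$positive[5])
  expect_error(classify_depots(m, x[, 1, drop = FALSE]), "f2")
})

patient_frame <- function(regions, lateralities, positive) {
  data.frame(patient_id = "P1", region = regions, laterality = lateralities,
             positive = positive)
}

test_that("patient criteria follow the symmetry rule on hand cases", {
  # only the left cervical depot positive: criterion 1 only
  d <- patient_frame(c("cervical", "cervical", "mediastinal"),
                     c("left", "right", "midline"),
                     c(TRUE, FALSE, FALSE))
  pc <- call_patients(d)
  expect_true(pc$criterion1); expect_false(pc$criterion2)

  # both supraclavicular sides positive: both criteria
  d2 <- patient_frame(c("supraclavicular", "supraclavicular"),
                      c("left", "right"), c(TRUE, TRUE))
  pc2 <- call_patients(d2)
  expect_true(pc2$criterion1); expect_true(pc2$criterion2)

  # a single positive mediastinal depot satisfies criterion 2
  d3 <- patient_frame(c("cervical", "cervical", "mediastinal"),
                      c("left", "right", "midline"),
                      c(FALSE, FALSE, TRUE))
  pc3 <- call_patients(d3)
  expect_true(pc3$criterion2)

  # nothing positive: both negative
  d4 <- patient_frame(c("axillary", "axillary"), c("left", "right"), c(FALSE, FALSE))
  pc4 <- call_patients(d4)
  expect_false(pc4$criterion1); expect_false(pc4$criterion2)

  # unpaired bilateral depot is an error
  d5 <- patient_frame("cervical", "left", TRUE)
  expect_error(call_patients(d5), "partner")
})

test_that("criterion 2 implies criterion 1 over all 2^6 positivity patterns", {
  regions <- c("cervical", "cervical", "supraclavicular", "supraclavicular",
               "axillary", "mediastinal")
  lats <- c("left", "right", "left", "right", "left", "midline")
  # give the lone axillary-left a partner to satisfy the pairing contract
  regions <- c(regions, "axillary"); lats <- c(lats, "right")
  for (bits in 0:(2^7 - 1)) {
    pos <- as.logical(bitwAnd(bits, 2^(0:6)))
    d <- patient_frame(regions, lats, pos)
    pc <- call_patients(d)
    # brute-force oracle of the rule text
    c1 <- any(pos)
    sym <- (pos[1] && pos[2]) || (pos[3] && pos[4]) || (pos[5] && pos[7])
    c2 <- sym || pos[6]
    expect_equal(pc$criterion1, c1)
    expect_equal(pc$criterion2, c2)
    expect_true(!pc$criterion2 || pc$criterion1)
  }
})

test_that("criterion dominance holds at cohort level", {
  run <- study_run()
  p1 <- run$patient_diagnostics$criterion1
  p2 <- run$patient_diagnostics$criterion2
  sens <- function(d) d$estimate[d$metric == "sensitivity"]
  spec <- function(d) d$estimate[d$metric == "specificity"]
  expect_lte(sens(p2), sens(p1))
  expect_gte(spec(p2), spec(p1))
})
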