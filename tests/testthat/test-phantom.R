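test_that("identical spec and seed give a bit-identical cohort", {
  sp <- phantom_spec(n_patients = 2, rng_seed = 7)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$patients[[1]]$ct$values, b$patients[[1]]$ct$values)
  expect_identical(a$patients[[2]]$pet$values, b$patients[[2]]$pet$values)
  expect_identical(a$truth$depots, b$truth$depots)
  expect_identical(lapply(a$patients[[1]]$depots, `[[`, "mask"),
                   lapply(b$patients[[1]]$depots, `[[`, "mask"))
})

test_that("zero BAT prevalence gives no BAT anywhere and sub-threshold SUV", {
  co <- generate_cohort(phantom_spec(n_patients = 3, bat_prevalence = 0, rng_seed = 5))
  expect_false(any(co$truth$depots$bat_flag))
  for (p in co$patients)
    for (roi in p$depots)
      expect_true(all(p$pet$values[roi$mask != 0] < 1.5))
})

test_that("depot counts stay within the configured 6-13 range", {
  co <- generate_cohort(phantom_spec(n_patients = 25, rng_seed = 12))
  counts <- table(co$truth$depots$patient_id)
  expect_true(all(counts >= 6 & counts <= 13))
  # both ends of the range are exercised across a cohort this size
  expect_gt(length(unique(as.integer(counts))), 3)
})

test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(n_patients = 0), "n_patients")
  expect_error(phantom_spec(depots_per_patient_range = c(4, 13)), "6, 13")
  expect_error(phantom_spec(depots_per_patient_range = c(9, 7)), "empty")
  expect_error(phantom_spec(wat_mean_hu = -5), "adipose window")
  expect_error(phantom_spec(wat_mean_hu = -20, bat_mean_hu_shift = 30), "adipose window")
  expect_error(phantom_spec(bat_suv_range = c(1.2, 3)), "1.5")
  expect_error(phantom_spec(wat_suv_range = c(0.5, 1.6)), "below")
})

test_that("depot voxels lie inside the adipose HU window", {
  co <- small_cohort()
  for (p in co$patients)
    for (roi in p$depots) {
      hu <- p$ct$values[roi$mask != 0]
      expect_true(all(hu >= -190 & hu <= -10))
    }
})

test_that("every non-mediastinal depot has a contralateral partner", {
  co <- generate_cohort(phantom_spec(n_patients = 15, rng_seed = 31))
  t <- co$truth$depots
  bil <- t[t$region != "mediastinal", ]
  for (pid in unique(bil$patient_id)) {
    d <- bil[bil$patient_id == pid, ]
    for (rg in unique(d$region))
      expect_equal(sum(d$region == rg & d$laterality == "left"),
                   sum(d$region == rg & d$laterality == "right"))
  }
  expect_true(all(t$laterality[t$region == "mediastinal"] == "midline"))
})

test_that("mean-HU separability increases with the configured HU shift", {
  aucs <- vapply(c(0, 5, 15, 30), function(shift) {
    co <- generate_cohort(phantom_spec(n_patients = 25, bat_mean_hu_shift = shift,
                                       hu_heterogeneity_sd = 10, rng_seed = 77))
    tr <- co$truth$depots
    mu <- mapply(function(i) {
      p <- co$patients[[match(tr$patient_id[i], vapply(co$patients, `[[`, "", "patient_id"))]]
      roi <- Find(function(r) r$depot_id == tr$depot_id[i], p$depots)
      mean(p$ct$values[roi$mask != 0])
    }, seq_len(nrow(tr)))
    expect_gt(nrow(tr), 200)
    auroc(mu, tr$bat_flag)
  }, 0)
  expect_true(all(diff(aucs) > -0.02))   # monotone up to Monte-Carlo noise
  expect_gt(aucs[4], aucs[1] + 0.2)
})

test_that("calcium injection honours count, territory and surroundings", {
  set.seed(3)
  d <- c(8L, 24L, 24L)
  ct <- volume_grid(array(40, d), c(5, 1, 1))
  terr <- array(0L, d)
  terr[3:6, 6:18, 6:18] <- 1L

  none <- inject_calcium(ct, terr, n_lesions = 0)
  expect_identical(none$ct$values, ct$values)

  one <- inject_calcium(ct, terr, n_lesions = 1, intensity = 300, lesion_size = 10)
  bright <- array(as.integer(one$ct$values > 130), d)
  lab <- batscan:::cpp_label_components(bright, 26L)
  expect_equal(max(lab), 1)
  expect_equal(sum(bright != 0), 10)
  expect_true(all(bright[terr == 0] == 0))
  expect_identical(one$ct$values[bright == 0], ct$values[bright == 0])

  two <- inject_calcium(ct, terr, n_lesions = 2, intensity = c(200, 500), lesion_size = 8)
  bright2 <- array(as.integer(two$ct$values > 130), d)
  z <- oracle_zone_sizes(bright2, conn = 26)
  expect_equal(nrow(z), 2)

  expect_error(inject_calcium(ct, terr, 1, intensity = 120), "130")
  expect_error(inject_calcium(ct, array(0L, d), 1), "empty")
  tiny <- array(0L, d); tiny[4, 12, 12] <- 1L
  expect_error(inject_calcium(ct, tiny, 1, lesion_size = 10), "does not fit")
})

test_that("phantom truth equals BARCIST labels (round trip)", {
  co <- small_cohort()
  lab <- label_cohort(co)
  tr <- co$truth$depots
  expect_equal(lab$bat_flag[match(tr$depot_id, lab$depot_id)], tr$bat_flag)
  pl <- label_patient(lab)
  pt <- co$truth$patients
  expect_equal(pl$bat_flag[match(pt$patient_id, pl$patient_id)], pt$bat_flag)
})

test_that("cohorts round-trip through NIfTI and CSV on disk", {
  co <- generate_cohort(phantom_spec(n_patients = 1, rng_seed = 9))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  img <- RNifti::readNifti(file.path(dir, "P001_ct.nii.gz"))
  back <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  expect_equal(back, co$patients[[1]]$ct$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})
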