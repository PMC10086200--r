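test_that("first-order statistics match hand arithmetic", {
  v <- array(c(1, 2, 3, 4), c(4, 1, 1))
  m <- array(1L, c(4, 1, 1))
  fo <- first_order_features(v, m, bin_width = 1, voxel_volume = 2)
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Variance"]), 1.25)      # population convention
  expect_equal(unname(fo["Range"]), 3)
  expect_equal(unname(fo["Energy"]), 30)
  expect_equal(unname(fo["TotalEnergy"]), 60)
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(30 / 4))
  expect_equal(unname(fo["Entropy"]), 2)          # 4 equal-mass unit bins
  expect_equal(unname(fo["Uniformity"]), 0.25)
})

test_that("a constant ROI yields degenerate-but-defined first-order values", {
  v <- array(-80, c(3, 3, 1))
  m <- array(1L, c(3, 3, 1))
  fo <- first_order_features(v, m)
  expect_equal(unname(fo["Mean"]), -80)
  expect_equal(unname(fo["Median"]), -80)
  expect_equal(unname(fo["Minimum"]), -80)
  expect_equal(unname(fo["Maximum"]), -80)
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Skewness"]), 0)
  expect_equal(unname(fo["Kurtosis"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_error(first_order_features(v, array(0L, dim(v))), "empty")
})

test_that("voxel volume and mesh descriptors behave on known solids", {
  m <- array(0L, c(2, 5, 5)); m[1, 1:2, 1:5] <- 1L   # 10 voxels
  sh <- shape_features(m, c(5, 1, 1))
  expect_equal(unname(sh["VoxelVolume"]), 50)

  # digital balls: sphericity approaches 1 from below as the radius grows
  sph <- vapply(c(4, 7, 10), function(r) {
    d <- 2L * r + 3L
    ball <- array(0L, c(d, d, d))
    ctr <- (d + 1) / 2
    idx <- which(array(TRUE, dim(ball)), arr.ind = TRUE)
    ball[idx[rowSums(sweep(idx, 2, ctr)^2) <= r^2, ]] <- 1L
    unname(shape_features(ball, c(1, 1, 1))["Sphericity"])
  }, 0)
  # approaches 1 within a digitization tolerance band
  expect_true(all(sph > 0.9 & sph < 1.001))
  expect_lte(abs(1 - sph[3]), abs(1 - sph[1]) + 0.01)
  expect_gt(sph[3], 0.95)
})

test_that("shape axis lengths recover an anisotropic ellipsoid ordering", {
  d <- c(9L, 31L, 15L)
  m <- batscan:::fill_ellipsoid(d, c(5, 16, 8), c(3, 14, 6))
  sh <- shape_features(m, c(1, 1, 1))
  expect_gt(sh[["MajorAxisLength"]], sh[["MinorAxisLength"]])
  expect_gt(sh[["MinorAxisLength"]], sh[["LeastAxisLength"]])
  expect_lt(sh[["Flatness"]], sh[["Elongation"]])
  expect_gt(sh[["Maximum3DDiameter"]], 26)
  # single voxel: finite, defined values
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  s1 <- shape_features(one, c(5, 1, 1))
  expect_true(all(is.finite(s1)))
  expect_equal(s1[["Elongation"]], 1)
})

test_that("GLCM counts match exhaustive pair enumeration on a 2x2 plane", {
  lev <- array(0L, c(1, 2, 2))
  lev[1, , ] <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  counts <- batscan:::cpp_glcm(lev, 2L)
  ds <- dirs13()
  for (k in seq_along(ds)) {
    S <- matrix(counts[, , k], 2, 2)
    expect_equal(S + t(S), oracle_glcm_dir(lev, 2L, ds[[k]]), info = paste("dir", k))
  }
})

test_that("constant and degenerate ROIs give defined texture values", {
  lev <- array(1L, c(2, 3, 3))
  g <- glcm_features(lev, 1)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["MaximumProbability"]), 1)
  expect_equal(unname(g["Correlation"]), 1)
  expect_equal(unname(g["Imc1"]), 0)
  expect_true(all(is.finite(g)))

  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_true(all(is.finite(glcm_features(one, 1))))
  expect_true(all(is.finite(glrlm_features(one, 1))))
  expect_true(all(is.finite(glszm_features(one, 1))))
  expect_true(all(is.finite(gldm_features(one, 1))))
  expect_true(all(is.finite(ngtdm_features(one, 1))))
})

test_that("GLRLM run counts match line tracing on a 1D pattern", {
  lev <- array(c(1L, 1L, 1L, 2L), c(1, 1, 4))
  counts <- batscan:::cpp_glrlm(lev, 2L)
  ds <- dirs13()
  along <- which(vapply(ds, function(d) all(d == c(0, 0, 1)), TRUE))
  P <- matrix(counts[, , along], 2, dim(counts)[2])
  expect_equal(P[1, 3], 1)   # one run of level 1, length 3
  expect_equal(P[2, 1], 1)   # one run of level 2, length 1
  expect_equal(sum(P), 2)
})

test_that("a constant ROI forms a single zone spanning the whole ROI", {
  lev <- array(1L, c(2, 3, 4))
  lab <- batscan:::cpp_label_components(lev, 26L)
  expect_equal(max(lab), 1)
  z <- glszm_features(lev, 1)
  expect_equal(unname(z["SizeZoneNonUniformityNormalized"]), 1)
  expect_equal(unname(z["ZonePercentage"]), 1 / 24)
  expect_equal(unname(z["LargeAreaEmphasis"]), 24^2)
})

test_that("all five texture matrices equal brute-force enumeration on random ROIs", {
  set.seed(1234)
  shapes <- expand.grid(a = 1:4, b = 1:4, c = 1:3)
  ds <- dirs13()
  for (rep in 1:2) {
    for (si in seq_len(nrow(shapes))) {
      dims <- as.integer(unlist(shapes[si, ]))
      lev <- random_level_array(dims, n_levels = sample(1:4, 1))
      L <- max(lev)
      glcm <- batscan:::cpp_glcm(lev, L)
      glrlm <- batscan:::cpp_glrlm(lev, L)
      for (k in seq_along(ds)) {
        S <- matrix(glcm[, , k], L, L)
        expect_equal(S + t(S), oracle_glcm_dir(lev, L, ds[[k]]))
        R <- matrix(glrlm[, , k], L, dim(glrlm)[2])
        O <- oracle_glrlm_dir(lev, L, ds[[k]])
        expect_equal(R[, seq_len(ncol(O)), drop = FALSE], O)
      }
      # GLSZM compared as level x size histograms
      mine <- batscan:::cpp_label_components(lev, 26L)
      sizes <- tabulate(mine[mine != 0])
      zl <- lev[mine != 0][match(seq_along(sizes), mine[mine != 0])]
      P1 <- matrix(0, L, max(sizes))
      for (z in seq_along(sizes)) P1[zl[z], sizes[z]] <- P1[zl[z], sizes[z]] + 1
      P2 <- oracle_glszm(lev, L)
      expect_equal(P1, P2[, seq_len(ncol(P1)), drop = FALSE])
      expect_equal(batscan:::cpp_gldm(lev, L, 0L), oracle_gldm(lev, L, 0))
      expect_equal(batscan:::cpp_ngtdm(lev, L), oracle_ngtdm(lev, L),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the census has exactly 1,743 entries with the printed partition", {
  co <- small_cohort()
  p <- co$patients[[1]]
  fv <- extract_features(p$ct, p$depots[[1]])
  expect_length(fv, 1743L)
  expect_true(all(is.finite(fv)))
  nm <- names(fv)
  expect_equal(sum(grepl("_firstorder_", nm)), 342L)
  expect_equal(sum(grepl("_shape_", nm)), 14L)
  expect_equal(sum(grepl("_glcm_", nm)), 418L)
  expect_equal(sum(grepl("_glszm_", nm)), 304L)
  expect_equal(sum(grepl("_glrlm_", nm)), 304L)
  expect_equal(sum(grepl("_gldm_", nm)), 266L)
  expect_equal(sum(grepl("_ngtdm_", nm)), 95L)
  texture <- grepl("_glcm_|_glszm_|_glrlm_|_gldm_|_ngtdm_", nm)
  expect_equal(sum(texture), 1387L)
  expect_equal(names(fv), canonical_feature_names())
})

test_that("extraction is deterministic and errors carry context", {
  co <- small_cohort()
  p <- co$patients[[1]]
  a <- extract_features(p$ct, p$depots[[2]])
  b <- extract_features(p$ct, p$depots[[2]])
  expect_identical(a, b)
  expect_error(extract_features(p$ct, array(0L, dim(p$ct$values))), "empty")
})

test_that("texture features are invariant to a constant intensity shift", {
  td <- toy_depot()
  cfg <- preprocess_config(filter_bank = "original")
  f1 <- extract_features(td$vol, td$mask, cfg)
  shifted <- volume_grid(td$vol$values + 40, td$vol$spacing)
  f2 <- extract_features(shifted, td$mask, cfg)
  tex <- grepl("_glcm_|_glszm_|_glrlm_|_gldm_|_ngtdm_", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-9)
})

test_that("direction-averaged GLCM features are invariant to 90-degree rotation", {
  set.seed(8)
  cube <- array(sample.int(4, 5^3, replace = TRUE), c(5, 5, 5))
  rot <- aperm(cube[, , 5:1], c(1, 3, 2))      # 90 degrees about the slice axis
  f1 <- glcm_features(cube, 4)
  f2 <- glcm_features(rot, 4)
  expect_equal(f1, f2, tolerance = 1e-9)
})
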