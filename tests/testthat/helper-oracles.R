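# Brute-force reference implementations, independent of the package's
# compiled kernels. All operate on integer level arrays (0 = outside ROI).

dirs13 <- function() {
  out <- list()
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    if (a == 0 && b == 0 && cc == 0) next
    if (a > 0 || (a == 0 && b > 0) || (a == 0 && b == 0 && cc > 0))
      out[[length(out) + 1L]] <- c(a, b, cc)
  }
  out
}

in_bounds <- function(v, d) all(v >= 1) && all(v <= d)

# symmetric co-occurrence matrix for one direction by exhaustive pair listing
oracle_glcm_dir <- function(lev, L, dir) {
  d <- dim(lev)
  P <- matrix(0, L, L)
  for (s in 1:d[1]) for (r in 1:d[2]) for (cc in 1:d[3]) {
    a <- lev[s, r, cc]
    if (a == 0) next
    for (sgn in c(1, -1)) {
      q <- c(s, r, cc) + sgn * dir
      if (!in_bounds(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b == 0) next
      P[a, b] <- P[a, b] + 1
    }
  }
  P
}

# run-length matrix for one direction via maximal-line tracing + rle
oracle_glrlm_dir <- function(lev, L, dir) {
  d <- dim(lev)
  maxrun <- max(d)
  P <- matrix(0, L, maxrun)
  for (s in 1:d[1]) for (r in 1:d[2]) for (cc in 1:d[3]) {
    start <- c(s, r, cc)
    if (in_bounds(start - dir, d)) next    # not the head of a lattice line
    seqv <- integer(0)
    p <- start
    while (in_bounds(p, d)) {
      seqv <- c(seqv, lev[p[1], p[2], p[3]])
      p <- p + dir
    }
    rl <- rle(seqv)
    for (k in seq_along(rl$values))
      if (rl$values[k] != 0)
        P[rl$values[k], rl$lengths[k]] <- P[rl$values[k], rl$lengths[k]] + 1
  }
  P
}

neighbors26 <- function() {
  out <- list()
  for (a in -1:1) for (b in -1:1) for (cc in -1:1)
    if (!(a == 0 && b == 0 && cc == 0)) out[[length(out) + 1L]] <- c(a, b, cc)
  out
}

# zone labeling by iterative min-label relaxation (independent of BFS)
oracle_zone_sizes <- function(lev, conn = 26) {
  d <- dim(lev)
  nbs <- neighbors26()
  if (conn == 8) nbs <- Filter(function(o) o[1] == 0, nbs)
  lab <- array(seq_along(lev), d)
  lab[lev == 0] <- 0L
  repeat {
    changed <- FALSE
    idx <- which(lev != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      p <- idx[k, ]
      for (o in nbs) {
        q <- p + o
        if (!in_bounds(q, d)) next
        if (lev[q[1], q[2], q[3]] == lev[p[1], p[2], p[3]]) {
          m <- min(lab[p[1], p[2], p[3]], lab[q[1], q[2], q[3]])
          if (lab[p[1], p[2], p[3]] != m) { lab[p[1], p[2], p[3]] <- m; changed <- TRUE }
          if (lab[q[1], q[2], q[3]] != m) { lab[q[1], q[2], q[3]] <- m; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  ids <- unique(lab[lab != 0])
  data.frame(level = vapply(ids, function(i) lev[which(lab == i)[1]], 0L),
             size = vapply(ids, function(i) sum(lab == i), 0L))
}

oracle_glszm <- function(lev, L, conn = 26) {
  z <- oracle_zone_sizes(lev, conn)
  P <- matrix(0, L, max(c(z$size, 1)))
  for (k in seq_len(nrow(z))) P[z$level[k], z$size[k]] <- P[z$level[k], z$size[k]] + 1
  P
}

oracle_gldm <- function(lev, L, alpha = 0) {
  d <- dim(lev)
  P <- matrix(0, L, 27)
  nbs <- neighbors26()
  for (s in 1:d[1]) for (r in 1:d[2]) for (cc in 1:d[3]) {
    g <- lev[s, r, cc]
    if (g == 0) next
    dep <- 0
    for (o in nbs) {
      q <- c(s, r, cc) + o
      if (!in_bounds(q, d)) next
      h <- lev[q[1], q[2], q[3]]
      if (h != 0 && abs(h - g) <= alpha) dep <- dep + 1
    }
    P[g, dep + 1] <- P[g, dep + 1] + 1
  }
  P
}

oracle_ngtdm <- function(lev, L) {
  d <- dim(lev)
  n_i <- numeric(L); s_i <- numeric(L)
  nbs <- neighbors26()
  for (s in 1:d[1]) for (r in 1:d[2]) for (cc in 1:d[3]) {
    g <- lev[s, r, cc]
    if (g == 0) next
    vals <- numeric(0)
    for (o in nbs) {
      q <- c(s, r, cc) + o
      if (in_bounds(q, d) && lev[q[1], q[2], q[3]] != 0)
        vals <- c(vals, lev[q[1], q[2], q[3]])
    }
    if (length(vals)) {
      n_i[g] <- n_i[g] + 1
      s_i[g] <- s_i[g] + abs(g - mean(vals))
    }
  }
  cbind(n_i, s_i)
}

# AUROC as the exhaustive concordant-pair fraction
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden optimum by explicit threshold enumeration (rule: positive iff >= t)
oracle_youden <- function(scores, labels) {
  best <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (J > best || (J == best && t > best_t)) { best <- J; best_t <- t }
  }
  list(cutoff = best_t, J = best)
}

# ICC(2,1) via base-R aov mean squares
oracle_icc_aov <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ target + rater, df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# per-slice 8-connected bright components >= min_px, scored by hand
oracle_agatston <- function(hu_slice, pixel_area, hu_thr = 130, min_px = 3) {
  d <- dim(hu_slice)
  lev <- array(0L, c(1L, d))
  lev[1, , ][hu_slice > hu_thr] <- 1L
  z <- oracle_zone_sizes(lev, conn = 8)
  # recover per-component max HU via an independent relabel
  comp <- array(seq_along(lev), dim(lev)); comp[lev == 0] <- 0
  score <- 0; vol_px <- 0
  if (nrow(z) == 0) return(list(score = 0, n_lesions = 0, vol_px = 0))
  # reuse relaxation labels to collect voxel sets
  nbs <- Filter(function(o) o[1] == 0, neighbors26())
  lab <- array(seq_along(lev), dim(lev)); lab[lev == 0] <- 0L
  repeat {
    changed <- FALSE
    idx <- which(lev != 0, arr.ind = TRUE)
    for (kk in seq_len(nrow(idx))) {
      p <- idx[kk, ]
      for (o in nbs) {
        q <- p + o
        if (!in_bounds(q, dim(lev))) next
        if (lev[q[1], q[2], q[3]] == 1 && lab[q[1], q[2], q[3]] != lab[p[1], p[2], p[3]]) {
          m <- min(lab[p[1], p[2], p[3]], lab[q[1], q[2], q[3]])
          lab[p[1], p[2], p[3]] <- m; lab[q[1], q[2], q[3]] <- m; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  n_les <- 0
  for (id in unique(lab[lab != 0])) {
    vox <- which(lab == id)
    if (length(vox) < min_px) next
    n_les <- n_les + 1
    mx <- max(hu_slice[arrayInd(vox, dim(lev))[, 2:3, drop = FALSE]])
    w <- if (mx >= 400) 4 else if (mx >= 300) 3 else if (mx >= 200) 2 else 1
    score <- score + length(vox) * pixel_area * w
    vol_px <- vol_px + length(vox)
  }
  list(score = score, n_lesions = n_les, vol_px = vol_px)
}

# random level lattice with a random ROI mask
random_level_array <- function(dims, n_levels, p_mask = 0.85) {
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  lev[runif(prod(dims)) > p_mask] <- 0L
  if (all(lev == 0)) lev[1] <- 1L
  array(as.integer(lev), dims)
}
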