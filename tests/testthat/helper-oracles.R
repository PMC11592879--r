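# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops) so they cannot share a defect with
# the vectorized implementations they check.

oracle_energy <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  s
}

oracle_region_stats <- function(image, mask) {
  vals <- c()
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (mask[i, j]) vals <- c(vals, image[i, j])
    }
  }
  n <- length(vals)
  mu <- sum(vals) / n
  list(mu = mu, sigma = sqrt(sum((vals - mu)^2) / (n - 1)))
}

# dense 3D convolution with an edge-renormalized separable Gaussian
oracle_gaussian_smooth <- function(vol, fwhm, voxel_size, truncate = 4) {
  d <- dim(vol)
  sigma <- (fwhm / (2 * sqrt(2 * log(2)))) / rep_len(voxel_size, 3)
  half <- pmax(1, ceiling(truncate * sigma))
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0; wsum <- 0
    for (di in -half[1]:half[1]) for (dj in -half[2]:half[2]) for (dk in -half[3]:half[3]) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      w <- exp(-di^2 / (2 * sigma[1]^2)) *
           exp(-dj^2 / (2 * sigma[2]^2)) *
           exp(-dk^2 / (2 * sigma[3]^2))
      acc <- acc + w * vol[ii, jj, kk]
      wsum <- wsum + w
    }
    out[i, j, k] <- acc / wsum
  }
  out
}

oracle_tmap <- function(patient, controls) {
  d <- dim(patient)
  n <- length(controls)
  t <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    xs <- vapply(controls, function(v) v[i, j, k], numeric(1))
    m <- mean(xs); s <- sd(xs)
    den <- s * sqrt(1 + 1 / n)
    t[i, j, k] <- if (den == 0) 0 else (m - patient[i, j, k]) / den
  }
  t
}

# recursive flood fill over a binary 3D map
oracle_label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  ordv <- abs(nbr$di) + abs(nbr$dj) + abs(nbr$dk)
  nbr <- nbr[ordv > 0 & ordv <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  cur <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] != 0) next
      lab[v] <- cur
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(nbr))) {
        ii <- ijk[1] + nbr$di[r]; jj <- ijk[2] + nbr$dj[r]; kk <- ijk[3] + nbr$dk[r]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        w <- (kk - 1L) * d[1] * d[2] + (jj - 1L) * d[1] + ii
        if (mask[w] && lab[w] == 0) stack <- c(stack, w)
      }
    }
  }
  lab
}

# canonicalize a labeling so two labelings are comparable
canon_labels <- function(lab) {
  v <- as.integer(lab)
  nz <- v != 0
  v[nz] <- match(v[nz], unique(v[nz]))
  array(v, dim(lab))
}

# synthetic hippocampal feature cohort: n patients per side, sclerotic
# side planted with jittered radii (>= 15% volume asymmetry on average)
make_lda_cohort <- function(n_per_side = 20, seed = 1) {
  set.seed(seed)
  rows <- list(); labels <- c()
  for (side in c("LEFT", "RIGHT")) {
    for (i in seq_len(n_per_side)) {
      base <- rnorm(1, 8, 0.35)
      cfg <- synth_hippo_config(
        n_slices = 6, sclerotic_side = side,
        left_radius = if (side == "LEFT") 0.82 * base else base + rnorm(1, 0, 0.2),
        right_radius = if (side == "RIGHT") 0.82 * base else base + rnorm(1, 0, 0.2),
        seed = sample.int(1e6, 1))
      st <- gen_hippo_study(cfg)
      f <- extract_features(st)
      rows[[length(rows) + 1]] <- c(f$vol_left, f$vol_right)
      labels <- c(labels, side)
    }
  }
  list(x = do.call(rbind, rows), y = labels)
}
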