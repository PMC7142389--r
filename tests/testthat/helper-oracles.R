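# Independent brute-force oracles used across the suite. Each deliberately
# takes the dumbest correct route (triple loops, flood fill, pair counting)
# so that agreement with the vectorised implementation is informative.

# direct O(n^2) discrete Gaussian convolution along one axis with scipy-style
# reflect boundary, applied axis by axis over a 3D array
oracle_gauss_smooth <- function(a, sigma_vox) {
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- dnorm(-r:r, sd = s); k <- k / sum(k)
    out <- array(0, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (m in seq_len(d[3])) {
      acc <- 0
      for (q in -r:r) {
        idx <- c(i, j, m)
        idx[ax] <- reflect(idx[ax] + q, d[ax])
        acc <- acc + k[q + r + 1] * a[idx[1], idx[2], idx[3]]
      }
      out[i, j, m] <- acc
    }
    a <- out
  }
  a
}

# flood-fill connected components by repeated neighbour scanning (no shared
# code with connected_components): returns list of sorted linear index sets
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1),
             , drop = FALSE]
  seen <- array(FALSE, dim = d)
  comps <- list()
  for (lin in which(mask != 0)) {
    if (seen[lin]) next
    stack <- lin
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      if (seen[cur]) next
      seen[cur] <- TRUE
      members <- c(members, cur)
      co <- arrayInd(cur, d)
      for (q in seq_len(nrow(off))) {
        nb <- co + off[q, ]
        if (all(nb >= 1) && all(nb <= d) && mask[nb[1], nb[2], nb[3]] != 0) {
          nlin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
          if (!seen[nlin]) stack <- c(stack, nlin)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(as.integer(members))
  }
  # order by minimum member index for comparability
  comps[order(vapply(comps, min, 0))]
}

# one-feature-at-a-time RFE: refit, drop the single argmin squared weight
# (ties by lowest column index), down to 'target' features
oracle_rfe_order <- function(X, y, C, target) {
  current <- seq_len(ncol(X))
  elim <- integer(0)
  while (length(current) > target) {
    f <- fit_linear_svm(X[, current, drop = FALSE], y, C)
    crit <- f$weights^2
    drop_i <- order(crit, current)[1]
    elim <- c(elim, current[drop_i])
    current <- current[-drop_i]
  }
  list(elim = elim, retained = current)
}

# AUC by exhaustive pair counting, ties counted 1/2
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# a small noisy two-group cohort with one planted blob
make_blob_cohort <- function(seed, grid = 12L, n1 = 10L, n2 = 10L,
                             effect = 1.5, radius = 2.5, voxel_sd = 0.3,
                             fwhm = 2) {
  spec <- cohort_spec(grid_shape = rep(grid, 3L), n_group1 = n1,
                      n_group2 = n2, voxel_sd = voxel_sd, fwhm_mm = fwhm,
                      blobs = list(blob_spec(rep(ceiling(grid / 2), 3),
                                             radius, effect)),
                      seed = seed)
  gen <- generate_cohort(spec)
  list(cohort = to_matrix(gen$volumes, gen$labels), truth = gen$truth,
       spec = spec)
}
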