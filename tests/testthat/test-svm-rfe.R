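test_that("linear SVM solves the symmetric separable toy exactly", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  fit <- fit_linear_svm(X, y, C = 1e4)
  expect_equal(fit$bias, 0, tolerance = 1e-6)
  expect_equal(predict(fit, X, "class"), y)
  # margin points at +-1: w = 1
  expect_equal(unname(fit$weights), 1, tolerance = 1e-6)
})

test_that("dual coefficients satisfy the KKT identities on random fits", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:30, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sign(X[, 1] + rnorm(n, sd = 0.5)); y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    C <- sample(c(0.1, 1, 10), 1)
    fit <- fit_linear_svm(X, y, C)
    # w = sum_i alpha_i y_i x_i
    expect_equal(unname(fit$weights),
                 unname(drop(t(fit$alpha * y) %*% X)), tolerance = 1e-6)
    expect_true(all(fit$alpha >= 0))
    expect_true(all(fit$alpha <= C + 1e-8))
    expect_lt(abs(sum(fit$alpha * y)), 1e-8)
  }
})

test_that("weights and predictions agree with an independent solver", {
  skip_if_not_installed("kernlab")
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- sign(X[, 1] - 0.5 * X[, 2] + rnorm(40, sd = 0.3)); y[y == 0] <- 1
  fit <- fit_linear_svm(X, y, C = 1)
  kf <- kernlab::ksvm(X, factor(y), type = "C-svc", C = 1,
                      kernel = "vanilladot", kpar = list(), scaled = FALSE)
  # kernlab's sign convention depends on factor order; compare up to sign
  wk <- drop(t(kernlab::coef(kf)[[1]]) %*%
               X[kernlab::alphaindex(kf)[[1]], , drop = FALSE])
  s <- sign(sum(wk * fit$weights))
  expect_equal(unname(fit$weights), unname(s * wk), tolerance = 1e-2)
  expect_equal(predict(fit, X, "class"),
               as.numeric(as.character(kernlab::predict(kf, X))))
})

test_that("an informative feature outweighs a noise feature", {
  set.seed(8)
  hits <- vapply(1:30, function(r) {
    y <- rep(c(1, -1), each = 20)
    X <- cbind(y, rnorm(40))
    fit <- fit_linear_svm(X, y, C = 1)
    abs(fit$weights[1]) > abs(fit$weights[2])
  }, TRUE)
  expect_true(all(hits))
})

test_that("svm input validation", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_linear_svm(X, rep(1, 5)), "single class")
  expect_error(fit_linear_svm(X, c(1, 1, 0, -1, -1)), "\\+1/-1")
  expect_error(fit_linear_svm(X, c(1, 1, -1, -1, 1), C = -1), "'C'")
})

test_that("single feature with retain_fraction 1 is a no-op", {
  set.seed(3)
  X <- matrix(rnorm(10), ncol = 1)
  y <- rep(c(1, -1), 5)
  rk <- rfe_rank(X, y, rfe_config(retain_fraction = 1))
  expect_equal(rk$retained, 1L)
  expect_equal(nrow(rk$log), 0L)
})

test_that("batch RFE with one removal per round equals the one-at-a-time oracle", {
  set.seed(19)
  for (rep in 1:5) {
    X <- matrix(rnorm(24 * 10), 24, 10)
    y <- rep(c(1, -1), each = 12)
    X[, 1] <- X[, 1] + y; X[, 2] <- X[, 2] + 0.5 * y
    cfg <- rfe_config(elim_fraction = 0.05, retain_fraction = 0.30)
    # 5% of <= 10 features rounds up to exactly 1 per round
    got <- rfe_rank(X, y, cfg)
    oracle <- oracle_rfe_order(X, y, cfg$C, target = 3)
    expect_identical(got$log$feature, oracle$elim)
    expect_identical(got$retained, sort(oracle$retained))
  }
})

test_that("elimination schedule matches a direct simulation of the rounds", {
  # n = 100, 5% per round, retain 40%: remove 5 per round down to 40
  set.seed(40)
  X <- matrix(rnorm(20 * 100), 20, 100)
  y <- rep(c(1, -1), 10)
  rk <- rfe_rank(X, y, rfe_config(elim_fraction = 0.05,
                                  retain_fraction = 0.40))
  removed_per_round <- as.integer(table(rk$log$round))
  sim <- local({
    n <- 100; target <- ceiling(0.4 * 100); out <- integer(0)
    while (n > target) {
      r <- min(max(1, ceiling(0.05 * n)), n - target)
      out <- c(out, as.integer(r)); n <- n - r
    }
    out
  })
  expect_identical(removed_per_round, sim)
  expect_length(rk$retained, 40L)
  # ranks are a permutation of 1..n
  expect_identical(sort(rk$rank), 1:100)

  # fractional schedule with ceil() and final truncation: n = 37, retain 0.5
  rk2 <- rfe_rank(X[, 1:37], y, rfe_config(elim_fraction = 0.1,
                                           retain_fraction = 0.5))
  expect_length(rk2$retained, ceiling(0.5 * 37))
  sim2 <- local({
    n <- 37; target <- ceiling(0.5 * 37); out <- integer(0)
    while (n > target) {
      r <- min(max(1, ceiling(0.1 * n)), n - target)
      out <- c(out, as.integer(r)); n <- n - r
    }
    out
  })
  expect_identical(as.integer(table(rk2$log$round)), sim2)
})

test_that("elimination order is equivariant to scaling X with C / c^2", {
  set.seed(27)
  X <- matrix(rnorm(20 * 12), 20, 12)
  y <- rep(c(1, -1), each = 10)
  X[, 3] <- X[, 3] + y
  c_scale <- 2
  r1 <- rfe_rank(X, y, rfe_config(C = 1, elim_fraction = 0.1,
                                  retain_fraction = 0.25))
  r2 <- rfe_rank(c_scale * X, y,
                 rfe_config(C = 1 / c_scale^2, elim_fraction = 0.1,
                            retain_fraction = 0.25))
  expect_identical(r1$log$feature, r2$log$feature)
  expect_identical(r1$retained, r2$retained)
})

test_that("RFE retains all informative features in a separable regime", {
  set.seed(55)
  for (rep in 1:5) {
    y <- rep(c(1, -1), each = 15)
    X <- matrix(rnorm(30 * 20, sd = 0.5), 30, 20)
    k_informative <- 4
    for (j in seq_len(k_informative)) X[, j] <- X[, j] + 2 * y
    rk <- rfe_rank(X, y, rfe_config(retain_fraction = 0.25))  # keeps 5 >= 4
    expect_true(all(seq_len(k_informative) %in% rk$retained))
  }
})

test_that("select_features composes screening and RFE with provenance", {
  bc <- make_blob_cohort(seed = 3)
  sres <- screen(bc$cohort, screening_config(min_cluster = 10))
  sel <- select_features(bc$cohort, sres, rfe_config())
  n_surv <- length(sres$selected_cols)
  expect_length(sel$cols, ceiling(0.4 * n_surv))
  expect_equal(ncol(sel$cohort$X), length(sel$cols))
  expect_true(all(sel$cols %in% sres$selected_cols))
  expect_equal(sel$provenance$n_screened, n_surv)
  expect_equal(sel$provenance$alpha, 0.05)

  # retain_fraction 1 on an all-pass screen is the identity
  all_pass <- screen(bc$cohort, screening_config(alpha = 1 - 1e-12,
                                                 min_cluster = 1))
  sel1 <- select_features(bc$cohort, all_pass,
                          rfe_config(retain_fraction = 1))
  expect_identical(sel1$cohort$X, bc$cohort$X)

  # empty surviving set errors with advice
  es <- suppressWarnings(screen(bc$cohort,
                                screening_config(alpha = 1e-10,
                                                 min_cluster = 1000)))
  expect_error(select_features(bc$cohort, es, rfe_config()), "relax")
})

test_that("RFE-retained voxels overlap the blob more than random subsets", {
  overlaps <- vapply(1:20, function(s) {
    bc <- make_blob_cohort(seed = 500 + s, grid = 10L, radius = 2,
                           effect = 1.2, voxel_sd = 0.4, fwhm = 2)
    sres <- screen(bc$cohort, screening_config(min_cluster = 5))
    sel <- select_features(bc$cohort, sres, rfe_config())
    blob <- bc$truth$blob_voxels[[1]]
    got <- length(intersect(bc$cohort$mask_linear[sel$cols], blob))
    set.seed(s)
    rnd <- vapply(1:20, function(i) {
      length(intersect(sample(bc$cohort$mask_linear, length(sel$cols)),
                       blob))
    }, 0)
    got > max(rnd)
  }, TRUE)
  expect_gte(mean(overlaps), 0.95)
})
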