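sep_cohort <- function(n1 = 6, n2 = 6) {
  # two constant, perfectly separating voxels in an 8-voxel grid
  y <- c(rep(1, n1), rep(-1, n2))
  vols <- lapply(y, function(lab) {
    a <- array(0.5, dim = c(2, 2, 2))
    a[1, 1, 1] <- 0.5 + lab
    a[2, 1, 1] <- 0.5 - lab
    volume3d(a)
  })
  to_matrix(vols, y)
}

test_that("separable cohort gives perfect LOO metrics in both modes", {
  cm <- sep_cohort()
  cfg <- screening_config(alpha = 0.05, min_cluster = 1)
  for (mode in c("nested", "pooled")) {
    e <- loo_evaluate(cm, cfg, rfe_config(retain_fraction = 1), mode)
    expect_equal(e$metrics$ACC, 1)
    expect_equal(e$metrics$AUC, 1)
    expect_equal(e$mode, mode)
  }
})

test_that("LOO bookkeeping holds one subject out exactly once", {
  bc <- make_blob_cohort(seed = 41, grid = 8L, n1 = 5L, n2 = 6L, fwhm = 0)
  e <- loo_evaluate(bc$cohort, screening_config(alpha = 0.2, min_cluster = 2),
                    rfe_config(), "nested")
  expect_equal(nrow(e$folds), 11)
  expect_identical(sort(e$folds$subject), 1:11)
  expect_equal(e$confusion$N, 5)
  expect_equal(e$confusion$M, 6)
  expect_equal(e$confusion$TP + e$confusion$FN, 1)
  expect_equal(e$confusion$TN + e$confusion$FP, 1)
  # metrics recompute from the pooled confusion entries
  m <- compute_metrics(e$confusion$N, e$confusion$M, e$confusion$N1,
                       e$confusion$M1)
  expect_equal(e$metrics$GM, m$GM)
})

test_that("nested selection is blind to the held-out subject", {
  bc <- make_blob_cohort(seed = 43, grid = 8L, n1 = 5L, n2 = 5L, fwhm = 0,
                         voxel_sd = 0.5)
  cfg <- screening_config(alpha = 0.2, min_cluster = 2)
  rcfg <- rfe_config()
  hold <- 3
  train_rows <- setdiff(1:10, hold)
  sel_of <- function(cohort) {
    train <- vbmrfe:::subset_rows(cohort, train_rows)
    sres <- screen(train, cfg)
    select_features(train, sres, rcfg)$cols
  }
  base_cols <- sel_of(bc$cohort)
  # wreck the held-out subject's values; the fold's selection cannot change
  mangled <- bc$cohort
  mangled$X[hold, ] <- 1e3 * rnorm(ncol(mangled$X))
  expect_identical(sel_of(mangled), base_cols)
})

test_that("null cohorts evaluate at chance accuracy", {
  accs <- vapply(1:8, function(s) {
    spec <- cohort_spec(grid_shape = c(8, 8, 8), n_group1 = 8, n_group2 = 8,
                        subject_sd = 0, voxel_sd = 1, blobs = list(),
                        fwhm_mm = 0, seed = 900 + s)
    gen <- generate_cohort(spec)
    cm <- to_matrix(gen$volumes, gen$labels)
    e <- suppressWarnings(
      loo_evaluate(cm, screening_config(alpha = 0.2, min_cluster = 2),
                   rfe_config(), "nested"))
    e$metrics$ACC
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * max(se, 0.05))
})

test_that("empty-surviving folds fall back to majority class with a warning", {
  set.seed(77)
  y <- c(rep(1, 3), rep(-1, 4))
  vols <- lapply(y, function(l) volume3d(array(rnorm(8), dim = c(2, 2, 2))))
  cm <- to_matrix(vols, y)
  expect_warning(
    e <- loo_evaluate(cm, screening_config(alpha = 1e-9, min_cluster = 8),
                      rfe_config(), "nested"),
    "majority")
  expect_true(all(e$folds$failed))
  expect_true(all(e$folds$score == 0))
  # training majority is always the full opposite class here except where
  # the held-out subject's own class keeps the majority
  expect_equal(e$folds$predicted[1], -1)  # 2 vs 4 -> majority -1
})

test_that("evaluation serialisation round trips the metrics", {
  cm <- sep_cohort()
  e <- loo_evaluate(cm, screening_config(min_cluster = 1),
                    rfe_config(retain_fraction = 1), "pooled")
  d <- withr::local_tempdir()
  write_evaluation(e, d)
  js <- jsonlite::read_json(file.path(d, "evaluation.json"))
  expect_equal(js$metrics$ACC, 1)
  expect_equal(js$mode, "pooled")
  folds <- read.delim(file.path(d, "folds.tsv"))
  expect_equal(nrow(folds), 12)
})

test_that("ctf_svm object exposes coef, predict and summary coherently", {
  bc <- make_blob_cohort(seed = 7)
  fit <- ctf_svm(bc$cohort, screening = screening_config(min_cluster = 10))
  w <- coef(fit)
  expect_length(w, length(fit$selection$cols))
  wv <- coef(fit, as_volume = TRUE)
  expect_equal(sum(!is.na(wv$data)), length(w))
  # predicting the training volumes reproduces fitted decision values
  sc_mat <- predict(fit, bc$cohort, type = "score")
  expect_equal(sc_mat, fitted(fit))
  cls <- predict(fit, bc$cohort)
  expect_true(all(cls %in% c(-1, 1)))
  s <- summary(fit)
  expect_s3_class(s, "summary.ctf_svm")
  expect_true(s$train_metrics$ACC >= 0.9)  # strong planted effect
  expect_error(predict(fit, matrix(0, 1, 3)), "columns")
  # plot renders without error
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); on.exit(grDevices::dev.off(), add = TRUE)
  expect_no_error(plot(fit))
})
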