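vols_from_matrix <- function(X, d) {
  lapply(seq_len(nrow(X)), function(i) volume3d(array(X[i, ], dim = d)))
}

test_that("pooled t statistic matches hand arithmetic and t.test", {
  # one voxel, groups (1,2,3) vs (4,5,6): pooled s^2 = 1,
  # T = -3 / sqrt(1 * (1/3 + 1/3)) = -3.6742, p on df = 4
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  cm <- to_matrix(vols_from_matrix(X, c(1, 1, 1)), c(1, 1, 1, -1, -1, -1))
  tw <- ttest_voxelwise(cm)
  expect_equal(tw$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tw$t, -3.674235, tolerance = 1e-6)
  expect_equal(tw$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)

  # 1000 random small draws against stats::t.test(var.equal = TRUE)
  set.seed(17)
  for (rep in 1:1000) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x1 <- rnorm(n1); x2 <- rnorm(n2, sd = runif(1, 0.5, 2))
    cm <- to_matrix(vols_from_matrix(matrix(c(x1, x2), ncol = 1),
                                     c(1, 1, 1)),
                    c(rep(1, n1), rep(-1, n2)))
    tw <- ttest_voxelwise(cm)
    tt <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(tw$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tw$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("t map is null on identical groups and antisymmetric in labels", {
  set.seed(2)
  X <- matrix(rnorm(40), nrow = 8)
  Xdup <- rbind(X[1:4, ], X[1:4, ])
  cm <- to_matrix(vols_from_matrix(Xdup, c(5, 1, 1)),
                  c(rep(1, 4), rep(-1, 4)))
  tw <- ttest_voxelwise(cm)
  expect_true(all(tw$t == 0) && all(tw$p == 1))

  cm1 <- to_matrix(vols_from_matrix(X, c(5, 1, 1)), c(rep(1, 4), rep(-1, 4)))
  cm2 <- to_matrix(vols_from_matrix(X, c(5, 1, 1)), c(rep(-1, 4), rep(1, 4)))
  t1 <- ttest_voxelwise(cm1); t2 <- ttest_voxelwise(cm2)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
})

test_that("zero-variance voxels follow the degenerate convention", {
  X <- cbind(c(1, 1, 1, 1), c(1, 1, 2, 2))  # voxel 1: equal consts; 2: sep
  cm <- to_matrix(vols_from_matrix(X, c(2, 1, 1)), c(1, 1, -1, -1))
  tw <- ttest_voxelwise(cm)
  expect_equal(tw$t[1], 0)
  expect_equal(tw$p[1], 1)
  expect_equal(tw$t[2], -Inf)
  expect_equal(tw$p[2], 0)
  expect_equal(tw$degenerate, c(TRUE, TRUE))
})

test_that("connected components match a flood-fill oracle", {
  expect_identical(connected_components(array(0, dim = c(3, 3, 3))), list())
  one <- connected_components(array(1, dim = c(3, 3, 3)))
  expect_length(one, 1)
  expect_equal(one[[1]]$size, 27)

  # two handcrafted blobs (sizes 4 and 2), > 1 voxel apart everywhere
  m <- array(0, dim = c(5, 5, 5))
  m[1:2, 1:2, 1] <- 1          # size 4
  m[5, 5, 4:5] <- 1            # size 2
  for (conn in c(6, 18, 26)) {
    cl <- connected_components(m, conn)
    expect_equal(vapply(cl, `[[`, 0L, "size"), c(4L, 2L))
    expect_identical(lapply(cl, `[[`, "indices"), oracle_flood_fill(m, conn))
  }

  # 50 random 8^3 masks under all three connectivities
  set.seed(23)
  for (rep in 1:50) {
    m <- array(runif(8^3) < 0.25, dim = c(8, 8, 8)) * 1
    conn <- sample(c(6, 18, 26), 1)
    got <- connected_components(m, conn)
    oracle <- oracle_flood_fill(m, conn)
    expect_identical(lapply(got, `[[`, "indices"), oracle)
  }
})

test_that("screen applies threshold and extent filter", {
  set.seed(31)
  bc <- make_blob_cohort(seed = 31)
  cfg <- screening_config(alpha = 1 - 1e-12, min_cluster = 1)
  sres <- screen(bc$cohort, cfg)
  # with alpha ~ 1 and extent 1, everything finite survives
  expect_equal(length(sres$selected_cols), ncol(bc$cohort$X))

  # planted blob, strong effect: surviving set covers >= 90% of blob voxels
  sres <- screen(bc$cohort, screening_config(alpha = 0.05, min_cluster = 10))
  blob <- bc$truth$blob_voxels[[1]]
  surv_lin <- bc$cohort$mask_linear[sres$selected_cols]
  expect_gte(mean(blob %in% surv_lin), 0.9)
  # the largest surviving cluster overlaps the blob
  big <- sres$clusters[[which.max(vapply(sres$clusters, `[[`, 0L, "size"))]]
  expect_gt(length(intersect(big$indices, blob)), 0)

  # surviving voxels are a subset of supra-threshold voxels, in clusters
  p_in <- sres$p_map$data[surv_lin]
  expect_true(all(p_in < 0.05))
  expect_true(all(vapply(sres$clusters, `[[`, 0L, "size") >= 10))
})

test_that("surviving sets shrink monotonically as alpha tightens", {
  bc <- make_blob_cohort(seed = 77, effect = 0.8, voxel_sd = 0.5)
  min_cl <- 5
  survs <- lapply(c(0.001, 0.01, 0.05), function(a) {
    s <- suppressWarnings(screen(bc$cohort,
                                 screening_config(alpha = a,
                                                  min_cluster = min_cl)))
    bc$cohort$mask_linear[s$selected_cols]
  })
  expect_true(all(survs[[1]] %in% survs[[2]]))
  expect_true(all(survs[[2]] %in% survs[[3]]))
})

test_that("empty screening result warns rather than errors", {
  set.seed(5)
  X <- matrix(rnorm(6 * 8), nrow = 6)
  cm <- to_matrix(vols_from_matrix(X, c(2, 2, 2)), c(1, 1, 1, -1, -1, -1))
  expect_warning(sres <- screen(cm, screening_config(alpha = 1e-6,
                                                     min_cluster = 8)),
                 "no voxel survives")
  expect_length(sres$selected_cols, 0)
})

test_that("screening output writes maps and cluster table", {
  bc <- make_blob_cohort(seed = 13)
  sres <- screen(bc$cohort, screening_config(min_cluster = 10))
  d <- withr::local_tempdir()
  write_screening(sres, d)
  expect_true(all(file.exists(file.path(
    d, c("t_map.nii.gz", "p_map.nii.gz", "surviving_mask.nii.gz",
         "clusters.tsv")))))
  tab <- read.delim(file.path(d, "clusters.tsv"))
  expect_equal(nrow(tab), length(sres$clusters))
  expect_true(all(tab$size >= 10))
})
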