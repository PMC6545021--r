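test_that("CPM normalisation scales columns to one million", {
  m <- matrix(c(2, 8, 5, 0), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  cpm <- compute_cpm(m)
  expect_equal(unname(cpm[, "c1"]), c(200000, 800000))
  expect_equal(unname(cpm[, "c2"]), c(1e6, 0))  # single nonzero feature
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-9)

  m0 <- cbind(m, c3 = c(0, 0))
  expect_error(compute_cpm(m0), "c3")

  # external library sizes override the column sums
  lib <- c(c1 = 100, c2 = 10)
  expect_equal(unname(compute_cpm(m, lib)[1, ]), c(2e4, 5e5))
})

test_that("CPM column sums hold for random synthetic matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnbinom(600, mu = 20, size = 2) + runif(600), 30, 20,
                dimnames = list(sprintf("r%d", 1:30), sprintf("c%d", 1:20)))
    expect_equal(unname(colSums(compute_cpm(m))), rep(1e6, 20),
                 tolerance = 1e-9)
  }
})

test_that("stage retention filter requires full detection in one stage", {
  meta <- toy_meta(4L)
  n <- nrow(meta)
  counts <- matrix(1, 3, n, dimnames = list(c("all", "one_stage", "partial"),
                                            meta$cell_id))
  # 'one_stage': high in every 4cell cell only; 'partial': 3 of 4 cells per stage
  counts["one_stage", ] <- 0.01
  counts["one_stage", meta$cell_id[meta$stage == "4cell"]] <- 50
  counts["partial", ] <- 0.01
  for (s in repdyn_stages())
    counts["partial", meta$cell_id[meta$stage == s][1:3]] <- 50
  counts["all", ] <- 50
  # library sizes chosen so CPM == counts
  cpm <- compute_cpm(counts, stats::setNames(rep(1e6, n), meta$cell_id))
  expect_setequal(filter_repeats_by_stage(cpm, meta), c("all", "one_stage"))
})

test_that("raising the stage-filter threshold never adds a repeat", {
  meta <- toy_meta(3L)
  set.seed(21)
  m <- matrix(rnbinom(50 * nrow(meta), mu = 15, size = 1), 50,
              nrow(meta), dimnames = list(sprintf("r%02d", 1:50), meta$cell_id))
  cpm <- compute_cpm(m)
  prev <- filter_repeats_by_stage(cpm, meta, threshold = 0.5)
  for (thr in c(1, 5, 50, 500)) {
    cur <- filter_repeats_by_stage(cpm, meta, threshold = thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("gene TPM filter compares stage means and keeps the boundary", {
  meta <- toy_meta(2L)
  tpm <- matrix(0.1, 3, nrow(meta),
                dimnames = list(c("hi_morula", "low_all", "exactly1"),
                                meta$cell_id))
  tpm["hi_morula", meta$cell_id[meta$stage == "morula"]] <- 5
  tpm["exactly1", meta$cell_id[meta$stage == "zygote"]] <- 1
  kept <- filter_genes_by_tpm(tpm, meta)
  expect_setequal(as.character(kept), c("hi_morula", "exactly1"))
})

test_that("log2 transform is guarded against double application", {
  m <- matrix(c(0, 1, 1023, 3), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  cpm <- compute_cpm(m, c(c1 = 1e6, c2 = 1e6))
  lg <- log2_cpm(cpm)
  expect_equal(unname(lg[, "c1"]), c(0, 1))
  expect_equal(lg["a", "c2"], 10)
  expect_error(log2_cpm(lg), "already")
})

test_that("stage CV matches closed forms and is scale invariant", {
  meta <- toy_meta(3L)
  m <- matrix(1, 2, nrow(meta), dimnames = list(c("x", "y"), meta$cell_id))
  m["x", meta$cell_id[meta$stage == "oocyte"]] <- c(2, 4, 6)
  m["y", meta$cell_id[meta$stage == "oocyte"]] <- c(4, 4, 4)
  m["y", meta$cell_id[meta$stage == "zygote"]] <- c(0, 0, 0)
  cv <- stage_cv(m, meta)
  expect_equal(cv$cv[cv$feature == "x" & cv$stage == "oocyte"], 0.5)
  expect_equal(cv$cv[cv$feature == "y" & cv$stage == "oocyte"], 0)
  expect_true(is.na(cv$cv[cv$feature == "y" & cv$stage == "zygote"]))

  # scale invariance: multiplying a stage's values by k > 0 leaves CV fixed
  m2 <- m
  m2[, meta$cell_id[meta$stage == "oocyte"]] <-
    m2[, meta$cell_id[meta$stage == "oocyte"]] * 7.3
  cv2 <- stage_cv(m2, meta)
  expect_equal(cv2$cv, cv$cv)
})

test_that("z-score profiles are standardised and location/scale invariant", {
  expect_equal(zscore_profile(c(3, 3, 3)), c(0, 0, 0))
  expect_equal(zscore_profile(c(0, 2)), c(-sqrt(0.5), sqrt(0.5)),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    v <- rnorm(9, sd = runif(1, 0.5, 4))
    z <- zscore_profile(v)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
    expect_equal(zscore_profile(2.5 * v + 17), z, tolerance = 1e-10)
  }
})

test_that("stage profiles carry per-stage means, SEMs and z-scores", {
  meta <- toy_meta(3L)
  m <- matrix(rnorm(2 * nrow(meta), 5), 2, nrow(meta),
              dimnames = list(c("a", "b"), meta$cell_id))
  pr <- stage_profiles(m, meta)
  expect_setequal(unique(pr$stage), repdyn_stages())
  oo <- m["a", meta$cell_id[meta$stage == "oocyte"]]
  row <- pr[pr$feature == "a" & pr$stage == "oocyte", ]
  expect_equal(row$mean, mean(oo))
  expect_equal(row$sem, sd(oo) / sqrt(3))
  za <- pr$z[pr$feature == "a"]
  expect_equal(mean(za), 0, tolerance = 1e-12)
  expect_equal(sd(za), 1, tolerance = 1e-12)
})

test_that("repeat read percentage follows 100 R / (R + G)", {
  rp <- read_percentage(c(a = 200, b = 5, c = 0),
                        c(a = 800, b = 0, c = 0))
  expect_equal(unname(rp), c(20, 100, NA))
})

test_that("PCA coordinates match an independent covariance eigensolve", {
  set.seed(5)
  expr <- matrix(rnorm(20), 5, 4,
                 dimnames = list(sprintf("f%d", 1:5), sprintf("c%d", 1:4)))
  pc <- pca_coordinates(expr, n_components = 2)
  # oracle: eigendecomposition of the cell covariance matrix
  x <- scale(t(expr), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  oracle <- x %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    # sign is conventional; coordinates must match up to a per-component flip
    expect_equal(min(max(abs(pc$coordinates[, j] - oracle[, j])),
                     max(abs(pc$coordinates[, j] + oracle[, j]))),
                 0, tolerance = 1e-8)
  }
  expect_equal(pc$explained_variance,
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)
  expect_true(sum(pc$explained_variance) <= 1 + 1e-12)
})

test_that("PC1 separates two cell clusters differing on one feature", {
  set.seed(6)
  expr <- matrix(rnorm(40 * 20, sd = 0.1), 40, 20,
                 dimnames = list(sprintf("f%d", 1:40), sprintf("c%d", 1:20)))
  expr[1, 11:20] <- expr[1, 11:20] + 10
  pc <- pca_coordinates(expr, 2)
  expect_true(max(pc$coordinates[1:10, 1]) < min(pc$coordinates[11:20, 1]) ||
                min(pc$coordinates[1:10, 1]) > max(pc$coordinates[11:20, 1]))
  expect_error(pca_coordinates(expr[1:2, ], 3), "fewer features")
})

test_that("class-stage means pool (repeat, cell) values with SEMs", {
  meta <- toy_meta(2L)
  m <- matrix(3, 4, nrow(meta),
              dimnames = list(c("s1", "s2", "l1", "l2"), meta$cell_id))
  cls <- c(s1 = "Satellite", s2 = "Satellite", l1 = "LINE", l2 = "LINE")
  m["s1", meta$cell_id[meta$stage == "4cell"]] <- c(10, 14)
  m["s2", meta$cell_id[meta$stage == "4cell"]] <- c(12, 16)
  cs <- class_stage_means(m, meta, cls)
  sat4 <- cs[cs$repeat_class == "Satellite" & cs$stage == "4cell", ]
  pool <- c(10, 14, 12, 16)
  expect_equal(sat4$mean, mean(pool))
  expect_equal(sat4$sem, sd(pool) / 2)
  expect_equal(sat4$n, 4L)
  # identical values give SEM 0
  line4 <- cs[cs$repeat_class == "LINE" & cs$stage == "4cell", ]
  expect_equal(line4$sem, 0)
  # with equal cell counts the pooled mean equals the mean of per-repeat means
  expect_equal(sat4$mean, mean(c(mean(c(10, 14)), mean(c(12, 16)))))
})
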