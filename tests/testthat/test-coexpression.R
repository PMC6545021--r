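test_that("eigengene is the first PC with a fixed, interpretable sign", {
  meta <- toy_meta(2L)
  n <- nrow(meta)
  set.seed(31)
  base <- rnorm(n)
  # rank-1 module: all genes share one profile (plus per-gene offsets)
  expr <- rbind(g1 = base + 1, g2 = base + 5, g3 = base - 2)
  colnames(expr) <- meta$cell_id
  eg <- compute_eigengene(expr)
  expect_equal(mean(eg), 0, tolerance = 1e-12)
  expect_true(abs(cor(eg, base)) > 0.999)
  expect_true(cor(eg, colMeans(expr)) > 0)  # sign convention

  expect_error(compute_eigengene(matrix(2, 3, n)), "constant")

  # eigensolve oracle on a 4-gene x 6-cell toy: scores match up to the
  # (conventional) sign, and no direction explains more variance
  toy <- matrix(rnorm(24), 4, 6)
  z <- t(scale(t(toy)))
  ev <- eigen(cov(scale(t(z), scale = FALSE)))
  oracle <- scale(t(z), scale = FALSE) %*% ev$vectors[, 1]
  eg2 <- compute_eigengene(toy)
  expect_equal(min(max(abs(eg2 - oracle)), max(abs(eg2 + oracle))), 0,
               tolerance = 1e-8)
  expect_gte(var(eg2) + 1e-10, max(apply(z, 1, var)))
})

test_that("stage specificity is the indicator correlation with t-test p", {
  meta <- toy_meta(3L)
  ind <- as.numeric(meta$stage == "8cell")
  names(ind) <- meta$cell_id
  ss <- stage_specificity(ind, meta, "8cell")
  expect_equal(ss$r, 1)

  # hand-checkable profile
  set.seed(7)
  sc <- rnorm(nrow(meta))
  names(sc) <- meta$cell_id
  ct <- cor.test(sc, ind)
  ss2 <- stage_specificity(sc, meta, "8cell")
  expect_equal(ss2$r, unname(ct$estimate))
  expect_equal(ss2$p, ct$p.value)

  const <- rep(1, nrow(meta))
  names(const) <- meta$cell_id
  expect_true(is.na(stage_specificity(const, meta, "8cell")$r))
})

test_that("permuting labels keeps stage correlations small", {
  set.seed(8)
  stages <- repdyn_stages()
  n <- 198  # 22 cells x 9 stages
  meta <- data.frame(cell_id = sprintf("c%03d", 1:n),
                     stage = factor(rep(stages, each = n / 9),
                                    levels = stages, ordered = TRUE),
                     embryo_id = "e", stringsAsFactors = FALSE)
  hits <- replicate(100, {
    sc <- rnorm(n)
    names(sc) <- sample(meta$cell_id)  # permuted pairing
    abs(stage_specificity(sc, meta, "4cell")$r) < 0.2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("module merging takes the transitive closure of r >= threshold", {
  meta <- toy_meta(2L)
  n <- nrow(meta)
  set.seed(41)
  pA <- rnorm(n); pB <- 0.9 * pA + 0.25 * rnorm(n); pC <- rnorm(n)
  mk <- function(p, prefix) {
    m <- rbind(p + 0.05 * rnorm(n), p + 0.05 * rnorm(n), p + 0.05 * rnorm(n))
    rownames(m) <- paste0(prefix, 1:3); colnames(m) <- meta$cell_id
    m
  }
  expr <- rbind(mk(pA, "a"), mk(pB, "b"), mk(-pA, "d"))
  mods <- data.frame(gene_id = rownames(expr),
                     module_label = rep(c("blue", "red", "grey"), each = 3))
  mg <- merge_modules(mods, expr, r_threshold = 0.7)
  lab <- mg$modules$module_label
  # blue and red merge; the anticorrelated module must not (threshold on r,
  # not |r|)
  expect_equal(unique(lab[mods$module_label %in% c("blue", "red")]), "blue+red")
  expect_equal(unique(lab[mods$module_label == "grey"]), "grey")
  # idempotence
  again <- merge_modules(mg$modules, expr, r_threshold = 0.7)
  expect_equal(sort(unique(again$modules$module_label)),
               sort(unique(mg$modules$module_label)))
  expect_equal(again$modules$module_label, mg$modules$module_label)
})

test_that("chained similarity merges all three modules", {
  # eigengene correlations A~B and B~C above threshold, A~C below:
  # transitive closure still yields one module
  meta <- toy_meta(3L)
  n <- nrow(meta)
  set.seed(43)
  u <- rnorm(n); v <- rnorm(n)
  pA <- u; pB <- (u + v) / sqrt(2); pC <- v
  mk <- function(p, prefix) {
    m <- do.call(rbind, lapply(1:3, function(i) p + 0.03 * rnorm(n)))
    rownames(m) <- paste0(prefix, 1:3); colnames(m) <- meta$cell_id
    m
  }
  expr <- rbind(mk(pA, "a"), mk(pB, "b"), mk(pC, "c"))
  mods <- data.frame(gene_id = rownames(expr),
                     module_label = rep(c("A", "B", "C"), each = 3))
  mg <- merge_modules(mods, expr, r_threshold = 0.65)
  expect_equal(unique(mg$modules$module_label), "A+B+C")
})

test_that("stage-module assigner recovers planted genes and drops the rest", {
  stages <- repdyn_stages()
  n_per <- 150L
  meta <- data.frame(cell_id = sprintf("c%04d", seq_len(9 * n_per)),
                     stage = factor(rep(stages, each = n_per),
                                    levels = stages, ordered = TRUE),
                     embryo_id = "e", stringsAsFactors = FALSE)
  set.seed(51)
  planted <- sprintf("g%03d", 1:40)
  expr <- matrix(rnorm(200 * nrow(meta)), 200, nrow(meta),
                 dimnames = list(sprintf("g%03d", 1:200), meta$cell_id))
  expr[planted, meta$stage == "8cell"] <-
    expr[planted, meta$stage == "8cell"] + 2  # 2-sd stage effect
  mods <- assign_stage_modules(expr, meta)
  expect_true(all(mods$stage == "8cell"))
  expect_gte(mean(planted %in% mods$gene_id), 0.90)
  expect_equal(unique(mods$module_label), "green")
  # flat-profile genes stay unassigned
  expect_lte(sum(!(mods$gene_id %in% planted)), 2L)

  # a planted group below the minimum module size is dropped entirely
  expr10 <- expr[c(1:10, 41:200), ]
  mods10 <- assign_stage_modules(expr10, meta, min_module_size = 30L)
  expect_equal(nrow(mods10), 0L)
})

test_that("module import validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tmodule_label\tstage",
               "g1\tblue\t4cell", "g2\tblue\t4cell", "g3\tred\t8cell"), f)
  mods <- import_modules(f)
  expect_equal(nrow(mods), 3L)

  export_modules(mods, f, seed = 3)
  expect_equal(import_modules(f), mods, ignore_attr = TRUE)

  writeLines(c("gene_id\tmodule_label", "g1\tblue", "g1\tred"), f)
  expect_error(import_modules(f), "more than one module")
})
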