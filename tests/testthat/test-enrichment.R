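test_that("promoter windows are strand-aware, half-open and clipped", {
  g <- data.frame(gene_id = c("p", "m", "edge"),
                  chrom = "chr1", tss = c(5000L, 5000L, 1000L),
                  strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  w <- promoter_windows(g, 2000L)
  expect_equal(w$start[w$gene_id == "p"], 3000L)
  expect_equal(w$end[w$gene_id == "p"], 5000L)
  expect_equal(w$start[w$gene_id == "m"], 5001L)
  expect_equal(w$end[w$gene_id == "m"], 7001L)
  expect_equal(w$start[w$gene_id == "edge"], 0L)
  expect_equal(w$end[w$gene_id == "edge"], 1000L)

  # clipping at the chromosome end, and TSS beyond it is an error
  w2 <- promoter_windows(g, 2000L, chrom_lengths = c(chr1 = 6000L))
  expect_equal(w2$end[w2$gene_id == "m"], 6000L)
  g$tss[1] <- 7000L
  expect_error(promoter_windows(g, 2000L, chrom_lengths = c(chr1 = 6000L)),
               "beyond chromosome end")

  # strand-ignorant mode places every window left of the TSS
  w3 <- promoter_windows(g[2, ], 2000L, strand_aware = FALSE)
  expect_equal(w3$start, 3000L)
  expect_equal(w3$end, 5000L)
})

test_that("window overlap counting honours half-open boundaries", {
  w <- data.frame(gene_id = "G1", chrom = "chr1", start = 3000L, end = 5000L,
                  strand = "+", stringsAsFactors = FALSE)
  mk_inst <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                       repeat_name = "R1",
                                       repeat_class = "Other",
                                       repeat_family = "Other", strand = ".",
                                       stringsAsFactors = FALSE)
  expect_equal(count_window_repeats(w, mk_inst(2999L, 3001L))$total, 1L)
  expect_equal(count_window_repeats(w, mk_inst(1000L, 3000L))$total, 0L)
  expect_equal(count_window_repeats(w, mk_inst(5000L, 5100L))$total, 0L)
})

test_that("overlap counts equal the brute-force all-pairs oracle", {
  for (seed in 1:20) {
    fx <- rand_fixture(seed, n_inst = 100L, n_genes = 20L)
    set.seed(seed + 1000)
    genes <- data.frame(gene_id = sprintf("G%02d", 1:20), chrom = "chrA",
                        tss = sample(2500:47000, 20),
                        strand = sample(c("+", "-"), 20, TRUE),
                        stringsAsFactors = FALSE)
    w <- promoter_windows(genes, 2000L)
    for (mode in c("instance", "pair")) {
      got <- count_window_repeats(w, fx, count_mode = mode)
      want <- oracle_window_counts(w, fx, count_mode = mode)
      expect_equal(got$total, want$total)
      gotc <- stats::setNames(got$per_repeat$count, got$per_repeat$repeat_name)
      expect_equal(gotc[sort(names(gotc))],
                   unlist(as.list(want$counts))[sort(names(gotc))],
                   ignore_attr = TRUE)
      expect_equal(lapply(got$gene_sets, sort), lapply(want$gene_sets, sort))
    }
  }
})

test_that("enrichment score follows (r/R)/(g/G) with degenerate contracts", {
  expect_equal(enrichment_score(10, 100, 50, 1000), 2.0)
  expect_equal(enrichment_score(5, 50, 100, 1000), 1.0)
  expect_equal(enrichment_score(0, 50, 100, 1000), 0)
  # degenerate contracts: zero numerator share scores 0, zero background
  # share with hits present is flagged infinite, empty margins are an error
  expect_true(is.infinite(enrichment_score(3, 10, 0, 1000)))
  expect_error(enrichment_score(1, 0, 1, 10), "R and G")
})

test_that("Fisher p matches hypergeometric enumeration", {
  expect_equal(fisher_pvalue(0, 0, 0, 0), 1.0)
  # [[5,0],[0,5]]: r=5, R=5, g=5, G=10
  expect_equal(fisher_pvalue(5, 5, 5, 10), 2 / 252, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:200) {
    G <- sample(5:60, 1)
    g <- sample(0:G, 1)
    R <- sample(1:G, 1)
    rr <- max(0, R - (G - g)):min(R, g)
    r <- rr[sample.int(length(rr), 1)]
    expect_equal(fisher_pvalue(r, R, g, G), oracle_fisher_p(r, R, g, G),
                 tolerance = 1e-9)
  }
  expect_error(fisher_pvalue(5, 4, 5, 10), "negative")
})

test_that("significance rule enforces gene count, ES and p thresholds", {
  res <- data.frame(
    repeat_name = c("a", "b", "c", "d"), module = "blue",
    r = 5, R = 50, g = 10, G = 1000,
    n_genes = c(6L, 4L, 20L, 6L),
    ES = c(2.0, 2.0, 1.49, 4.0),
    p = c(1e-5, 1e-5, 1e-9, 1e-5),
    significant = NA, fig_tier = NA, stringsAsFactors = FALSE)
  keep <- significant_enrichments(res)
  expect_setequal(keep$repeat_name, c("a", "d"))
})

test_that("uniform placement gives ES near 1 and full driver flags planted pairs", {
  # a repeat placed like the background should not look enriched
  es <- vapply(1:20, function(seed) {
    set.seed(seed)
    genes <- data.frame(gene_id = sprintf("G%03d", 1:120), chrom = "chrA",
                        tss = sample(3000:996000, 120),
                        strand = sample(c("+", "-"), 120, TRUE),
                        stringsAsFactors = FALSE)
    inst <- data.frame(chrom = "chrA",
                       start = sample(0:999000, 900, replace = TRUE),
                       repeat_name = sample(c("X", paste0("bg", 1:8)), 900,
                                            replace = TRUE,
                                            prob = c(0.2, rep(0.1, 8))),
                       repeat_class = "Other", repeat_family = "Other",
                       strand = ".", stringsAsFactors = FALSE)
    inst$end <- inst$start + 300L
    mods <- data.frame(gene_id = sprintf("G%03d", 1:40), module_label = "blue")
    enr <- enrich_repeats(genes, inst, mods)
    x <- enr$ES[enr$repeat_name == "X"]
    if (length(x) == 0) NA_real_ else x
  }, numeric(1))
  expect_gte(mean(es, na.rm = TRUE), 0.8)
  expect_lte(mean(es, na.rm = TRUE), 1.2)
})
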