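# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's interval/count machinery.

# all-pairs half-open interval intersection; returns the (instance, window)
# hit pairs
oracle_overlap_pairs <- function(windows, instances) {
  hits_i <- integer(0)
  hits_j <- integer(0)
  for (i in seq_len(nrow(instances))) {
    for (j in seq_len(nrow(windows))) {
      if (instances$chrom[i] == windows$chrom[j] &&
          min(instances$end[i], windows$end[j]) -
            max(instances$start[i], windows$start[j]) >= 1) {
        hits_i <- c(hits_i, i)
        hits_j <- c(hits_j, j)
      }
    }
  }
  list(instance = hits_i, window = hits_j)
}

# per-repeat counts matching count_window_repeats contracts
oracle_window_counts <- function(windows, instances, count_mode = "instance") {
  h <- oracle_overlap_pairs(windows, instances)
  rn <- instances$repeat_name[h$instance]
  gid <- windows$gene_id[h$window]
  if (count_mode == "instance") {
    counts <- tapply(h$instance, rn, function(ix) length(unique(ix)))
  } else {
    counts <- tapply(h$instance, rn, length)
  }
  gene_sets <- lapply(split(gid, rn), unique)
  list(counts = counts, total = sum(counts), gene_sets = gene_sets)
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (no fisher.test involved)
oracle_fisher_p <- function(r, R, g, G) {
  supp <- max(0L, R - (G - g)):min(R, g)
  d <- stats::dhyper(supp, g, G - g, R)
  sum(d[d <= d[supp == r] * (1 + 1e-7)])
}

# brute-force point-in-interval assignment for CpGs
oracle_cpg_assign <- function(records, instances) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    for (j in seq_len(nrow(instances))) {
      if (records$chrom[i] == instances$chrom[j] &&
          records$pos[i] >= instances$start[j] &&
          records$pos[i] < instances$end[j]) {
        out[[length(out) + 1L]] <- data.frame(rec = i,
                                              repeat_name = instances$repeat_name[j])
      }
    }
  }
  if (length(out) == 0L) return(data.frame(rec = integer(0),
                                           repeat_name = character(0)))
  do.call(rbind, out)
}

# random small annotation fixture on a 2 x 50 kb genome
rand_fixture <- function(seed, n_inst = 30L, n_genes = 8L) {
  set.seed(seed)
  chroms <- c("chrA", "chrB")
  genes <- data.frame(
    gene_id = sprintf("G%02d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    tss = sample(2500:47000, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  len <- sample(50:800, n_inst, replace = TRUE)
  inst <- data.frame(
    chrom = sample(chroms, n_inst, replace = TRUE),
    start = sample(0:49000, n_inst, replace = TRUE),
    repeat_name = sample(c("ALU1", "L1X", "SVA_T", "SAT9"), n_inst,
                         replace = TRUE),
    repeat_class = "Other", repeat_family = "Other",
    strand = ".", stringsAsFactors = FALSE)
  inst$end <- inst$start + len
  inst[, c("chrom", "start", "end", "repeat_name", "repeat_class",
           "repeat_family", "strand")]
}

# minimal cell metadata over all 9 stages
toy_meta <- function(cells_per_stage = 4L) {
  stages <- repdyn_stages()
  data.frame(
    cell_id = sprintf("c%03d", seq_len(cells_per_stage * length(stages))),
    stage = factor(rep(stages, each = cells_per_stage), levels = stages,
                   ordered = TRUE),
    embryo_id = "e1", stringsAsFactors = FALSE)
}
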