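#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator. The defaults
#' emulate the structure of single-cell pre-implantation datasets: 9 ordered
#' stages (oocyte through late blastocyst plus two ESC passages) with around
#' a dozen cells each, ~300 repeat types across 8 classes with negative
#' binomial counts, a planted Satellite peak at the 4-cell stage, a planted
#' SVA peak at the 8-cell and morula stages, a mild global expression dip at
#' the blastocyst stage, stage-specific gene modules, a promoter-enriched
#' (repeat, module) pair, and a global DNA-methylation dip at the 4-cell
#' stage with a slight 8-cell rebound.
#'
#' @param seed integer seed; every simulate_* call derives its RNG stream
#'   from it, so outputs are fully reproducible.
#' @param cells_per_stage cells per developmental stage (default 13).
#' @param class_sizes named integer vector: repeats per class.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean counts
#'   for repeats.
#' @param dispersion negative binomial dispersion (default 0.3; size =
#'   1/dispersion).
#' @param satellite_peak_stage,satellite_peak_log2fc planted Satellite
#'   effect (default +2 log2 at 4cell).
#' @param sva_peak_stages,sva_peak_log2fc planted SVA effect (default +2
#'   log2 at 8cell and morula).
#' @param blastocyst_shift_log2 global late-blastocyst shift (default -0.5).
#' @param stage_walk_sd per-stage-step standard deviation (log2 units) of
#'   the per-repeat developmental random walk; 0 disables it.
#' @param n_genes number of genes (default 600).
#' @param module_stages,module_size,module_log2fc planted gene modules: one
#'   module of `module_size` genes per stage listed, up-shifted by
#'   `module_log2fc` log2 units at that stage.
#' @param gene_baseline_meanlog,gene_baseline_sdlog gene baseline
#'   distribution.
#' @param n_chrom,chrom_length synthetic genome (default 5 x 10 Mb, small
#'   enough for brute-force interval oracles).
#' @param n_background_instances uniformly placed repeat instances.
#' @param instance_len_range repeat instance length range in bp.
#' @param planted_enrichment data.frame `repeat_name`, `module_stage`,
#'   `target_es`, `n_module_windows`: pairs planted by constructive
#'   placement so that the realised (r/R)/(g/G) is close to the target.
#' @param promoter_width upstream window width used during planting.
#' @param n_meth_repeats repeats carrying CpG records (Satellite and SVA
#'   always included).
#' @param cpgs_per_repeat_cell CpG sites simulated per (repeat, cell).
#' @param coverage_mean,coverage_size negative binomial read coverage model.
#' @param low_coverage_frac fraction of CpGs drawn with coverage < 5 to
#'   exercise the coverage filter.
#' @param meth_stage_rates named per-stage methylation rates in [0,1]
#'   (default: 0.8 everywhere, 0.4 at 4cell, 0.85 at 8cell).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       cells_per_stage = 13L,
                       class_sizes = c(LINE = 60L, SINE = 60L, LTR = 60L,
                                       DNA = 40L, Satellite = 30L, SVA = 10L,
                                       smallRNA = 20L, Other = 20L),
                       baseline_meanlog = log(20), baseline_sdlog = 1,
                       dispersion = 0.3,
                       satellite_peak_stage = "4cell",
                       satellite_peak_log2fc = 2,
                       sva_peak_stages = c("8cell", "morula"),
                       sva_peak_log2fc = 2,
                       blastocyst_shift_log2 = -0.5,
                       stage_walk_sd = 0.5,
                       n_genes = 600L,
                       module_stages = c("4cell", "8cell", "morula"),
                       module_size = 40L, module_log2fc = 2,
                       gene_baseline_meanlog = log(30),
                       gene_baseline_sdlog = 1,
                       n_chrom = 5L, chrom_length = 1e7,
                       n_background_instances = 3000L,
                       instance_len_range = c(200L, 1500L),
                       planted_enrichment = data.frame(
                         repeat_name = "SVA_1", module_stage = "8cell",
                         target_es = 4, n_module_windows = 12L,
                         stringsAsFactors = FALSE),
                       promoter_width = 2000L,
                       n_meth_repeats = 60L,
                       cpgs_per_repeat_cell = 8L,
                       coverage_mean = 20, coverage_size = 10,
                       low_coverage_frac = 0.1,
                       meth_stage_rates = c(oocyte = 0.8, zygote = 0.8,
                                            `2cell` = 0.8, `4cell` = 0.4,
                                            `8cell` = 0.85, morula = 0.8,
                                            late_blastocyst = 0.8,
                                            ESC_P0 = 0.8, ESC_P10 = 0.8)) {
  cfg <- as.list(environment())
  .assert(is.numeric(seed) && length(seed) == 1L && !is.na(seed),
          "seed must be a single integer")
  .assert(cells_per_stage >= 2L, "need >= 2 cells per stage")
  .assert(all(class_sizes >= 0L) && all(names(class_sizes) %in% repeat_classes()),
          "class_sizes must be named by known repeat classes")
  .assert(dispersion > 0, "dispersion must be > 0")
  .assert(stage_walk_sd >= 0, "stage_walk_sd must be >= 0")
  .assert(all(meth_stage_rates >= 0 & meth_stage_rates <= 1),
          "methylation rates must lie in [0, 1]")
  .assert(all(repdyn_stages() %in% names(meth_stage_rates)),
          "meth_stage_rates must cover all stages")
  .assert(all(module_stages %in% repdyn_stages()), "unknown module stage")
  .assert(n_genes >= length(module_stages) * module_size,
          "n_genes too small for the planted modules")
  class(cfg) <- "sim_config"
  cfg
}

# repeat names and class map implied by the config
.sim_repeats <- function(config) {
  nm <- unlist(lapply(names(config$class_sizes), function(cl)
    if (config$class_sizes[[cl]] > 0L)
      paste0(cl, "_", seq_len(config$class_sizes[[cl]]))
    else character(0)))
  cls <- rep(names(config$class_sizes), times = config$class_sizes)
  stats::setNames(cls, nm)
}

# gene ids and planted module membership; deterministic in config$seed only,
# so counts and annotation simulations agree without sharing state
.planted_module_genes <- function(config) {
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 7919L)
  picked <- sample(gene_ids, config$module_size * length(config$module_stages))
  data.frame(gene_id = picked,
             stage = rep(config$module_stages, each = config$module_size),
             module_label = .stage_colour(
               rep(config$module_stages, each = config$module_size)),
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate repeat counts, gene TPMs and cell metadata
#'
#' Counts are negative binomial with mean `baseline * 2^(planted effect)`.
#' The default scenario plants a +2 log2 Satellite effect at the 4-cell
#' stage, a +2 log2 SVA effect at 8-cell and morula, and a -0.5 log2 global
#' shift at the late blastocyst; planted module genes are up-shifted at
#' their stage. On top of the planted programmes every repeat follows a
#' small log2 random walk across the ordered stages, giving the broad
#' developmental drift seen in real embryonic repeatomes. A quarter of repeat count entries receive a sub-integer
#' fractional component, emulating fractional multi-mapping read assignment.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (repeat x cell), `tpm` (gene x cell, columns
#'   scaled to 1e6), `meta` (cell metadata), and `truth` (repeat class map,
#'   planted peak stages, module gene table).
#' @export
simulate_counts <- function(config) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  mg <- .planted_module_genes(config)
  set.seed(config$seed)
  stages <- repdyn_stages()
  n_cells <- config$cells_per_stage * length(stages)
  meta <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n_cells)),
    stage = .as_stage(rep(stages, each = config$cells_per_stage)),
    embryo_id = paste0(rep(stages, each = config$cells_per_stage), "_e",
                       rep(ceiling(seq_len(config$cells_per_stage) / 4L),
                           times = length(stages))),
    stringsAsFactors = FALSE)

  cls <- .sim_repeats(config)
  nR <- length(cls)
  baseline <- stats::rlnorm(nR, config$baseline_meanlog, config$baseline_sdlog)
  effect <- matrix(0, nR, length(stages), dimnames = list(names(cls), stages))
  effect[cls == "Satellite", config$satellite_peak_stage] <-
    config$satellite_peak_log2fc
  effect[cls == "SVA", config$sva_peak_stages] <- config$sva_peak_log2fc
  effect[, "late_blastocyst"] <- effect[, "late_blastocyst"] +
    config$blastocyst_shift_log2
  # broad developmental drift: each repeat follows a random walk across the
  # ordered stages (anchored at the oocyte), so the transcriptome changes
  # progressively along the trajectory rather than only at the planted peaks
  if (config$stage_walk_sd > 0) {
    steps <- matrix(stats::rnorm(nR * (length(stages) - 1L),
                                 sd = config$stage_walk_sd),
                    nR, length(stages) - 1L)
    walk <- cbind(0, t(apply(steps, 1L, cumsum)))
    effect <- effect + walk
  }
  size <- 1 / config$dispersion
  mu <- baseline * 2^effect[, as.character(meta$stage), drop = FALSE]
  counts <- matrix(stats::rnbinom(nR * n_cells, mu = mu, size = size),
                   nR, n_cells, dimnames = list(names(cls), meta$cell_id))
  frac <- stats::runif(length(counts)) < 0.25
  counts[frac] <- counts[frac] + round(stats::runif(sum(frac), 0.01, 0.99), 2)

  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  gbase <- stats::rlnorm(config$n_genes, config$gene_baseline_meanlog,
                         config$gene_baseline_sdlog)
  geff <- matrix(0, config$n_genes, length(stages),
                 dimnames = list(gene_ids, stages))
  geff[cbind(match(mg$gene_id, gene_ids), match(mg$stage, stages))] <-
    config$module_log2fc
  gmu <- gbase * 2^geff[, as.character(meta$stage), drop = FALSE]
  graw <- matrix(stats::rnbinom(config$n_genes * n_cells, mu = gmu, size = size),
                 config$n_genes, n_cells,
                 dimnames = list(gene_ids, meta$cell_id))
  tpm <- sweep(graw, 2L, colSums(graw), `/`) * 1e6

  peak <- c(stats::setNames(rep(config$satellite_peak_stage,
                                sum(cls == "Satellite")),
                            names(cls)[cls == "Satellite"]),
            stats::setNames(rep(config$sva_peak_stages[1L], sum(cls == "SVA")),
                            names(cls)[cls == "SVA"]))
  list(counts = counts, tpm = tpm, meta = meta,
       truth = list(repeat_class = cls, repeat_peak_stage = peak,
                    module_genes = mg))
}

#' Simulate repeat and gene annotation with planted promoter enrichment
#'
#' Places gene TSSs and background repeat instances uniformly over a small
#' synthetic genome, then plants each configured (repeat, module) enrichment
#' pair constructively: `n_module_windows` instances go into distinct
#' module-gene promoter windows, and the number of additional instances in
#' non-module windows is solved from the target ES given the exact
#' background counts, so the realised score lands close to the target. The
#' realised r, R, g, G and ES are recomputed by exact recount and recorded
#' in the returned truth.
#'
#' @param config a [sim_config()].
#' @return list with `instances`, `genes`, `chrom_lengths`, `module_genes`,
#'   and `truth` (realised enrichment per planted pair).
#' @export
simulate_annotation <- function(config) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  mg <- .planted_module_genes(config)
  set.seed(config$seed + 1L)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  chrom_lengths <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                                   chroms)
  w <- config$promoter_width
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = sample(chroms, config$n_genes, replace = TRUE),
    tss = as.integer(floor(stats::runif(config$n_genes, w + 2,
                                        config$chrom_length - w - 2))),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)

  cls <- .sim_repeats(config)
  planted_names <- unique(config$planted_enrichment$repeat_name)
  .assert(all(planted_names %in% names(cls)),
          "planted repeat(s) not in the configured repeat set")
  bg_names <- setdiff(names(cls), planted_names)
  n_bg <- config$n_background_instances
  len <- as.integer(floor(stats::runif(n_bg, config$instance_len_range[1L],
                                       config$instance_len_range[2L] + 1L)))
  inst <- data.frame(
    chrom = sample(chroms, n_bg, replace = TRUE),
    start = as.integer(floor(stats::runif(n_bg, 0,
                                          config$chrom_length - max(len)))),
    repeat_name = sample(bg_names, n_bg, replace = TRUE),
    stringsAsFactors = FALSE)
  inst$end <- inst$start + len
  inst$repeat_class <- unname(cls[inst$repeat_name])
  inst$repeat_family <- inst$repeat_class
  inst$strand <- sample(c("+", "-"), n_bg, replace = TRUE)
  inst <- inst[, c("chrom", "start", "end", "repeat_name", "repeat_class",
                   "repeat_family", "strand")]

  all_w <- promoter_windows(genes, w, chrom_lengths)
  truth <- list()
  plant_len <- 150L  # planted instances are short, always inside one window
  for (k in seq_len(nrow(config$planted_enrichment))) {
    pe <- config$planted_enrichment[k, ]
    mod_ids <- mg$gene_id[mg$stage == pe$module_stage]
    .assert(length(mod_ids) >= pe$n_module_windows,
            "planted module smaller than n_module_windows")
    mod_w <- all_w[all_w$gene_id %in% mod_ids, , drop = FALSE]
    oth_w <- all_w[!(all_w$gene_id %in% mod_ids), , drop = FALSE]
    R0 <- count_window_repeats(mod_w, inst)$total
    G0 <- count_window_repeats(all_w, inst)$total
    A <- pe$n_module_windows
    denom <- pe$target_es * (R0 + A) - A
    x_b <- round(A * (G0 + A - pe$target_es * (R0 + A)) / denom)
    if (denom <= 0 || x_b < 0 || x_b > nrow(oth_w))
      .halt(paste("target ES %.2f infeasible: background gives R0=%d, G0=%d;",
                  "solved off-module count %.0f outside [0, %d]"),
            pe$target_es, R0, G0,
            A * (G0 + A - pe$target_es * (R0 + A)) / denom, nrow(oth_w))
    place_in <- function(wins) {
      off <- as.integer(floor(stats::runif(nrow(wins), 0,
                                           wins$end - wins$start - plant_len)))
      data.frame(chrom = wins$chrom, start = wins$start + off,
                 end = wins$start + off + plant_len,
                 repeat_name = pe$repeat_name,
                 repeat_class = unname(cls[pe$repeat_name]),
                 repeat_family = unname(cls[pe$repeat_name]),
                 strand = "+", stringsAsFactors = FALSE)
    }
    sel_mod <- mod_w[sample.int(nrow(mod_w), A), , drop = FALSE]
    sel_oth <- oth_w[sample.int(nrow(oth_w), x_b), , drop = FALSE]
    inst <- rbind(inst, place_in(sel_mod),
                  if (x_b > 0L) place_in(sel_oth))
    # exact recount: the realised score, not the algebraic target, is truth
    fg <- count_window_repeats(mod_w, inst)
    bg <- count_window_repeats(all_w, inst)
    r <- fg$per_repeat$count[fg$per_repeat$repeat_name == pe$repeat_name]
    g <- bg$per_repeat$count[bg$per_repeat$repeat_name == pe$repeat_name]
    truth[[k]] <- data.frame(
      repeat_name = pe$repeat_name,
      module_label = .stage_colour(pe$module_stage),
      module_stage = pe$module_stage,
      r = r, R = fg$total, g = g, G = bg$total,
      realised_es = enrichment_score(r, fg$total, g, bg$total),
      target_es = pe$target_es, stringsAsFactors = FALSE)
  }
  rownames(inst) <- NULL
  list(instances = validate_repeat_instances(inst), genes = genes,
       chrom_lengths = chrom_lengths, module_genes = mg,
       truth = if (length(truth) > 0L) do.call(rbind, truth) else NULL)
}

#' Simulate per-CpG methylation records
#'
#' For each (repeat, cell) pair of the methylation subset, CpG positions are
#' sampled inside the repeat's instances; read coverage is negative binomial
#' (default mean 20) with a configurable fraction of low-coverage (< 5 reads)
#' sites to exercise the coverage filter, and methylated read counts are
#' binomial with the (repeat, stage) rate. The default rate table applies
#' the per-stage profile (global 4-cell dip, slight 8-cell rebound) to every
#' repeat; an explicit repeat-by-stage `rates` matrix overrides it, which is
#' how inverse methylation-expression couplings are constructed.
#'
#' @param config a [sim_config()].
#' @param instances repeat instance table (e.g. from
#'   [simulate_annotation()]).
#' @param meta cell metadata (e.g. from [simulate_counts()]).
#' @param rates optional repeat-by-stage rate matrix in [0,1]; rownames are
#'   repeat names, colnames stages.
#' @return list with `records` (CpG record data.frame) and `truth` (the
#'   rate matrix used).
#' @export
simulate_methylation <- function(config, instances, meta, rates = NULL) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(config$seed + 2L)
  cls <- .sim_repeats(config)
  have_inst <- intersect(names(cls), unique(instances$repeat_name))
  core <- have_inst[cls[have_inst] %in% c("Satellite", "SVA")]
  extra <- setdiff(have_inst, core)
  n_extra <- max(0L, config$n_meth_repeats - length(core))
  sel <- c(core, extra[seq_len(min(n_extra, length(extra)))])
  if (!is.null(rates)) {
    .assert(all(rownames(rates) %in% names(cls)) &&
              all(repdyn_stages() %in% colnames(rates)) &&
              all(rates >= 0 & rates <= 1),
            "rates must be a repeat-by-stage matrix with values in [0, 1]")
    sel <- intersect(sel, rownames(rates))
    .assert(length(sel) > 0L, "no selected repeat present in rates")
  } else {
    rates <- matrix(rep(config$meth_stage_rates[repdyn_stages()],
                        each = length(sel)),
                    nrow = length(sel),
                    dimnames = list(sel, repdyn_stages()))
  }
  inst_by_rep <- split(seq_len(nrow(instances)), instances$repeat_name)
  n_cpg <- config$cpgs_per_repeat_cell
  recs <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    rn <- sel[i]
    idx <- inst_by_rep[[rn]]
    pick <- idx[sample.int(length(idx), n_cpg * nrow(meta), replace = TRUE)]
    pos <- instances$start[pick] +
      as.integer(floor(stats::runif(length(pick)) *
                         (instances$end[pick] - instances$start[pick])))
    cell <- rep(meta$cell_id, each = n_cpg)
    stage <- rep(as.character(meta$stage), each = n_cpg)
    cov <- stats::rnbinom(length(pick), mu = config$coverage_mean,
                          size = config$coverage_size)
    cov <- pmax(cov, 1L)
    low <- stats::runif(length(pick)) < config$low_coverage_frac
    cov[low] <- sample(1:4, sum(low), replace = TRUE)
    meth <- stats::rbinom(length(pick), cov, rates[rn, stage])
    recs[[i]] <- data.frame(cell_id = cell, chrom = instances$chrom[pick],
                            pos = pos, meth_reads = meth, total_reads = cov,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = validate_cpg_records(records), truth = rates)
}

#' Run the full generator and write all pipeline inputs
#'
#' Emits `counts.tsv`, `genes_tpm.tsv`, `meta.tsv`, `rmsk.bed`, `genes.bed`,
#' `cpgs.bed` and the machine-readable ground truth `truth.json` into
#' `out_dir`. Every file passes its own reader's validation, and the seed is
#' recorded in each TSV header.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return list of the written paths plus the in-memory objects, invisibly.
#' @export
simulate_repeatome <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- simulate_counts(config)
  ann <- simulate_annotation(config)
  mth <- simulate_methylation(config, ann$instances, cnt$meta)
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    genes_tpm = file.path(out_dir, "genes_tpm.tsv"),
    meta = file.path(out_dir, "meta.tsv"),
    rmsk = file.path(out_dir, "rmsk.bed"),
    genes = file.path(out_dir, "genes.bed"),
    cpgs = file.path(out_dir, "cpgs.bed"),
    truth = file.path(out_dir, "truth.json"))
  write_count_matrix(cnt$counts, paths$counts, row_label = "repeat_name",
                     seed = config$seed)
  write_count_matrix(cnt$tpm, paths$genes_tpm, row_label = "gene_id",
                     seed = config$seed)
  write_cell_metadata(cnt$meta, paths$meta, seed = config$seed)
  write_repeat_annotation(ann$instances, paths$rmsk)
  write_gene_models(ann$genes, paths$genes)
  write_cpg_records(mth$records, paths$cpgs)
  truth <- list(
    seed = config$seed,
    repeat_class = as.list(cnt$truth$repeat_class),
    repeat_peak_stage = as.list(cnt$truth$repeat_peak_stage),
    module_genes = cnt$truth$module_genes,
    planted_enrichment = ann$truth,
    chrom_lengths = as.list(ann$chrom_lengths),
    methylation_rates = list(repeats = rownames(mth$truth),
                             stages = colnames(mth$truth),
                             rates = unname(as.data.frame(mth$truth))))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(counts = cnt, annotation = ann, methylation = mth)))
}
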