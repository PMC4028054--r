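#' Default pipeline configuration
#'
#' Returns the bundled demo configuration: a fully synthetic study small
#' enough to run in seconds, with the study-scale defaults (two replicate
#' 454-style libraries of ~316 nt reads, 1% planted chimeras, UTR-padded
#' contigs, coverage-dependent assembly completeness).
#'
#' @param seed Global seed stored in the config.
#' @return A nested configuration list (see the bundled
#'   `inst/extdata/demo_config.yaml`).
#' @export
demo_config <- function(seed = 42L) {
  path <- system.file("extdata", "demo_config.yaml", package = "tsepipe")
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(seed)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config Nested configuration list (see [demo_config()]).
#' @return Character vector of human-readable violations; empty iff the
#'   configuration is runnable.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (is.null(config$seed) || !num(config$seed)) {
    say("seed: mandatory integer seed is missing")
  }
  s <- config$synth %||% list()
  if (!is.null(s$n_families) && (!num(s$n_families) || s$n_families < 1)) {
    say("synth.n_families: must be >= 1")
  }
  if (!is.null(s$zero_fraction) &&
      (!num(s$zero_fraction) || s$zero_fraction < 0 || s$zero_fraction >= 1)) {
    say("synth.zero_fraction: must lie in [0, 1)")
  }
  if (!is.null(s$chimera_fraction) &&
      (!num(s$chimera_fraction) || s$chimera_fraction < 0 ||
       s$chimera_fraction > 0.5)) {
    say("synth.chimera_fraction: must lie in [0, 0.5]")
  }
  if (!is.null(s$miss_rate) &&
      (!num(s$miss_rate) || s$miss_rate < 0 || s$miss_rate > 1)) {
    say("synth.miss_rate: must lie in [0, 1]")
  }
  if (!is.null(s$spurious_rate) &&
      (!num(s$spurious_rate) || s$spurious_rate < 0 || s$spurious_rate >= 1)) {
    say("synth.spurious_rate: must lie in [0, 1)")
  }
  if (!is.null(s$mean_len) && (!num(s$mean_len) || s$mean_len < 50)) {
    say("synth.mean_len: must be >= 50")
  }
  if (!is.null(s$utr_padding) &&
      !(s$utr_padding %in% c("true_utr", "none"))) {
    say("synth.utr_padding: must be 'true_utr' or 'none'")
  }
  li <- config$lineages %||% list()
  if (!is.null(li$evalue_cutoff) &&
      (!num(li$evalue_cutoff) || li$evalue_cutoff <= 0)) {
    say("lineages.evalue_cutoff: must be > 0")
  }
  e <- config$expression %||% list()
  if (!is.null(e$min_count) && (!num(e$min_count) || e$min_count < 1)) {
    say("expression.min_count: must be >= 1")
  }
  r <- config$rarefaction %||% list()
  if (!is.null(r$theta) && (!num(r$theta) || r$theta < 0)) {
    say("rarefaction.theta: must be >= 0")
  }
  if (!is.null(r$reps) && (!num(r$reps) || r$reps < 1)) {
    say("rarefaction.reps: must be >= 1")
  }
  cx <- config$crossx %||% list()
  if (!is.null(cx$detection_threshold) && !num(cx$detection_threshold)) {
    say("crossx.detection_threshold: must be a finite number")
  }
  a <- config$annotate %||% list()
  for (fld in c("min_segment", "max_overlap", "chimera_max_evalue")) {
    if (!is.null(a[[fld]]) && (!num(a[[fld]]) || a[[fld]] < 0)) {
      say(paste0("annotate.", fld, ": must be >= 0"))
    }
  }
  v
}

#' Run the full synthetic benchmark pipeline
#'
#' Executes all stages in dependency order — simulate, annotate,
#' quantify (TSE1 and TSE2), rarefy, decompose lineages, cross-platform
#' comparison, qPCR validation — writes every table under `outdir`, and
#' returns (and writes) a machine-readable run report. Identical
#' (config, seed) pairs yield byte-identical outputs.
#'
#' @param config Configuration list (see [demo_config()]); validated
#'   before any stage runs.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return The run report, invisibly (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  viol <- validate_config(config)
  if (length(viol) > 0L) {
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[tsepipe] ", ...)
  seed <- as.integer(config$seed)
  s <- config$synth %||% list()
  tsv <- function(df, file) {
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- synth ---------------------------------------------------------
  log_stage("synth: generating universe")
  fam <- generate_universe(
    n_families = s$n_families %||% 800,
    seed = child_seed(seed, "universe"))
  fam <- generate_abundances(
    fam, meanlog = s$abundance_meanlog %||% 2,
    sdlog = s$abundance_sdlog %||% 1.5,
    zero_fraction = s$zero_fraction %||% 0.2,
    seed = child_seed(seed, "abundance"))
  reads <- generate_reads(
    fam, n_reads = s$n_reads %||% 3e4, mean_len = s$mean_len %||% 316,
    sd_len = s$sd_len %||% 80, n_replicates = s$n_replicates %||% 2,
    seed = child_seed(seed, "reads"))
  contigs <- generate_contigs(
    fam, chimera_fraction = s$chimera_fraction %||% 0.01,
    utr_padding = s$utr_padding %||% "true_utr",
    completeness = s$completeness %||% "auto",
    assembly_depth = s$n_reads %||% 3e4,
    seed = child_seed(seed, "contigs"))
  hits <- generate_hit_tables(
    contigs, fam, miss_rate = s$miss_rate %||% 0,
    spurious_rate = s$spurious_rate %||% 0,
    seed = child_seed(seed, "hits"))
  tse1_hits <- generate_read_hits(
    reads$truth, fam, target = "reference",
    miss_rate = s$miss_rate %||% 0, spurious_rate = s$spurious_rate %||% 0,
    seed = child_seed(seed, "tse1"))
  tse2_hits <- generate_read_hits(
    reads$truth, fam, target = "contigs", contig_sim = contigs,
    miss_rate = s$miss_rate %||% 0, spurious_rate = s$spurious_rate %||% 0,
    seed = child_seed(seed, "tse2"))
  array <- generate_microarray(
    fam, detection_threshold = (config$crossx %||% list())$detection_threshold %||% 100,
    seed = child_seed(seed, "array"))
  for (rep_name in names(reads$reads)) {
    write_fasta(reads$reads[[rep_name]],
                file.path(outdir, paste0("reads_rep", rep_name, ".fasta")))
  }
  write_fasta(contigs$contigs, file.path(outdir, "contigs.fasta"))
  for (tax in names(hits)) {
    write_hit_table(hits[[tax]]$fwd,
                    file.path(outdir, paste0("hits_", tax, "_fwd.tsv")))
  }

  ## -- annotate ------------------------------------------------------
  log_stage("annotate: reciprocal best hits and chimera flags")
  rbh <- reciprocal_best_hits(hits$At$fwd, hits$At$rev)
  a <- config$annotate %||% list()
  chim <- flag_chimeras(hits$Th$fwd,
                        min_segment = a$min_segment %||% 100,
                        max_overlap = a$max_overlap %||% 30,
                        max_evalue = a$chimera_max_evalue %||% 1e-10)
  tsv(rbh, "annotation.tsv")
  tsv(data.frame(contig_id = chim$contig_id, n_segments = chim$n_segments),
      "chimeras.tsv")

  ## -- expression ----------------------------------------------------
  log_stage("expression: TSE1/TSE2 counting and RPKM")
  e <- config$expression %||% list()
  at_lengths <- stats::setNames(fam$th_cds_length,
                                paste0("At_", fam$family_id))[fam$At]
  ctg_lengths <- stats::setNames(contigs$truth$length,
                                 contigs$truth$contig_id)
  cnt1 <- count_reads(tse1_hits)
  excl <- if (isTRUE(e$exclude_chimeras)) chim$contig_id else character(0)
  cnt2 <- count_reads(tse2_hits, exclude_subjects = excl)
  tab1 <- rpkm_table(cnt1$counts, at_lengths, cnt1$n_mappable, "TSE1")
  keep2 <- setdiff(names(ctg_lengths), excl)
  tab2 <- rpkm_table(cnt2$counts, ctg_lengths[keep2], cnt2$n_mappable,
                     "TSE2")
  # one gene keyspace for both strategies: contigs relabelled through
  # their reciprocal-best-hit annotation
  ctg2gene <- stats::setNames(rbh$gene_id, rbh$contig_id)
  ref_gene <- e$reference_gene %||% "auto"
  if (identical(ref_gene, "auto")) {
    cand <- fam[fam$At & fam$true_abundance > 0, ]
    cand <- cand[order(-cand$true_abundance), ]
    cand_gene <- paste0("At_", cand$family_id)
    ok <- cand_gene %in% ctg2gene & cand_gene %in% tab1$gene_id
    if (!any(ok)) stop("expression: no usable auto reference gene")
    ref_gene <- cand_gene[ok][1L]
  }
  prof1 <- normalize_to_reference(tab1, ref_gene)
  ref_contig <- names(ctg2gene)[match(ref_gene, ctg2gene)]
  prof2_ctg <- normalize_to_reference(tab2, ref_contig)
  annotated <- names(prof2_ctg) %in% names(ctg2gene)
  prof2 <- stats::setNames(prof2_ctg[annotated],
                           ctg2gene[names(prof2_ctg)[annotated]])
  tsv(cbind(tab1, normalized_ratio = prof1), "expression_tse1.tsv")
  tsv(cbind(tab2, normalized_ratio = prof2_ctg), "expression_tse2.tsv")

  ## -- rarefaction ---------------------------------------------------
  log_stage("rarefaction: per-replicate and merged curves")
  r <- config$rarefaction %||% list()
  repl_of_read <- stats::setNames(reads$truth$replicate,
                                  reads$truth$read_id)
  libs <- lapply(sort(unique(reads$truth$replicate)), function(k) {
    h <- tse2_hits[repl_of_read[tse2_hits$query_id] == k, , drop = FALSE]
    ck <- count_reads(h, exclude_subjects = excl)
    rarefaction_library(ck$counts)
  })
  merged <- Reduce(merge_libraries, libs)
  grid_n <- r$grid_points %||% 40
  curves <- lapply(c(libs, list(merged)), function(lb) {
    g <- unique(round(seq(0, attr(lb, "N"), length.out = grid_n)))
    rarefaction_curve_analytic(lb, g)
  })
  names(curves) <- c(paste0("replicate", seq_along(libs)), "merged")
  mc <- rarefaction_curve_mc(
    merged, grid = curves$merged$n, reps = r$reps %||% 200,
    seed = child_seed(seed, "rarefy"))
  sat <- lapply(curves, assess_saturation, theta = r$theta %||% 1e-3)
  for (nm in names(curves)) {
    tsv(as.data.frame(curves[[nm]]), paste0("rarefaction_", nm, ".tsv"))
  }
  tsv(as.data.frame(mc), "rarefaction_merged_mc.tsv")

  ## -- lineages ------------------------------------------------------
  log_stage("lineages: presence vectors and subset decomposition")
  li <- config$lineages %||% list()
  vec <- presence_vectors(
    list(At = hits$At$fwd, Br = hits$Br$fwd, Cp = hits$Cp$fwd,
         Pt = hits$Pt$fwd),
    evalue_cutoff = li$evalue_cutoff %||% 1e-10,
    contig_ids = contigs$truth$contig_id)
  part <- decompose_sets(vec)
  tree <- taxon_tree(li$newick %||% NULL)
  events <- summarize_births_losses(part, tree)
  tsv(part$assignment, "lineage_subsets.tsv")
  tsv(events, "lineage_events.tsv")

  ## -- crossx --------------------------------------------------------
  log_stage("crossx: microarray vs sequencing presence")
  cx <- config$crossx %||% list()
  uniq <- filter_unique_probes(array$probe_map)
  probed_genes <- intersect(uniq$gene_id, rownames(array$expr))
  present_a <- microarray_presence(
    array$expr[probed_genes, , drop = FALSE],
    cx$detection_threshold %||% array$detection_threshold)
  present_b <- call_presence(tab2, min_count = e$min_count %||% 1L)
  homology <- data.frame(gene_a = rbh$gene_id, gene_b = rbh$contig_id,
                         stringsAsFactors = FALSE)
  comp <- compare_presence(present_a, present_b, homology)
  for (nm in c("only_a", "only_b", "shared_a", "unmapped_a", "unmapped_b")) {
    writeLines(sort(comp[[nm]]), file.path(outdir, paste0("crossx_", nm, ".txt")))
  }

  ## -- qpcr ----------------------------------------------------------
  log_stage("qpcr: dilution series, fold changes, TSE validation")
  q <- config$qpcr %||% list()
  panel_n <- q$n_panel %||% 14
  shared_genes <- intersect(names(prof1), names(prof2))
  shared_genes <- setdiff(shared_genes, ref_gene)
  fam_ab <- stats::setNames(fam$true_abundance,
                            paste0("At_", fam$family_id))
  shared_genes <- shared_genes[fam_ab[shared_genes] > 0]
  ord <- order(fam_ab[shared_genes], decreasing = TRUE)
  pick <- shared_genes[ord[unique(round(seq(1, length(ord),
                                            length.out = panel_n)))]]
  panel <- c(ref_gene, pick)
  qseed <- child_seed(seed, "qpcr")
  eff <- with_seed(qseed, stats::setNames(
    stats::runif(length(panel), 1.85, 2), panel))
  ab <- fam_ab[panel]
  outlier <- character(0)
  if (isTRUE(q$plant_outlier %||% TRUE) && length(pick) >= 2L) {
    # one discordant gene: qPCR sees several-fold more transcript than
    # sequencing attributes to it (cross-mapping gene-family analogue)
    outlier <- pick[[2L]]
    ab[outlier] <- ab[outlier] * (q$outlier_fold %||% 8)
  }
  flower_cq <- -log(ab * 1e-9) / log(eff[panel])
  leaf_cq <- flower_cq + with_seed(qseed + 1L,
                                   stats::rnorm(length(panel), 0, 1.5))
  gm <- cbind(flower = flower_cq, leaf = leaf_cq)
  rownames(gm) <- panel
  cqexp <- generate_cq(panel, eff, ref_gene, gm,
                       replicate_sd = q$replicate_sd %||% 0.15,
                       seed = qseed)
  eff_fit <- vapply(panel, function(g) {
    fit_efficiency(cqexp$dilution[cqexp$dilution$gene_id == g, ])$efficiency
  }, numeric(1L))
  qprof <- qpcr_profile(cqexp$cq, ref_gene, efficiencies = eff_fit,
                        group = "flower")
  val_all <- validate_against_qpcr(prof1[c(ref_gene, pick)], qprof,
                                   log_scale = TRUE)
  val_ex <- if (length(outlier) > 0L) {
    validate_against_qpcr(prof1[c(ref_gene, pick)], qprof,
                          exclude = outlier, log_scale = TRUE)
  } else val_all
  anova_p <- vapply(panel, function(g) {
    by_group <- split(cqexp$cq$cq[cqexp$cq$gene_id == g],
                      cqexp$cq$group[cqexp$cq$gene_id == g])
    one_way_anova(by_group)$p_value
  }, numeric(1L))
  tsv(data.frame(gene_id = panel, efficiency_true = unname(eff[panel]),
                 efficiency_fit = unname(eff_fit),
                 anova_p = unname(anova_p)), "qpcr_assays.tsv")
  tsv(val_all$data, "qpcr_vs_tse1.tsv")

  ## -- report --------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("tsepipe")),
    seed = seed,
    counts = list(
      n_families = nrow(fam),
      n_expressed = sum(fam$true_abundance > 0),
      n_reads = nrow(reads$truth),
      n_contigs = nrow(contigs$truth),
      n_annotated = nrow(rbh),
      n_chimeric_flagged = nrow(chim),
      n_chimeric_planted = sum(contigs$truth$n_constituents > 1L),
      n_mappable_tse1 = cnt1$n_mappable,
      n_mappable_tse2 = cnt2$n_mappable,
      distinct_genes_merged = attr(merged, "S")
    ),
    subset_sizes = as.list(part$sizes),
    saturation = lapply(sat, function(x) {
      list(tail_slope = x$tail_slope, is_saturated = x$is_saturated)
    }),
    expression = list(
      reference_gene = ref_gene,
      median_ratio_tse1 = stats::median(prof1[shared_genes]),
      median_ratio_tse2 = stats::median(prof2[shared_genes])
    ),
    crossx = list(
      probes_total = length(unique(array$probe_map$probe_id)),
      probes_unique = length(unique(uniq$probe_id)),
      present_array = length(present_a),
      present_rnaseq = length(present_b),
      only_array = length(comp$only_a),
      only_rnaseq = length(comp$only_b)
    ),
    qpcr = list(
      panel_size = length(panel),
      r_squared_all = val_all$r_squared,
      r_squared_excl_outlier = val_ex$r_squared,
      excluded = outlier,
      max_efficiency_error = max(abs(eff_fit - eff[panel]))
    ),
    invariant_checks = list(
      counts_conserved = (sum(cnt1$counts) == cnt1$n_mappable) &&
        (sum(cnt2$counts) == cnt2$n_mappable),
      partition_exhaustive = sum(part$sizes) == nrow(contigs$truth),
      annotated_leq_contigs = nrow(rbh) <= nrow(contigs$truth)
    )
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: report written to ", file.path(outdir, "run_report.json"))
  invisible(report)
}
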