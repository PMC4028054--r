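test_that("single-best-hit counting conserves reads and matches the oracle", {
  h <- rbind(
    data.frame(query_id = "r1", subject_id = c("g1", "g2"),
               bitscore = c(100, 90), evalue = 1e-30),
    data.frame(query_id = "r2", subject_id = "g2",
               bitscore = 50, evalue = 1e-10)
  )
  h <- cbind(h, pct_identity = 90, aln_length = 100L, mismatches = 0L,
             gap_open = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
             s_end = 100L, s_strand = "+")
  got <- count_reads(h)
  expect_equal(got$counts, c(g1 = 1L, g2 = 1L))
  expect_equal(got$n_mappable, 2L)

  expect_equal(count_reads(h[0, ])$n_mappable, 0L)
  expect_length(count_reads(h[0, ])$counts, 0L)

  withr::local_seed(303)
  for (i in 1:30) {
    rh <- random_hit_table(15, 8, sample(10:60, 1))
    got <- count_reads(rh)
    want <- table(unlist(oracle_best_hit(rh)))
    expect_equal(got$counts, setNames(as.integer(want), names(want)))
    expect_equal(got$n_mappable, sum(got$counts))
    # exclusion removes subjects before selection
    ex <- count_reads(rh, exclude_subjects = unique(rh$subject_id)[1])
    expect_false(unique(rh$subject_id)[1] %in% names(ex$counts))
    expect_equal(ex$n_mappable, sum(ex$counts))
  }
})

test_that("RPKM follows the closed formula and the length-mismatch ratio", {
  t1 <- rpkm_table(c(gA = 10L), c(gA = 1000), 1e6)
  expect_equal(t1$rpkm, 10)
  t2 <- rpkm_table(c(gA = 50L), c(gA = 2000), 5e6)
  expect_equal(t2$rpkm, 5)

  # equal counts, contig 629 nt vs reference CDS 2406 nt: the contig-
  # normalised value exceeds the CDS-normalised one by 2406/629
  cds <- rpkm_table(c(SPL7 = 40L), c(SPL7 = 2406), 1e5, "TSE1")
  ctg <- rpkm_table(c(SPL7 = 40L), c(SPL7 = 629), 1e5, "TSE2")
  expect_equal(ctg$rpkm / cds$rpkm, 2406 / 629)
  expect_equal(ctg$rpkm / cds$rpkm, 3.825, tolerance = 1e-3)

  # genes with a model length but no reads appear with zero RPKM
  t3 <- rpkm_table(c(gA = 5L), c(gA = 500, gB = 800), 100)
  expect_equal(t3$rpkm[t3$gene_id == "gB"], 0)
  expect_error(rpkm_table(c(gA = 5L), c(gA = 500), 0), "n_mappable")
  expect_error(rpkm_table(c(gA = 5L), c(gB = 500), 10), "model length")
})

test_that("RPKM is invariant under joint scaling of counts and depth", {
  withr::local_seed(9)
  counts <- setNames(rpois(50, 40) + 1L, paste0("g", 1:50))
  lens <- setNames(sample(300:3000, 50), paste0("g", 1:50))
  base <- rpkm_table(counts, lens, sum(counts))
  for (k in c(2L, 10L)) {
    scaled <- rpkm_table(counts * k, lens, sum(counts) * k)
    expect_equal(scaled$rpkm, base$rpkm)
  }
})

test_that("reference normalisation yields unit reference and scale-free ratios", {
  counts <- c(ref = 20L, gA = 40L, gB = 5L)
  lens <- c(ref = 1000, gA = 1000, gB = 500)
  tab <- rpkm_table(counts, lens, sum(counts))
  prof <- normalize_to_reference(tab, "ref")
  expect_equal(prof[["ref"]], 1)
  expect_equal(prof[["gA"]], 2)
  scaled <- rpkm_table(counts * 3L, lens, sum(counts) * 3L)
  expect_equal(normalize_to_reference(scaled, "ref"), prof)
  zero <- rpkm_table(c(ref = 0L, gA = 2L), lens[1:2], 2)
  expect_error(normalize_to_reference(zero, "ref"), "no reads")
})

test_that("presence calls respect and shrink monotonically with min_count", {
  tab <- rpkm_table(c(gA = 1L, gB = 7L), c(gA = 100, gB = 100, gC = 100), 8)
  expect_setequal(call_presence(tab), c("gA", "gB"))
  expect_setequal(call_presence(tab, 5), "gB")
  expect_true(all(call_presence(tab, 5) %in% call_presence(tab, 1)))
  expect_error(call_presence(tab, 0), "min_count")
})

test_that("qPCR validation recovers perfect fits and benefits from outlier removal", {
  x <- setNames(c(1, 2, 4, 8, 0.5), paste0("g", 1:5))
  ident <- validate_against_qpcr(x, x)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  doubled <- validate_against_qpcr(2 * x, x)
  expect_equal(doubled$r_squared, 1)
  expect_equal(doubled$slope, 2)

  # a 14-gene panel with one discordant gene: exclusion lifts R^2
  withr::local_seed(17)
  q <- setNames(exp(rnorm(14, 0, 1)), paste0("g", 1:14))
  tse <- q * exp(rnorm(14, 0, 0.1))
  tse[["g7"]] <- q[["g7"]] * 12
  with_out <- validate_against_qpcr(tse, q, log_scale = TRUE)
  without <- validate_against_qpcr(tse, q, exclude = "g7",
                                   log_scale = TRUE)
  expect_gt(without$r_squared, with_out$r_squared)
  expect_equal(without$n, 13L)
  expect_error(validate_against_qpcr(x[1:2], x[1:2]), "at least 3")
})

test_that("TSE1 ranks recover truth and TSE2 ratios sit above TSE1 ratios", {
  st <- make_small_study(seed = 55, n_families = 600, n_reads = 4e4,
                         chimera_fraction = 0.01)
  h1 <- generate_read_hits(st$reads$truth, st$fam, "reference", seed = 56)
  h2 <- generate_read_hits(st$reads$truth, st$fam, "contigs",
                           contig_sim = st$contigs, seed = 57)
  c1 <- count_reads(h1)
  c2 <- count_reads(h2)
  expect_equal(sum(c1$counts), c1$n_mappable)
  expect_equal(sum(c2$counts), c2$n_mappable)
  at_len <- setNames(st$fam$th_cds_length,
                     paste0("At_", st$fam$family_id))[st$fam$At]
  t1 <- rpkm_table(c1$counts, at_len, c1$n_mappable, "TSE1")
  t2 <- rpkm_table(c2$counts,
                   setNames(st$contigs$truth$length,
                            st$contigs$truth$contig_id),
                   c2$n_mappable, "TSE2")
  ab <- setNames(st$fam$true_abundance, paste0("At_", st$fam$family_id))
  expect_gt(cor(ab[t1$gene_id], t1$rpkm, method = "spearman"), 0.9)

  cand <- st$fam[st$fam$At & st$fam$true_abundance > 0, ]
  ref <- paste0("At_", cand$family_id[which.max(cand$true_abundance)])
  refc <- st$contigs$truth$contig_id[
    match(sub("At_", "", ref), st$contigs$truth$family_id)]
  p1 <- normalize_to_reference(t1, ref)
  p2 <- normalize_to_reference(t2, refc)
  names(p2) <- paste0(
    "At_", st$contigs$truth$family_id[match(names(p2),
                                            st$contigs$truth$contig_id)])
  shared <- intersect(names(p1), names(p2))
  expect_gte(median(p2[shared]), median(p1[shared]))
})
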