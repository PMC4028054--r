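test_that("universe generation is seed-deterministic and respects forced regimes", {
  u1 <- generate_universe(200, seed = 5)
  u2 <- generate_universe(200, seed = 5)
  expect_identical(u1, u2)
  expect_false(identical(u1, generate_universe(200, seed = 6)))

  # no losses, all births at the root: every comparator taxon present
  all_root <- generate_universe(
    100, birth_probs = c(root = 1, malvids = 0, coreBrassicales = 0, Th = 0),
    loss_rates = c(Pt = 0, Cp = 0, Brassicaceae = 0, At = 0, Br = 0),
    seed = 1)
  expect_true(all(all_root$At & all_root$Br & all_root$Cp & all_root$Pt))

  # births confined to the focal terminal branch: fully lineage-specific
  th_only <- generate_universe(
    100, birth_probs = c(root = 0, malvids = 0, coreBrassicales = 0, Th = 1),
    seed = 1)
  expect_false(any(th_only$At | th_only$Br | th_only$Cp | th_only$Pt))
  expect_true(all(th_only$th_cds_length >= 150))
})

test_that("abundance model hits its zero fraction and degenerate limit", {
  fam <- generate_universe(1000, seed = 2)
  ab <- generate_abundances(fam, zero_fraction = 0.3, seed = 3)
  n_zero <- sum(ab$true_abundance == 0)
  # binomial: 300 +/- 4 sd (sd = sqrt(1000 * .3 * .7) ~ 14.5)
  expect_gt(n_zero, 300 - 4 * 14.5)
  expect_lt(n_zero, 300 + 4 * 14.5)

  degen <- generate_abundances(fam, meanlog = 1.3, sdlog = 1e-12,
                               zero_fraction = 0, seed = 4)
  expect_equal(degen$true_abundance, rep(exp(1.3), 1000), tolerance = 1e-6)
  expect_error(generate_abundances(fam, zero_fraction = 1), "zero_fraction")
})

test_that("read simulation matches the configured length model and replicate contract", {
  # long transcripts so that truncation does not bias the mean
  fam <- generate_universe(50, cds_meanlog = log(2500), cds_sdlog = 0.2,
                           seed = 8)
  fam <- generate_abundances(fam, zero_fraction = 0, seed = 9)
  sim <- generate_reads(fam, n_reads = 10000, mean_len = 316, sd_len = 80,
                        n_replicates = 2, seed = 10)
  se <- 80 / sqrt(10000)
  expect_lt(abs(mean(sim$truth$length) - 316), 3 * se)
  expect_identical(sim, generate_reads(fam, n_reads = 10000, mean_len = 316,
                                       sd_len = 80, n_replicates = 2,
                                       seed = 10))
  # replicates are disjoint and together carry all reads
  ids <- lapply(sim$reads, names)
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  expect_equal(sum(lengths(ids)), 10000)

  one <- fam[1, , drop = FALSE]
  one$true_abundance <- 5
  sim1 <- generate_reads(one, n_reads = 50, seed = 1)
  expect_true(all(sim1$truth$family_id == one$family_id))
})

test_that("read counts follow the abundance-times-length sampling law", {
  fam <- generate_universe(20, seed = 30)
  fam <- generate_abundances(fam, zero_fraction = 0, seed = 31)
  sim <- generate_reads(fam, n_reads = 1e5, seed = 32)
  obs <- table(factor(sim$truth$family_id, levels = fam$family_id))
  w <- fam$true_abundance * (fam$th_cds_length + fam$utr_length)
  gof <- suppressWarnings(stats::chisq.test(obs, p = w / sum(w)))
  expect_gt(gof$p.value, 1e-3)
})

test_that("contig assembly honours chimera fraction and UTR padding", {
  fam <- generate_universe(1200, seed = 12)
  fam <- generate_abundances(fam, zero_fraction = 1 / 6, seed = 13)

  pure <- generate_contigs(fam, chimera_fraction = 0, seed = 14)
  expect_true(all(pure$truth$n_constituents == 1L))

  full <- generate_contigs(fam, chimera_fraction = 0, completeness = 1,
                           seed = 14)
  i <- match(full$truth$family_id, fam$family_id)
  expect_equal(full$truth$length,
               fam$th_cds_length[i] + fam$utr_length[i])
  expect_equal(nchar(full$contigs), unname(full$truth$length),
               ignore_attr = TRUE)

  no_utr <- generate_contigs(fam, chimera_fraction = 0, completeness = 1,
                             utr_padding = "none", seed = 14)
  expect_equal(no_utr$truth$length, fam$th_cds_length[i])

  chim <- generate_contigs(fam, chimera_fraction = 0.1, seed = 15)
  n_exp <- sum(fam$true_abundance > 0)
  n_chim <- sum(chim$truth$n_constituents > 1L)
  sd_bin <- sqrt(n_exp * 0.1 * 0.9)
  expect_gt(n_chim, 0.1 * n_exp - 4 * sd_bin)
  expect_lt(n_chim, 0.1 * n_exp + 4 * sd_bin)
  # chimeric contigs concatenate their two constituents' contig sequences
  seg <- chim$segments
  expect_true(all(seg$q_end - seg$q_start + 1L >= 100L))
})

test_that("hit tables reproduce planted presence exactly when noise-free", {
  st <- make_small_study(seed = 21, n_families = 150, chimera_fraction = 0)
  vec <- presence_vectors(lapply(st$hits[c("At", "Br", "Cp", "Pt")],
                                 `[[`, "fwd"),
                          contig_ids = st$contigs$truth$contig_id)
  truth <- st$fam[match(st$contigs$truth$family_id, st$fam$family_id), ]
  for (tax in c("At", "Br", "Cp", "Pt")) {
    expect_equal(vec[[tax]], unname(truth[[tax]]), label = tax)
  }
  # total miss: no hits at all
  none <- generate_hit_tables(st$contigs, st$fam, miss_rate = 1, seed = 1)
  expect_equal(nrow(none$At$fwd), 0L)
  # determinism
  expect_identical(st$hits,
                   generate_hit_tables(st$contigs, st$fam, seed = 25))
})

test_that("dilution-series Cq follows the efficiency model exactly", {
  genes <- c("ref", "t1")
  eff <- c(ref = 2, t1 = 2)
  gm <- matrix(c(20, 24, 20, 24), 2, dimnames = list(genes, c("a", "b")))
  cq <- generate_cq(genes, eff, "ref", gm, replicate_sd = 0,
                    dilutions = 10^-(1:4), seed = 3)
  d <- cq$dilution[cq$dilution$gene_id == "t1", ]
  expect_equal(diff(d$cq[order(-d$log10_amount)]),
               rep(log2(10), 3), tolerance = 1e-12)
  # zero replicate noise: all replicates identical to the group mean
  expect_equal(unique(cq$cq$cq), c(20, 24))
  expect_identical(cq, generate_cq(genes, eff, "ref", gm, replicate_sd = 0,
                                   dilutions = 10^-(1:4), seed = 3))
  expect_error(generate_cq(genes, c(ref = 1, t1 = 2), "ref", gm),
               "efficiencies")
})
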