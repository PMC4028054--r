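mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               pct_identity = 95, aln_length = 100L, mismatches = 2L,
               gap_open = 0L,
               q_start = as.integer(r[["qs"]] %||% 1L),
               q_end = as.integer(r[["qe"]] %||% 100L),
               s_start = 1L, s_end = 100L,
               evalue = as.numeric(r[["e"]] %||% 1e-30),
               bitscore = as.numeric(r[["b"]] %||% 100),
               s_strand = "+", stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("best-hit selection applies the score/e-value/id tie-break", {
  h <- mk_hits(list("c1", "g1", b = 100), list("c1", "g2", b = 90))
  expect_equal(best_hit_per_query(h)$subject_id, "g1")

  h <- mk_hits(list("c1", "g1", b = 80, e = 1e-20),
               list("c1", "g2", b = 80, e = 1e-30))
  expect_equal(best_hit_per_query(h)$subject_id, "g2")

  h <- mk_hits(list("c1", "gB", b = 80, e = 1e-30),
               list("c1", "gA", b = 80, e = 1e-30))
  expect_equal(best_hit_per_query(h)$subject_id, "gA")
})

test_that("best-hit selection equals the brute-force oracle on random tables", {
  withr::local_seed(101)
  for (i in 1:50) {
    h <- random_hit_table(6, 6, sample(5:30, 1))
    got <- best_hit_per_query(h)
    want <- oracle_best_hit(h)
    expect_equal(setNames(got$subject_id, got$query_id),
                 unlist(want)[got$query_id])
  }
})

test_that("reciprocal best hits match brute force and are order-invariant", {
  fwd <- mk_hits(list("c1", "g1", b = 100), list("c2", "g1", b = 90))
  rev <- mk_hits(list("g1", "c1", b = 100))
  got <- reciprocal_best_hits(fwd, rev)
  expect_equal(got$contig_id, "c1")
  expect_equal(got$gene_id, "g1")

  withr::local_seed(202)
  for (i in 1:50) {
    fwd <- random_hit_table(sample(3:20, 1), sample(3:20, 1),
                            sample(10:60, 1))
    rev <- random_hit_table(20, 20, sample(10:60, 1))
    names(rev)[1:2] <- c("query_id", "subject_id")
    # make rev genuinely gene->contig
    tmp <- rev$query_id
    rev$query_id <- sub("c", "g", tmp)
    rev$subject_id <- sub("g", "c", rev$subject_id)
    got <- reciprocal_best_hits(fwd, rev)
    want <- oracle_rbh(fwd, rev)
    expect_equal(got[order(got$contig_id), c("contig_id", "gene_id")],
                 want, ignore_attr = TRUE)
    # shuffling input rows must not change the matching
    got2 <- reciprocal_best_hits(fwd[sample.int(nrow(fwd)), ],
                                 rev[sample.int(nrow(rev)), ])
    expect_equal(got2[order(got2$contig_id), c("contig_id", "gene_id")],
                 want, ignore_attr = TRUE)
    # partial matching: no contig or gene twice
    expect_false(anyDuplicated(got$contig_id) > 0)
    expect_false(anyDuplicated(got$gene_id) > 0)
  }
})

test_that("chimera flagging requires two long, compatible segments", {
  h <- mk_hits(list("c1", "gA", qs = 1, qe = 300),
               list("c1", "gB", qs = 401, qe = 700))
  call <- flag_chimeras(h)
  expect_equal(call$contig_id, "c1")
  expect_equal(call$n_segments, 2L)

  # overlap 51 > 30: not chimeric
  h <- mk_hits(list("c1", "gA", qs = 1, qe = 300),
               list("c1", "gB", qs = 250, qe = 600))
  expect_equal(nrow(flag_chimeras(h)), 0L)

  # two hits to the same gene never flag
  h <- mk_hits(list("c1", "gA", qs = 1, qe = 300),
               list("c1", "gA", qs = 401, qe = 700))
  expect_equal(nrow(flag_chimeras(h)), 0L)

  # short or weak segments are ignored
  h <- mk_hits(list("c1", "gA", qs = 1, qe = 300),
               list("c1", "gB", qs = 401, qe = 480),
               list("c1", "gC", qs = 500, qe = 700, e = 1e-5))
  expect_equal(nrow(flag_chimeras(h)), 0L)
})

test_that("noise-free synthetic data yields exact chimera and annotation recovery", {
  st <- make_small_study(seed = 77, n_families = 500,
                         chimera_fraction = 0.05)
  planted <- st$contigs$truth$contig_id[st$contigs$truth$n_constituents > 1L]
  called <- flag_chimeras(st$hits$Th$fwd)
  expect_setequal(called$contig_id, planted)

  # families untouched by any chimera annotate perfectly via RBH
  rbh <- reciprocal_best_hits(st$hits$At$fwd, st$hits$At$rev)
  seg <- st$contigs$segments
  chim_fams <- unique(seg$family_id[seg$contig_id %in% planted])
  truth <- st$contigs$truth
  clean <- truth[!(truth$family_id %in% chim_fams), ]
  at_clean <- clean[st$fam$At[match(clean$family_id, st$fam$family_id)], ]
  want <- setNames(paste0("At_", at_clean$family_id), at_clean$contig_id)
  got <- setNames(rbh$gene_id, rbh$contig_id)[at_clean$contig_id]
  expect_equal(got, want)
  # and no clean contig annotates to a wrong gene
  extra <- setdiff(rbh$contig_id, truth$contig_id)
  expect_length(extra, 0)
})
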