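test_that("presence flags apply the e-value cutoff per taxon", {
  at <- data.frame(query_id = "c1", subject_id = "At_f1", evalue = 1e-20)
  cp <- data.frame(query_id = "c1", subject_id = "Cp_f1", evalue = 1e-5)
  vec <- presence_vectors(list(At = at, Br = at[0, ], Cp = cp, Pt = cp[0, ]),
                          evalue_cutoff = 1e-10, contig_ids = c("c1", "c2"))
  expect_equal(vec$At, c(TRUE, FALSE))
  expect_equal(vec$Cp, c(FALSE, FALSE))  # 1e-5 fails the cutoff
  expect_equal(unlist(vec[vec$contig_id == "c2", c("At", "Br", "Cp", "Pt")]),
               c(At = FALSE, Br = FALSE, Cp = FALSE, Pt = FALSE))
  expect_error(presence_vectors(list(At = at), evalue_cutoff = 0), "cutoff")
})

test_that("subset decomposition partitions contigs and applies letter names", {
  vec <- data.frame(
    contig_id = paste0("c", 1:5),
    At = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    Br = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    Cp = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    Pt = c(FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  part <- decompose_sets(vec)
  lab <- setNames(part$assignment$label, part$assignment$contig_id)
  expect_equal(unname(lab[c("c1", "c2", "c3", "c4", "c5")]),
               c("B", "Z", "I", "O", "C"))
  expect_equal(sum(part$sizes), 5L)
  expect_length(part$sizes, 16L)
  expect_error(decompose_sets(rbind(vec, vec[1, ])), "duplicate")
})

test_that("Dollo labelling matches exhaustive single-gain enumeration", {
  tree <- taxon_tree()
  for (flags in all_masks()) {
    got <- dollo_events(flags, tree)
    want <- oracle_dollo(flags)
    expect_equal(got$birth_branch, want$gain,
                 label = paste(names(flags)[flags], collapse = "+"))
    expect_setequal(got$loss_branches, want$losses)
  }
  # the worked cases: K, I and Z
  k <- dollo_events(c(At = FALSE, Br = FALSE, Cp = TRUE, Pt = TRUE), tree)
  expect_equal(k$birth_branch, "root")
  expect_equal(k$loss_branches, "Brassicaceae")
  i <- dollo_events(c(At = TRUE, Br = TRUE, Cp = TRUE, Pt = TRUE), tree)
  expect_equal(i$birth_branch, "root")
  expect_length(i$loss_branches, 0)
  z <- dollo_events(c(At = FALSE, Br = FALSE, Cp = FALSE, Pt = FALSE), tree)
  expect_equal(z$birth_branch, "Th")
  expect_length(z$loss_branches, 0)
})

test_that("per-branch summaries aggregate Dollo events", {
  vec <- data.frame(contig_id = paste0("c", 1:7),
                    At = TRUE, Br = TRUE, Cp = TRUE, Pt = TRUE)
  part <- decompose_sets(vec)
  ev <- summarize_births_losses(part)
  expect_equal(ev$gains[ev$branch == "root"], 7L)
  expect_equal(sum(ev$gains), 7L)
  expect_equal(sum(ev$losses), 0L)

  empty <- decompose_sets(vec[0, ])
  ev0 <- summarize_births_losses(empty)
  expect_true(all(ev0$gains == 0L) && all(ev0$losses == 0L))
})

test_that("planted gain/loss structure is recovered from noise-free hits", {
  st <- make_small_study(seed = 99, n_families = 400, chimera_fraction = 0)
  vec <- presence_vectors(lapply(st$hits[c("At", "Br", "Cp", "Pt")],
                                 `[[`, "fwd"),
                          contig_ids = st$contigs$truth$contig_id)
  part <- decompose_sets(vec)
  expect_equal(sum(part$sizes), nrow(st$contigs$truth))
  got <- summarize_births_losses(part)
  # oracle: Dollo events recomputed per planted presence mask
  truth <- st$fam[match(st$contigs$truth$family_id, st$fam$family_id), ]
  want_gain <- setNames(rep(0L, nrow(got)), got$branch)
  want_loss <- want_gain
  for (i in seq_len(nrow(truth))) {
    ev <- oracle_dollo(unlist(truth[i, c("At", "Br", "Cp", "Pt")]))
    want_gain[ev$gain] <- want_gain[ev$gain] + 1L
    for (b in ev$losses) want_loss[b] <- want_loss[b] + 1L
  }
  expect_equal(setNames(got$gains, got$branch), want_gain)
  expect_equal(setNames(got$losses, got$branch), want_loss)
})

test_that("lineage-specific detection is robust to realistic hit noise", {
  fam <- generate_universe(2000, seed = 1)
  fam <- generate_abundances(fam, zero_fraction = 0, seed = 2)
  contigs <- generate_contigs(fam, chimera_fraction = 0, seed = 3)
  hits <- generate_hit_tables(contigs, fam, miss_rate = 0.05,
                              spurious_rate = 0.01, seed = 4)
  vec <- presence_vectors(lapply(hits[c("At", "Br", "Cp", "Pt")],
                                 `[[`, "fwd"),
                          contig_ids = contigs$truth$contig_id)
  part <- decompose_sets(vec)
  called <- part$assignment$contig_id[part$assignment$label == "Z"]
  truth <- fam[match(contigs$truth$family_id, fam$family_id), ]
  true_z <- contigs$truth$contig_id[
    !(truth$At | truth$Br | truth$Cp | truth$Pt)]
  tp <- length(intersect(called, true_z))
  expect_gte(tp / length(called), 0.9)
  expect_gte(tp / length(true_z), 0.9)
})
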