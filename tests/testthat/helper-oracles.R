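# Independent brute-force oracles used to pin down expected values.

# Exact rarefaction expectation by exhaustive enumeration of all
# C(N, n) subsamples (feasible for N <= 12).
oracle_richness <- function(support, n) {
  gene_of_read <- rep(names(support), support)
  N <- length(gene_of_read)
  if (n == 0) return(0)
  combs <- utils::combn(N, n)
  mean(apply(combs, 2L, function(idx) {
    length(unique(gene_of_read[idx]))
  }))
}

# Best hit per query by explicit pairwise comparison (no sorting).
oracle_best_hit <- function(hits) {
  out <- list()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    best <- 1L
    for (i in seq_len(nrow(h))[-1L]) {
      better <- h$bitscore[i] > h$bitscore[best] ||
        (h$bitscore[i] == h$bitscore[best] &&
         h$evalue[i] < h$evalue[best]) ||
        (h$bitscore[i] == h$bitscore[best] &&
         h$evalue[i] == h$evalue[best] &&
         h$subject_id[i] < h$subject_id[best])
      if (better) best <- i
    }
    out[[q]] <- h$subject_id[best]
  }
  out
}

# Reciprocal best hits by brute-force double enumeration.
oracle_rbh <- function(fwd, rev) {
  bf <- oracle_best_hit(fwd)
  br <- oracle_best_hit(rev)
  pairs <- list()
  for (ctg in names(bf)) {
    g <- bf[[ctg]]
    if (!is.null(br[[g]]) && br[[g]] == ctg) {
      pairs[[length(pairs) + 1L]] <- c(ctg, g)
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(contig_id = character(), gene_id = character()))
  }
  m <- do.call(rbind, pairs)
  df <- data.frame(contig_id = m[, 1L], gene_id = m[, 2L],
                   stringsAsFactors = FALSE)
  df[order(df$contig_id), , drop = FALSE]
}

# Random hit table with deliberate score ties.
random_hit_table <- function(n_queries, n_subjects, n_hits, allow_ties = TRUE) {
  q <- sprintf("c%02d", sample.int(n_queries, n_hits, replace = TRUE))
  s <- sprintf("g%02d", sample.int(n_subjects, n_hits, replace = TRUE))
  bits <- if (allow_ties) sample(seq(50, 90, by = 10), n_hits, replace = TRUE)
          else runif(n_hits, 50, 300)
  ev <- signif(10^-sample(5:30, n_hits, replace = TRUE), 3)
  data.frame(
    query_id = q, subject_id = s, pct_identity = 90, aln_length = 100L,
    mismatches = 5L, gap_open = 0L, q_start = 1L, q_end = 100L,
    s_start = 1L, s_end = 100L, evalue = ev, bitscore = bits,
    s_strand = "+", stringsAsFactors = FALSE
  )
}

# Dollo oracle: exhaustive enumeration of single-gain scenarios on the
# fixed five-taxon tree. Edges are named after their child node; the
# edge above the root node is "root".
oracle_dollo <- function(flags) {
  paths <- list(
    Pt = c("root", "Pt"),
    Cp = c("root", "malvids", "Cp"),
    Th = c("root", "malvids", "coreBrassicales", "Th"),
    At = c("root", "malvids", "coreBrassicales", "Brassicaceae", "At"),
    Br = c("root", "malvids", "coreBrassicales", "Brassicaceae", "Br")
  )
  edges <- unique(unlist(paths))
  target <- c(Th = TRUE, flags[c("At", "Br", "Cp", "Pt")])
  best <- NULL
  for (gain in edges) {
    below <- setdiff(edges, gain)
    loss_pool <- Filter(function(e) {
      any(vapply(paths, function(p) {
        gi <- match(gain, p)
        ei <- match(e, p)
        !is.na(gi) && !is.na(ei) && ei > gi
      }, logical(1L)))
    }, below)
    for (k in 0:length(loss_pool)) {
      for (losses in if (k == 0) list(character(0)) else
           asplit(utils::combn(loss_pool, k), 2L)) {
        pres <- vapply(names(paths), function(leaf) {
          p <- paths[[leaf]]
          gi <- match(gain, p)
          if (is.na(gi)) return(FALSE)
          !any(losses %in% p[seq_along(p) > gi])
        }, logical(1L))
        if (all(pres == target[names(paths)])) {
          if (is.null(best) || length(losses) < length(best$losses)) {
            best <- list(gain = gain, losses = sort(unname(unlist(losses))))
          }
        }
      }
    }
  }
  best
}

# All 16 comparator presence masks.
all_masks <- function() {
  g <- expand.grid(At = c(TRUE, FALSE), Br = c(TRUE, FALSE),
                   Cp = c(TRUE, FALSE), Pt = c(TRUE, FALSE))
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ]))
}

# Small ready-made synthetic study shared by several tests.
make_small_study <- function(seed = 42L, n_families = 400L,
                             n_reads = 20000L, chimera_fraction = 0.02,
                             miss_rate = 0, spurious_rate = 0) {
  fam <- generate_universe(n_families, seed = seed)
  fam <- generate_abundances(fam, zero_fraction = 0.2,
                             seed = seed + 1L)
  reads <- generate_reads(fam, n_reads = n_reads, seed = seed + 2L)
  contigs <- generate_contigs(fam, chimera_fraction = chimera_fraction,
                              assembly_depth = n_reads, seed = seed + 3L)
  hits <- generate_hit_tables(contigs, fam, miss_rate = miss_rate,
                              spurious_rate = spurious_rate,
                              seed = seed + 4L)
  list(fam = fam, reads = reads, contigs = contigs, hits = hits)
}
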