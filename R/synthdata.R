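#' Generate a synthetic gene-family universe with planted presence/absence
#'
#' Families arise ("birth") on one of the branches leading to the focal
#' taxon Th (the root stem, the malvid stem, the core-Brassicales stem or
#' the Th terminal branch) and are then lost independently on branches
#' below the birth point, per the supplied per-branch probabilities. The
#' focal taxon is present for every family by construction; presence flags
#' for the four comparator taxa (At, Br, Cp, Pt) follow from the realised
#' birth and loss events. Each family also receives a coding sequence
#' (>= 150 nt) and a 3' UTR, emulating floral transcripts.
#'
#' @param n_families Number of gene families (>= 1).
#' @param birth_probs Named probabilities over branches
#'   `c(root, malvids, coreBrassicales, Th)`; normalised to sum to 1.
#' @param loss_rates Named per-branch loss probabilities for the branches
#'   off the focal lineage: `c(Pt, Cp, Brassicaceae, At, Br)`.
#' @param cds_meanlog,cds_sdlog Log-normal parameters for CDS length (nt);
#'   lengths are floored at 150 nt.
#' @param utr_shape,utr_scale Gamma parameters for 3' UTR length (nt);
#'   defaults give a mean around 250 nt, the scale of UTR carry-over seen
#'   in 454 floral assemblies.
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters and seed.
#' @return A `data.frame` with one row per family: `family_id`,
#'   `birth_branch`, logical presence flags `At`, `Br`, `Cp`, `Pt`,
#'   `th_cds_length`, `utr_length`, `cds_seq`, `utr_seq`, and a
#'   `loss_branches` list column with the realised loss events.
#' @export
generate_universe <- function(n_families,
                              birth_probs = c(root = 0.80, malvids = 0.03,
                                              coreBrassicales = 0.05,
                                              Th = 0.12),
                              loss_rates = c(Pt = 0.04, Cp = 0.04,
                                             Brassicaceae = 0.02,
                                             At = 0.03, Br = 0.03),
                              cds_meanlog = log(800), cds_sdlog = 0.45,
                              utr_shape = 2, utr_scale = 125,
                              seed = 1L) {
  if (n_families < 1) stop("n_families must be >= 1")
  need_b <- c("root", "malvids", "coreBrassicales", "Th")
  need_l <- c("Pt", "Cp", "Brassicaceae", "At", "Br")
  if (!all(need_b %in% names(birth_probs))) {
    stop("birth_probs must name branches ", paste(need_b, collapse = ", "))
  }
  if (!all(need_l %in% names(loss_rates))) {
    stop("loss_rates must name branches ", paste(need_l, collapse = ", "))
  }
  if (any(birth_probs < 0) || sum(birth_probs) <= 0) {
    stop("birth_probs must be non-negative and not all zero")
  }
  if (any(loss_rates < 0 | loss_rates > 1)) {
    stop("loss_rates must lie in [0, 1]")
  }
  with_seed(seed, {
    ids <- sprintf("fam%05d", seq_len(n_families))
    birth <- sample(need_b, n_families, replace = TRUE,
                    prob = birth_probs[need_b] / sum(birth_probs[need_b]))
    loss <- vapply(need_l, function(b) {
      stats::runif(n_families) < loss_rates[[b]]
    }, logical(n_families))
    if (n_families == 1L) loss <- matrix(loss, nrow = 1L,
                                         dimnames = list(NULL, need_l))
    # a loss event only applies where the branch lies below the birth point
    reach_pt <- birth == "root"
    reach_cp <- birth %in% c("root", "malvids")
    reach_bs <- birth %in% c("root", "malvids", "coreBrassicales")
    pt <- reach_pt & !loss[, "Pt"]
    cp <- reach_cp & !loss[, "Cp"]
    at <- reach_bs & !loss[, "Brassicaceae"] & !loss[, "At"]
    br <- reach_bs & !loss[, "Brassicaceae"] & !loss[, "Br"]
    loss_list <- lapply(seq_len(n_families), function(i) {
      applies <- c(reach_pt[i], reach_cp[i], reach_bs[i],
                   reach_bs[i] & !loss[i, "Brassicaceae"],
                   reach_bs[i] & !loss[i, "Brassicaceae"])
      need_l[applies & loss[i, ]]
    })
    cds_len <- pmax(150L, as.integer(round(
      stats::rlnorm(n_families, cds_meanlog, cds_sdlog))))
    utr_len <- as.integer(round(
      stats::rgamma(n_families, shape = utr_shape, scale = utr_scale)))
    fam <- data.frame(
      family_id = ids, birth_branch = birth,
      At = at, Br = br, Cp = cp, Pt = pt,
      th_cds_length = cds_len, utr_length = utr_len,
      stringsAsFactors = FALSE
    )
    fam$cds_seq <- random_dna(n_families, cds_len)
    fam$utr_seq <- ifelse(utr_len > 0L, random_dna(n_families, pmax(utr_len, 1L)), "")
    fam$utr_seq[utr_len == 0L] <- ""
    fam$loss_branches <- loss_list
    fam
  })
}

#' Assign true transcript abundances to families
#'
#' Abundances are i.i.d. log-normal on a transcripts-per-million-like
#' scale, with a configurable fraction of families silenced (abundance 0),
#' emulating genes absent from the floral transcriptome.
#'
#' @param families Universe `data.frame` from [generate_universe()].
#' @param meanlog,sdlog Log-normal parameters of the expressed abundances.
#' @param zero_fraction Fraction of families set to zero abundance
#'   (in `[0, 1)`).
#' @param seed Integer seed.
#' @return `families` with a `true_abundance` column added.
#' @export
generate_abundances <- function(families, meanlog = 2, sdlog = 1.5,
                                zero_fraction = 0.2, seed = 1L) {
  if (sdlog < 0) stop("sdlog must be >= 0")
  if (zero_fraction < 0 || zero_fraction >= 1) {
    stop("zero_fraction must lie in [0, 1)")
  }
  with_seed(seed, {
    n <- nrow(families)
    ab <- stats::rlnorm(n, meanlog, sdlog)
    ab[stats::runif(n) < zero_fraction] <- 0
    if (all(ab == 0)) stop("all families drew zero abundance; lower zero_fraction")
    families$true_abundance <- ab
    families
  })
}

#' Simulate 454-style read libraries from the synthetic transcriptome
#'
#' Reads are sampled family-wise with probability proportional to
#' `true_abundance * transcript_length` (a fragmentation model: longer
#' transcripts shed more fragments), and each read is a random substring
#' of the transcript (CDS plus 3' UTR) with length drawn from a normal
#' distribution truncated to `[50, transcript length]`. Reads are split
#' round-robin into disjoint replicate libraries.
#'
#' @param families Universe with `true_abundance` (see
#'   [generate_abundances()]).
#' @param n_reads Total number of reads across all replicates.
#' @param mean_len,sd_len Read length distribution (nt); the default mean
#'   of 316 nt matches a typical 454 titanium library.
#' @param n_replicates Number of replicate libraries (>= 1).
#' @param seed Integer seed.
#' @return A list with `reads` (a list of named sequence vectors, one per
#'   replicate) and `truth` (a `data.frame`: `read_id`, `replicate`,
#'   `family_id`, `start`, `end`, `length`).
#' @export
generate_reads <- function(families, n_reads = 1e5, mean_len = 316,
                           sd_len = 80, n_replicates = 2, seed = 1L) {
  if (mean_len < 50) stop("mean_len must be >= 50")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(families$true_abundance)) {
    stop("families lack true_abundance; run generate_abundances() first")
  }
  tx_len <- families$th_cds_length + families$utr_length
  if (any(tx_len <= 0)) stop("family with zero transcript length")
  w <- families$true_abundance * tx_len
  if (sum(w) <= 0) stop("no expressed family to sample reads from")
  with_seed(seed, {
    fam_idx <- sample.int(nrow(families), n_reads, replace = TRUE,
                          prob = w / sum(w))
    lens <- pmin(pmax(as.integer(round(stats::rnorm(n_reads, mean_len, sd_len))),
                      50L), tx_len[fam_idx])
    start <- 1L + as.integer(floor(stats::runif(n_reads) *
                                   (tx_len[fam_idx] - lens + 1L)))
    end <- start + lens - 1L
    repl <- rep_len(seq_len(n_replicates), n_reads)
    read_id <- sprintf("rep%d_r%07d", repl, seq_len(n_reads))
    tx <- paste0(families$cds_seq, families$utr_seq)
    seqs <- substring(tx[fam_idx], start, end)
    names(seqs) <- read_id
    truth <- data.frame(
      read_id = read_id, replicate = repl,
      family_id = families$family_id[fam_idx],
      start = start, end = end, length = lens,
      stringsAsFactors = FALSE
    )
    list(reads = split(seqs, repl), truth = truth)
  })
}

#' Assemble synthetic de novo contigs with UTR padding and chimeras
#'
#' One contig is produced per expressed family. A contig carries a
#' 3'-anchored portion of the CDS plus (optionally) the full 3' UTR. How
#' much of the CDS is assembled is governed by `completeness`: the default
#' `"auto"` model makes completeness increase with expected read coverage,
#' so abundant transcripts assemble to full length while rare ones remain
#' fragmentary — the characteristic behaviour of shallow 454 de novo
#' assemblies. A configurable fraction of contigs are chimeras: the
#' primary family's contig with a second family's contig sequence
#' concatenated onto it.
#'
#' @param families Universe with `true_abundance`.
#' @param chimera_fraction Fraction of contigs that are chimeric
#'   (in `[0, 0.5]`).
#' @param utr_padding `"true_utr"` (append the family's 3' UTR) or
#'   `"none"`.
#' @param completeness Either `"auto"` (coverage-dependent, see Details)
#'   or a number in `(0, 1]` applied to every contig; `1` assembles the
#'   full CDS.
#' @param assembly_depth Nominal library size (reads) used by the `"auto"`
#'   completeness model.
#' @param seed Integer seed.
#' @return A list with `contigs` (named sequences), `truth` (a
#'   `data.frame`: `contig_id`, `family_id` (primary), `n_constituents`,
#'   `length`, `cds_assembled`, `completeness`) and `segments` (a
#'   `data.frame` mapping each contig to the CDS interval of every
#'   constituent family: `contig_id`, `family_id`, `q_start`, `q_end`,
#'   `role`).
#' @details The auto model sets
#'   `completeness = min(1, 0.45 + 0.18 * log10(1 + expected_reads))`,
#'   with the assembled CDS portion floored at 120 nt (or the full CDS if
#'   shorter), so that every constituent leaves a detectable footprint.
#' @export
generate_contigs <- function(families, chimera_fraction = 0.01,
                             utr_padding = c("true_utr", "none"),
                             completeness = "auto",
                             assembly_depth = 1e5, seed = 1L) {
  utr_padding <- match.arg(utr_padding)
  if (chimera_fraction < 0 || chimera_fraction > 0.5) {
    stop("chimera_fraction must lie in [0, 0.5]")
  }
  if (is.null(families$true_abundance)) {
    stop("families lack true_abundance; run generate_abundances() first")
  }
  expr <- which(families$true_abundance > 0)
  if (length(expr) == 0L) stop("no expressed families")
  if (chimera_fraction > 0 && length(expr) < 2L) {
    stop("chimera_fraction > 0 requires at least 2 expressed families")
  }
  with_seed(seed, {
    fam <- families[expr, , drop = FALSE]
    n <- nrow(fam)
    tx_len <- fam$th_cds_length + fam$utr_length
    if (identical(completeness, "auto")) {
      w <- fam$true_abundance * tx_len
      exp_reads <- assembly_depth * w / sum(w)
      compl <- pmin(1, 0.45 + 0.18 * log10(1 + exp_reads))
    } else {
      if (!is.numeric(completeness) || completeness <= 0 || completeness > 1) {
        stop("completeness must be 'auto' or a number in (0, 1]")
      }
      compl <- rep(completeness, n)
    }
    asm <- pmax(pmin(fam$th_cds_length, 120L),
                as.integer(round(compl * fam$th_cds_length)))
    cds_part <- substring(fam$cds_seq, fam$th_cds_length - asm + 1L,
                          fam$th_cds_length)
    base <- if (utr_padding == "true_utr") paste0(cds_part, fam$utr_seq)
            else cds_part
    base_len <- nchar(base)
    contig_id <- sprintf("ctg%05d", seq_len(n))
    is_chim <- stats::runif(n) < chimera_fraction
    partner <- rep(NA_integer_, n)
    if (any(is_chim)) {
      partner[is_chim] <- vapply(which(is_chim), function(i) {
        sample(setdiff(seq_len(n), i), 1L)
      }, integer(1L))
    }
    seqs <- base
    seqs[is_chim] <- paste0(base[is_chim], base[partner[is_chim]])
    names(seqs) <- contig_id
    seg_primary <- data.frame(
      contig_id = contig_id, family_id = fam$family_id,
      q_start = 1L, q_end = asm, role = "primary",
      stringsAsFactors = FALSE
    )
    seg_partner <- NULL
    if (any(is_chim)) {
      i <- which(is_chim)
      p <- partner[i]
      seg_partner <- data.frame(
        contig_id = contig_id[i], family_id = fam$family_id[p],
        q_start = base_len[i] + 1L, q_end = base_len[i] + asm[p],
        role = "partner", stringsAsFactors = FALSE
      )
    }
    segments <- rbind(seg_primary, seg_partner)
    segments <- segments[order(segments$contig_id, segments$q_start), ]
    rownames(segments) <- NULL
    truth <- data.frame(
      contig_id = contig_id, family_id = fam$family_id,
      n_constituents = 1L + as.integer(is_chim),
      length = nchar(seqs), cds_assembled = asm,
      completeness = asm / fam$th_cds_length,
      stringsAsFactors = FALSE
    )
    list(contigs = seqs, truth = truth, segments = segments)
  })
}

#' @keywords internal
bitscore_from_evalue <- function(evalue) {
  # anti-monotone in e-value by construction
  round(30 - 2 * log10(evalue), 2)
}

#' @keywords internal
make_hits <- function(query_id, subject_id, q_start, q_end, s_start, s_end,
                      evalue, pct_identity) {
  n <- length(query_id)
  if (n == 0L) return(empty_hit_table())
  aln <- q_end - q_start + 1L
  data.frame(
    query_id = query_id, subject_id = subject_id,
    pct_identity = round(pct_identity, 2), aln_length = as.integer(aln),
    mismatches = as.integer(round(aln * (1 - pct_identity / 100))),
    gap_open = 0L,
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    evalue = evalue, bitscore = bitscore_from_evalue(evalue),
    s_strand = "+", stringsAsFactors = FALSE
  )
}

#' Simulate per-taxon similarity-hit tables for contigs
#'
#' Stands in for the alignment engine: for every contig segment whose
#' origin family is present in a taxon, a "true" hit to that taxon's gene
#' is emitted (dropped with probability `miss_rate`), with
#' `log10(e-value) ~ U(-180, -11)` — always beyond a 1e-10 detection
#' cutoff. Spurious hits to random genes are added per (contig, taxon)
#' with probability `spurious_rate` and `log10(e-value) ~ U(-12, -2)`,
#' straddling the cutoff. Bit scores are anti-monotone in e-value.
#' Reciprocal (gene-to-contig) tables are emitted as mirror images.
#'
#' @param contig_sim Output of [generate_contigs()] (uses `$segments`).
#' @param families Universe `data.frame` (presence flags).
#' @param miss_rate,spurious_rate Noise rates in `[0, 1]` / `[0, 1)`.
#' @param taxa Taxa to emit tables for; `"Th"` (the focal taxon itself,
#'   where every family is present) supports chimera detection and
#'   self-annotation.
#' @param seed Integer seed.
#' @return A named list (one element per taxon) of lists with `fwd`
#'   (contig-to-gene hits) and `rev` (gene-to-contig mirror) hit tables.
#'   Subject gene identifiers are `<taxon>_<family_id>`.
#' @export
generate_hit_tables <- function(contig_sim, families, miss_rate = 0,
                                spurious_rate = 0,
                                taxa = c("At", "Br", "Cp", "Pt", "Th"),
                                seed = 1L) {
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must lie in [0, 1]")
  if (spurious_rate < 0 || spurious_rate >= 1) {
    stop("spurious_rate must lie in [0, 1)")
  }
  seg <- contig_sim$segments
  pres <- presence_lookup(families)
  contig_ids <- contig_sim$truth$contig_id
  with_seed(seed, {
    out <- lapply(taxa, function(tax) {
      present <- if (tax == "Th") rep(TRUE, nrow(seg))
                 else pres[seg$family_id, tax]
      keep <- present & stats::runif(nrow(seg)) >= miss_rate
      s <- seg[keep, , drop = FALSE]
      ev <- 10^stats::runif(nrow(s), -180, -11)
      seglen <- s$q_end - s$q_start + 1L
      fwd <- make_hits(
        query_id = s$contig_id,
        subject_id = paste0(tax, "_", s$family_id),
        q_start = s$q_start, q_end = s$q_end,
        s_start = 1L, s_end = seglen,
        evalue = ev, pct_identity = stats::runif(nrow(s), 85, 100)
      )
      if (spurious_rate > 0) {
        sp <- which(stats::runif(length(contig_ids)) < spurious_rate)
        if (length(sp) > 0L) {
          fam_pool <- families$family_id
          tgt <- fam_pool[sample.int(length(fam_pool), length(sp),
                                     replace = TRUE)]
          len <- pmin(150L, contig_sim$truth$length[sp])
          ev2 <- 10^stats::runif(length(sp), -12, -2)
          fwd <- rbind(fwd, make_hits(
            query_id = contig_ids[sp],
            subject_id = paste0(tax, "_", tgt),
            q_start = 1L, q_end = len, s_start = 1L, s_end = len,
            evalue = ev2, pct_identity = stats::runif(length(sp), 70, 90)
          ))
        }
      }
      rev <- mirror_hits(fwd)
      list(fwd = fwd, rev = rev)
    })
    names(out) <- taxa
    out
  })
}

#' @keywords internal
presence_lookup <- function(families) {
  pres <- as.matrix(families[, c("At", "Br", "Cp", "Pt")])
  rownames(pres) <- families$family_id
  pres
}

#' Swap the query and subject sides of a hit table
#'
#' @param hits Hit `data.frame`.
#' @return The mirrored hit table (scores and e-values unchanged).
#' @export
mirror_hits <- function(hits) {
  out <- hits
  out$query_id <- hits$subject_id
  out$subject_id <- hits$query_id
  out$q_start <- hits$s_start
  out$q_end <- hits$s_end
  out$s_start <- hits$q_start
  out$s_end <- hits$q_end
  out
}

#' Simulate read-mapping hit tables for expression counting
#'
#' Family-identity mapping model: a read hits the target sequence(s) that
#' contain its origin family — the orthologous reference-taxon CDS under
#' `target = "reference"` (only for families present in that taxon), or
#' every contig carrying the family under `target = "contigs"` (so reads
#' of a chimera's constituents hit the chimeric contig too). Each hit is
#' dropped with probability `miss_rate`; spurious hits are added per read
#' at `spurious_rate`. E-value and bit-score models are as in
#' [generate_hit_tables()].
#'
#' @param read_truth Read truth `data.frame` from [generate_reads()].
#' @param families Universe `data.frame`.
#' @param target `"reference"` or `"contigs"`.
#' @param contig_sim Output of [generate_contigs()]; required for
#'   `target = "contigs"`.
#' @param reference_taxon Taxon whose CDS set is the mapping reference
#'   under `target = "reference"` (default `"At"`).
#' @param miss_rate,spurious_rate Noise rates.
#' @param seed Integer seed.
#' @return A hit `data.frame` (reads as queries).
#' @export
generate_read_hits <- function(read_truth, families,
                               target = c("reference", "contigs"),
                               contig_sim = NULL, reference_taxon = "At",
                               miss_rate = 0, spurious_rate = 0,
                               seed = 1L) {
  target <- match.arg(target)
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must lie in [0, 1]")
  if (spurious_rate < 0 || spurious_rate >= 1) {
    stop("spurious_rate must lie in [0, 1)")
  }
  with_seed(seed, {
    if (target == "reference") {
      pres <- presence_lookup(families)
      ok <- pres[read_truth$family_id, reference_taxon]
      df <- read_truth[ok, , drop = FALSE]
      subj <- paste0(reference_taxon, "_", df$family_id)
      subj_pool <- paste0(reference_taxon, "_", families$family_id)
    } else {
      if (is.null(contig_sim)) stop("contig_sim required for target='contigs'")
      seg <- contig_sim$segments
      idx <- split(seq_len(nrow(seg)), seg$family_id)
      hit_idx <- idx[read_truth$family_id]
      reps <- lengths(hit_idx)
      has <- reps > 0L
      df <- read_truth[rep(which(has), reps[has]), , drop = FALSE]
      subj <- seg$contig_id[unlist(hit_idx[has], use.names = FALSE)]
      subj_pool <- contig_sim$truth$contig_id
    }
    keep <- stats::runif(nrow(df)) >= miss_rate
    df <- df[keep, , drop = FALSE]
    subj <- subj[keep]
    ev <- 10^stats::runif(nrow(df), -180, -11)
    hits <- make_hits(
      query_id = df$read_id, subject_id = subj,
      q_start = 1L, q_end = df$length, s_start = 1L, s_end = df$length,
      evalue = ev, pct_identity = stats::runif(nrow(df), 90, 100)
    )
    if (spurious_rate > 0) {
      sp <- which(stats::runif(nrow(read_truth)) < spurious_rate)
      if (length(sp) > 0L) {
        tgt <- subj_pool[sample.int(length(subj_pool), length(sp),
                                    replace = TRUE)]
        len <- pmin(80L, read_truth$length[sp])
        ev2 <- 10^stats::runif(length(sp), -12, -2)
        hits <- rbind(hits, make_hits(
          query_id = read_truth$read_id[sp], subject_id = tgt,
          q_start = 1L, q_end = len, s_start = 1L, s_end = len,
          evalue = ev2, pct_identity = stats::runif(length(sp), 70, 90)
        ))
      }
    }
    rownames(hits) <- NULL
    hits
  })
}

#' Simulate a microarray probe map and expression matrix
#'
#' Builds a probe-to-gene map for the reference taxon's genes (a fraction
#' of probes hybridise to more than one gene and are later discarded by
#' the unique-probe filter) and a genes-by-stages expression matrix in
#' which a configurable fraction of genes stays below the detection
#' threshold in every floral stage.
#'
#' @param families Universe `data.frame`.
#' @param reference_taxon Taxon providing the gene set (default `"At"`).
#' @param n_stages Number of floral stages/sample subsets.
#' @param absent_fraction Fraction of genes undetected in all stages.
#' @param multi_target_fraction Fraction of probes targeting two genes.
#' @param detection_threshold Detection threshold on the intensity scale.
#' @param seed Integer seed.
#' @return A list with `probe_map` (`data.frame`: `probe_id`, `gene_id`;
#'   multi-target probes occupy several rows), `expr` (numeric matrix,
#'   genes x stages), `detection_threshold`, and `truth` (`data.frame`:
#'   `gene_id`, `present`).
#' @export
generate_microarray <- function(families, reference_taxon = "At",
                                n_stages = 5, absent_fraction = 0.06,
                                multi_target_fraction = 0.07,
                                detection_threshold = 100, seed = 1L) {
  genes <- paste0(reference_taxon, "_",
                  families$family_id[families[[reference_taxon]]])
  if (length(genes) < 2L) stop("need at least 2 genes present in the taxon")
  with_seed(seed, {
    n <- length(genes)
    absent <- stats::runif(n) < absent_fraction
    expr <- matrix(stats::rlnorm(n * n_stages,
                                 meanlog = log(detection_threshold * 8),
                                 sdlog = 1),
                   nrow = n, dimnames = list(genes, paste0("stage", seq_len(n_stages))))
    # absent genes: background intensity strictly below threshold everywhere
    expr[absent, ] <- matrix(
      stats::runif(sum(absent) * n_stages, 0, detection_threshold * 0.9),
      nrow = sum(absent))
    # present genes are guaranteed detection in at least one stage
    peak <- sample.int(n_stages, n, replace = TRUE)
    lo <- which(!absent & apply(expr >= detection_threshold, 1L, sum) == 0)
    if (length(lo) > 0L) {
      expr[cbind(lo, peak[lo])] <- detection_threshold *
        stats::runif(length(lo), 1.5, 10)
    }
    probe_gene <- genes
    multi <- which(stats::runif(n) < multi_target_fraction)
    probe_id <- sprintf("p%05d", seq_len(n))
    probe_map <- data.frame(probe_id = probe_id, gene_id = probe_gene,
                            stringsAsFactors = FALSE)
    if (length(multi) > 0L) {
      extra <- data.frame(
        probe_id = probe_id[multi],
        gene_id = genes[(multi %% n) + 1L],
        stringsAsFactors = FALSE
      )
      probe_map <- rbind(probe_map, extra)
      probe_map <- probe_map[!duplicated(probe_map), ]
    }
    list(probe_map = probe_map, expr = expr,
         detection_threshold = detection_threshold,
         truth = data.frame(gene_id = genes, present = !absent,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate qPCR dilution series and replicate Cq tables
#'
#' The standard-dose-response model is
#' `Cq = intercept - log10(amount) / log10(E)`: with efficiency `E = 2`
#' and ten-fold dilutions, successive Cq values differ by exactly
#' `log2(10) = 3.3219`. Dilution-series points are noise-free; per-group
#' replicate Cq values are drawn `Normal(mean, replicate_sd)`.
#'
#' @param genes Character vector of assayed gene identifiers (including
#'   the reference gene).
#' @param efficiencies Named per-gene amplification efficiencies in
#'   `(1, 2]`.
#' @param reference_gene Identifier of the normaliser gene.
#' @param group_means Numeric matrix of true mean Cq values,
#'   genes x groups (rownames = genes).
#' @param replicate_sd Replicate standard deviation of Cq (cycles).
#' @param n_replicates Replicates per (gene, group) — biological x
#'   technical collapsed to one stratum (default 6, i.e. duplicates x
#'   triplicates).
#' @param dilutions Strictly decreasing relative template amounts for the
#'   standard curve; the default spans 1:50 to 1:50,000.
#' @param intercepts Optional named per-gene Cq intercepts at amount 1;
#'   drawn uniformly in [18, 24] when omitted.
#' @param seed Integer seed.
#' @return A list with `dilution` (`data.frame`: `gene_id`,
#'   `log10_amount`, `cq`), `cq` (`data.frame`: `gene_id`, `group`,
#'   `replicate`, `cq`) and `truth` (efficiencies, intercepts,
#'   group_means).
#' @export
generate_cq <- function(genes, efficiencies, reference_gene, group_means,
                        replicate_sd = 0.15, n_replicates = 6,
                        dilutions = c(1 / 50, 1 / 500, 1 / 5000, 1 / 50000),
                        intercepts = NULL, seed = 1L) {
  if (any(efficiencies <= 1 | efficiencies > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  if (!all(genes %in% names(efficiencies))) {
    stop("every gene needs a named efficiency")
  }
  if (!(reference_gene %in% genes)) stop("reference_gene must be in genes")
  if (any(diff(dilutions) >= 0)) {
    stop("dilutions must be strictly decreasing template amounts")
  }
  if (!all(genes %in% rownames(group_means))) {
    stop("group_means must have one row per gene")
  }
  with_seed(seed, {
    if (is.null(intercepts)) {
      intercepts <- stats::setNames(stats::runif(length(genes), 18, 24), genes)
    }
    dil <- expand.grid(gene_id = genes, amount = dilutions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    dil$log10_amount <- log10(dil$amount)
    dil$cq <- intercepts[dil$gene_id] -
      dil$log10_amount / log10(efficiencies[dil$gene_id])
    dil <- dil[, c("gene_id", "log10_amount", "cq")]
    groups <- colnames(group_means)
    cq <- expand.grid(gene_id = genes, group = groups,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- group_means[cbind(cq$gene_id, cq$group)]
    cq$cq <- stats::rnorm(nrow(cq), mu, replicate_sd)
    list(dilution = dil, cq = cq,
         truth = list(efficiencies = efficiencies, intercepts = intercepts,
                      group_means = group_means))
  })
}
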