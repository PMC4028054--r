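#' Select the single best hit per query
#'
#' The best hit maximises the bit score; ties are broken by lower
#' e-value, then by lexicographically smallest subject identifier, making
#' the selection deterministic and invariant to input row order.
#'
#' @param hits Hit `data.frame` (see [parse_hit_table()]).
#' @return A hit `data.frame` with exactly one row per distinct query, in
#'   query order.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Annotate contigs by reciprocal best bidirectional hits
#'
#' A contig/gene pair is kept iff the contig's best forward hit is that
#' gene and the gene's best reverse hit is that contig. The result is a
#' partial matching: every contig and every gene occurs in at most one
#' pair.
#'
#' @param fwd Forward hits (contigs as queries, genes as subjects).
#' @param rev Reverse hits (genes as queries, contigs as subjects).
#' @return A `data.frame` with columns `contig_id`, `gene_id`,
#'   `fwd_evalue`, `rev_evalue`, `fwd_bitscore`, `rev_bitscore`.
#' @export
reciprocal_best_hits <- function(fwd, rev) {
  bf <- best_hit_per_query(fwd)
  br <- best_hit_per_query(rev)
  rev_best <- stats::setNames(br$subject_id, br$query_id)
  keep <- !is.na(rev_best[bf$subject_id]) &
    rev_best[bf$subject_id] == bf$query_id
  keep[is.na(keep)] <- FALSE
  bf <- bf[keep, , drop = FALSE]
  m <- match(bf$subject_id, br$query_id)
  out <- data.frame(
    contig_id = bf$query_id, gene_id = bf$subject_id,
    fwd_evalue = bf$evalue, rev_evalue = br$evalue[m],
    fwd_bitscore = bf$bitscore, rev_bitscore = br$bitscore[m],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Flag chimeric contigs from a similarity-hit table
#'
#' A contig is flagged as chimeric if it carries alignments to at least
#' two distinct reference genes such that each qualifying alignment spans
#' at least `min_segment` nucleotides of the contig at an e-value of at
#' most `max_evalue`, and the retained query intervals overlap pairwise
#' by at most `max_overlap` nucleotides. Per gene the highest-scoring
#' qualifying hit is considered; compatible segments are then chosen
#' greedily along the contig (earliest interval end first).
#'
#' @param hits Hit `data.frame` (contigs as queries). Tables against
#'   several reference sets may be concatenated beforehand.
#' @param min_segment Minimum query-interval length (nt).
#' @param max_overlap Maximum pairwise query-interval overlap (nt).
#' @param max_evalue E-value ceiling for a qualifying alignment.
#' @return A `data.frame` of chimera calls with columns `contig_id`,
#'   `n_segments`, and `segments` (a list column of per-segment
#'   `data.frame`s: `gene_id`, `q_start`, `q_end`).
#' @export
flag_chimeras <- function(hits, min_segment = 100, max_overlap = 30,
                          max_evalue = 1e-10) {
  if (min_segment <= 0 || max_overlap < 0 || max_evalue <= 0) {
    stop("chimera thresholds must be positive")
  }
  empty <- data.frame(contig_id = character(), n_segments = integer(),
                      stringsAsFactors = FALSE)
  empty$segments <- list()
  if (nrow(hits) == 0L) return(empty)
  h <- hits[hits$evalue <= max_evalue &
            (hits$q_end - hits$q_start + 1L) >= min_segment, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  # per (contig, gene): the strongest qualifying alignment
  o <- order(h$query_id, h$subject_id, -h$bitscore, h$evalue,
             method = "radix")
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h[, c("query_id", "subject_id")]), , drop = FALSE]
  calls <- lapply(split(h, h$query_id), function(ch) {
    if (nrow(ch) < 2L) return(NULL)
    ch <- ch[order(ch$q_end, ch$q_start), , drop = FALSE]
    sel <- integer(0)
    last_end <- -Inf
    for (i in seq_len(nrow(ch))) {
      ov <- last_end - ch$q_start[i] + 1L
      if (ov <= max_overlap) {
        sel <- c(sel, i)
        last_end <- ch$q_end[i]
      }
    }
    if (length(sel) < 2L) return(NULL)
    seg <- data.frame(gene_id = ch$subject_id[sel],
                      q_start = ch$q_start[sel], q_end = ch$q_end[sel],
                      stringsAsFactors = FALSE)
    list(contig_id = ch$query_id[1L], seg = seg)
  })
  calls <- calls[!vapply(calls, is.null, logical(1L))]
  if (length(calls) == 0L) return(empty)
  out <- data.frame(
    contig_id = vapply(calls, `[[`, character(1L), "contig_id"),
    n_segments = vapply(calls, function(x) nrow(x$seg), integer(1L)),
    stringsAsFactors = FALSE
  )
  out$segments <- lapply(calls, `[[`, "seg")
  rownames(out) <- NULL
  out
}
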