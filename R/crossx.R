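#' Keep only probes hybridising to a single gene
#'
#' Microarray probes targeting more than one gene cannot support a
#' gene-level presence call and are discarded.
#'
#' @param probe_map `data.frame` with columns `probe_id`, `gene_id`
#'   (multi-target probes occupy several rows).
#' @return The filtered probe map (probes with exactly one target).
#' @export
filter_unique_probes <- function(probe_map) {
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop("probe_map needs columns probe_id and gene_id")
  }
  n_targets <- table(probe_map$probe_id)
  keep <- names(n_targets)[n_targets == 1L]
  out <- probe_map[probe_map$probe_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call gene presence from a microarray expression matrix
#'
#' A gene is present iff its value reaches the detection threshold in at
#' least one floral stage / sample subset. Boolean matrices use any-TRUE.
#'
#' @param expr Numeric or logical matrix, genes x stages, with row
#'   names.
#' @param detection_threshold Detection threshold (ignored for logical
#'   matrices).
#' @return Character vector of present gene identifiers.
#' @export
microarray_presence <- function(expr, detection_threshold) {
  if (is.null(rownames(expr))) stop("expr must have gene row names")
  if (is.logical(expr)) {
    present <- rowSums(expr) > 0L
  } else {
    if (!is.finite(detection_threshold)) {
      stop("detection_threshold must be finite")
    }
    present <- rowSums(expr >= detection_threshold) > 0L
  }
  rownames(expr)[present]
}

#' Qualitative presence/absence comparison across platforms
#'
#' Compares two transcriptomes through a one-to-one homology map (for
#' example the reciprocal-best-hit annotation): a gene is "only A" if it
#' is present on side A, has a mapped partner, and that partner is
#' absent on side B (and symmetrically). Genes without a partner are
#' reported separately and never enter the differential lists; the
#' comparison is strictly qualitative and never mixes the platforms'
#' magnitudes.
#'
#' @param present_a,present_b Character vectors of present identifiers
#'   on each side.
#' @param homology `data.frame` with columns `gene_a`, `gene_b` forming
#'   a partial matching (no identifier may occur twice on its side).
#' @return A list with `only_a`, `only_b`, `shared_a`, `shared_b`,
#'   `unmapped_a`, `unmapped_b`.
#' @export
compare_presence <- function(present_a, present_b, homology) {
  if (!all(c("gene_a", "gene_b") %in% names(homology))) {
    stop("homology needs columns gene_a and gene_b")
  }
  if (anyDuplicated(homology$gene_a) || anyDuplicated(homology$gene_b)) {
    stop("homology is not a partial matching (duplicate partner)")
  }
  a2b <- stats::setNames(homology$gene_b, homology$gene_a)
  b2a <- stats::setNames(homology$gene_a, homology$gene_b)
  mapped_a <- present_a[present_a %in% names(a2b)]
  mapped_b <- present_b[present_b %in% names(b2a)]
  list(
    only_a = mapped_a[!(a2b[mapped_a] %in% present_b)],
    only_b = mapped_b[!(b2a[mapped_b] %in% present_a)],
    shared_a = mapped_a[a2b[mapped_a] %in% present_b],
    shared_b = mapped_b[b2a[mapped_b] %in% present_a],
    unmapped_a = setdiff(present_a, names(a2b)),
    unmapped_b = setdiff(present_b, names(b2a))
  )
}
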