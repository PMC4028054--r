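#' Count reads by their single best hit
#'
#' Every read contributes exactly one count, to the subject of its best
#' retained hit (bit score, then e-value, then subject identifier, as in
#' [best_hit_per_query()]). Hits to excluded subjects (for example
#' flagged chimeric contigs) are discarded before selection; reads with
#' no retained hit are unmapped.
#'
#' @param read_hits Hit `data.frame` with reads as queries.
#' @param exclude_subjects Character vector of subject identifiers to
#'   drop before best-hit selection.
#' @return A list with `counts` (named integer vector, one entry per
#'   subject that received reads) and `n_mappable` (number of reads with
#'   a retained hit; equals `sum(counts)`).
#' @export
count_reads <- function(read_hits, exclude_subjects = character()) {
  h <- read_hits
  if (length(exclude_subjects) > 0L) {
    h <- h[!(h$subject_id %in% exclude_subjects), , drop = FALSE]
  }
  best <- best_hit_per_query(h)
  counts <- if (nrow(best) == 0L) {
    stats::setNames(integer(0), character(0))
  } else {
    tab <- table(best$subject_id)
    stats::setNames(as.integer(tab), names(tab))
  }
  list(counts = counts, n_mappable = sum(counts))
}

#' Build an RPKM expression table
#'
#' RPKM (reads per kilobase of gene model per million mappable reads) is
#' `count * 1e9 / (model_length * n_mappable)`. Genes present in
#' `lengths` but without counted reads are included with zero RPKM, so a
#' table covers the whole gene universe of its mapping strategy.
#'
#' @param counts Named integer vector of per-gene read counts.
#' @param lengths Named numeric vector of gene-model lengths (nt): the
#'   orthologous reference CDS length under TSE1, the contig length under
#'   TSE2.
#' @param n_mappable Total mappable reads (must be > 0 and equal
#'   `sum(counts)` for a self-consistent table).
#' @param strategy `"TSE1"` or `"TSE2"` (recorded as an attribute).
#' @return An `expression_table`: a `data.frame` with columns `gene_id`,
#'   `read_count`, `model_length`, `rpkm`, with attributes `n_mappable`
#'   and `strategy`.
#' @export
rpkm_table <- function(counts, lengths, n_mappable,
                       strategy = c("TSE1", "TSE2")) {
  strategy <- match.arg(strategy)
  if (n_mappable <= 0) stop("n_mappable must be > 0")
  if (any(lengths <= 0)) stop("gene-model lengths must be > 0")
  missing_len <- setdiff(names(counts), names(lengths))
  if (length(missing_len) > 0L) {
    stop("no model length for counted gene(s): ",
         paste(utils::head(missing_len, 3L), collapse = ", "))
  }
  gene_id <- names(lengths)
  cnt <- stats::setNames(rep(0L, length(gene_id)), gene_id)
  cnt[names(counts)] <- counts
  tab <- data.frame(
    gene_id = gene_id,
    read_count = as.integer(cnt),
    model_length = as.numeric(lengths),
    rpkm = as.numeric(cnt) * 1e9 / (as.numeric(lengths) * n_mappable),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(tab, n_mappable = n_mappable, strategy = strategy,
            class = c("expression_table", "data.frame"))
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("Expression table (%s): %d gene models, %d mappable reads\n",
              attr(x, "strategy"), nrow(x), attr(x, "n_mappable")))
  NextMethod()
}

#' Normalise an expression table to a reference gene
#'
#' Expression ratios relative to a housekeeping reference (the ACT7-style
#' internal control): `ratio_g = rpkm_g / rpkm_ref`. The profile is
#' invariant to jointly rescaling all counts and the mappable total.
#'
#' @param table An `expression_table` from [rpkm_table()].
#' @param reference_gene Identifier of the reference gene; it must have a
#'   positive read count.
#' @return A named numeric vector of ratios (the reference maps to 1).
#' @export
normalize_to_reference <- function(table, reference_gene) {
  i <- match(reference_gene, table$gene_id)
  if (is.na(i)) stop("reference gene ", reference_gene, " not in table")
  if (table$read_count[i] == 0L) {
    stop("reference gene ", reference_gene, " has no reads")
  }
  stats::setNames(table$rpkm / table$rpkm[i], table$gene_id)
}

#' Call transcript presence from read support
#'
#' @param table An `expression_table`.
#' @param min_count Minimum read count for presence (>= 1).
#' @return Character vector of present gene identifiers.
#' @export
call_presence <- function(table, min_count = 1L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  table$gene_id[table$read_count >= min_count]
}

#' Compare a sequencing-derived profile with a qPCR profile
#'
#' Fits an ordinary least-squares line of the sequencing-based normalised
#' ratios on the qPCR ratios over the genes shared by both profiles
#' (after exclusions) and reports the squared Pearson correlation. With
#' `log_scale = TRUE` both profiles are log10-transformed first (genes
#' with non-positive values are dropped).
#'
#' @param tse_profile Named ratio vector (see
#'   [normalize_to_reference()]).
#' @param qpcr_profile Named ratio vector from the qPCR side.
#' @param exclude Gene identifiers to leave out (for example members of
#'   large gene families whose reads cross-map).
#' @param log_scale Compare on log10 scale.
#' @return A list with `r_squared`, `slope`, `intercept`, `n`,
#'   `excluded`, and `data` (the paired values used).
#' @export
validate_against_qpcr <- function(tse_profile, qpcr_profile,
                                  exclude = character(),
                                  log_scale = FALSE) {
  shared <- setdiff(intersect(names(tse_profile), names(qpcr_profile)),
                    exclude)
  x <- qpcr_profile[shared]
  y <- tse_profile[shared]
  if (log_scale) {
    ok <- x > 0 & y > 0
    x <- log10(x[ok])
    y <- log10(y[ok])
    shared <- shared[ok]
  }
  if (length(shared) < 3L) {
    stop("need at least 3 shared genes after exclusion, have ",
         length(shared))
  }
  fit <- stats::lm(y ~ x)
  list(
    r_squared = stats::cor(x, y)^2,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n = length(shared),
    excluded = exclude,
    data = data.frame(gene_id = shared, qpcr = unname(x), tse = unname(y),
                      stringsAsFactors = FALSE)
  )
}
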