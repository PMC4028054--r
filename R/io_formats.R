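#' Parse a BLAST-style tabular hit file (outfmt 6)
#'
#' Reads a 12-column tab-separated similarity-hit table (the BLAST
#' `-outfmt 6` convention: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' e-value, bit score). Coordinates are 1-based and inclusive. Hits whose
#' query coordinates are reversed are normalised so that
#' `q_start <= q_end`; minus-strand subject hits are likewise normalised,
#' with the original orientation retained in the `s_strand` column.
#'
#' @param path Path to the tab-separated hit file.
#' @param dialect Input dialect; only `"outfmt6"` is supported. Files with
#'   more than 12 columns are accepted with a warning (extra columns are
#'   ignored).
#' @return A `data.frame` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_open`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, `s_strand`
#'   (`"+"`/`"-"`), one row per input line, in file order.
#' @details Malformed lines (fewer than 12 columns, non-numeric numeric
#'   fields, negative e-values, empty identifiers) raise an error naming
#'   the offending line number; no line is ever silently dropped.
#' @seealso [write_hit_table()], [best_hit_per_query()]
#' @export
parse_hit_table <- function(path, dialect = c("outfmt6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < 12L)) {
    bad <- which(nfld < 12L)[1L]
    stop("malformed hit line ", bad, " in ", path, ": expected 12 ",
         "tab-separated columns, found ", nfld[bad])
  }
  if (any(nfld > 12L)) {
    warning("hit table ", path, " has >12 columns; extra columns ignored")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:12)), ncol = 12L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop("malformed hit line ", which(is.na(v))[1L], " in ", path,
           ": non-numeric ", what)
    }
    v
  }
  hits <- data.frame(
    query_id     = m[, 1L],
    subject_id   = m[, 2L],
    pct_identity = num(3L, "percent identity"),
    aln_length   = as.integer(num(4L, "alignment length")),
    mismatches   = as.integer(num(5L, "mismatch count")),
    gap_open     = as.integer(num(6L, "gap open count")),
    q_start      = as.integer(num(7L, "query start")),
    q_end        = as.integer(num(8L, "query end")),
    s_start      = as.integer(num(9L, "subject start")),
    s_end        = as.integer(num(10L, "subject end")),
    evalue       = num(11L, "e-value"),
    bitscore     = num(12L, "bit score"),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(hits$query_id)) || any(!nzchar(hits$subject_id))) {
    bad <- which(!nzchar(hits$query_id) | !nzchar(hits$subject_id))[1L]
    stop("malformed hit line ", bad, " in ", path, ": empty identifier")
  }
  if (any(hits$evalue < 0)) {
    bad <- which(hits$evalue < 0)[1L]
    stop("invalid hit line ", bad, " in ", path, ": negative e-value")
  }
  if (any(hits$bitscore < 0)) {
    bad <- which(hits$bitscore < 0)[1L]
    stop("invalid hit line ", bad, " in ", path, ": negative bit score")
  }
  normalize_hit_coords(hits)
}

#' @keywords internal
empty_hit_table <- function() {
  data.frame(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_length = integer(),
    mismatches = integer(), gap_open = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric(),
    s_strand = character(), stringsAsFactors = FALSE
  )
}

#' @keywords internal
normalize_hit_coords <- function(hits) {
  # orientation is carried by the subject interval in outfmt6; a reversed
  # query interval is treated the same way and folded into s_strand
  rev_q <- hits$q_start > hits$q_end
  rev_s <- hits$s_start > hits$s_end
  if (any(rev_q)) {
    tmp <- hits$q_start[rev_q]
    hits$q_start[rev_q] <- hits$q_end[rev_q]
    hits$q_end[rev_q] <- tmp
  }
  if (any(rev_s)) {
    tmp <- hits$s_start[rev_s]
    hits$s_start[rev_s] <- hits$s_end[rev_s]
    hits$s_end[rev_s] <- tmp
  }
  hits$s_strand <- ifelse(xor(rev_q, rev_s), "-", "+")
  hits
}

#' Write a hit table in outfmt-6 layout
#'
#' Inverse of [parse_hit_table()]: writes the 12 canonical columns as
#' tab-separated text (UTF-8, LF). Minus-strand hits have their subject
#' coordinates emitted in descending order so that a write/read round trip
#' is the identity.
#'
#' @param hits A hit `data.frame` as returned by [parse_hit_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  s_start <- hits$s_start
  s_end <- hits$s_end
  minus <- !is.null(hits$s_strand) & hits$s_strand == "-"
  if (any(minus)) {
    tmp <- s_start[minus]
    s_start[minus] <- s_end[minus]
    s_end[minus] <- tmp
  }
  out <- data.frame(
    hits$query_id, hits$subject_id, hits$pct_identity, hits$aln_length,
    hits$mismatches, hits$gap_open, hits$q_start, hits$q_end,
    s_start, s_end, format_evalue(hits$evalue), hits$bitscore
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
format_evalue <- function(e) {
  # fixed significand formatting keeps round trips exact at read precision
  formatC(e, format = "g", digits = 15)
}

#' Read a nucleotide FASTA file
#'
#' Identifiers are taken up to the first whitespace and sequences are
#' uppercased. Duplicate identifiers and empty records are errors.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A named character vector of uppercase sequences.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier '", ids[duplicated(ids)][1L],
         "' in ", path)
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("empty sequence for FASTA record '", ids[widths == 0L][1L],
         "' in ", path)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (any(nchar(seqs) == 0L)) stop("refusing to write empty sequences")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a rectangular TSV matrix
#'
#' Expects a header row of column identifiers and a first column of row
#' identifiers. Values are either numeric (`value_kind = "real"`) or
#' logical (`"bool"`, accepting TRUE/FALSE/1/0).
#'
#' @param path Path to the TSV file.
#' @param value_kind `"real"` or `"bool"`.
#' @return A matrix with row and column names.
#' @export
read_matrix <- function(path, value_kind = c("real", "bool")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stop("empty matrix file: ", path)
  if (length(unique(nf)) != 1L) {
    stop("ragged matrix file ", path, ": line ",
         which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
         " fields, expected ", nf[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file ", path, " has no value columns")
  row_ids <- as.character(df[[1L]])
  if (anyDuplicated(row_ids)) stop("duplicate row id in ", path)
  vals <- df[, -1L, drop = FALSE]
  if (anyDuplicated(colnames(vals))) stop("duplicate column id in ", path)
  m <- as.matrix(vals)
  if (value_kind == "real") {
    suppressWarnings(storage.mode(m) <- "numeric")
    if (anyNA(m)) stop("non-numeric cell in real-valued matrix ", path)
  } else {
    if (is.character(m)) {
      up <- toupper(trimws(m))
      ok <- up %in% c("TRUE", "FALSE", "1", "0")
      if (!all(ok)) stop("non-boolean cell in boolean matrix ", path)
      m <- matrix(up %in% c("TRUE", "1"), nrow = nrow(m),
                  dimnames = dimnames(m))
    } else {
      if (!all(m %in% c(0, 1))) {
        stop("non-boolean cell in boolean matrix ", path)
      }
      storage.mode(m) <- "logical"
    }
  }
  rownames(m) <- row_ids
  m
}

#' Write a matrix as TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_col Header for the row-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must have row and column names")
  }
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
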