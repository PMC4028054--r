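#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their parameters and seed without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Fixed arithmetic derivation so each pipeline stage has its own
#' reproducible stream; results stay below 2^31.
#'
#' @param seed Parent integer seed.
#' @param label Stage name.
#' @return An integer seed.
#' @export
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' @keywords internal
random_dna <- function(n_seqs, lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1L))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
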