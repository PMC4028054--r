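#' Construct a rarefaction library from per-gene read support
#'
#' A library lists each gene with the number of reads supporting it
#' (N_i >= 1); N is the total read count and S the number of distinct
#' genes.
#'
#' @param support Named integer vector `gene_id -> N_i`, all >= 1 (zeros
#'   are dropped).
#' @return A `rarefaction_library` (named integer vector with attributes
#'   `N` and `S`).
#' @export
rarefaction_library <- function(support) {
  if (is.null(names(support)) || any(!nzchar(names(support)))) {
    stop("support must be a named vector")
  }
  if (anyDuplicated(names(support))) stop("duplicate gene id in support")
  support <- support[support > 0]
  if (length(support) == 0L) stop("library must contain at least one read")
  if (any(support != round(support))) stop("read support must be integer")
  s <- stats::setNames(as.integer(support), names(support))
  structure(s, N = sum(s), S = length(s), class = "rarefaction_library")
}

#' @export
print.rarefaction_library <- function(x, ...) {
  cat(sprintf("Rarefaction library: S = %d genes, N = %d reads\n",
              attr(x, "S"), attr(x, "N")))
  invisible(x)
}

#' Expected gene richness in a without-replacement subsample
#'
#' The closed-form (Hurlbert) rarefaction expectation
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated
#' through log-gamma so that libraries with millions of reads do not
#' overflow. This is the exact expectation of the number of distinct
#' genes among `n` reads drawn uniformly without replacement.
#'
#' @param lib A `rarefaction_library`.
#' @param n Subsample size(s), each in `[0, N]`; vectorised.
#' @return Numeric vector of expected richness values.
#' @export
expected_richness_analytic <- function(lib, n) {
  N <- attr(lib, "N")
  if (any(n < 0 | n > N)) stop("subsample size must lie in [0, N]")
  Ni <- as.integer(lib)
  vapply(n, function(nn) {
    # lchoose returns -Inf where N - Ni < nn, i.e. gene certainly sampled
    lp <- lchoose(N - Ni, nn) - lchoose(N, nn)
    sum(1 - exp(lp))
  }, numeric(1L))
}

#' Monte Carlo rarefaction curve
#'
#' Reproduces the resampling procedure behind rarefaction software: reads
#' are drawn without replacement (each gene with probability proportional
#' to its remaining support), the number of distinct genes is recorded at
#' every grid depth, and means and standard deviations over `reps`
#' replicates are returned.
#'
#' @param lib A `rarefaction_library`.
#' @param grid Increasing subsample sizes within `[0, N]`; defaults to 50
#'   evenly spaced depths from 0 to N.
#' @param reps Number of resampling replicates (default 1000).
#' @param seed Integer seed.
#' @return A `rarefaction_curve`: `data.frame` with columns `n`,
#'   `expected_richness` (MC mean), `mc_sd`, plus attribute `reps`.
#' @export
rarefaction_curve_mc <- function(lib, grid = NULL, reps = 1000, seed = 1L) {
  N <- attr(lib, "N")
  if (is.null(grid)) grid <- unique(round(seq(0, N, length.out = 50L)))
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 0 | grid > N)) stop("grid point outside [0, N]")
  if (reps < 1) stop("reps must be >= 1")
  gene_of_read <- rep.int(seq_along(lib), as.integer(lib))
  with_seed(seed, {
    rich <- matrix(0, nrow = reps, ncol = length(grid))
    for (r in seq_len(reps)) {
      perm <- gene_of_read[sample.int(N)]
      first_pos <- which(!duplicated(perm))
      rich[r, ] <- findInterval(grid, first_pos)
    }
    curve <- data.frame(
      n = grid,
      expected_richness = colMeans(rich),
      mc_sd = apply(rich, 2L, stats::sd)
    )
    structure(curve, reps = reps,
              class = c("rarefaction_curve", "data.frame"))
  })
}

#' Analytic rarefaction curve
#'
#' Convenience wrapper evaluating [expected_richness_analytic()] on a
#' depth grid; the default grid matches [rarefaction_curve_mc()].
#'
#' @inheritParams rarefaction_curve_mc
#' @return A `rarefaction_curve` `data.frame` (`n`,
#'   `expected_richness`; `mc_sd` is `NA`).
#' @export
rarefaction_curve_analytic <- function(lib, grid = NULL) {
  N <- attr(lib, "N")
  if (is.null(grid)) grid <- unique(round(seq(0, N, length.out = 50L)))
  grid <- sort(unique(as.integer(grid)))
  curve <- data.frame(
    n = grid,
    expected_richness = expected_richness_analytic(lib, grid),
    mc_sd = NA_real_
  )
  structure(curve, reps = 0L, class = c("rarefaction_curve", "data.frame"))
}

#' Merge two rarefaction libraries
#'
#' Per-gene supports are summed; the merged library models pooling the
#' reads of two replicate sequencing runs.
#'
#' @param lib_a,lib_b `rarefaction_library` objects.
#' @return The merged `rarefaction_library`.
#' @export
merge_libraries <- function(lib_a, lib_b) {
  genes <- union(names(lib_a), names(lib_b))
  s <- stats::setNames(integer(length(genes)), genes)
  s[names(lib_a)] <- s[names(lib_a)] + as.integer(lib_a)
  s[names(lib_b)] <- s[names(lib_b)] + as.integer(lib_b)
  rarefaction_library(s)
}

#' Decide sequencing saturation from a rarefaction curve
#'
#' The tail slope is the marginal gene-discovery rate over the last
#' decile of sequencing depth: the difference in expected richness
#' between the deepest grid point and the grid point nearest 90% of that
#' depth, divided by the depth difference. The library is saturated when
#' the tail slope falls below `theta` (new genes per additional read).
#'
#' @param curve A `rarefaction_curve`.
#' @param theta Saturation threshold (genes/read, default 1e-3).
#' @return A list with `tail_slope`, `theta`, `is_saturated`, and the
#'   two grid depths used.
#' @export
assess_saturation <- function(curve, theta = 1e-3) {
  if (nrow(curve) < 2L) stop("curve needs at least 2 grid points")
  n_last <- curve$n[nrow(curve)]
  i0 <- which.min(abs(curve$n - 0.9 * n_last))
  if (curve$n[i0] == n_last) i0 <- nrow(curve) - 1L
  dn <- n_last - curve$n[i0]
  if (dn <= 0) stop("degenerate grid: no depth spread in the tail")
  slope <- (curve$expected_richness[nrow(curve)] -
            curve$expected_richness[i0]) / dn
  list(tail_slope = slope, theta = theta,
       is_saturated = slope < theta,
       n_from = curve$n[i0], n_to = n_last)
}
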