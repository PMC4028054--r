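#' Fit amplification efficiency from a standard dose-response series
#'
#' Least-squares fit of Cq against log10 relative template amount; the
#' amplification efficiency is `E = 10^(-1/slope)` (E = 2 corresponds to
#' perfect doubling, slope -3.3219 per 10-fold dilution).
#'
#' @param series `data.frame` with columns `log10_amount` and `cq`
#'   (at least 3 points).
#' @return A list with `slope`, `efficiency`, `intercept`, `r_squared`,
#'   `n`. Efficiencies outside `(1, 2.2]` trigger a warning (suspect
#'   assay).
#' @export
fit_efficiency <- function(series) {
  if (!all(c("log10_amount", "cq") %in% names(series))) {
    stop("series needs columns log10_amount and cq")
  }
  if (nrow(series) < 3L) {
    stop("a dose-response series needs at least 3 points")
  }
  fit <- stats::lm(cq ~ log10_amount, data = series)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    stop("non-negative dose-response slope: assay failure")
  }
  eff <- 10^(-1 / slope)
  if (eff <= 1 || eff > 2.2) {
    warning(sprintf("efficiency %.3f outside the plausible (1, 2.2] range",
                    eff))
  }
  list(slope = slope, efficiency = eff,
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = stats::cor(series$log10_amount, series$cq)^2,
       n = nrow(series))
}

#' Efficiency-corrected relative quantification (comparative Cq)
#'
#' Computes the fold change of a target gene between a test and a
#' control group, normalised to a reference gene, with per-gene
#' amplification efficiencies:
#' `fold = E_target^(-dCq_target) / E_ref^(-dCq_ref)` where
#' `dCq = mean(Cq_test) - mean(Cq_control)`. With both efficiencies
#' equal to 2 this reduces to the textbook `2^(-ddCq)` identity, where
#' `ddCq = dCq_target - dCq_ref`.
#'
#' @param target_cq,reference_cq `data.frame`s with columns `group` and
#'   `cq` (replicate rows).
#' @param groups Length-2 character vector `c(test, control)`.
#' @param e_target,e_ref Amplification efficiencies (default 2).
#' @return A list with `dcq_target`, `dcq_ref`, `ddcq`, `fold`,
#'   `group_means` (per gene and group).
#' @export
fold_change <- function(target_cq, reference_cq, groups,
                        e_target = 2, e_ref = 2) {
  if (length(groups) != 2L) stop("groups must be c(test, control)")
  if (e_target <= 1 || e_ref <= 1) stop("efficiencies must be > 1")
  mean_cq <- function(df, g) {
    v <- df$cq[df$group == g]
    if (length(v) == 0L) stop("no Cq measurements for group '", g, "'")
    mean(v)
  }
  mt <- vapply(groups, mean_cq, numeric(1L), df = target_cq)
  mr <- vapply(groups, mean_cq, numeric(1L), df = reference_cq)
  dcq_t <- mt[[1L]] - mt[[2L]]
  dcq_r <- mr[[1L]] - mr[[2L]]
  list(
    dcq_target = dcq_t, dcq_ref = dcq_r, ddcq = dcq_t - dcq_r,
    fold = e_target^(-dcq_t) / e_ref^(-dcq_r),
    group_means = data.frame(
      group = rep(groups, 2L),
      gene = rep(c("target", "reference"), each = 2L),
      mean_cq = c(mt, mr), stringsAsFactors = FALSE
    )
  )
}

#' Reference-normalised expression profile from Cq measurements
#'
#' Converts mean Cq values (within one group) into relative quantities
#' `E^(-Cq)` per gene and normalises them to the reference gene —
#' the qPCR analogue of a reference-normalised RPKM profile.
#'
#' @param cq `data.frame` with columns `gene_id`, `cq` (replicates), and
#'   optionally `group` (filtered to `group` when given).
#' @param reference_gene Identifier of the normaliser gene.
#' @param efficiencies Named per-gene efficiencies; genes missing from
#'   the vector default to 2.
#' @param group Optional group label to restrict to.
#' @return Named numeric vector of ratios (reference = 1).
#' @export
qpcr_profile <- function(cq, reference_gene, efficiencies = NULL,
                         group = NULL) {
  if (!is.null(group)) cq <- cq[cq$group == group, , drop = FALSE]
  if (nrow(cq) == 0L) stop("no Cq measurements selected")
  mean_cq <- tapply(cq$cq, cq$gene_id, mean)
  genes <- names(mean_cq)
  if (!(reference_gene %in% genes)) {
    stop("reference gene ", reference_gene, " not measured")
  }
  eff <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) {
    known <- intersect(genes, names(efficiencies))
    eff[known] <- efficiencies[known]
  }
  q <- eff^(-as.numeric(mean_cq))
  names(q) <- genes
  q / q[[reference_gene]]
}

#' Classical one-way analysis of variance
#'
#' Between/within mean-square F statistic and p-value across two or more
#' replicate groups. The degenerate case of zero variance both between
#' and within groups is defined as `F = 0, p = 1`; zero within-group
#' variance with a real group difference yields `F = Inf, p = 0`.
#'
#' @param groups List (>= 2) of numeric replicate vectors (each >= 2
#'   values).
#' @return A list with `f`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 replicate values")
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  ssb <- sum(lengths(groups) *
             (vapply(groups, mean, numeric(1L)) - mean(values))^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  if (ssw == 0 && ssb == 0) {
    return(list(f = 0, p_value = 1, df_between = df_b, df_within = df_w))
  }
  if (ssw == 0) {
    return(list(f = Inf, p_value = 0, df_between = df_b, df_within = df_w))
  }
  a <- stats::anova(stats::lm(values ~ fac))
  list(f = a$`F value`[1L], p_value = a$`Pr(>F)`[1L],
       df_between = df_b, df_within = df_w)
}
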