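#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1 || is.na(m) || m < 1)
    stop_input("m must be a positive test count", "phewascan_bad_arg")
  if (alpha <= 0 || alpha >= 1)
    stop_input("alpha must lie in (0, 1)", "phewascan_bad_arg")
  alpha / m
}

#' Benjamini-Hochberg p-value threshold
#'
#' The step-up rule at FDR `q`: with p-values sorted ascending, the threshold
#' is the largest `p_(k)` with `p_(k) <= k * q / m`; every test with
#' `p <= threshold` is a discovery. Returns 0 when nothing passes.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param q Target false discovery rate (default 0.05).
#' @return The p-value threshold (0 if no discoveries).
#' @export
bh_threshold <- function(pvals, q = 0.05) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0)
    stop_input("no p-values supplied", "phewascan_bad_arg")
  if (any(pvals < 0 | pvals > 1))
    stop_input("p-values must lie in [0, 1]", "phewascan_bad_arg")
  m <- length(pvals)
  sp <- sort(pvals)
  pass <- which(sp <= seq_len(m) * q / m)
  if (length(pass) == 0) 0 else sp[max(pass)]
}

#' simpleM effective number of independent tests
#'
#' Eigenvalue-based estimate of the number of independent tests among
#' correlated ones: the effective number is the smallest count of leading
#' eigenvalues of the correlation matrix whose cumulative sum reaches a
#' fraction `C` of the total (eigenvalues numerically below zero are clipped
#' to zero first).
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param C Variance-explained cutoff (default 0.995, the conventional
#'   simpleM value).
#' @return Integer effective test count `Meff`, `1 <= Meff <= ncol(corr)`.
#' @export
simple_m <- function(corr, C = 0.995) {
  corr <- as.matrix(corr)
  if (!isSymmetric(corr, tol = 1e-8))
    stop_input("correlation matrix must be symmetric", "phewascan_bad_arg")
  if (any(abs(diag(corr) - 1) > 1e-6))
    stop_input("correlation matrix must have unit diagonal",
               "phewascan_bad_arg")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / sum(ev)
  as.integer(which(frac >= C)[1])
}

#' Phenotype-side correlation matrix for simpleM
#'
#' Correlates case-indicator vectors (case = 1, control = 0, excluded =
#' missing) across phenotypes with pairwise-complete observations.
#' Undefined entries (a pair with no overlap or a constant indicator) are
#' set to 0 so the matrix stays usable.
#'
#' @param pmat A `phenotype_matrix`.
#' @return Correlation matrix over retained phenotypes.
#' @export
phenotype_correlation <- function(pmat) {
  ind <- matrix(NA_real_, nrow = length(pmat$individuals),
                ncol = ncol(pmat$status), dimnames = dimnames(pmat$status))
  ind[pmat$status == "case"] <- 1
  ind[pmat$status == "control"] <- 0
  cc <- suppressWarnings(stats::cor(ind, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' SNP-side correlation matrix for simpleM
#'
#' Pairwise-complete dosage correlations; undefined entries set to 0.
#'
#' @param gs A `genotype_set`.
#' @return Correlation matrix over SNPs.
#' @export
snp_correlation <- function(gs) {
  cc <- suppressWarnings(stats::cor(gs$dosages, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Compute the threshold set for a scan
#'
#' Bonferroni at `alpha / m`, the Benjamini-Hochberg threshold of the
#' observed p-values at rate `fdr_q`, and a simpleM-corrected threshold
#' `alpha / Meff`. For a SNP-by-phenotype scan the combined effective test
#' count is the product of the SNP-side and phenotype-side effective counts
#' (either side may be omitted).
#'
#' @param pvals Observed p-values of the test family (`NA` ignored).
#' @param alpha Family-wise rate (default 0.05).
#' @param fdr_q FDR target (default 0.05).
#' @param snp_corr,phe_corr Optional correlation matrices for the simpleM
#'   sides; both `NULL` gives `meff = m`.
#' @param simplem_c Variance-explained cutoff for simpleM.
#' @param m Number of tests; defaults to `length(pvals)` after `NA` removal.
#' @return One-row tibble of class `threshold_set`: `alpha, m, bonferroni_p,
#'   fdr_q, bh_p, meff, simplem_p`.
#' @export
significance_thresholds <- function(pvals, alpha = 0.05, fdr_q = 0.05,
                                    snp_corr = NULL, phe_corr = NULL,
                                    simplem_c = 0.995, m = NULL) {
  pv <- pvals[!is.na(pvals)]
  if (is.null(m)) m <- length(pv)
  meff_snp <- if (!is.null(snp_corr)) simple_m(snp_corr, simplem_c) else NA_integer_
  meff_phe <- if (!is.null(phe_corr)) simple_m(phe_corr, simplem_c) else NA_integer_
  meff <- if (is.na(meff_snp) && is.na(meff_phe)) as.integer(m)
          else prod(c(meff_snp, meff_phe), na.rm = TRUE)
  out <- tibble::tibble(
    alpha = alpha, m = as.integer(m),
    bonferroni_p = bonferroni_threshold(alpha, m),
    fdr_q = fdr_q, bh_p = bh_threshold(pv, fdr_q),
    meff_snp = meff_snp, meff_phe = meff_phe, meff = as.integer(meff),
    simplem_p = alpha / meff
  )
  class(out) <- c("threshold_set", class(out))
  out
}

#' Flag results against a threshold set
#'
#' Adds `pass_bonferroni`, `pass_bh`, and `pass_simplem` columns; p-values
#' exactly equal to a threshold pass. A BH threshold of 0 (no discoveries)
#' never passes.
#'
#' @param results A tibble with a `p` column (scan or meta table).
#' @param thresholds A `threshold_set` from [significance_thresholds()].
#' @return `results` with the three logical columns appended.
#' @export
annotate_significance <- function(results, thresholds) {
  results <- dplyr::mutate(
    results,
    pass_bonferroni = !is.na(.data$p) & .data$p <= thresholds$bonferroni_p,
    pass_bh = !is.na(.data$p) & thresholds$bh_p > 0 &
      .data$p <= thresholds$bh_p,
    pass_simplem = !is.na(.data$p) & .data$p <= thresholds$simplem_p
  )
  rlang::inform(paste0(
    sum(results$pass_bonferroni), " pass Bonferroni, ",
    sum(results$pass_bh), " pass BH, ",
    sum(results$pass_simplem), " pass simpleM"
  ), class = "phewascan_log")
  results
}
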