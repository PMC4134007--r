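#' Standard error of a log odds ratio from a published 95% CI
#'
#' Reconstructs the SE of the log OR from an odds ratio and its 95%
#' confidence bounds: `(log(ci_hi) - log(ci_lo)) / (2 * z_0.975)`. Useful for
#' pooling effects reported only as OR (95% CI).
#'
#' @param or_ Odds ratio.
#' @param ci_lo,ci_hi Confidence bounds, `0 < ci_lo <= or_ <= ci_hi`.
#' @return Standard error of the log odds ratio.
#' @export
ci_to_se <- function(or_, ci_lo, ci_hi) {
  if (any(ci_lo <= 0 | ci_lo > or_ | or_ > ci_hi))
    stop_input("need 0 < ci_lo <= or <= ci_hi", "phewascan_bad_arg")
  (log(ci_hi) - log(ci_lo)) / (2 * z975())
}

#' Align per-cohort effects to a common effect allele
#'
#' Expresses every cohort's log OR per copy of the first cohort's effect
#' allele: identical allele labels pass through, swapped labels flip the sign
#' of beta, and any other combination is an error (strand-ambiguity
#' resolution is not attempted).
#'
#' @param effects Tibble with `cohort, beta, se, effect_allele, other_allele`.
#' @return The harmonized tibble.
#' @export
harmonize_effects <- function(effects) {
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) == 0)
    stop_input("no effects to harmonize", "phewascan_bad_arg")
  ea <- toupper(effects$effect_allele); oa <- toupper(effects$other_allele)
  same <- ea == ea[1] & oa == oa[1]
  swapped <- ea == oa[1] & oa == ea[1]
  if (!all(same | swapped))
    stop_input(paste0("allele labels do not match under swap: ",
                      paste(unique(paste0(ea, "/", oa)[!(same | swapped)]),
                            collapse = ", ")),
               "phewascan_allele_mismatch")
  effects$beta[swapped] <- -effects$beta[swapped]
  effects$effect_allele <- ea[1]
  effects$other_allele <- oa[1]
  effects
}

#' Fixed-effects inverse-variance meta-analysis of one cell
#'
#' Pools per-cohort log odds ratios with weights `1/se^2`:
#' `beta = sum(w_i beta_i) / sum(w_i)`, `se = 1/sqrt(sum(w_i))`,
#' `z = beta/se`, `p = 2 * pnorm(-|z|)`. Cochran's Q and I-squared are
#' reported for information; they never gate results.
#'
#' @param beta Numeric vector of per-cohort log odds ratios (already
#'   allele-harmonized).
#' @param se Positive standard errors.
#' @return One-row tibble `beta, se, or, ci_lo, ci_hi, z, p, k, q_het, i2`.
#' @export
inverse_variance_meta <- function(beta, se) {
  if (length(beta) == 0)
    stop_input("no effects to pool", "phewascan_bad_arg")
  if (length(beta) != length(se) || any(is.na(se)) || any(se <= 0))
    stop_input("standard errors must be positive and match beta",
               "phewascan_bad_arg")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  q <- sum(w * (beta - b)^2)
  k <- length(beta)
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) else 0
  tibble::tibble(beta = b, se = s, or = exp(b),
                 ci_lo = exp(b - z975() * s), ci_hi = exp(b + z975() * s),
                 z = z, p = 2 * stats::pnorm(-abs(z)), k = k,
                 q_het = q, i2 = i2)
}

#' Meta-analyze per-cohort PheWAS scan tables
#'
#' Pools cohorts over the intersection of SNPs and phenotypes that are
#' testable (converged, with a finite effect) in \emph{every} cohort; cells
#' untestable anywhere are omitted rather than pooled over the remainder.
#'
#' @param tables Named list of two or more `phewas_scan` tibbles (one per
#'   cohort, same adjustment).
#' @return A `phewas_meta` tibble: `snp_id, phecode, description, category,
#'   n_cases, n_controls` (summed), pooled `beta, se, or, ci_lo, ci_hi, z, p`,
#'   and `k`.
#' @export
meta_phewas <- function(tables) {
  if (length(tables) < 2)
    stop_input("meta-analysis needs at least two cohort tables",
               "phewascan_bad_arg")
  k_total <- length(tables)
  all_rows <- purrr::imap(tables, function(tb, nm) {
    dplyr::mutate(tibble::as_tibble(tb), cohort = nm)
  }) |> purrr::list_rbind()
  testable <- dplyr::filter(all_rows, .data$converged, !is.na(.data$beta),
                            !is.na(.data$se), .data$se > 0)
  shared <- dplyr::filter(
    dplyr::add_count(testable, .data$snp_id, .data$phecode, name = "k_avail"),
    .data$k_avail == k_total
  )
  n_cells <- dplyr::n_distinct(all_rows$snp_id, all_rows$phecode)
  n_shared <- dplyr::n_distinct(shared$snp_id, shared$phecode)
  rlang::inform(paste0("meta-analysis over ", n_shared, " of ", n_cells,
                       " SNP x phenotype cells testable in all ",
                       k_total, " cohorts"), class = "phewascan_log")
  if (nrow(shared) == 0) {
    rlang::warn("no SNP x phenotype cells shared across cohorts")
    out <- tibble::tibble(snp_id = character(), phecode = numeric(),
                          description = character(), category = character(),
                          n_cases = integer(), n_controls = integer(),
                          beta = numeric(), se = numeric(), or = numeric(),
                          ci_lo = numeric(), ci_hi = numeric(),
                          z = numeric(), p = numeric(), k = integer())
    class(out) <- c("phewas_meta", class(out))
    return(out)
  }
  out <- shared |>
    dplyr::group_by(.data$snp_id, .data$phecode) |>
    dplyr::group_modify(function(g, key) {
      pooled <- inverse_variance_meta(g$beta, g$se)
      dplyr::bind_cols(
        tibble::tibble(description = g$description[1],
                       category = g$category[1],
                       n_cases = sum(g$n_cases),
                       n_controls = sum(g$n_controls)),
        pooled
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$snp_id, .data$phecode)
  class(out) <- c("phewas_meta", class(out))
  out
}

#' @export
tidy.phewas_meta <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a meta-analysis table
#'
#' @param x A `phewas_meta`.
#' @param ... Unused.
#' @export
glance.phewas_meta <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_snps = dplyr::n_distinct(x$snp_id),
    n_phenotypes = dplyr::n_distinct(x$phecode),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    max_i2 = if (nrow(x) > 0 && "i2" %in% names(x)) max(x$i2) else NA_real_
  )
}
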