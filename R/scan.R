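#' Covariate design matrix for the association models
#'
#' Builds the standard adjustment design: age, sex indicator, reference-coded
#' site indicators (dropped automatically within a single-site cohort), and
#' the first three principal components, plus average BMI when requested.
#' Columns that are constant over the analysis rows are dropped, so the
#' design stays full rank for single-sex or single-site strata.
#'
#' @param covariates Tibble aligned with the individuals: `age`, `sex`
#'   (`"F"`/`"M"`), `site`, `pc1`, `pc2`, `pc3`, and optionally `avg_bmi`.
#' @param adjust_bmi Include `avg_bmi` as a covariate?
#' @return Numeric matrix (no intercept column).
#' @keywords internal
covariate_design <- function(covariates, adjust_bmi = FALSE) {
  cv <- tibble::as_tibble(covariates)
  cols <- list(age = as.numeric(cv$age),
               sexM = as.numeric(cv$sex == "M"))
  site <- factor(cv$site)
  if (nlevels(droplevels(site)) > 1) {
    sm <- stats::model.matrix(~ site)[, -1, drop = FALSE]
    for (j in seq_len(ncol(sm))) cols[[colnames(sm)[j]]] <- sm[, j]
  }
  for (pc in c("pc1", "pc2", "pc3"))
    if (pc %in% names(cv)) cols[[pc]] <- as.numeric(cv[[pc]])
  if (adjust_bmi) {
    if (!"avg_bmi" %in% names(cv))
      stop_input("adjust_bmi = TRUE but covariates have no avg_bmi column",
                 "phewascan_bad_arg")
    cols$avg_bmi <- as.numeric(cv$avg_bmi)
  }
  do.call(cbind, cols)
}

untestable_row <- function(snp_id, phecode, n_cases, n_controls,
                           bmi_adjusted, reason) {
  tibble::tibble(snp_id = snp_id, phecode = phecode,
                 n_cases = n_cases, n_controls = n_controls,
                 beta = NA_real_, se = NA_real_, or = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                 bmi_adjusted = bmi_adjusted, converged = FALSE,
                 reason = reason)
}

#' Logistic association between one SNP and one phenotype
#'
#' Fits `case ~ dosage + covariates` by additive-model logistic regression
#' among case/control individuals. Excluded individuals and rows with missing
#' dosage or covariates (and missing average BMI when adjusting) are dropped
#' before fitting. Effects are Wald: two-sided p and a 95% CI on the odds
#' ratio scale.
#'
#' @param dosage Named (or positionally aligned) numeric dosage vector.
#' @param status Character status vector (`case`/`control`/`excluded`).
#' @param covariates Tibble aligned with `status`; see [covariate_design()].
#' @param adjust_bmi Adjust for average BMI?
#' @param snp_id,phecode Labels copied into the result.
#' @return One-row tibble: `snp_id, phecode, n_cases, n_controls, beta, se,
#'   or, ci_lo, ci_hi, p, bmi_adjusted, converged, reason`. Cells that cannot
#'   be tested (no cases or controls after exclusions, constant dosage,
#'   rank-deficient design) are flagged with a `reason`, never dropped.
#' @export
snp_phenotype_assoc <- function(dosage, status, covariates,
                                adjust_bmi = FALSE,
                                snp_id = "snp", phecode = NA_real_) {
  Z <- covariate_design(covariates, adjust_bmi = adjust_bmi)
  keep <- status %in% c("case", "control") & !is.na(dosage) &
    stats::complete.cases(Z)
  y <- as.numeric(status[keep] == "case")
  n_cases <- sum(y == 1); n_controls <- sum(y == 0)
  if (n_cases == 0 || n_controls == 0)
    return(untestable_row(snp_id, phecode, n_cases, n_controls, adjust_bmi,
                          "no cases or no controls after exclusions"))
  if (length(unique(dosage[keep])) == 1)
    return(untestable_row(snp_id, phecode, n_cases, n_controls, adjust_bmi,
                          "constant dosage"))
  X <- cbind(`(Intercept)` = 1, dosage = dosage[keep], Z[keep, , drop = FALSE])
  # drop covariate columns that are constant in this stratum
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  const[1:2] <- FALSE
  X <- X[, !const, drop = FALSE]
  fit <- tryCatch(fit_logistic(y, X), phewascan_error = function(e) e)
  if (inherits(fit, "error"))
    return(untestable_row(snp_id, phecode, n_cases, n_controls, adjust_bmi,
                          conditionMessage(fit)))
  b <- fit$beta[["dosage"]]; s <- fit$se[["dosage"]]
  tibble::tibble(
    snp_id = snp_id, phecode = phecode,
    n_cases = n_cases, n_controls = n_controls,
    beta = b, se = s, or = exp(b),
    ci_lo = exp(b - z975() * s), ci_hi = exp(b + z975() * s),
    p = 2 * stats::pnorm(-abs(b / s)),
    bmi_adjusted = adjust_bmi, converged = fit$converged,
    reason = NA_character_
  )
}

#' Phenome-wide association scan
#'
#' Runs [snp_phenotype_assoc()] for every SNP in the genotype set against
#' every retained phenotype, in deterministic `(snp_id, phecode)` order.
#' Untestable cells are kept in the table with their reason.
#'
#' @param gs A `genotype_set` (post-QC).
#' @param pmat A `phenotype_matrix` sharing the same individuals.
#' @param covariates Tibble with one row per individual of `pmat`, in order.
#' @param adjust_bmi Adjust every fit for average BMI?
#' @return A `phewas_scan` tibble with one row per SNP x phenotype, carrying
#'   the phenotype description and category.
#' @export
run_phewas <- function(gs, pmat, covariates, adjust_bmi = FALSE) {
  if (!identical(gs$individuals, pmat$individuals))
    stop_input("genotypes and phenotype matrix must share individual order",
               "phewascan_bad_arg")
  snp_ids <- sort(gs$snps$snp_id)
  phe <- dplyr::arrange(pmat$phenotypes, .data$phecode)
  rows <- purrr::map(snp_ids, function(s) {
    d <- gs$dosages[, s]
    purrr::map(phe$phecode, function(pc) {
      snp_phenotype_assoc(d, phenotype_status(pmat, pc), covariates,
                          adjust_bmi = adjust_bmi, snp_id = s, phecode = pc)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- dplyr::left_join(rows,
                          phe[, c("phecode", "description", "category")],
                          by = "phecode") |>
    dplyr::relocate("description", "category", .after = "phecode")
  class(out) <- c("phewas_scan", class(out))
  out
}

#' Linear association between a SNP and average BMI
#'
#' Ordinary least squares of cleaned average BMI on dosage plus the standard
#' covariates; the per-allele effect is in kg/m^2 with a symmetric Wald 95%
#' CI.
#'
#' @param dosage Numeric dosage vector.
#' @param avg_bmi Numeric average-BMI vector (`NA` dropped).
#' @param covariates Tibble aligned with `dosage`; see [covariate_design()].
#' @param snp_id Label copied into the result.
#' @return One-row tibble `snp_id, beta, se, ci_lo, ci_hi, p, n`.
#' @export
snp_bmi_assoc <- function(dosage, avg_bmi, covariates, snp_id = "snp") {
  Z <- covariate_design(covariates, adjust_bmi = FALSE)
  keep <- !is.na(dosage) & !is.na(avg_bmi) & stats::complete.cases(Z)
  df <- data.frame(avg_bmi = avg_bmi[keep], dosage = dosage[keep])
  Zk <- Z[keep, , drop = FALSE]
  Zk <- Zk[, apply(Zk, 2, function(col) length(unique(col)) > 1), drop = FALSE]
  X <- cbind(dosage = df$dosage, Zk)
  if (nrow(df) < ncol(X) + 2)
    stop_input("too few complete cases for the BMI model", "phewascan_bad_arg")
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop_input("rank-deficient BMI design", "phewascan_rank_deficient")
  fit <- stats::lm(df$avg_bmi ~ X)
  b <- stats::coef(fit)[["Xdosage"]]
  s <- sqrt(diag(stats::vcov(fit)))[["Xdosage"]]
  tibble::tibble(snp_id = snp_id, beta = b, se = s,
                 ci_lo = b - z975() * s, ci_hi = b + z975() * s,
                 p = 2 * stats::pnorm(-abs(b / s)), n = nrow(df))
}

#' @export
tidy.phewas_scan <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a scan table
#'
#' @param x A `phewas_scan`.
#' @param ... Unused.
#' @export
glance.phewas_scan <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_snps = dplyr::n_distinct(x$snp_id),
    n_phenotypes = dplyr::n_distinct(x$phecode),
    n_untestable = sum(!is.na(x$reason)),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE))
  )
}
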