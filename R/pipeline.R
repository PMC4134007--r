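#' Run the full two-cohort PheWAS pipeline
#'
#' Per cohort: genotype QC, relatedness pruning, BMI cleaning, phenotype
#' matrix construction, and additive-model logistic scans (unadjusted and/or
#' BMI-adjusted), plus per-SNP linear BMI models. Cohorts are then pooled by
#' fixed-effects inverse-variance meta-analysis over the SNP x phenotype
#' cells testable everywhere, significance thresholds are computed, and the
#' meta tables annotated. Every filter count is collected in the run log.
#'
#' @param study A `phewas_study` from [generate_study()], or any list with
#'   the same shape (per-cohort `demographics`, `events`, `bmi`, `genotypes`,
#'   `ibd`) plus `map`.
#' @param min_cases Minimum case count per phenotype (default 20).
#' @param adjust_bmi `"both"` (default), `"yes"`, or `"no"`.
#' @param index_snp SNP whose meta p-values define the threshold family;
#'   defaults to the study's index SNP, else the first shared SNP.
#' @param alpha,fdr_q,simplem_c Multiple-testing parameters.
#' @param min_call_rate,min_maf,min_info QC thresholds, see [qc_filter()].
#' @param ibd_threshold Relatedness cutoff, see [prune_related()].
#' @param seed Seed for the random member choice in relatedness pruning.
#' @return A `phewas_pipeline` list: `cohorts` (each with the post-QC
#'   genotype set, retained ids, phenotype matrix, covariates, scan tables,
#'   and BMI association table), `meta` (annotated tibbles, one per
#'   adjustment), `thresholds`, and `log` (a tibble of filter counts).
#' @export
run_phewas_pipeline <- function(study, min_cases = 20L,
                                adjust_bmi = c("both", "yes", "no"),
                                index_snp = NULL,
                                alpha = 0.05, fdr_q = 0.05, simplem_c = 0.995,
                                min_call_rate = 0.99, min_maf = 0.01,
                                min_info = 0.7, ibd_threshold = 0.25,
                                seed = 1L) {
  adjust_bmi <- match.arg(adjust_bmi)
  adjustments <- switch(adjust_bmi, both = c(FALSE, TRUE), yes = TRUE,
                        no = FALSE)
  if (is.null(index_snp) && !is.null(study$truth$index_snp))
    index_snp <- study$truth$index_snp
  log_rows <- list()
  note <- function(cohort, stage, n) {
    log_rows[[length(log_rows) + 1]] <<-
      tibble::tibble(cohort = cohort, stage = stage, n = as.integer(n))
  }

  cohorts <- purrr::imap(study$cohorts, function(co, cname) {
    gs <- qc_filter(co$genotypes, min_call_rate = min_call_rate,
                    min_maf = min_maf, min_info = min_info)
    note(cname, "snps_input", nrow(co$genotypes$snps))
    note(cname, "snps_dropped_qc", nrow(attr(gs, "dropped")))
    kept <- prune_related(co$demographics$person_id, co$ibd,
                          threshold = ibd_threshold,
                          seed = substream_seed(seed, paste0(cname, ":prune")))
    note(cname, "individuals_input", nrow(co$demographics))
    note(cname, "individuals_pruned", nrow(co$demographics) - length(kept))
    demo <- co$demographics[match(kept, co$demographics$person_id), ]
    gs <- subset_individuals(gs, kept)
    avg <- clean_bmi(co$bmi)
    covars <- dplyr::left_join(demo, avg[, c("person_id", "avg_bmi")],
                               by = "person_id")
    pmat <- build_phenotype_matrix(co$events, demo, study$map,
                                   min_cases = min_cases)
    note(cname, "phenotypes_retained", nrow(pmat$phenotypes))
    note(cname, "phenotypes_dropped", nrow(pmat$dropped))
    scans <- purrr::map(adjustments, function(adj) {
      run_phewas(gs, pmat, covars, adjust_bmi = adj)
    })
    names(scans) <- ifelse(adjustments, "adjusted", "unadjusted")
    bmi_assoc <- purrr::map(gs$snps$snp_id, function(s) {
      snp_bmi_assoc(gs$dosages[, s], covars$avg_bmi, covars, snp_id = s)
    }) |> purrr::list_rbind()
    list(genotypes = gs, retained_ids = kept, covariates = covars,
         phenotype_matrix = pmat, scans = scans, bmi_assoc = bmi_assoc)
  })

  meta <- purrr::map(stats::setNames(adjustments,
                                     ifelse(adjustments, "adjusted",
                                            "unadjusted")),
                     function(adj) {
    nm <- if (adj) "adjusted" else "unadjusted"
    meta_phewas(purrr::map(cohorts, function(co) co$scans[[nm]]))
  })

  family <- meta[[1]]
  if (!is.null(index_snp) && index_snp %in% family$snp_id)
    family <- family[family$snp_id == index_snp, ]
  first <- cohorts[[1]]
  meta_snps <- intersect(first$genotypes$snps$snp_id, meta[[1]]$snp_id)
  snp_corr <- if (length(meta_snps) > 1) {
    snp_correlation(genotype_set(
      first$genotypes$individuals,
      first$genotypes$snps[first$genotypes$snps$snp_id %in% meta_snps, ],
      first$genotypes$dosages[, meta_snps, drop = FALSE]
    ))
  } else NULL
  thresholds <- significance_thresholds(
    family$p, alpha = alpha, fdr_q = fdr_q,
    snp_corr = snp_corr,
    phe_corr = phenotype_correlation(first$phenotype_matrix),
    simplem_c = simplem_c,
    m = dplyr::n_distinct(family$phecode)
  )
  meta <- purrr::map(meta, annotate_significance, thresholds = thresholds)

  structure(
    list(cohorts = cohorts, meta = meta, thresholds = thresholds,
         index_snp = index_snp, log = purrr::list_rbind(log_rows)),
    class = "phewas_pipeline"
  )
}

#' @export
print.phewas_pipeline <- function(x, ...) {
  cat("<phewas_pipeline> ", length(x$cohorts), " cohorts; adjustments: ",
      paste(names(x$meta), collapse = ", "), "\n", sep = "")
  print(x$thresholds)
  invisible(x)
}

#' Write pipeline result tables as TSV
#'
#' @param pipeline A `phewas_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_tables <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cname in names(pipeline$cohorts)) {
    co <- pipeline$cohorts[[cname]]
    for (nm in names(co$scans))
      readr::write_tsv(co$scans[[nm]],
                       file.path(dir, paste0("scan_", cname, "_", nm, ".tsv")))
    readr::write_tsv(co$bmi_assoc,
                     file.path(dir, paste0("bmi_assoc_", cname, ".tsv")))
  }
  for (nm in names(pipeline$meta))
    readr::write_tsv(pipeline$meta[[nm]],
                     file.path(dir, paste0("meta_", nm, ".tsv")))
  readr::write_tsv(pipeline$thresholds, file.path(dir, "thresholds.tsv"))
  readr::write_tsv(pipeline$log, file.path(dir, "run_log.tsv"))
  invisible(dir)
}
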