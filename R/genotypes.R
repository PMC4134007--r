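#' Construct a genotype set
#'
#' A genotype set holds an additive-dosage matrix (0/1/2 copies of the effect
#' allele, `NA` for missing) over an ordered set of individuals, plus per-SNP
#' metadata. Call rate and minor allele frequency are computed from the
#' dosages; an imputation info score, when supplied, is carried as metadata.
#'
#' @param individuals Character vector of person ids (row order of `dosages`).
#' @param snps Tibble with `snp_id`, `effect_allele`, `other_allele`, and
#'   optionally `info` (imputation quality in \[0,1\], `NA` for genotyped SNPs).
#' @param dosages Numeric matrix, individuals x SNPs.
#' @return A `genotype_set`.
#' @export
genotype_set <- function(individuals, snps, dosages) {
  individuals <- as.character(individuals)
  snps <- tibble::as_tibble(snps)
  if (!"info" %in% names(snps)) snps$info <- NA_real_
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(individuals) || ncol(dosages) != nrow(snps))
    stop_input("dosage matrix does not match individuals x snps",
               "phewascan_bad_arg")
  dimnames(dosages) <- list(individuals, snps$snp_id)
  structure(list(individuals = individuals, snps = snps, dosages = dosages),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", length(x$individuals), " individuals x ",
      nrow(x$snps), " SNPs\n", sep = "")
  print(snp_stats(x), ...)
  invisible(x)
}

#' Minor allele frequency of a dosage vector
#'
#' `min(f, 1 - f)` where `f` is the effect-allele frequency
#' `sum(dosage) / (2 * n_nonmissing)`; missing dosages are ignored.
#'
#' @param dosages Numeric vector of 0/1/2 dosages, `NA` allowed.
#' @return Frequency in \[0, 0.5\].
#' @export
minor_allele_freq <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0)
    stop_input("all dosages missing; MAF undefined", "phewascan_all_missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Per-SNP summary statistics
#'
#' @param gs A `genotype_set`.
#' @return Tibble `snp_id, effect_allele, other_allele, call_rate, maf, info`.
#' @export
snp_stats <- function(gs) {
  cr <- colMeans(!is.na(gs$dosages))
  maf <- apply(gs$dosages, 2, function(d) {
    if (all(is.na(d))) NA_real_ else minor_allele_freq(d)
  })
  dplyr::mutate(gs$snps, call_rate = unname(cr), maf = unname(maf),
                .after = "other_allele")
}

#' Genotype quality-control filter
#'
#' Retains SNPs with call rate strictly above `min_call_rate`, minor allele
#' frequency strictly above `min_maf`, and — for imputed SNPs carrying an info
#' score — info at least `min_info`. Dropped SNPs and the reason for each drop
#' are attached as the `"dropped"` attribute and reported via a message.
#'
#' @param gs A `genotype_set`.
#' @param min_call_rate,min_maf Strict lower bounds (defaults 0.99, 0.01).
#' @param min_info Inclusive lower bound on the info score (default 0.7);
#'   ignored for SNPs without one.
#' @return Filtered `genotype_set`; idempotent.
#' @export
qc_filter <- function(gs, min_call_rate = 0.99, min_maf = 0.01,
                      min_info = 0.7) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1, min_info >= 0, min_info <= 1)
  st <- snp_stats(gs)
  reason <- dplyr::case_when(
    is.na(st$maf) | st$call_rate <= min_call_rate ~ "call_rate",
    st$maf <= min_maf ~ "maf",
    !is.na(st$info) & st$info < min_info ~ "info",
    .default = NA_character_
  )
  keep <- is.na(reason)
  dropped <- tibble::tibble(snp_id = st$snp_id[!keep],
                            reason = reason[!keep])
  if (nrow(dropped) > 0)
    rlang::inform(paste0("QC dropped ", nrow(dropped), " SNP(s): ",
                         paste(dropped$snp_id, " (", dropped$reason, ")",
                               sep = "", collapse = ", ")),
                  class = "phewascan_log")
  out <- genotype_set(gs$individuals, gs$snps[keep, , drop = FALSE],
                      gs$dosages[, keep, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Restrict a genotype set to a subset of individuals
#'
#' @param gs A `genotype_set`.
#' @param ids Character vector of person ids to keep (order preserved).
#' @export
subset_individuals <- function(gs, ids) {
  ids <- as.character(ids)
  if (!all(ids %in% gs$individuals))
    stop_input("unknown individual id(s) in subset", "phewascan_bad_arg")
  genotype_set(ids, gs$snps, gs$dosages[ids, , drop = FALSE])
}

#' Hard-call genotypes from posterior probabilities
#'
#' Converts imputation posterior triples (P(dosage = 0), P(1), P(2)) into
#' hard dosage calls at the maximum posterior, breaking ties toward the lower
#' dosage for determinism.
#'
#' @param posteriors Numeric vector of length 3, or a matrix with 3 columns
#'   (one row per individual). Rows must be non-negative and sum to 1
#'   within 1e-6.
#' @return Integer dosage(s) in 0/1/2.
#' @export
hard_call <- function(posteriors) {
  p <- if (is.matrix(posteriors)) posteriors else matrix(posteriors, nrow = 1)
  if (ncol(p) != 3)
    stop_input("posteriors must have 3 components", "phewascan_bad_arg")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6))
    stop_input("posteriors must be a probability simplex (sum 1 within 1e-6)",
               "phewascan_bad_arg")
  calls <- max.col(p, ties.method = "first") - 1L
  if (is.matrix(posteriors)) calls else calls[[1]]
}

#' Read a dosage matrix from TSV
#'
#' @param path TSV with header
#'   `snp_id, effect_allele, other_allele, <one column per person>`.
#'   Optionally an `info` column before the person columns. Empty cells are
#'   missing dosages.
#' @return A `genotype_set`.
#' @export
read_dosage_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- intersect(c("snp_id", "effect_allele", "other_allele", "info"),
                         names(raw))
  persons <- setdiff(names(raw), meta_cols)
  dos <- t(as.matrix(raw[, persons]))
  genotype_set(persons, raw[, meta_cols], dos)
}

#' Write a genotype set as a dosage TSV
#'
#' @param gs A `genotype_set`.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(gs, path) {
  out <- dplyr::bind_cols(
    gs$snps[, c("snp_id", "effect_allele", "other_allele", "info")],
    tibble::as_tibble(t(gs$dosages))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Uses the `DS` FORMAT field when present, otherwise additive-codes `GT`
#' (count of ALT alleles). The ALT allele is the effect allele.
#'
#' @param path Path to a VCF (may be bgzipped).
#' @return A `genotype_set`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF requires the vcfR package", "phewascan_missing_dep")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) NA_real_
        else sum(a != "0")
      }, numeric(1))
    })
  }
  genotype_set(
    colnames(dos),
    tibble::tibble(snp_id = ids, effect_allele = fix[, "ALT"],
                   other_allele = fix[, "REF"]),
    t(dos)
  )
}
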