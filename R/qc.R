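#' Prune related individuals by identity-by-descent
#'
#' Builds a relatedness graph over pairs with IBD proportion (pi-hat)
#' strictly above `threshold` and keeps exactly one randomly chosen member of
#' each connected component; everyone untouched by such a pair is kept.
#' Random selection uses its own seeded stream, so results are reproducible
#' and the caller's RNG is untouched.
#'
#' @param individuals Character vector of all person ids.
#' @param pairs Tibble `id_a, id_b, pi_hat` of pairwise IBD estimates.
#' @param threshold Strict pi-hat cutoff (default 0.25).
#' @param seed Integer seed for the random choice within each component.
#' @return Character vector of retained ids, in the original order.
#' @export
prune_related <- function(individuals, pairs, threshold = 0.25, seed = 1L) {
  individuals <- as.character(individuals)
  pairs <- tibble::as_tibble(pairs)
  rel <- pairs[pairs$pi_hat > threshold, , drop = FALSE]
  if (nrow(rel) == 0) return(individuals)
  ids <- unique(c(as.character(rel$id_a), as.character(rel$id_b)))
  if (!all(ids %in% individuals))
    stop_input("IBD pairs reference unknown individuals", "phewascan_bad_arg")
  # union-find over the related subgraph
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(rel))) {
    ra <- find(match(as.character(rel$id_a[k]), ids))
    rb <- find(match(as.character(rel$id_b[k]), ids))
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  keep_related <- with_local_seed(seed, {
    unlist(lapply(split(ids, comp), function(members) {
      members[sample.int(length(members), 1L)]
    }), use.names = FALSE)
  })
  drop <- setdiff(ids, keep_related)
  rlang::inform(paste0("relatedness pruning removed ", length(drop),
                       " of ", length(ids), " related individuals"),
                class = "phewascan_log")
  individuals[!individuals %in% drop]
}

#' Read pairwise IBD estimates
#'
#' @param path TSV with header `id_a,id_b,pi_hat`.
#' @export
read_ibd <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id_a = readr::col_character(),
                    id_b = readr::col_character(),
                    pi_hat = readr::col_double()
                  ))
}

#' Clean and average BMI measurements
#'
#' EHR BMI streams contain data-entry errors; measurements outside a
#' plausibility window are discarded and the rest averaged per person. The
#' window is inclusive at both ends.
#'
#' @param bmi Tibble `person_id, bmi`, one row per measurement.
#' @param lo,hi Plausibility window in kg/m^2 (defaults 15 and 70).
#' @return Tibble `person_id, avg_bmi, n_used, n_dropped`; `avg_bmi` is `NA`
#'   when no measurement falls in the window.
#' @export
clean_bmi <- function(bmi, lo = 15, hi = 70) {
  bmi <- tibble::as_tibble(bmi)
  dplyr::summarise(
    dplyr::group_by(bmi, person_id = as.character(.data$person_id)),
    avg_bmi = {
      ok <- .data$bmi >= lo & .data$bmi <= hi
      if (any(ok)) mean(.data$bmi[ok]) else NA_real_
    },
    n_used = sum(.data$bmi >= lo & .data$bmi <= hi),
    n_dropped = sum(.data$bmi < lo | .data$bmi > hi),
    .groups = "drop"
  )
}

#' Read BMI measurements
#'
#' @param path CSV with header `person_id,bmi`, one row per measurement.
#' @export
read_bmi <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(person_id = readr::col_character(),
                                          bmi = readr::col_double()))
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of additive dosages over individuals with both
#' values observed (composite LD, appropriate for unphased genotypes).
#' Symmetric, and invariant to allele flipping (`dosage -> 2 - dosage`).
#'
#' @param dosages_a,dosages_b Numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2)
    stop_input("need >= 2 pairwise-complete individuals", "phewascan_bad_arg")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop_input("monomorphic SNP: zero dosage variance", "phewascan_monomorphic")
  stats::cor(a, b)^2
}

#' Linkage-disequilibrium group relative to an index SNP
#'
#' High LD is r^2 > 0.80, moderate is 0.60 < r^2 <= 0.80, and low is
#' r^2 <= 0.60.
#'
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return Factor with levels `high`, `moderate`, `low`.
#' @export
ld_group <- function(r2) {
  if (any(is.na(r2) | r2 < 0 | r2 > 1))
    stop_input("r2 must lie in [0, 1]", "phewascan_bad_arg")
  factor(ifelse(r2 > 0.80, "high", ifelse(r2 > 0.60, "moderate", "low")),
         levels = c("high", "moderate", "low"))
}
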