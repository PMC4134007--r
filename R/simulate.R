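#' Default planted phenotype models
#'
#' The effect architecture the generator plants around the index SNP, chosen
#' to mirror the canonical obesity-locus pattern: fully BMI-mediated
#' phenotypes (obesity-spectrum codes, sleep apnea), partially mediated ones
#' (type 2 diabetes, fatty liver disease), one direct protective female-only
#' phenotype (fibrocystic breast disease), and common background phenotypes
#' with no genetic effect. `direct_log_or` acts per effect allele on the
#' logit; `bmi_log_or` acts per kg/m^2 of latent BMI above the population
#' mean, so the SNP reaches such phenotypes only through its BMI effect.
#'
#' @return Tibble `phecode, direct_log_or, bmi_log_or, baseline_prevalence`.
#' @export
default_phenotype_models <- function() {
  # mediated channels: per-allele log OR ~ bmi_log_or * 0.535 (the per-allele
  # BMI effect); baselines are set so the marginal case fraction lands near
  # the intended population prevalence despite the heavy BMI tail.
  tibble::tribble(
    ~phecode, ~direct_log_or, ~bmi_log_or, ~baseline_prevalence,
    278.0,    0,              0.29,        0.0675, # overweight: mediated
    278.1,    0,              0.42,        0.0059, # obesity: mediated
    278.11,   0,              0.55,        4e-04,  # morbid obesity: mediated
    250.2,    log(1.09),      0.09,        0.137,  # T2D: partially mediated
    327.3,    0,              0.245,       0.038,  # sleep apnea: mediated
    571.8,    log(1.15),      0.05,        0.024,  # NAFLD: mostly direct
    610.1,    log(0.81),      0,           0.08,   # fibrocystic breast: direct, protective, female-only
    041.1,    log(1.16),      0,           0.029,  # staphylococcus: direct
    041.0,    log(1.21),      0,           0.017,  # streptococcus: direct
    480.1,    0,              0,           0.010,
    038.2,    0,              0,           0.012,
    401.1,    0,              0,           0.35,
    272.1,    0,              0,           0.28,
    530.11,   0,              0,           0.16,
    729.5,    0,              0,           0.22,
    780.7,    0,              0,           0.24,
    585.1,    0,              0,           0.065,
    707.1,    0,              0,           0.025,
    681.1,    0,              0,           0.10,
    710.1,    0,              0,           0.012,
    719.1,    0,              0,           0.014,
    622.1,    0,              0,           0.035,
    523.3,    log(1.25),      0,           0.05    # periodontitis: direct, BMI-independent
  )
}

#' Default SNP panel around the index variant
#'
#' An index SNP at MAF 0.41 plus satellites at several target r-squared
#' levels, including quality-control bait (a low imputation info score, a
#' rare variant, a high-missingness variant) that the QC filter should
#' remove. The `cohorts` column controls which cohort is genotyped for each
#' SNP, so the meta-analysis intersection logic is exercised: only the index
#' and the high-LD satellite are shared.
#'
#' @return Tibble `snp_id, effect_allele, other_allele, maf, target_r2, info,
#'   missing_rate, cohorts`.
#' @export
default_snp_panel <- function() {
  tibble::tribble(
    ~snp_id,      ~effect_allele, ~other_allele, ~maf,  ~target_r2, ~info,     ~missing_rate, ~cohorts,
    "rs_index",   "A",            "C",           0.41,  1.00,       NA_real_,  0,             "both",
    "rs_high",    "A",            "T",           0.42,  0.92,       NA_real_,  0,             "both",
    "rs_mod",     "G",            "A",           0.44,  0.64,       NA_real_,  0,             "cohort1",
    "rs_low",     "G",            "A",           0.39,  0.06,       NA_real_,  0,             "cohort1",
    "rs_lowinfo", "T",            "C",           0.35,  0.90,       0.65,      0,             "cohort1",
    "rs_rare",    "T",            "G",           0.005, 0.00,       NA_real_,  0,             "cohort1",
    "rs_lowcall", "C",            "G",           0.30,  0.80,       NA_real_,  0.05,          "cohort1"
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic two-cohort study. Defaults emulate
#' the published study conditions: two European-ancestry-like cohorts of
#' 10,487 and 13,711 individuals, an index SNP at MAF 0.41 with a per-allele
#' BMI effect of 0.535 kg/m^2, BMI around Normal(29.5, 7.0^2), and the
#' mediated/direct effect architecture of [default_phenotype_models()].
#'
#' @param n_per_cohort Named integer vector of cohort sizes.
#' @param seed Master seed; every stage draws from a named substream of it.
#' @param snps SNP panel tibble, see [default_snp_panel()]. `cohorts` values
#'   are `"both"`, `"cohort1"`, `"cohort2"`.
#' @param index_snp Id of the index SNP within `snps`.
#' @param bmi_mean,bmi_sd Latent BMI distribution (kg/m^2).
#' @param bmi_beta_per_allele Per-allele additive effect on latent BMI.
#' @param bmi_measure_sd Within-person measurement noise (kg/m^2).
#' @param n_bmi_measurements Inclusive range of measurements per person.
#' @param bmi_outlier_rate Fraction of measurements replaced by implausible
#'   values outside the 15-70 cleaning window.
#' @param phenotype_models Planted models, see [default_phenotype_models()].
#' @param n_null_phenotypes Extra synthetic null phenotypes appended to the
#'   map (prevalence `null_prevalence`, no genetic or BMI effect).
#' @param null_prevalence Baseline prevalence of the synthetic nulls.
#' @param single_mention_rate Probability that a non-case emits one single-day
#'   code of the phenotype, exercising the single-mention exclusion.
#' @param related_pair_frac Fraction of each cohort planted as related pairs
#'   (pi-hat around 0.5) in the IBD table.
#' @param female_frac,age_range,n_sites Demographic plumbing.
#' @param event_window Calendar window events are drawn from.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = c(cohort1 = 10487L, cohort2 = 13711L),
                       seed = 20160L,
                       snps = default_snp_panel(),
                       index_snp = "rs_index",
                       bmi_mean = 29.5, bmi_sd = 7.0,
                       bmi_beta_per_allele = 0.535,
                       bmi_measure_sd = 1.5,
                       n_bmi_measurements = c(1L, 4L),
                       bmi_outlier_rate = 0.02,
                       phenotype_models = default_phenotype_models(),
                       n_null_phenotypes = 10L,
                       null_prevalence = 0.05,
                       single_mention_rate = 0.05,
                       related_pair_frac = 0.005,
                       female_frac = 0.53,
                       age_range = c(40, 80),
                       n_sites = c(cohort1 = 3L, cohort2 = 1L),
                       event_window = as.Date(c("2002-01-01", "2011-12-31"))) {
  stopifnot(length(n_per_cohort) >= 1, all(n_per_cohort > 0),
            bmi_outlier_rate >= 0, bmi_outlier_rate <= 1,
            single_mention_rate >= 0, single_mention_rate <= 1,
            all(snps$target_r2 >= 0 & snps$target_r2 <= 1),
            index_snp %in% snps$snp_id)
  if (is.null(names(n_per_cohort)))
    names(n_per_cohort) <- paste0("cohort", seq_along(n_per_cohort))
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic map entries for null phenotypes
#'
#' @param n Number of null phenotypes (at most 1000).
#' @return A tibble of map rows (one ICD-9 code per null phecode, exclusion
#'   interval equal to the phecode itself).
#' @keywords internal
null_phecode_entries <- function(n) {
  if (n == 0) return(NULL)
  stopifnot(n <= 1000)
  i <- seq_len(n) - 1L
  icd <- sprintf("9%02d.%02d", i %/% 100, i %% 100)
  phe <- 900 + (i %/% 100) + (i %% 100) / 100
  tibble::tibble(icd9 = icd, phecode = phe,
                 description = sprintf("Synthetic null phenotype %d", i + 1L),
                 category = "synthetic null",
                 exclusion_lo = phe, exclusion_hi = phe, sex = "none")
}

#' Generate genotypes for one cohort
#'
#' The index SNP is drawn as two haplotypic Bernoulli(maf) alleles. Each
#' satellite copies the index allele per haplotype with probability
#' `sqrt(target_r2)` and otherwise draws fresh at its own MAF; with equal
#' MAFs the realized r-squared hits the target in expectation. Missingness
#' is injected at each SNP's `missing_rate`.
#'
#' @param n Number of individuals.
#' @param snps SNP panel rows to generate (must include the index SNP).
#' @param index_snp Id of the index SNP.
#' @param ids Person ids.
#' @return A `genotype_set`.
#' @export
generate_genotypes <- function(n, snps, index_snp, ids = sprintf("id_%05d", seq_len(n))) {
  idx <- snps[snps$snp_id == index_snp, ]
  if (nrow(idx) != 1)
    stop_input("index SNP missing from panel", "phewascan_bad_arg")
  h1 <- stats::rbinom(n, 1, idx$maf)
  h2 <- stats::rbinom(n, 1, idx$maf)
  dos <- matrix(NA_real_, n, nrow(snps),
                dimnames = list(ids, snps$snp_id))
  for (j in seq_len(nrow(snps))) {
    s <- snps[j, ]
    if (s$snp_id == index_snp) {
      d <- h1 + h2
    } else {
      cpy <- sqrt(s$target_r2)
      m1 <- stats::rbinom(n, 1, cpy); m2 <- stats::rbinom(n, 1, cpy)
      a1 <- m1 * h1 + (1 - m1) * stats::rbinom(n, 1, s$maf)
      a2 <- m2 * h2 + (1 - m2) * stats::rbinom(n, 1, s$maf)
      d <- a1 + a2
    }
    if (s$missing_rate > 0)
      d[stats::runif(n) < s$missing_rate] <- NA_real_
    dos[, j] <- d
  }
  genotype_set(ids, snps[, c("snp_id", "effect_allele", "other_allele", "info")],
               dos)
}

#' Generate BMI measurements for one cohort
#'
#' Latent true BMI is Normal(`bmi_mean`, `bmi_sd`^2) plus the per-allele
#' additive genetic effect; each person contributes 1 or more measurements
#' with Normal(0, `bmi_measure_sd`^2) noise, and a small fraction of
#' measurements is corrupted to implausible values so the cleaning window
#' has work to do.
#'
#' @param dosage Index-SNP dosage vector.
#' @param config A `sim_config`.
#' @param ids Person ids aligned with `dosage`.
#' @return List with `latent` (numeric vector) and `measurements` (tibble
#'   `person_id, bmi`).
#' @export
generate_bmi <- function(dosage, config, ids) {
  n <- length(dosage)
  latent <- stats::rnorm(n, config$bmi_mean, config$bmi_sd) +
    config$bmi_beta_per_allele * dosage
  k <- sample(seq(config$n_bmi_measurements[1], config$n_bmi_measurements[2]),
              n, replace = TRUE)
  # honest measurements are clipped into the plausibility band, so
  # out-of-window values arise only from injected corruption
  meas <- tibble::tibble(
    person_id = rep(ids, times = k),
    bmi = pmin(pmax(rep(latent, times = k) +
                      stats::rnorm(sum(k), 0, config$bmi_measure_sd), 15), 70)
  )
  out <- stats::runif(nrow(meas)) < config$bmi_outlier_rate
  if (any(out)) {
    lo <- stats::runif(sum(out)) < 0.5
    meas$bmi[out] <- ifelse(lo, stats::runif(sum(out), 3, 14.5),
                            stats::runif(sum(out), 70.5, 200))
  }
  list(latent = latent, measurements = meas)
}

#' Generate phenotypes and ICD-9 billing events for one cohort
#'
#' Each phenotype model turns into per-person case probabilities
#' `plogis(qlogis(prevalence) + direct_log_or * dosage +
#' bmi_log_or * (latent_bmi - bmi_mean))`; sex-restricted phenotypes apply
#' only to the matching sex. True cases emit 2-5 mapped codes on distinct
#' days; non-cases emit one single-day code with probability
#' `single_mention_rate`, which downstream must exclude from controls.
#'
#' @param persons Tibble `person_id, sex`.
#' @param dosage Index-SNP dosage aligned with `persons`.
#' @param latent_bmi Latent BMI aligned with `persons`.
#' @param models Tibble of planted models (phecode must be in `map`).
#' @param map A `phecode_map` covering all modeled phecodes.
#' @param config A `sim_config`.
#' @return List with `events` (tibble `person_id, date, icd9`) and `truth`
#'   (tibble of planted parameters and realized case counts).
#' @export
generate_phenotypes_and_events <- function(persons, dosage, latent_bmi,
                                           models, map, config) {
  map_tb <- tibble::as_tibble(map)
  defs <- phecode_definitions(map)
  window_days <- as.integer(config$event_window[2] - config$event_window[1])
  n <- nrow(persons)
  ev_list <- list()
  truth <- list()
  dosage_f <- ifelse(is.na(dosage), 0, dosage)
  for (r in seq_len(nrow(models))) {
    mod <- models[r, ]
    codes <- map_tb$icd9[map_tb$phecode == mod$phecode]
    if (length(codes) == 0)
      stop_input(paste0("model phecode ", mod$phecode, " not in map"),
                 "phewascan_bad_arg")
    restr <- defs$sex[defs$phecode == mod$phecode]
    eligible <- if (restr == "none") rep(TRUE, n)
                else persons$sex == (if (restr == "female") "F" else "M")
    eligible[is.na(eligible)] <- FALSE
    pr <- stats::plogis(stats::qlogis(mod$baseline_prevalence) +
                          mod$direct_log_or * dosage_f +
                          mod$bmi_log_or * (latent_bmi - config$bmi_mean))
    is_case <- eligible & stats::rbinom(n, 1, pr) == 1
    case_idx <- which(is_case)
    if (length(case_idx) > 0) {
      k <- sample(2:5, length(case_idx), replace = TRUE)
      day_off <- unlist(lapply(k, function(kk)
        sample.int(window_days, kk) - 1L), use.names = FALSE)
      ev_list[[length(ev_list) + 1]] <- tibble::tibble(
        person_id = rep(persons$person_id[case_idx], times = k),
        date = config$event_window[1] + day_off,
        icd9 = sample(codes, sum(k), replace = TRUE)
      )
    }
    single <- which(eligible & !is_case &
                      stats::runif(n) < config$single_mention_rate)
    if (length(single) > 0) {
      ev_list[[length(ev_list) + 1]] <- tibble::tibble(
        person_id = persons$person_id[single],
        date = config$event_window[1] +
          (sample.int(window_days, length(single), replace = TRUE) - 1L),
        icd9 = sample(codes, length(single), replace = TRUE)
      )
    }
    truth[[r]] <- tibble::tibble(
      phecode = mod$phecode,
      direct_log_or = mod$direct_log_or,
      bmi_log_or = mod$bmi_log_or,
      baseline_prevalence = mod$baseline_prevalence,
      sex_restriction = restr,
      n_true_cases = length(case_idx),
      n_single_mentions = length(single)
    )
  }
  list(events = purrr::list_rbind(ev_list), truth = purrr::list_rbind(truth))
}

#' Generate a complete two-cohort synthetic study
#'
#' Deterministic given the configuration seed: demographics, genotypes
#' (with QC bait), BMI measurement streams, ICD-9 events realizing the
#' planted mediated/direct architecture, planted related pairs in the IBD
#' tables, and a machine-readable truth table sufficient to score recovery.
#'
#' @param config A [sim_config()].
#' @return A `phewas_study`: list with `cohorts` (each holding
#'   `demographics`, `events`, `bmi`, `genotypes`, `ibd`, `latent_bmi`),
#'   `map`, `truth`, and `config`.
#' @export
generate_study <- function(config = sim_config()) {
  map <- dplyr::bind_rows(tibble::as_tibble(phecode_map_synthetic()),
                          null_phecode_entries(config$n_null_phenotypes))
  map <- as_phecode_map(map)
  nulls <- null_phecode_entries(config$n_null_phenotypes)
  models <- config$phenotype_models
  if (!is.null(nulls)) {
    models <- dplyr::bind_rows(models, tibble::tibble(
      phecode = unique(nulls$phecode), direct_log_or = 0, bmi_log_or = 0,
      baseline_prevalence = config$null_prevalence
    ))
  }
  cohorts <- list()
  truth_snps <- list()
  truth_phe <- list()
  for (ci in seq_along(config$n_per_cohort)) {
    cname <- names(config$n_per_cohort)[ci]
    n <- config$n_per_cohort[[ci]]
    ids <- sprintf("%s_%06d", cname, seq_len(n))
    ckey <- if (ci == 1) "cohort1" else "cohort2"
    panel <- config$snps[config$snps$cohorts %in% c("both", ckey), ]

    demo <- with_local_seed(substream_seed(config$seed, paste0(cname, ":demo")), {
      n_site <- if (cname %in% names(config$n_sites)) config$n_sites[[cname]]
                else config$n_sites[[min(ci, length(config$n_sites))]]
      tibble::tibble(
        person_id = ids,
        age = stats::runif(n, config$age_range[1], config$age_range[2]),
        sex = ifelse(stats::runif(n) < config$female_frac, "F", "M"),
        site = paste0(cname, "_site", sample.int(n_site, n, replace = TRUE)),
        pc1 = stats::rnorm(n, 0, 0.1),
        pc2 = stats::rnorm(n, 0, 0.1),
        pc3 = stats::rnorm(n, 0, 0.1)
      )
    })
    gs <- with_local_seed(substream_seed(config$seed, paste0(cname, ":geno")),
                          generate_genotypes(n, panel, config$index_snp, ids))
    dosage <- gs$dosages[, config$index_snp]
    bmi <- with_local_seed(substream_seed(config$seed, paste0(cname, ":bmi")),
                           generate_bmi(dosage, config, ids))
    phen <- with_local_seed(substream_seed(config$seed, paste0(cname, ":phen")),
      generate_phenotypes_and_events(demo[, c("person_id", "sex")], dosage,
                                     bmi$latent, models, map, config))
    ibd <- with_local_seed(substream_seed(config$seed, paste0(cname, ":ibd")), {
      n_rel <- floor(config$related_pair_frac * n)
      if (n_rel > 0) {
        picks <- sample(ids, 2 * n_rel)
        tibble::tibble(
          id_a = picks[seq_len(n_rel)],
          id_b = picks[n_rel + seq_len(n_rel)],
          pi_hat = stats::runif(n_rel, 0.45, 0.55)
        )
      } else {
        tibble::tibble(id_a = character(), id_b = character(),
                       pi_hat = numeric())
      }
    })
    st <- snp_stats(gs)
    truth_snps[[cname]] <- dplyr::mutate(
      st[, c("snp_id", "maf", "call_rate")],
      cohort = cname,
      r2_index = vapply(st$snp_id, function(s) {
        if (s == config$index_snp) 1
        else ld_r2(gs$dosages[, s], dosage)
      }, numeric(1))
    )
    truth_phe[[cname]] <- dplyr::mutate(phen$truth, cohort = cname)
    cohorts[[cname]] <- list(demographics = demo, events = phen$events,
                             bmi = bmi$measurements, genotypes = gs,
                             ibd = ibd, latent_bmi = bmi$latent)
  }
  structure(
    list(cohorts = cohorts, map = map,
         truth = list(snps = purrr::list_rbind(truth_snps),
                      phenotypes = purrr::list_rbind(truth_phe),
                      bmi_beta_per_allele = config$bmi_beta_per_allele,
                      index_snp = config$index_snp),
         config = config),
    class = "phewas_study"
  )
}

#' @export
print.phewas_study <- function(x, ...) {
  cat("<phewas_study> cohorts:",
      paste0(names(x$cohorts), " (n = ",
             vapply(x$cohorts, function(co) nrow(co$demographics), numeric(1)),
             ")", collapse = ", "),
      "\n  ", dplyr::n_distinct(tibble::as_tibble(x$map)$phecode),
      " phenotypes in map; index SNP ", x$truth$index_snp, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the same plain-text dialects the pipeline reads: per-cohort
#' `events.csv`, `demographics.csv`, `bmi.csv`, `genotypes.tsv`, `ibd.tsv`,
#' plus `phecode_map.csv` and `truth.json`.
#'
#' @param study A `phewas_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cname in names(study$cohorts)) {
    co <- study$cohorts[[cname]]
    cdir <- file.path(dir, cname)
    dir.create(cdir, showWarnings = FALSE)
    readr::write_csv(co$events, file.path(cdir, "events.csv"))
    readr::write_csv(co$demographics, file.path(cdir, "demographics.csv"))
    readr::write_csv(co$bmi, file.path(cdir, "bmi.csv"))
    readr::write_tsv(co$ibd, file.path(cdir, "ibd.tsv"))
    write_dosage_tsv(co$genotypes, file.path(cdir, "genotypes.tsv"))
  }
  readr::write_csv(tibble::as_tibble(study$map),
                   file.path(dir, "phecode_map.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
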