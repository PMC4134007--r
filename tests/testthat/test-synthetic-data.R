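small_config <- function(n = c(a = 1000L), seed = 101L, ...) {
  sim_config(n_per_cohort = n, seed = seed, ...)
}

test_that("the generator is deterministic given the seed", {
  cfg <- small_config(n = c(a = 400L, b = 300L), n_null_phenotypes = 3L)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$cohorts$a$events, s2$cohorts$a$events)
  expect_identical(s1$cohorts$b$genotypes$dosages,
                   s2$cohorts$b$genotypes$dosages)
  expect_identical(s1$cohorts$a$bmi, s2$cohorts$a$bmi)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(small_config(n = c(a = 400L, b = 300L), seed = 999L,
                                    n_null_phenotypes = 3L))
  expect_false(identical(s1$cohorts$a$events, s3$cohorts$a$events))
})

test_that("satellite SNPs realize their target LD with the index", {
  set.seed(55)
  panel <- tibble::tibble(
    snp_id = c("idx", "perfect", "target", "indep"),
    effect_allele = "A", other_allele = "C",
    maf = c(0.41, 0.41, 0.41, 0.41),
    target_r2 = c(1, 1, 0.64, 0),
    info = NA_real_, missing_rate = 0, cohorts = "both"
  )
  gs <- generate_genotypes(20000, panel, "idx")
  d <- gs$dosages
  expect_identical(d[, "perfect"], d[, "idx"])
  r2 <- ld_r2(d[, "target"], d[, "idx"])
  expect_gt(r2, 0.58); expect_lt(r2, 0.70)
  gs2 <- generate_genotypes(10000, panel, "idx")
  expect_lt(ld_r2(gs2$dosages[, "indep"], gs2$dosages[, "idx"]), 0.01)
  # realized MAF close to target at large n (3 binomial MC SDs)
  maf_tol <- 3 * sqrt(0.41 * 0.59 / (2 * 20000))
  expect_lt(abs(minor_allele_freq(d[, "idx"]) - 0.41), maf_tol)
})

test_that("BMI generation plants the per-allele effect and the outliers", {
  cfg <- small_config()
  set.seed(77)
  n <- 10000
  dosage <- rbinom(n, 2, 0.41)
  ids <- sprintf("i%05d", 1:n)
  bmi <- generate_bmi(dosage, cfg, ids)
  cl <- clean_bmi(bmi$measurements)
  cl <- cl[match(ids, cl$person_id), ]
  res <- snp_bmi_assoc(dosage, cl$avg_bmi, flat_covariates(n))
  expect_lt(abs(res$beta - 0.535), 2 * res$se)
  # zero genetic effect: cohort mean within 3 SE of the configured mean
  cfg0 <- small_config(bmi_beta_per_allele = 0)
  bmi0 <- generate_bmi(dosage, cfg0, ids)
  se_mean <- cfg0$bmi_sd / sqrt(n)
  expect_lt(abs(mean(bmi0$latent) - cfg0$bmi_mean), 3 * se_mean)
  # no outliers configured: cleaning drops nothing
  cfg_clean <- small_config(bmi_outlier_rate = 0)
  bmi_c <- generate_bmi(dosage[1:500], cfg_clean, ids[1:500])
  expect_true(all(bmi_c$measurements$bmi >= 15 &
                    bmi_c$measurements$bmi <= 70))
  expect_equal(sum(clean_bmi(bmi_c$measurements)$n_dropped), 0)
})

test_that("event emission exercises the single-mention exclusion rule", {
  cfg <- small_config(n = c(a = 2000L), single_mention_rate = 0.2,
                      n_null_phenotypes = 2L)
  st <- generate_study(cfg)
  pm <- suppressMessages(build_phenotype_matrix(
    st$cohorts$a$events, st$cohorts$a$demographics, st$map, min_cases = 1))
  # null phenotypes exclude only their single mentions; with the rule
  # active there must be some excluded individuals
  null_phe <- st$truth$phenotypes$phecode[
    st$truth$phenotypes$direct_log_or == 0 &
      st$truth$phenotypes$bmi_log_or == 0 &
      st$truth$phenotypes$phecode >= 900]
  counts <- pm$phenotypes[pm$phenotypes$phecode %in% null_phe, ]
  expect_true(all(counts$n_excluded > 0))
  # and with the rate at zero, synthetic nulls have no exclusions at all
  cfg0 <- small_config(n = c(a = 800L), single_mention_rate = 0,
                       n_null_phenotypes = 2L)
  st0 <- generate_study(cfg0)
  pm0 <- suppressMessages(build_phenotype_matrix(
    st0$cohorts$a$events, st0$cohorts$a$demographics, st0$map, min_cases = 1))
  counts0 <- pm0$phenotypes[pm0$phenotypes$phecode >= 900, ]
  expect_true(all(counts0$n_excluded == 0))
})

test_that("case counts in the matrix match the generator's truth table", {
  cfg <- small_config(n = c(a = 1500L), n_null_phenotypes = 2L)
  st <- generate_study(cfg)
  pm <- suppressMessages(build_phenotype_matrix(
    st$cohorts$a$events, st$cohorts$a$demographics, st$map, min_cases = 20))
  truth <- st$truth$phenotypes
  for (i in seq_len(nrow(pm$phenotypes))) {
    phe <- pm$phenotypes$phecode[i]
    expect_equal(pm$phenotypes$n_cases[i],
                 truth$n_true_cases[truth$phecode == phe])
  }
  # retained set is exactly the phenotypes whose planted case count >= 20
  expect_setequal(pm$phenotypes$phecode,
                  truth$phecode[truth$n_true_cases >= 20])
})

test_that("planted related pairs and sex restriction are realized", {
  cfg <- small_config(n = c(a = 1000L), related_pair_frac = 0.01,
                      n_null_phenotypes = 0L)
  st <- generate_study(cfg)
  ibd <- st$cohorts$a$ibd
  expect_gt(nrow(ibd), 0)
  expect_true(all(ibd$pi_hat > 0.25))
  kept <- suppressMessages(prune_related(st$cohorts$a$demographics$person_id,
                                         ibd, seed = 3))
  expect_equal(length(kept), 1000 - nrow(ibd))
  # female-only phenotype: no male cases
  ev <- st$cohorts$a$events
  demo <- st$cohorts$a$demographics
  pm <- suppressMessages(build_phenotype_matrix(ev, demo, st$map,
                                                min_cases = 1))
  if ("610.1" %in% colnames(pm$status)) {
    cases <- pm$individuals[pm$status[, "610.1"] == "case"]
    expect_true(all(demo$sex[match(cases, demo$person_id)] == "F"))
    males <- demo$person_id[demo$sex == "M"]
    expect_true(all(pm$status[match(males, pm$individuals), "610.1"] !=
                      "control"))
  }
})

test_that("a study round-trips through the plain-text writers", {
  cfg <- small_config(n = c(a = 200L), n_null_phenotypes = 1L)
  st <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  ev <- read_events(file.path(dir, "a", "events.csv"))
  expect_equal(nrow(ev), nrow(st$cohorts$a$events))
  gs <- read_dosage_tsv(file.path(dir, "a", "genotypes.tsv"))
  expect_equal(gs$dosages, st$cohorts$a$genotypes$dosages)
  map2 <- read_phecode_map(file.path(dir, "phecode_map.csv"))
  expect_equal(nrow(map2), nrow(st$map))
  bmi <- read_bmi(file.path(dir, "a", "bmi.csv"))
  expect_equal(nrow(bmi), nrow(st$cohorts$a$bmi))
  ibd <- read_ibd(file.path(dir, "a", "ibd.tsv"))
  expect_equal(nrow(ibd), nrow(st$cohorts$a$ibd))
})

test_that("VCF genotypes load with GT additive coding", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1\tp2\tp3",
    "16\t53816275\trs_test\tC\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "16\t53820527\t.\tT\tG\t.\tPASS\t.\tGT\t0/0\t./.\t0/1"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gs <- read_genotypes_vcf(path)
  expect_equal(gs$individuals, c("p1", "p2", "p3"))
  expect_equal(unname(gs$dosages[, "rs_test"]), c(1, 2, 0))
  expect_equal(gs$snps$effect_allele[1], "A")
  expect_true(is.na(gs$dosages[2, 2]))
})
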