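# Small in-code fixtures shared across test files.

# A three-group map: weight phenotypes sharing one exclusion range, an
# unrelated phenotype, and a female-only phenotype.
tiny_map <- function() {
  as_phecode_map(tibble::tribble(
    ~icd9,    ~phecode, ~description,      ~category, ~exclusion_lo, ~exclusion_hi, ~sex,
    "278.00", 278.1,    "Obesity",         "metab",   278,           278.99,        "none",
    "278.02", 278.0,    "Overweight",      "metab",   278,           278.99,        "none",
    "401.10", 401.1,    "Hypertension",    "circ",    401,           405.99,        "none",
    "610.10", 610.1,    "Cystic breast",   "gu",      610,           611.99,        "female"
  ))
}

events_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    person_id = vapply(rows, `[[`, "", 1),
    date = as.Date(vapply(rows, `[[`, "", 2)),
    icd9 = vapply(rows, `[[`, "", 3)
  )
}

demo_tbl <- function(ids, sex = rep("F", length(ids))) {
  tibble::tibble(person_id = ids, sex = sex)
}

# Covariates with no real structure, for fits where only the dosage matters.
flat_covariates <- function(n, sex = rep(c("F", "M"), length.out = n),
                            avg_bmi = NULL) {
  cv <- tibble::tibble(
    age = seq(40, 80, length.out = n),
    sex = sex,
    site = "s1",
    pc1 = 0, pc2 = 0, pc3 = 0
  )
  if (!is.null(avg_bmi)) cv$avg_bmi <- avg_bmi
  cv
}

# Closed-form odds ratio of a 2x2 table given exposure counts.
or_2x2 <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  (case_exp * ctrl_unexp) / (case_unexp * ctrl_exp)
}

# Build y/x vectors from 2x2 counts.
vectors_2x2 <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  list(
    y = rep(c(1, 1, 0, 0), c(case_exp, case_unexp, ctrl_exp, ctrl_unexp)),
    x = rep(c(1, 0, 1, 0), c(case_exp, case_unexp, ctrl_exp, ctrl_unexp))
  )
}
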