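test_that("normalize_icd9 canonicalizes and is idempotent", {
  expect_equal(normalize_icd9("25000"), "250.00")
  expect_equal(normalize_icd9("250.00"), "250.00")
  expect_equal(normalize_icd9(" v70 "), "V70")
  expect_equal(normalize_icd9("v7012"), "V70.12")
  expect_equal(normalize_icd9("E8801"), "E880.1")
  x <- c("25000", "E8801", "v7012", "038.0")
  expect_equal(normalize_icd9(normalize_icd9(x)), normalize_icd9(x))
  expect_error(normalize_icd9("banana"), "malformed.*banana")
  expect_error(normalize_icd9(""), class = "phewascan_bad_icd9")
})

test_that("phecode map validation enforces its invariants", {
  expect_s3_class(tiny_map(), "phecode_map")
  bad_interval <- tibble::tibble(icd9 = "250.00", phecode = 250.2,
                                 description = "x", category = "c",
                                 exclusion_lo = 251, exclusion_hi = 252,
                                 sex = "none")
  expect_error(as_phecode_map(bad_interval), class = "phewascan_bad_map")
  inconsistent <- dplyr::bind_rows(
    tibble::tibble(icd9 = "250.00", phecode = 250.2, description = "a",
                   category = "c", exclusion_lo = 249, exclusion_hi = 251,
                   sex = "none"),
    tibble::tibble(icd9 = "250.02", phecode = 250.2, description = "a",
                   category = "c", exclusion_lo = 248, exclusion_hi = 251,
                   sex = "none")
  )
  expect_error(as_phecode_map(inconsistent), class = "phewascan_bad_map")
})

test_that("bundled synthetic map loads and is internally consistent", {
  map <- phecode_map_synthetic()
  defs <- phecode_definitions(map)
  expect_gt(nrow(map), 25)
  expect_true(all(defs$exclusion_lo <= defs$phecode &
                    defs$phecode <= defs$exclusion_hi))
  expect_true(all(defs$sex %in% c("none", "female", "male")))
})

test_that("two codes on different days make a case; one day does not", {
  map <- tiny_map()
  two_days <- events_tbl(list("p1", "2010-01-01", "278.00"),
                         list("p1", "2010-02-01", "278.00"))
  expect_equal(assign_status(two_days, 278.1, map, sex = "F"), "case")
  same_day <- events_tbl(list("p1", "2010-01-01", "278.00"),
                         list("p1", "2010-01-01", "278.00"))
  expect_equal(assign_status(same_day, 278.1, map, sex = "F"), "excluded")
  # two different codes of the same phecode group on different days also
  # count: the distinct-date rule applies at the phecode level
  mixed <- events_tbl(list("p1", "2010-01-01", "278.00"),
                      list("p1", "2010-03-01", "27800"))
  expect_equal(assign_status(mixed, 278.1, map, sex = "F"), "case")
})

test_that("exclusion interval and sex restriction keep people out of controls", {
  map <- tiny_map()
  # single mention of a related (not target) phenotype: excluded from controls
  overweight_once <- events_tbl(list("p1", "2010-01-01", "278.02"))
  expect_equal(assign_status(overweight_once, 278.1, map, sex = "F"),
               "excluded")
  # unrelated codes leave the person a control
  unrelated <- events_tbl(list("p1", "2010-01-01", "401.10"))
  expect_equal(assign_status(unrelated, 278.1, map, sex = "F"), "control")
  expect_equal(assign_status(events_tbl()[0, ], 278.1, map, sex = "F"),
               "control")
  # sex restriction: males and unknown-sex people cannot be controls for a
  # female-only phenotype
  expect_equal(assign_status(unrelated, 610.1, map, sex = "M"), "excluded")
  expect_equal(assign_status(unrelated, 610.1, map, sex = NA), "excluded")
  expect_equal(assign_status(unrelated, 610.1, map, sex = "F"), "control")
  expect_error(assign_status(unrelated, 999.9, map, sex = "F"),
               class = "phewascan_unknown_phecode")
})

test_that("build_phenotype_matrix applies the min-case filter and logs drops", {
  map <- tiny_map()
  n_a <- 25; n_b <- 10
  ev <- dplyr::bind_rows(
    tibble::tibble(person_id = sprintf("a%02d", seq_len(n_a)),
                   date = as.Date("2010-01-01"), icd9 = "278.00"),
    tibble::tibble(person_id = sprintf("a%02d", seq_len(n_a)),
                   date = as.Date("2010-02-01"), icd9 = "278.00"),
    tibble::tibble(person_id = sprintf("b%02d", seq_len(n_b)),
                   date = as.Date("2010-01-01"), icd9 = "401.10"),
    tibble::tibble(person_id = sprintf("b%02d", seq_len(n_b)),
                   date = as.Date("2010-02-01"), icd9 = "401.10")
  )
  demo <- demo_tbl(c(sprintf("a%02d", 1:25), sprintf("b%02d", 1:10),
                     sprintf("c%02d", 1:5)))
  pm <- suppressMessages(build_phenotype_matrix(ev, demo, map, min_cases = 20))
  expect_equal(pm$phenotypes$phecode, 278.1)
  expect_equal(pm$phenotypes$n_cases, 25)
  expect_true(401.1 %in% pm$dropped$phecode)
  expect_message(build_phenotype_matrix(ev, demo, map, min_cases = 20),
                 class = "phewascan_log")
  # min_cases = 1 retains every phenotype with at least one case
  pm1 <- suppressMessages(build_phenotype_matrix(ev, demo, map, min_cases = 1))
  expect_setequal(pm1$phenotypes$phecode, c(278.1, 401.1))
  # empty event table: matrix with zero retained phenotypes, not an error
  pm0 <- suppressMessages(build_phenotype_matrix(ev[0, ], demo, map))
  expect_equal(nrow(pm0$phenotypes), 0)
})

test_that("status is invariant to event order and same-day duplicates", {
  map <- tiny_map()
  ev <- dplyr::bind_rows(
    tibble::tibble(person_id = "p1", date = as.Date("2010-01-01"), icd9 = "278.00"),
    tibble::tibble(person_id = "p1", date = as.Date("2010-02-01"), icd9 = "278.02"),
    tibble::tibble(person_id = "p2", date = as.Date("2010-01-01"), icd9 = "278.00"),
    tibble::tibble(person_id = "p2", date = as.Date("2010-03-05"), icd9 = "278.00")
  )
  demo <- demo_tbl(c("p1", "p2"))
  base <- suppressMessages(build_phenotype_matrix(ev, demo, map, min_cases = 1))
  shuffled <- ev[c(4, 2, 1, 3), ]
  duplicated <- dplyr::bind_rows(ev, ev)
  for (variant in list(shuffled, duplicated)) {
    pm <- suppressMessages(build_phenotype_matrix(variant, demo, map,
                                                  min_cases = 1))
    expect_identical(pm$status, base$status)
  }
})

test_that("controls never carry a code inside the exclusion interval", {
  set.seed(11)
  map <- tiny_map()
  codes <- c("278.00", "278.02", "401.10", "610.10")
  ev <- tibble::tibble(
    person_id = sample(sprintf("p%02d", 1:40), 300, replace = TRUE),
    date = as.Date("2010-01-01") + sample.int(400, 300, replace = TRUE),
    icd9 = sample(codes, 300, replace = TRUE)
  )
  demo <- demo_tbl(sprintf("p%02d", 1:40),
                   sex = sample(c("F", "M"), 40, replace = TRUE))
  pm <- suppressMessages(build_phenotype_matrix(ev, demo, map, min_cases = 1))
  hits <- dplyr::inner_join(ev, tibble::as_tibble(map)[, c("icd9", "phecode")],
                            by = "icd9")
  for (i in seq_len(nrow(pm$phenotypes))) {
    d <- pm$phenotypes[i, ]
    ctrls <- pm$individuals[pm$status[, i] == "control"]
    carriers <- unique(hits$person_id[hits$phecode >= d$exclusion_lo &
                                        hits$phecode <= d$exclusion_hi])
    expect_length(intersect(ctrls, carriers), 0)
  }
})

test_that("composite phenotypes follow any-case / all-control logic", {
  map <- tiny_map()
  ev <- dplyr::bind_rows(
    # p1: case of obesity, control of hypertension
    tibble::tibble(person_id = "p1", date = as.Date(c("2010-01-01", "2010-02-01")),
                   icd9 = "278.00"),
    # p2: single mention of overweight -> excluded for obesity, control of htn
    tibble::tibble(person_id = "p2", date = as.Date("2010-01-01"),
                   icd9 = "278.02"),
    # p4: hypertension case so the 401.1 column is retained
    tibble::tibble(person_id = "p4", date = as.Date(c("2010-01-01", "2010-02-01")),
                   icd9 = "401.10")
  )
  demo <- demo_tbl(c("p1", "p2", "p3", "p4"))
  pm <- suppressMessages(build_phenotype_matrix(ev, demo, map, min_cases = 1))
  comp <- make_composite(pm, c(278.1, 401.1))
  expect_equal(comp$status[comp$person_id == "p1"], "case")
  expect_equal(comp$status[comp$person_id == "p2"], "excluded")
  expect_equal(comp$status[comp$person_id == "p3"], "control")
  # composite of a single phenotype is that phenotype
  expect_equal(make_composite(pm, 278.1)$status,
               unname(phenotype_status(pm, 278.1)))
  expect_error(make_composite(pm, numeric()), class = "phewascan_bad_arg")
  pm2 <- add_composite(pm, c(278.1, 401.1), 900.9, "combined")
  expect_true(900.9 %in% pm2$phenotypes$phecode)
  expect_equal(unname(phenotype_status(pm2, 900.9)), comp$status)
})

test_that("tidy and glance summarize the phenotype matrix", {
  map <- tiny_map()
  ev <- events_tbl(list("p1", "2010-01-01", "278.00"),
                   list("p1", "2010-02-01", "278.00"))
  pm <- suppressMessages(build_phenotype_matrix(ev, demo_tbl(c("p1", "p2")),
                                                map, min_cases = 1))
  long <- tidy(pm)
  expect_equal(nrow(long), 2 * nrow(pm$phenotypes))
  expect_setequal(unique(long$status), c("case", "control", "excluded")[
    c("case", "control", "excluded") %in% long$status])
  g <- glance(pm)
  expect_equal(g$n_individuals, 2)
})
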