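#' Case/control/excluded status for one person and one phecode
#'
#' Applies the PheWAS case rule to a single person's billing events:
#' \itemize{
#'   \item \strong{case} — ICD-9 codes mapping to the phecode occur on at
#'     least two distinct calendar days;
#'   \item \strong{excluded} — not a case, and either some code maps into the
#'     phecode's exclusion interval (a single mention of the phecode itself
#'     always does, since a phecode lies in its own interval), or the map's
#'     sex restriction conflicts with the person's sex;
#'   \item \strong{control} — otherwise.
#' }
#' An unknown sex conflicts with any sex restriction: eligibility cannot be
#' verified, so the person is kept out of the control group.
#'
#' @param events Data frame of one person's events with columns `date`
#'   and `icd9`.
#' @param phecode Target phecode (present in `map`).
#' @param map A [phecode_map][read_phecode_map].
#' @param sex `"F"`, `"M"`, or `NA` (unknown).
#' @return One of `"case"`, `"control"`, `"excluded"`.
#' @export
assign_status <- function(events, phecode, map, sex = NA_character_) {
  defs <- phecode_definitions(map)
  def <- defs[defs$phecode == phecode, ]
  if (nrow(def) == 0)
    stop_input(paste0("phecode ", phecode, " is not in the map"),
               "phewascan_unknown_phecode")
  if (nrow(events) == 0) {
    hit_codes <- tibble::tibble(phecode = numeric(), date = as.Date(character()))
  } else {
    ev <- tibble::tibble(icd9 = normalize_icd9(events$icd9),
                         date = as.Date(events$date))
    hit_codes <- dplyr::inner_join(ev, tibble::as_tibble(map)[, c("icd9", "phecode")],
                                   by = "icd9", relationship = "many-to-many")
  }
  n_days <- length(unique(hit_codes$date[hit_codes$phecode == phecode]))
  if (n_days >= 2) return("case")
  in_excl <- any(hit_codes$phecode >= def$exclusion_lo &
                 hit_codes$phecode <= def$exclusion_hi)
  sex_conflict <- def$sex != "none" &&
    (is.na(sex) || (def$sex == "female" && sex != "F") ||
       (def$sex == "male" && sex != "M"))
  if (in_excl || sex_conflict) "excluded" else "control"
}

#' Build the person-by-phenotype status matrix
#'
#' Applies the case rule of [assign_status()] to every person in the
#' demographics table and every phecode in the map, then drops phenotypes
#' with fewer than `min_cases` cases. People with no billing events are
#' controls everywhere (subject to sex restrictions).
#'
#' @param events Tibble of all events: `person_id`, `date`, `icd9`.
#' @param demographics Tibble with `person_id` and `sex` (`"F"`/`"M"`/`NA`);
#'   its `person_id` column defines the cohort and the row order.
#' @param map A [phecode_map][read_phecode_map].
#' @param min_cases Minimum case count for a phenotype to be retained
#'   (default 20).
#' @return A `phenotype_matrix` object: a list with `individuals`,
#'   `phenotypes` (phecode, description, category, counts), `status` (a
#'   person-by-phecode character matrix), and `dropped` (phenotypes below
#'   the case threshold, with their counts).
#' @export
build_phenotype_matrix <- function(events, demographics, map, min_cases = 20L) {
  if (min_cases < 1)
    stop_input("min_cases must be >= 1", "phewascan_bad_arg")
  persons <- as.character(demographics$person_id)
  if (anyDuplicated(persons))
    stop_input("duplicate person_id in demographics", "phewascan_bad_arg")
  sex <- if ("sex" %in% names(demographics)) as.character(demographics$sex)
         else rep(NA_character_, length(persons))
  defs <- phecode_definitions(map)

  if (nrow(events) > 0) {
    ev <- tibble::tibble(person_id = as.character(events$person_id),
                         icd9 = normalize_icd9(events$icd9),
                         date = as.Date(events$date))
    ev <- ev[ev$person_id %in% persons, ]
    hits <- dplyr::inner_join(ev, tibble::as_tibble(map)[, c("icd9", "phecode")],
                              by = "icd9", relationship = "many-to-many")
    # distinct billing days per person x phecode (same-day duplicates collapse)
    days <- dplyr::summarise(
      dplyr::group_by(dplyr::distinct(hits, .data$person_id, .data$phecode,
                                      .data$date),
                      .data$person_id, .data$phecode),
      n_days = dplyr::n(), .groups = "drop"
    )
  } else {
    days <- tibble::tibble(person_id = character(), phecode = numeric(),
                           n_days = integer())
  }

  status <- matrix("control", nrow = length(persons), ncol = nrow(defs),
                   dimnames = list(persons, format_phecode(defs$phecode)))
  pid_index <- stats::setNames(seq_along(persons), persons)

  for (j in seq_len(nrow(defs))) {
    d <- defs[j, ]
    case_ids <- days$person_id[days$phecode == d$phecode & days$n_days >= 2]
    carried <- unique(days$person_id[days$phecode >= d$exclusion_lo &
                                     days$phecode <= d$exclusion_hi])
    excl_ids <- setdiff(carried, case_ids)
    if (d$sex != "none") {
      want <- if (d$sex == "female") "F" else "M"
      mismatch <- persons[is.na(sex) | sex != want]
      excl_ids <- union(excl_ids, setdiff(mismatch, case_ids))
    }
    status[pid_index[excl_ids], j] <- "excluded"
    status[pid_index[case_ids], j] <- "case"
  }

  counts <- tibble::tibble(
    phecode = defs$phecode,
    description = defs$description,
    category = defs$category,
    sex = defs$sex,
    exclusion_lo = defs$exclusion_lo,
    exclusion_hi = defs$exclusion_hi,
    n_cases = unname(colSums(status == "case")),
    n_controls = unname(colSums(status == "control")),
    n_excluded = unname(colSums(status == "excluded"))
  )
  keep <- counts$n_cases >= min_cases
  dropped <- counts[!keep, c("phecode", "description", "n_cases")]
  if (nrow(dropped) > 0)
    rlang::inform(paste0(
      nrow(dropped), " phenotype(s) below min_cases = ", min_cases,
      " dropped: ", paste(format_phecode(dropped$phecode), collapse = ", ")
    ), class = "phewascan_log")

  structure(
    list(individuals = persons,
         phenotypes = counts[keep, ],
         status = status[, keep, drop = FALSE],
         dropped = dropped,
         min_cases = as.integer(min_cases)),
    class = "phenotype_matrix"
  )
}

format_phecode <- function(x) formatC(x, format = "g", digits = 10)

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("<phenotype_matrix> ", length(x$individuals), " individuals x ",
      nrow(x$phenotypes), " phenotypes (min_cases = ", x$min_cases, ")\n",
      sep = "")
  print(x$phenotypes[, c("phecode", "description", "n_cases",
                         "n_controls", "n_excluded")], ...)
  invisible(x)
}

#' Status vector for one phenotype
#'
#' @param pmat A `phenotype_matrix`.
#' @param phecode A retained phecode.
#' @return Named character vector over individuals.
#' @export
phenotype_status <- function(pmat, phecode) {
  key <- format_phecode(phecode)
  if (!key %in% colnames(pmat$status))
    stop_input(paste0("phecode ", key, " is not a retained phenotype"),
               "phewascan_unknown_phecode")
  pmat$status[, key]
}

#' Composite phenotype from several phecodes
#'
#' A person is a case of the composite if a case of any member, a control if
#' a control for all members, and excluded otherwise. The composite of a
#' single phenotype is that phenotype.
#'
#' @param pmat A `phenotype_matrix`.
#' @param phecodes Non-empty vector of retained phecodes.
#' @return Tibble `person_id`, `status`.
#' @export
make_composite <- function(pmat, phecodes) {
  if (length(phecodes) == 0)
    stop_input("composite needs at least one phecode", "phewascan_bad_arg")
  cols <- vapply(phecodes, function(p) phenotype_status(pmat, p),
                 character(length(pmat$individuals)))
  any_case <- rowSums(cols == "case") > 0
  all_ctrl <- rowSums(cols == "control") == length(phecodes)
  status <- ifelse(any_case, "case", ifelse(all_ctrl, "control", "excluded"))
  tibble::tibble(person_id = pmat$individuals, status = unname(status))
}

#' Append a composite phenotype as a new column of the matrix
#'
#' @inheritParams make_composite
#' @param phecode Numeric code for the new composite column.
#' @param description,category Metadata for the new column.
#' @return The extended `phenotype_matrix`.
#' @export
add_composite <- function(pmat, phecodes, phecode, description,
                          category = "composite") {
  comp <- make_composite(pmat, phecodes)
  key <- format_phecode(phecode)
  pmat$status <- cbind(pmat$status, stats::setNames(list(comp$status), key)[[1]])
  colnames(pmat$status)[ncol(pmat$status)] <- key
  pmat$phenotypes <- dplyr::bind_rows(pmat$phenotypes, tibble::tibble(
    phecode = phecode, description = description, category = category,
    sex = "none", exclusion_lo = phecode, exclusion_hi = phecode,
    n_cases = sum(comp$status == "case"),
    n_controls = sum(comp$status == "control"),
    n_excluded = sum(comp$status == "excluded")
  ))
  pmat
}

#' Tidy a phenotype matrix into long form
#'
#' @param x A `phenotype_matrix`.
#' @param ... Unused.
#' @return Tibble `person_id`, `phecode`, `status`.
#' @export
tidy.phenotype_matrix <- function(x, ...) {
  tibble::tibble(
    person_id = rep(x$individuals, times = ncol(x$status)),
    phecode = rep(x$phenotypes$phecode, each = length(x$individuals)),
    status = as.vector(x$status)
  )
}

#' One-row summary of a phenotype matrix
#'
#' @param x A `phenotype_matrix`.
#' @param ... Unused.
#' @export
glance.phenotype_matrix <- function(x, ...) {
  tibble::tibble(
    n_individuals = length(x$individuals),
    n_phenotypes = nrow(x$phenotypes),
    n_dropped = nrow(x$dropped),
    min_cases = x$min_cases,
    median_cases = stats::median(x$phenotypes$n_cases)
  )
}
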