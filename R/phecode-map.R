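#' Normalize raw ICD-9 code strings
#'
#' Billing extracts write ICD-9 codes inconsistently: with or without the
#' decimal point, with stray whitespace, in either case. `normalize_icd9()`
#' canonicalizes them: uppercase, trimmed, and with the decimal point inserted
#' after the third digit (after the fourth character for E-codes) when it is
#' missing. The function is idempotent.
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of canonical ICD-9 codes (e.g. `"250.00"`,
#'   `"V70"`, `"E880.1"`).
#' @examples
#' normalize_icd9(c("25000", "250.00", " v70 "))
#' @export
normalize_icd9 <- function(raw) {
  if (length(raw) == 0) return(character())
  x <- toupper(trimws(as.character(raw)))
  if (any(is.na(x) | x == ""))
    stop_input("ICD-9 codes must be non-empty strings", "phewascan_bad_icd9")
  no_dot <- !grepl(".", x, fixed = TRUE)
  head_len <- ifelse(startsWith(x, "E"), 4L, 3L)
  need <- no_dot & nchar(x) > head_len
  x[need] <- paste0(
    substr(x[need], 1L, head_len[need]), ".",
    substring(x[need], head_len[need] + 1L)
  )
  ok <- grepl("^([0-9]{3}|V[0-9]{2}|E[0-9]{3})(\\.[0-9]{1,2})?$", x)
  if (any(!ok)) {
    stop_input(
      paste0("malformed ICD-9 code(s): ",
             paste(unique(raw[!ok]), collapse = ", ")),
      "phewascan_bad_icd9"
    )
  }
  x
}

#' Read a phecode map
#'
#' A phecode map assigns ICD-9 codes to phenotype codes (phecodes), each with
#' a description, a phenotype category used for plot ordering, a closed
#' exclusion interval of related phecodes whose carriers may not serve as
#' controls, and an optional sex restriction.
#'
#' @param path CSV file with header
#'   `icd9,phecode,description,category,exclusion_lo,exclusion_hi,sex`.
#'   `sex` is one of `none`, `female`, `male`.
#' @return A tibble of class `phecode_map`.
#' @seealso [phecode_map_synthetic()] for the bundled miniature map.
#' @export
read_phecode_map <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           icd9 = readr::col_character(),
                           phecode = readr::col_double(),
                           description = readr::col_character(),
                           category = readr::col_character(),
                           exclusion_lo = readr::col_double(),
                           exclusion_hi = readr::col_double(),
                           sex = readr::col_character()
                         ))
  as_phecode_map(raw)
}

#' Construct a phecode map from a data frame
#'
#' @param df Data frame with the columns of [read_phecode_map()].
#' @return A `phecode_map` tibble, validated.
#' @export
as_phecode_map <- function(df) {
  need <- c("icd9", "phecode", "description", "category",
            "exclusion_lo", "exclusion_hi", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_input(paste0("phecode map is missing column(s): ",
                      paste(miss, collapse = ", ")), "phewascan_bad_map")
  df <- tibble::as_tibble(df)
  df$icd9 <- normalize_icd9(df$icd9)
  df$sex <- tolower(df$sex)
  if (!all(df$sex %in% c("none", "female", "male")))
    stop_input("map sex restriction must be none/female/male",
               "phewascan_bad_map")
  if (any(df$phecode <= 0))
    stop_input("phecodes must be positive", "phewascan_bad_map")
  bad <- df$exclusion_lo > df$phecode | df$phecode > df$exclusion_hi
  if (any(bad))
    stop_input(paste0("exclusion interval must contain its own phecode: ",
                      paste(unique(df$phecode[bad]), collapse = ", ")),
               "phewascan_bad_map")
  # one exclusion interval, category, description, sex rule per phecode
  per <- dplyr::summarise(
    dplyr::group_by(df, .data$phecode),
    n_def = dplyr::n_distinct(.data$description, .data$category,
                              .data$exclusion_lo, .data$exclusion_hi,
                              .data$sex),
    .groups = "drop"
  )
  if (any(per$n_def > 1))
    stop_input(paste0("inconsistent definitions for phecode(s): ",
                      paste(per$phecode[per$n_def > 1], collapse = ", ")),
               "phewascan_bad_map")
  class(df) <- c("phecode_map", class(df))
  df
}

#' Bundled synthetic miniature phecode map
#'
#' A ~40-entry map, generated for this package (not extracted from any
#' production phecode table), covering the phenotype groups the pipeline's
#' worked examples use: weight phenotypes with a shared exclusion range, type 2
#' diabetes, sleep apnea, fibrocystic breast disease (female-restricted),
#' non-alcoholic liver disease, the gram-positive infection family, and
#' several common phenotypes that carry no planted genetic effect.
#'
#' @return A `phecode_map` tibble.
#' @export
phecode_map_synthetic <- function() {
  read_phecode_map(system.file("extdata", "phecode_map_synthetic.csv",
                               package = "phewascan", mustWork = TRUE))
}

#' Phenotype definitions contained in a map
#'
#' One row per distinct phecode with its description, category, exclusion
#' interval and sex restriction.
#'
#' @param map A `phecode_map`.
#' @return Tibble with one row per phecode.
#' @export
phecode_definitions <- function(map) {
  dplyr::distinct(
    tibble::as_tibble(map),
    .data$phecode, .data$description, .data$category,
    .data$exclusion_lo, .data$exclusion_hi, .data$sex
  ) |>
    dplyr::arrange(.data$phecode)
}

#' Read an ICD-9 billing-event table
#'
#' @param path CSV with header `person_id,date,icd9` and ISO-8601 dates.
#' @return Tibble with columns `person_id` (character), `date` (Date),
#'   `icd9` (canonical ICD-9 string).
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          person_id = readr::col_character(),
                          date = readr::col_date(),
                          icd9 = readr::col_character()
                        ))
  ev$icd9 <- normalize_icd9(ev$icd9)
  ev
}
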