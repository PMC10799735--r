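# Census table input/output and derived demography.
#
# The census dialect is one row per individual with pedigree links
# (mother_id/father_id/partner_id), demography and the four cultural traits:
# three binary language indicators (mandarin, sichuan, naru) and an ordinal
# jeans-wearing frequency on a 1-4 scale.

CENSUS_COLUMNS <- c(
  "person_id", "sex", "ethnicity", "birth_year", "death_year",
  "mother_id", "father_id", "partner_id", "village", "household_id",
  "education_years", "occupation", "income_level", "tourism",
  "mandarin", "sichuan", "naru", "jeans", "surveyed", "intermarriage"
)

.census_integer_cols <- c(
  "birth_year", "death_year", "education_years", "occupation",
  "income_level", "tourism", "mandarin", "sichuan", "naru", "jeans",
  "surveyed", "intermarriage"
)

#' Survey configuration
#'
#' Bundles the survey constants used throughout the pipeline: the census
#' year, the age of adulthood, the birth-year window delimiting the
#' completed-fertility cohort used for reproductive-skew estimation, the age
#' to which offspring must survive to be counted, and the sex-specific
#' reproductive window used when computing reproductive exposure.
#'
#' @param survey_year Calendar year of the census (default 2017).
#' @param adult_age Minimum age in years to count as an adult participant
#'   (default 15).
#' @param skew_cohort Length-2 integer vector `c(min, max)` of birth years
#'   delimiting the cohort entering skew estimation (default
#'   `c(1911, 1950)`, i.e. people who had completed reproduction before
#'   birth-limitation policies took effect).
#' @param survival_age Age in years an offspring must reach to count as
#'   surviving (default 15).
#' @param maturity_age Age at which reproductive exposure starts (default 15).
#' @param terminal_age_f,terminal_age_m Age at which reproductive exposure
#'   ends for females and males (defaults 50 and 60).
#' @param jeans_scheme Default binarization of the ordinal jeans variable,
#'   `"high"` (often/always = 1) or `"ever"` (rarely/often/always = 1).
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(survey_year = 2017L, adult_age = 15L,
                          skew_cohort = c(1911L, 1950L), survival_age = 15L,
                          maturity_age = 15L, terminal_age_f = 50L,
                          terminal_age_m = 60L, jeans_scheme = "high") {
  stopifnot(length(skew_cohort) == 2, skew_cohort[1] <= skew_cohort[2],
            adult_age >= 0, survival_age >= 0, maturity_age >= 0)
  jeans_scheme <- match.arg(jeans_scheme, c("high", "ever"))
  structure(list(
    survey_year = as.integer(survey_year),
    adult_age = as.integer(adult_age),
    skew_cohort = as.integer(skew_cohort),
    survival_age = as.integer(survival_age),
    maturity_age = as.integer(maturity_age),
    terminal_age_f = as.integer(terminal_age_f),
    terminal_age_m = as.integer(terminal_age_m),
    jeans_scheme = jeans_scheme
  ), class = "survey_config")
}

#' Read and validate a census table
#'
#' Reads the CSV census dialect (header exactly [CENSUS_COLUMNS], missing
#' cells as empty strings or `"NA"`) and validates every record: unique
#' person identifiers, parent sexes consistent with their role, children
#' born after their parents, death after birth, trait codes in range, and
#' no dangling pedigree or partner references.
#'
#' @param path Path to a census CSV file.
#' @param config A [survey_config()].
#' @return A validated `census` data frame (one row per individual).
#' @seealso [write_census()], [validate_census()]
#' @export
read_census <- function(path, config = survey_config()) {
  if (!file.exists(path)) stop("census file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(CENSUS_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[CENSUS_COLUMNS]
  for (col in .census_integer_cols) {
    parsed <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("unparseable value in column '%s' at row(s) %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
    }
    raw[[col]] <- parsed
  }
  as_census(raw, config = config)
}

#' Construct a census object from a data frame
#'
#' @param df Data frame with the census columns.
#' @param config A [survey_config()].
#' @param validate Validate invariants (default `TRUE`).
#' @return A `census` data frame.
#' @export
as_census <- function(df, config = survey_config(), validate = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CENSUS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df[CENSUS_COLUMNS], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("census", "data.frame")
  attr(df, "config") <- config
  if (validate) validate_census(df)
  df
}

#' Validate census invariants
#'
#' Checks identifier uniqueness, sex codes, parent-sex consistency,
#' birth-order consistency between parents and children, death after birth,
#' trait domains, and that every mother/father/partner reference resolves.
#' All violations are collected and reported together with row numbers.
#'
#' @param census A `census` data frame.
#' @return Invisibly `TRUE`; stops with an itemized message on violation.
#' @export
validate_census <- function(census) {
  errs <- character(0)
  id <- census$person_id
  if (anyNA(id) || any(id == "")) errs <- c(errs, "missing person_id")
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    errs <- c(errs, paste0("duplicate person_id: ",
                           paste(unique(dup), collapse = ", ")))
  }
  bad_sex <- which(!is.na(census$sex) & !census$sex %in% c("F", "M"))
  if (length(bad_sex) > 0) {
    errs <- c(errs, paste0("invalid sex code at row(s) ",
                           paste(utils::head(bad_sex, 5), collapse = ", ")))
  }
  for (ref in c("mother_id", "father_id", "partner_id")) {
    refs <- census[[ref]]
    dangling <- which(!is.na(refs) & is.na(match(refs, id)))
    if (length(dangling) > 0) {
      errs <- c(errs, sprintf("dangling %s at row(s) %s", ref,
                              paste(utils::head(dangling, 5), collapse = ", ")))
    }
  }
  mi <- match(census$mother_id, id)
  fi <- match(census$father_id, id)
  bad_mom <- which(!is.na(mi) & !is.na(census$sex[mi]) & census$sex[mi] != "F")
  if (length(bad_mom) > 0) {
    errs <- c(errs, sprintf(
      "mother of '%s' (row %d) is '%s', who is not F",
      id[bad_mom[1]], bad_mom[1], census$mother_id[bad_mom[1]]))
  }
  bad_dad <- which(!is.na(fi) & !is.na(census$sex[fi]) & census$sex[fi] != "M")
  if (length(bad_dad) > 0) {
    errs <- c(errs, sprintf(
      "father of '%s' (row %d) is '%s', who is not M",
      id[bad_dad[1]], bad_dad[1], census$father_id[bad_dad[1]]))
  }
  by <- census$birth_year
  for (pi in list(mi, fi)) {
    bad <- which(!is.na(pi) & !is.na(by) & !is.na(by[pi]) & by <= by[pi])
    if (length(bad) > 0) {
      errs <- c(errs, sprintf(
        "child '%s' (row %d) born in or before parent's birth year",
        id[bad[1]], bad[1]))
    }
  }
  bad_death <- which(!is.na(census$death_year) & !is.na(by) &
                       census$death_year < by)
  if (length(bad_death) > 0) {
    errs <- c(errs, sprintf("death before birth at row(s) %s",
                            paste(utils::head(bad_death, 5), collapse = ", ")))
  }
  bad_jeans <- which(!is.na(census$jeans) & !census$jeans %in% 1:4)
  if (length(bad_jeans) > 0) {
    errs <- c(errs, sprintf("jeans out of range (must be 1-4) at row(s) %s",
                            paste(utils::head(bad_jeans, 5), collapse = ", ")))
  }
  for (col in c("mandarin", "sichuan", "naru", "occupation", "tourism",
                "surveyed")) {
    bad <- which(!is.na(census[[col]]) & !census[[col]] %in% 0:1)
    if (length(bad) > 0) {
      errs <- c(errs, sprintf("%s must be 0/1; violated at row(s) %s", col,
                              paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  bad_im <- which(!is.na(census$intermarriage) & !census$intermarriage %in% 0:2)
  if (length(bad_im) > 0) {
    errs <- c(errs, sprintf("intermarriage must be 0/1/2; row(s) %s",
                            paste(utils::head(bad_im, 5), collapse = ", ")))
  }
  if (length(errs) > 0) {
    stop("census validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Write a census table
#'
#' Writes the CSV dialect read by [read_census()]; missing cells become
#' empty strings so the file round-trips exactly.
#'
#' @param census A `census` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_census <- function(census, path) {
  out <- as.data.frame(census)[CENSUS_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Age at the survey
#'
#' Years between birth and the survey for individuals alive at the survey;
#' `NA` for those who died before it or whose birth year is unknown. Only
#' living participants answered the cultural survey, so the age of the dead
#' is deliberately undefined here (they remain in the census for pedigree
#' and offspring counting).
#'
#' @param census A `census` data frame (or any data frame with `birth_year`
#'   and `death_year`).
#' @param config A [survey_config()].
#' @return Integer vector of ages, `NA` where undefined.
#' @export
age_at_survey <- function(census, config = survey_config()) {
  age <- config$survey_year - census$birth_year
  age[!is.na(census$death_year) & census$death_year < config$survey_year] <- NA
  if (any(age < 0, na.rm = TRUE)) {
    stop("negative age at survey: birth_year after survey_year at row(s) ",
         paste(utils::head(which(age < 0), 5), collapse = ", "))
  }
  as.integer(age)
}

#' Binarize the ordinal jeans variable
#'
#' Two published collapsings of the 1-4 wearing-frequency scale:
#' `"high"` codes often/always (3,4) as 1 and never/rarely (1,2) as 0;
#' `"ever"` codes rarely/often/always (2,3,4) as 1 and never (1) as 0.
#' Missing values stay missing (pairwise deletion downstream).
#'
#' @param value Integer vector with values in 1-4 or `NA`.
#' @param scheme `"high"` or `"ever"`.
#' @return Integer 0/1 vector with `NA` preserved.
#' @export
binarize_jeans <- function(value, scheme = c("high", "ever")) {
  scheme <- match.arg(scheme)
  if (any(!is.na(value) & !value %in% 1:4)) {
    stop("jeans out of range (must be 1-4)")
  }
  cut_at <- if (scheme == "high") 3L else 2L
  as.integer(ifelse(is.na(value), NA, as.integer(value >= cut_at)))
}

#' Derived reproductive outcomes
#'
#' For each ego: the number of offspring known to survive to
#' `config$survival_age` (dead children count if they lived past that age;
#' living children count once old enough at the survey; living children
#' still younger than the threshold are right-censored and not counted),
#' the number of children currently alive (any age), and age at first birth.
#'
#' @param census A `census` data frame.
#' @param ego Optional character vector of person ids; default all
#'   individuals.
#' @param config A [survey_config()].
#' @return Data frame with columns `person_id`, `offspring_surviving`,
#'   `live_children`, `age_first_birth`.
#' @export
derive_reproduction <- function(census, ego = NULL, config = survey_config()) {
  ids <- census$person_id
  if (is.null(ego)) {
    ego <- ids
  } else {
    missing_ego <- setdiff(ego, ids)
    if (length(missing_ego) > 0) {
      stop("ego not in census: ", paste(missing_ego, collapse = ", "))
    }
  }
  child_age_end <- ifelse(is.na(census$death_year),
                          config$survey_year - census$birth_year,
                          census$death_year - census$birth_year)
  survives <- !is.na(child_age_end) & child_age_end >= config$survival_age
  alive <- is.na(census$death_year)

  res <- data.frame(person_id = ego, offspring_surviving = 0L,
                    live_children = 0L, age_first_birth = NA_integer_,
                    stringsAsFactors = FALSE)
  parent_of <- function(e) which((!is.na(census$mother_id) & census$mother_id == e) |
                                   (!is.na(census$father_id) & census$father_id == e))
  ego_by <- census$birth_year[match(ego, ids)]
  for (k in seq_along(ego)) {
    ch <- parent_of(ego[k])
    if (length(ch) == 0) next
    res$offspring_surviving[k] <- sum(survives[ch])
    res$live_children[k] <- sum(alive[ch])
    cb <- census$birth_year[ch]
    if (!all(is.na(cb)) && !is.na(ego_by[k])) {
      res$age_first_birth[k] <- as.integer(min(cb, na.rm = TRUE) - ego_by[k])
    }
  }
  res
}

#' Trait values for a named trait
#'
#' Returns the per-individual 0/1 value of one of the four cultural traits,
#' applying the requested jeans binarization for the jeans trait.
#'
#' @param census A `census` data frame.
#' @param trait One of `"mandarin"`, `"sichuan"`, `"naru"`, `"jeans"`.
#' @param jeans_scheme Binarization for jeans, see [binarize_jeans()].
#' @return Integer 0/1 vector aligned with `census` rows, `NA` if missing.
#' @export
trait_values <- function(census, trait, jeans_scheme = "high") {
  trait <- match.arg(trait, c("mandarin", "sichuan", "naru", "jeans"))
  if (trait == "jeans") {
    binarize_jeans(census$jeans, jeans_scheme)
  } else {
    census[[trait]]
  }
}

#' @export
print.census <- function(x, ...) {
  cat(sprintf("<census> %d individuals (%d surveyed)\n",
              nrow(x), sum(x$surveyed == 1L, na.rm = TRUE)))
  eth <- table(x$ethnicity, useNA = "no")
  cat("  ethnicity:", paste(names(eth), eth, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
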