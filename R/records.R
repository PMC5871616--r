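# Canonical data model for individual-based monitoring records.
#
# Two tables drive every analysis in the package:
#   * bear-years  -- one monitored female in one hunting-season year,
#   * litters     -- one reproductive event with its realized care duration.
# Both are plain data frames with a documented CSV serialization (comma
# separated, UTF-8, "." decimal, booleans as true/false, missing values as
# empty fields; "unknown" and "lost" are explicit tokens, not blanks).

BEAR_YEAR_COLS <- c(
  "bear_id", "year", "age", "tactic", "status", "survived",
  "cause_of_death", "available_for_hunting", "recruits"
)
LITTER_COLS <- c(
  "litter_id", "mother_id", "birth_year", "weaning_year",
  "care_duration", "litter_size", "mother_primiparous"
)

#' Validate a table of bear-year records
#'
#' Checks every record against the invariants of the data model:
#' integer age >= 1; `tactic` in `T15`/`T25`/`unknown`; `status` in
#' `solitary`/`with_offspring`/`with_mother`; survivors have
#' `cause_of_death = "none"` and deaths have `"hunting"` or `"other"`;
#' females in a family group (`with_offspring`, `with_mother`) are not
#' available for hunting (the legal protection rule); `recruits`, when
#' present, is an integer count 0-3 of yearling daughters.
#'
#' @param records Data frame with the bear-year columns.
#' @return The validated data frame, invisibly typed (`year`, `age`,
#'   `recruits` integer; `survived`, `available_for_hunting` logical).
#' @export
validate_bear_years <- function(records) {
  missing_cols <- setdiff(BEAR_YEAR_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("bear-year schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, BEAR_YEAR_COLS]
  records$bear_id <- as.character(records$bear_id)
  records$year <- as.integer(records$year)
  records$age <- as.integer(records$age)
  records$recruits <- as.integer(records$recruits)
  records$survived <- as_bool(records$survived)
  records$available_for_hunting <- as_bool(records$available_for_hunting)

  fail <- function(rows, rule) {
    if (any(rows, na.rm = TRUE)) {
      stop("bear-year validation error (rows ",
           paste(utils::head(which(rows), 5), collapse = ", "),
           if (sum(rows, na.rm = TRUE) > 5) ", ..." else "",
           "): ", rule, call. = FALSE)
    }
  }
  fail(is.na(records$age) | records$age < 1, "age must be an integer >= 1")
  fail(!records$tactic %in% c("T15", "T25", "unknown"),
       "tactic must be one of T15, T25, unknown")
  fail(!records$status %in% c("solitary", "with_offspring", "with_mother"),
       "status must be one of solitary, with_offspring, with_mother")
  fail(is.na(records$survived), "survived must be true/false")
  fail(!records$cause_of_death %in% c("none", "hunting", "other"),
       "cause_of_death must be one of none, hunting, other")
  fail(records$survived & records$cause_of_death != "none",
       "survivors must have cause_of_death = none")
  fail(!records$survived & records$cause_of_death == "none",
       "deaths must have cause_of_death hunting or other")
  fail(records$status %in% c("with_offspring", "with_mother") &
         records$available_for_hunting,
       "family-group members are not available for hunting")
  fail(!is.na(records$recruits) &
         (records$recruits < 0 | records$recruits > 3),
       "recruits must be in 0..3 when present")
  records
}

#' Validate a table of litter records
#'
#' Enforces: litter size 1-4; `care_duration` one of `"1.5"`, `"2.5"` or
#' `"lost"` (lost before weaning); for weaned litters,
#' `weaning_year - birth_year` must equal 1 (1.5-year tactic) or
#' 2 (2.5-year tactic); `mother_primiparous` true/false/unknown.
#'
#' @param litters Data frame with the litter columns.
#' @return The validated data frame.
#' @export
validate_litters <- function(litters) {
  missing_cols <- setdiff(LITTER_COLS, names(litters))
  if (length(missing_cols) > 0) {
    stop("litter schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  litters <- litters[, LITTER_COLS]
  litters$litter_id <- as.character(litters$litter_id)
  litters$mother_id <- as.character(litters$mother_id)
  litters$birth_year <- as.integer(litters$birth_year)
  litters$weaning_year <- as.integer(litters$weaning_year)
  litters$care_duration <- as.character(litters$care_duration)
  litters$litter_size <- as.integer(litters$litter_size)
  litters$mother_primiparous <- as.character(litters$mother_primiparous)

  fail <- function(rows, rule) {
    if (any(rows, na.rm = TRUE)) {
      stop("litter validation error (rows ",
           paste(utils::head(which(rows), 5), collapse = ", "),
           if (sum(rows, na.rm = TRUE) > 5) ", ..." else "",
           "): ", rule, call. = FALSE)
    }
  }
  fail(!litters$care_duration %in% c("1.5", "2.5", "lost"),
       "care_duration must be one of 1.5, 2.5, lost")
  weaned <- litters$care_duration != "lost"
  gap <- litters$weaning_year - litters$birth_year
  fail(weaned & litters$care_duration == "1.5" & (is.na(gap) | gap != 1),
       "1.5-year litters must have weaning_year - birth_year = 1")
  fail(weaned & litters$care_duration == "2.5" & (is.na(gap) | gap != 2),
       "2.5-year litters must have weaning_year - birth_year = 2")
  fail(is.na(litters$litter_size) |
         litters$litter_size < 1 | litters$litter_size > 4,
       "litter_size must be in 1..4")
  fail(!litters$mother_primiparous %in% c("true", "false", "unknown"),
       "mother_primiparous must be true, false or unknown")
  litters
}

as_bool <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[tolower(as.character(x)) %in% c("true", "t", "1")] <- TRUE
  out[tolower(as.character(x)) %in% c("false", "f", "0")] <- FALSE
  out
}

#' Read bear-year records from CSV
#'
#' @param path Path to a `bear_years.csv` file with a header row.
#' @return Validated data frame of bear-year records, row order preserved.
#' @seealso [write_bear_years()], [validate_bear_years()]
#' @export
read_bear_years <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "")
  validate_bear_years(raw)
}

#' Write bear-year records to CSV
#'
#' Serializes with the documented column order; booleans become
#' `true`/`false`, missing values empty fields. `read_bear_years()` composed
#' with `write_bear_years()` is the identity on valid records.
#'
#' @param records Valid bear-year data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bear_years <- function(records, path) {
  records <- validate_bear_years(records)
  out <- records
  out$survived <- tolower(as.character(out$survived))
  out$available_for_hunting <- tolower(as.character(out$available_for_hunting))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read litter records from CSV
#' @param path Path to a `litters.csv` file with a header row.
#' @return Validated data frame of litter records.
#' @export
read_litters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "")
  validate_litters(raw)
}

#' Write litter records to CSV
#' @param litters Valid litter data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_litters <- function(litters, path) {
  litters <- validate_litters(litters)
  utils::write.csv(litters, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Numeric care duration of weaned litters (NA for lost litters).
care_years <- function(litters) {
  suppressWarnings(as.numeric(litters$care_duration))
}
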