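# Observation-level data model: per-fish DELT records, agency anomaly
# crosswalks, naive prevalence summaries.

#' Column schema for fish observation files
#'
#' Maps the canonical observation fields onto the column names of a delimited
#' input file. Files may carry either a pre-aggregated binary `delt` column,
#' per-anomaly flag columns (to be harmonized with [crosswalk_anomalies()]),
#' or both.
#'
#' @param stream_id,species,agency,ecoregion,year Column names holding the
#'   stream identifier (e.g. an NHDPlus COMID), species label, collection
#'   agency, ecoregion and calendar year.
#' @param delt Column name of a pre-aggregated binary DELT flag, or `NULL`
#'   if the file only carries per-anomaly columns.
#' @param anomalies Named character vector mapping anomaly categories
#'   (`deformity`, `erosion`, `lesion`, `tumor`, `parasite`, `other`) to
#'   column names, or `NULL` if the file has no per-anomaly columns. Flag
#'   columns may hold `"present"`/`"absent"`/`"not_assessed"` or
#'   `1`/`0`/`NA`.
#' @param young_of_year Optional column name of a logical (or 0/1) flag
#'   marking young-of-year individuals, which are dropped at read time.
#'   Absent the column, the data are assumed pre-filtered upstream.
#' @return A schema list consumed by [read_fish_observations()].
#' @export
delt_schema <- function(stream_id = "stream_id", species = "species",
                        agency = "agency", ecoregion = "ecoregion",
                        year = "year", delt = "delt", anomalies = NULL,
                        young_of_year = NULL) {
  if (!is.null(anomalies)) {
    bad <- setdiff(names(anomalies), .anomaly_categories)
    if (length(bad) > 0L) {
      stop("unknown anomaly categories in schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  list(stream_id = stream_id, species = species, agency = agency,
       ecoregion = ecoregion, year = year, delt = delt,
       anomalies = anomalies, young_of_year = young_of_year)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(unname(cols), names(df))
  if (length(missing) > 0L) {
    stop("schema error: ", what, " column(s) not found in file: ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
}

.clean_label <- function(x, field) {
  x <- trimws(as.character(x))
  bad <- which(is.na(x) | x == "")
  if (length(bad) > 0L) {
    stop("row ", bad[1L], ": empty or missing ", field, " label",
         call. = FALSE)
  }
  x
}

.parse_flag <- function(x, column) {
  # normalize an anomaly flag column to "present"/"absent"/"not_assessed"
  if (is.numeric(x) || is.logical(x)) {
    out <- ifelse(is.na(x), "not_assessed", ifelse(x != 0, "present", "absent"))
    return(out)
  }
  x <- trimws(tolower(as.character(x)))
  x[is.na(x) | x == "" | x == "na"] <- "not_assessed"
  ok <- x %in% c("present", "absent", "not_assessed", "1", "0")
  if (!all(ok)) {
    stop("row ", which(!ok)[1L], ": unparseable anomaly flag in column '",
         column, "': '", x[which(!ok)[1L]], "'", call. = FALSE)
  }
  x[x == "1"] <- "present"
  x[x == "0"] <- "absent"
  x
}

#' Read per-fish observation records from a delimited file
#'
#' One row per individual inspected fish. Returns the observation table
#' (with `delt` taken verbatim when the file carries a binary DELT column)
#' and, when the schema maps per-anomaly columns, the aligned anomaly flag
#' records for later harmonization via [crosswalk_anomalies()].
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema A [delt_schema()] list mapping canonical fields to columns.
#' @return A list with components `observations` (data frame with columns
#'   `stream_id`, `species`, `agency`, `ecoregion`, `year`, `delt`; `delt`
#'   is `NA` when only anomaly columns were supplied) and `anomalies`
#'   (data frame of flag columns aligned row-for-row with `observations`,
#'   or `NULL`).
#' @export
read_fish_observations <- function(path, schema = delt_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  core <- c(stream_id = schema$stream_id, species = schema$species,
            agency = schema$agency, ecoregion = schema$ecoregion,
            year = schema$year)
  for (field in names(core)) {
    if (!core[[field]] %in% names(df)) {
      stop("schema error: missing column '", field, "' (file column '",
           core[[field]], "')", call. = FALSE)
    }
  }
  has_delt <- !is.null(schema$delt) && schema$delt %in% names(df)
  has_anom <- !is.null(schema$anomalies) &&
    all(unname(schema$anomalies) %in% names(df))
  if (!has_delt && !has_anom) {
    stop("schema error: file carries neither a '", schema$delt %||% "delt",
         "' column nor the mapped anomaly columns", call. = FALSE)
  }

  year <- suppressWarnings(as.integer(df[[schema$year]]))
  if (anyNA(year)) {
    stop("row ", which(is.na(year))[1L], ": unparseable year '",
         df[[schema$year]][which(is.na(year))[1L]], "'", call. = FALSE)
  }

  obs <- data.frame(
    stream_id = .clean_label(df[[schema$stream_id]], "stream_id"),
    species   = .clean_label(df[[schema$species]], "species"),
    agency    = .clean_label(df[[schema$agency]], "agency"),
    ecoregion = .clean_label(df[[schema$ecoregion]], "ecoregion"),
    year      = year,
    delt      = NA_integer_,
    stringsAsFactors = FALSE
  )

  if (has_delt) {
    delt <- suppressWarnings(as.integer(df[[schema$delt]]))
    bad <- which(is.na(delt) | !(delt %in% c(0L, 1L)))
    if (length(bad) > 0L) {
      stop("row ", bad[1L], ": delt flag must be 0 or 1, got '",
           df[[schema$delt]][bad[1L]], "'", call. = FALSE)
    }
    obs$delt <- delt
  }

  anomalies <- NULL
  if (has_anom) {
    anomalies <- as.data.frame(
      lapply(names(schema$anomalies), function(cat) {
        .parse_flag(df[[schema$anomalies[[cat]]]], schema$anomalies[[cat]])
      }),
      stringsAsFactors = FALSE
    )
    names(anomalies) <- names(schema$anomalies)
  }

  if (!is.null(schema$young_of_year) && schema$young_of_year %in% names(df)) {
    yoy <- df[[schema$young_of_year]]
    keep <- !(as.logical(yoy) %in% TRUE)
    obs <- obs[keep, , drop = FALSE]
    if (!is.null(anomalies)) anomalies <- anomalies[keep, , drop = FALSE]
    rownames(obs) <- NULL
    if (!is.null(anomalies)) rownames(anomalies) <- NULL
  }

  list(observations = obs, anomalies = anomalies)
}

#' Write observation records to CSV
#'
#' Inverse of [read_fish_observations()] under the default schema; a write
#' followed by a read recovers an identical collection.
#'
#' @param observations Observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fish_observations <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' Restrict observations to a study window of calendar years
#'
#' @param observations Observation data frame with a `year` column.
#' @param start_year,end_year Inclusive window bounds.
#' @return The observations with `start_year <= year <= end_year`.
#' @export
filter_observation_window <- function(observations, start_year, end_year) {
  if (start_year > end_year) {
    stop("inverted window: start_year (", start_year,
         ") > end_year (", end_year, ")", call. = FALSE)
  }
  out <- observations[observations$year >= start_year &
                        observations$year <= end_year, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate an agency anomaly crosswalk table
#'
#' A crosswalk row states, for one agency and one anomaly category, whether
#' that category counts toward the binary DELT aggregate for fish recorded
#' by that agency. Agencies differ in what they assess (most count external
#' parasites; some do not), so the crosswalk is user-supplied data.
#'
#' @param crosswalk Data frame with columns `agency`, `category` and
#'   `counted` (logical, or the strings `"counted"`/`"excluded"`).
#' @return The validated crosswalk with a logical `counted` column.
#' @export
validate_crosswalk <- function(crosswalk) {
  .require_columns(crosswalk, c("agency", "category", "counted"), "crosswalk")
  bad <- setdiff(unique(crosswalk$category), .anomaly_categories)
  if (length(bad) > 0L) {
    stop("crosswalk error: unknown anomaly category: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counted <- crosswalk$counted
  if (!is.logical(counted)) {
    counted <- trimws(tolower(as.character(counted)))
    ok <- counted %in% c("counted", "excluded")
    if (!all(ok)) {
      stop("crosswalk error: 'counted' must be logical or ",
           "'counted'/'excluded'", call. = FALSE)
    }
    counted <- counted == "counted"
  }
  crosswalk$agency <- trimws(as.character(crosswalk$agency))
  crosswalk$category <- as.character(crosswalk$category)
  crosswalk$counted <- counted
  if (anyDuplicated(crosswalk[c("agency", "category")]) > 0L) {
    stop("crosswalk error: duplicated (agency, category) row", call. = FALSE)
  }
  crosswalk
}

#' Harmonize per-anomaly flags to a binary DELT indicator
#'
#' A fish is DELT-positive iff at least one anomaly flag is `"present"`
#' among the categories the crosswalk marks as counted for its recording
#' agency. Categories that are `"not_assessed"` or excluded by the agency's
#' crosswalk never contribute, so e.g. an agency that does not count
#' external parasites yields 0 for a parasite-only fish.
#'
#' @param anomalies Data frame of anomaly flag columns (subset of
#'   `deformity`, `erosion`, `lesion`, `tumor`, `parasite`, `other`), each
#'   holding `"present"`, `"absent"` or `"not_assessed"`.
#' @param agency Character vector of recording agencies, length 1 or
#'   `nrow(anomalies)`.
#' @param crosswalk A crosswalk table accepted by [validate_crosswalk()].
#' @return Integer vector of binary DELT indicators.
#' @export
crosswalk_anomalies <- function(anomalies, agency, crosswalk) {
  crosswalk <- validate_crosswalk(crosswalk)
  bad <- setdiff(names(anomalies), .anomaly_categories)
  if (length(bad) > 0L) {
    stop("unknown anomaly category column: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  agency <- trimws(as.character(agency))
  if (length(agency) == 1L) agency <- rep(agency, nrow(anomalies))
  stopifnot(length(agency) == nrow(anomalies))
  unknown <- setdiff(unique(agency), unique(crosswalk$agency))
  if (length(unknown) > 0L) {
    stop("crosswalk error: no crosswalk row for agency: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  present <- vapply(anomalies, function(col) col == "present",
                    logical(nrow(anomalies)))
  present <- matrix(present, nrow = nrow(anomalies),
                    dimnames = list(NULL, names(anomalies)))
  out <- integer(nrow(anomalies))
  for (ag in unique(agency)) {
    counted <- crosswalk$category[crosswalk$agency == ag & crosswalk$counted]
    cols <- intersect(counted, colnames(present))
    rows <- agency == ag
    if (length(cols) > 0L) {
      out[rows] <- as.integer(rowSums(present[rows, cols, drop = FALSE]) > 0L)
    }
  }
  out
}

#' Naive (non-model) DELT prevalence summaries
#'
#' Observed counts and proportions of DELT-positive fish, overall or by
#' species or stream. "Naive" means directly observed, with no model
#' adjustment or pooling.
#'
#' @param observations Observation data frame with a binary `delt` column.
#' @param group_by `"overall"`, `"species"` or `"stream"`.
#' @return Data frame with columns `group`, `n_inspected`, `n_delt`,
#'   `prevalence`. Groups with zero inspected fish do not appear.
#' @export
compute_naive_prevalence <- function(observations,
                                     group_by = c("overall", "species",
                                                  "stream")) {
  group_by <- match.arg(group_by)
  if (is.null(observations) || nrow(observations) == 0L) {
    stop("empty input: no observations to summarize", call. = FALSE)
  }
  if (anyNA(observations$delt)) {
    stop("observations carry unresolved delt flags; apply ",
         "crosswalk_anomalies() first", call. = FALSE)
  }
  key <- switch(group_by,
                overall = rep("overall", nrow(observations)),
                species = observations$species,
                stream  = observations$stream_id)
  n <- tapply(observations$delt, key, length)
  d <- tapply(observations$delt, key, sum)
  out <- data.frame(group = names(n),
                    n_inspected = as.integer(n),
                    n_delt = as.integer(d),
                    prevalence = as.numeric(d) / as.numeric(n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select focal species for species-specific modeling
#'
#' Species qualify for a single-species landscape model when their naive
#' DELT prevalence is at least `min_prevalence` and their sample size is
#' strictly greater than `min_n`: with very low prevalence there is no
#' occurrence variation to model, and small samples give unstable fits.
#'
#' @param summaries Per-species output of
#'   `compute_naive_prevalence(..., group_by = "species")`.
#' @param min_prevalence Minimum naive prevalence (inclusive); default 0.05.
#' @param min_n Sample-size threshold (exclusive); default 100.
#' @return Sorted character vector of qualifying species.
#' @export
select_focal_species <- function(summaries, min_prevalence = 0.05,
                                 min_n = 100) {
  if (is.null(summaries) || nrow(summaries) == 0L) return(character(0))
  keep <- summaries$prevalence >= min_prevalence & summaries$n_inspected > min_n
  sort(summaries$group[keep])
}
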