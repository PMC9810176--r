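## Closed vocabularies for the trial-record schema. Region labels follow the
## USFWS administrative regions; habitat is the predominant land cover at the
## facility; bird_type separates large raptor carcasses from the pen-raised
## game bird surrogates (pheasant/duck) used in most monitoring programmes.

#' Closed label vocabularies of the trial-record schema
#'
#' The admissible levels of the stratum columns. The first element of each
#' vector is the treatment-coding baseline (fall, Region 1, cropland,
#' raptor).
#'
#' @return character vector of levels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
region_levels <- function() paste0("R", 1:8)

#' @rdname vocabularies
#' @export
habitat_levels <- function() c("cropland", "grassland", "forest", "shrub_scrub")

#' @rdname vocabularies
#' @export
season_levels <- function() c("fall", "spring", "summer", "winter")

#' @rdname vocabularies
#' @export
bird_type_levels <- function() c("raptor", "gamebird")

trial_columns <- function() {
  c("carcass_id", "study_id", "site_id", "state", "region", "habitat",
    "season", "bird_type", "species", "placement_time", "last_present",
    "first_absent", "monitor_mode", "trial_length")
}

#' Assign a season label from a calendar date
#'
#' Season windows follow the field-trial convention: summer Jun 15 - Sep 14,
#' fall Sep 15 - Nov 14, winter Nov 15 - Mar 14, spring Mar 15 - Jun 14.
#' Used when a trials file carries placement dates but no season column.
#'
#' @param date a `Date` vector.
#' @return character vector of season labels.
#' @export
season_from_date <- function(date) {
  stopifnot(inherits(date, "Date"))
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  out <- character(length(md))
  out[md >= 615 & md <= 914] <- "summer"
  out[md >= 915 & md <= 1114] <- "fall"
  out[md >= 1115 | md <= 314] <- "winter"
  out[md >= 315 & md <= 614] <- "spring"
  out
}

validate_trials <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(setdiff(trial_columns(), "species"), names(df))
  if (length(missing_cols)) {
    stop("trials file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"species" %in% names(df)) df$species <- NA_character_

  chk_levels <- function(col, levels) {
    bad <- setdiff(unique(as.character(df[[col]])), levels)
    if (length(bad)) {
      stop("unknown ", col, " label(s): ", paste(bad, collapse = ", "),
           "; expected one of: ", paste(levels, collapse = ", "),
           call. = FALSE)
    }
  }
  chk_levels("region", region_levels())
  chk_levels("habitat", habitat_levels())
  chk_levels("season", season_levels())
  chk_levels("bird_type", bird_type_levels())
  chk_levels("monitor_mode", c("in_person", "camera"))

  num_cols <- c("placement_time", "last_present", "first_absent", "trial_length")
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad)) {
        stop("unparseable ", col, " for carcass_id ",
             paste(df$carcass_id[bad], collapse = ", "), call. = FALSE)
      }
      df[[col]] <- vn
    }
  }

  censored <- is.na(df$first_absent)
  if (any(df$last_present < 0, na.rm = TRUE))
    stop("negative last_present for carcass_id ",
         paste(df$carcass_id[which(df$last_present < 0)], collapse = ", "),
         call. = FALSE)
  ## In-person checks bracket the removal strictly; camera records carry an
  ## exact removal time encoded as last_present == first_absent.
  strict <- !censored & df$monitor_mode == "in_person"
  bad <- which(strict & df$first_absent <= df$last_present)
  bad <- c(bad, which(!censored & df$monitor_mode == "camera" &
                        df$first_absent < df$last_present))
  if (length(bad)) {
    stop("first_absent precedes last_present for carcass_id ",
         paste(df$carcass_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(censored & df$last_present > df$trial_length)
  if (length(bad)) {
    stop("right-censored record beyond trial_length for carcass_id ",
         paste(df$carcass_id[bad], collapse = ", "), call. = FALSE)
  }
  df <- df[, trial_columns()]
  class(df) <- c("cpt_trials", "data.frame")
  df
}

#' Read carcass persistence trial records
#'
#' Reads a UTF-8 CSV of trial records, one row per carcass, and validates it
#' against the closed schema: identifiers (`carcass_id`, `study_id`,
#' `site_id`, `state`), stratum labels (`region` in `"R1"`..`"R8"`,
#' `habitat`, `season`, `bird_type`), timing (`placement_time`,
#' `last_present`, `first_absent` in days since placement; `first_absent`
#' empty for a carcass still present at the final check), `monitor_mode`
#' (`in_person` or `camera`) and `trial_length`. Camera-monitored removals
#' carry the exact removal time in both `last_present` and `first_absent`.
#'
#' @param path path to the CSV file.
#' @return a `cpt_trials` data frame.
#' @seealso [make_intervals()], [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("placement_time", "last_present", "first_absent",
                "trial_length")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      v[v == ""] <- NA_character_
      df[[col]] <- v
    }
  }
  validate_trials(df)
}

#' Write trial records to CSV
#'
#' Inverse of [read_trials()]: a written collection reads back identically.
#'
#' @param trials a `cpt_trials` data frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "cpt_trials"))
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build interval-censored observations from trial records
#'
#' Converts checked trial records to the half-open intervals `[left, right)`
#' that the interval-censored likelihood consumes. An in-person record maps
#' to `[last_present, first_absent)`; a right-censored record to
#' `[last_present, Inf)`; a camera record with exact removal time `t` to the
#' narrow interval `[t - camera_delta, t)`, so a single likelihood code path
#' serves both monitoring modes.
#'
#' @param trials a `cpt_trials` data frame.
#' @param camera_delta width in days of the pseudo-interval for camera-exact
#'   removal times. Default 0.04 d (about one hour).
#' @return a `cpt_obs` data frame with columns `left`, `right`, `weight`, the
#'   stratum labels, and the record identifiers.
#' @export
make_intervals <- function(trials, camera_delta = 0.04) {
  stopifnot(inherits(trials, "cpt_trials"), camera_delta > 0)
  censored <- is.na(trials$first_absent)
  left <- trials$last_present
  right <- trials$first_absent
  right[censored] <- Inf

  cam <- !censored & trials$monitor_mode == "camera"
  if (any(cam)) {
    t_exact <- trials$first_absent[cam]
    left[cam] <- pmax(t_exact - camera_delta, 0)
    right[cam] <- t_exact
  }
  bad <- which(!censored & right <= left)
  if (length(bad)) {
    stop("degenerate interval for carcass_id ",
         paste(trials$carcass_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    left = left, right = right, weight = 1L,
    carcass_id = trials$carcass_id, study_id = trials$study_id,
    site_id = trials$site_id, state = trials$state,
    region = trials$region, habitat = trials$habitat,
    season = trials$season, bird_type = trials$bird_type,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cpt_obs", "data.frame")
  out
}

#' @export
print.cpt_trials <- function(x, ...) {
  cat("Carcass persistence trial records: ", nrow(x), " carcasses, ",
      length(unique(x$study_id)), " studies\n", sep = "")
  cat("  bird types: ",
      paste(names(table(x$bird_type)), table(x$bird_type),
            sep = "=", collapse = ", "),
      "; right-censored: ", sum(is.na(x$first_absent)), "\n", sep = "")
  NextMethod()
}

#' @export
print.cpt_obs <- function(x, ...) {
  cat("Interval-censored observations: ", nrow(x), " rows (",
      sum(!is.finite(x$right)), " right-censored)\n", sep = "")
  NextMethod()
}
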