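# Data model and I/O for minute-level step streams, patient metadata and
# derived day summaries. Minutes absent from a stream mean "no data
# recorded", never an implicit zero: the biomarker layer decides per metric
# how absence is treated (wear time was not monitored, so absence is
# ambiguous).

VALID_JOINTS <- c("hip", "knee")
VALID_SURGERY_TYPES <- c("total", "unicondylar", "revision", "resurfacing")

# Column orders of the on-disk CSV schemas (fixed, documented contracts).
MINUTE_COLS <- c("patient_id", "date", "minute_of_day", "steps")
META_COLS <- c("patient_id", "joint", "surgery_type", "surgery_date",
               "age", "gender", "bmi", "fjs_pre", "fjs_3m")
DAY_SUMMARY_COLS <- c("patient_id", "date", "day_post_op", "steps",
                      "p1m", "p6mc", "min_sedentary", "min_light",
                      "min_moderate", "min_vigorous",
                      "n_minutes_recorded", "n_outliers_removed")

# '#'-prefixed metadata lines, then the CSV body (fwrite cannot take a
# connection, so append after the header)
write_csv_with_header <- function(dt, path, header_lines = NULL) {
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), path)
    data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(dt, path)
  }
  invisible(path)
}

# fread wrapper that skips '#'-prefixed artifact-metadata header lines
fread_skip_comments <- function(path, ...) {
  first <- readLines(path, n = 50L, warn = FALSE)
  nskip <- 0L
  while (nskip < length(first) && startsWith(first[nskip + 1L], "#"))
    nskip <- nskip + 1L
  data.table::fread(path, skip = nskip, ...)
}

#' Read a minute-level step stream CSV
#'
#' Expected columns (header required): `patient_id,date,minute_of_day,steps`.
#' Dates are ISO 8601 calendar dates; `minute_of_day` is local clock time in
#' 0..1439; `steps` is the non-negative step count accumulated in that
#' minute. Zero-step rows are permitted and retained. Minutes may be absent:
#' absence means "not recorded" and is not imputed here.
#'
#' @param path Path to a CSV file. Leading lines starting with `#` are
#'   treated as artifact metadata and skipped.
#' @return A `data.table` with columns `patient_id` (character), `date`
#'   (`IDate`), `minute_of_day` (integer), `steps` (integer), keyed by
#'   patient, date, minute.
#' @export
read_minute_csv <- function(path) {
  stopifnot(file.exists(path))
  dt <- fread_skip_comments(path, colClasses = list(character = "patient_id"))
  missing_cols <- setdiff(MINUTE_COLS, names(dt))
  if (length(missing_cols))
    stop("minute CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  dt <- dt[, MINUTE_COLS, with = FALSE]
  validate_minute_records(dt)
}

#' Validate an in-memory minute-record table
#'
#' Enforces the minute-stream invariants: integer `minute_of_day` in
#' 0..1439, non-negative integer steps, and at most one record per
#' (patient, date, minute). Offending row numbers are named in errors.
#'
#' @param dt A data.frame/data.table with the minute-stream columns.
#' @return The validated records as a keyed `data.table` (a copy).
#' @export
validate_minute_records <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) == 0L)
    return(data.table::data.table(patient_id = character(0),
                                  date = data.table::as.IDate(integer(0)),
                                  minute_of_day = integer(0),
                                  steps = integer(0),
                                  key = c("patient_id", "date", "minute_of_day")))
  dt[, patient_id := as.character(patient_id)]
  dt[, date := data.table::as.IDate(date)]
  if (anyNA(dt$date)) stop("unparseable date(s) in rows: ",
                           row_list(which(is.na(dt$date))))
  mo <- dt$minute_of_day
  if (!is.numeric(mo) || any(is.na(mo)) || any(mo != as.integer(mo)))
    stop("non-integer minute_of_day in rows: ",
         row_list(which(is.na(mo) | mo != suppressWarnings(as.integer(mo)))))
  bad <- which(mo < 0 | mo > 1439)
  if (length(bad)) stop("minute_of_day outside 0..1439 in rows: ", row_list(bad))
  st <- dt$steps
  if (!is.numeric(st) || any(is.na(st)))
    stop("missing/non-numeric steps in rows: ", row_list(which(is.na(st))))
  bad <- which(st < 0)
  if (length(bad)) stop("negative steps in rows: ", row_list(bad))
  bad <- which(st != as.integer(st))
  if (length(bad)) stop("non-integer steps in rows: ", row_list(bad))
  dt[, minute_of_day := as.integer(minute_of_day)]
  dt[, steps := as.integer(steps)]
  dup <- duplicated(dt, by = c("patient_id", "date", "minute_of_day"))
  if (any(dup))
    stop("duplicate (patient_id, date, minute_of_day) in rows: ",
         row_list(which(dup)))
  data.table::setkeyv(dt, c("patient_id", "date", "minute_of_day"))
  dt[]
}

row_list <- function(i, max_show = 10L) {
  shown <- head(i, max_show)
  extra <- if (length(i) > max_show) sprintf(" (+%d more)", length(i) - max_show) else ""
  paste0(paste(shown, collapse = ", "), extra)
}

#' Read a patient metadata CSV
#'
#' Expected columns: `patient_id,joint,surgery_type,surgery_date,age,gender,`
#' `bmi,fjs_pre,fjs_3m`. Joint/surgery-type combinations are validated
#' (unicondylar is knee-only, resurfacing hip-only). A missing `fjs_3m` is
#' allowed; such patients are flagged ineligible for MCID stratification via
#' the derived logical column `fjs_complete`.
#'
#' @param path Path to a CSV file (leading `#` lines skipped).
#' @return A `data.table` of patient metadata keyed by `patient_id`, with
#'   the derived column `fjs_complete`.
#' @export
read_metadata_csv <- function(path) {
  stopifnot(file.exists(path))
  dt <- fread_skip_comments(path, colClasses = list(character = "patient_id"))
  missing_cols <- setdiff(META_COLS, names(dt))
  if (length(missing_cols))
    stop("metadata CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  validate_metadata(dt[, META_COLS, with = FALSE])
}

#' Validate patient metadata
#'
#' @param dt A data.frame/data.table with the metadata columns.
#' @return Validated metadata as a keyed `data.table` with `fjs_complete`.
#' @export
validate_metadata <- function(dt) {
  dt <- data.table::as.data.table(dt)
  dt[, patient_id := as.character(patient_id)]
  if (anyDuplicated(dt$patient_id))
    stop("duplicate patient_id in metadata: ",
         row_list(dt$patient_id[duplicated(dt$patient_id)]))
  bad <- which(!dt$joint %in% VALID_JOINTS)
  if (length(bad)) stop("unknown joint token in rows: ", row_list(bad))
  bad <- which(!dt$surgery_type %in% VALID_SURGERY_TYPES)
  if (length(bad)) stop("unknown surgery_type token in rows: ", row_list(bad))
  bad <- which((dt$surgery_type == "unicondylar" & dt$joint != "knee") |
               (dt$surgery_type == "resurfacing" & dt$joint != "hip"))
  if (length(bad))
    stop("invalid joint/surgery_type combination in rows: ", row_list(bad))
  dt[, surgery_date := data.table::as.IDate(surgery_date)]
  if (anyNA(dt$surgery_date))
    stop("unparseable surgery_date in rows: ", row_list(which(is.na(dt$surgery_date))))
  bad <- which(is.na(dt$age) | dt$age <= 0)
  if (length(bad)) stop("age must be positive; offending rows: ", row_list(bad))
  if (any(!dt$gender %in% c("female", "male")))
    stop("gender must be 'female' or 'male'")
  for (col in c("fjs_pre", "fjs_3m")) {
    v <- dt[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) stop(col, " outside [0, 100] in rows: ", row_list(bad))
  }
  if (anyNA(dt$fjs_pre))
    stop("fjs_pre missing in rows: ", row_list(which(is.na(dt$fjs_pre))))
  dt[, fjs_complete := !is.na(fjs_3m)]
  data.table::setkeyv(dt, "patient_id")
  dt[]
}

#' Annotate minute records or day summaries with surgery-relative day
#'
#' Adds `day_post_op = date - surgery_date` in whole days: the surgery day
#' itself is day 0, the first post-operative day is day 1, pre-operative
#' days are negative. Translation-equivariant: shifting all dates and
#' surgery dates by the same offset leaves `day_post_op` unchanged.
#'
#' @param records A table with `patient_id` and `date` columns.
#' @param meta Patient metadata with `surgery_date` for every patient
#'   present in `records`.
#' @return A copy of `records` with an integer `day_post_op` column.
#' @export
align_to_surgery <- function(records, meta) {
  records <- data.table::as.data.table(records)
  meta <- data.table::as.data.table(meta)
  missing_pat <- setdiff(unique(records$patient_id), meta$patient_id)
  if (length(missing_pat))
    stop("no surgery_date for patient(s): ", paste(missing_pat, collapse = ", "))
  out <- merge(records, meta[, .(patient_id, surgery_date)],
               by = "patient_id", sort = FALSE)
  out[, day_post_op := as.integer(data.table::as.IDate(date) - surgery_date)]
  out[, surgery_date := NULL]
  out[]
}

#' Write day summaries to CSV
#'
#' Columns are written in the fixed documented order
#' `patient_id,date,day_post_op,steps,p1m,p6mc,min_sedentary,min_light,`
#' `min_moderate,min_vigorous,n_minutes_recorded,n_outliers_removed`. Optional
#' `header_lines` (artifact metadata, e.g. seed and config hash) are
#' prefixed with `#`; [read_day_summaries()] skips them.
#'
#' @param summaries A non-empty day-summary table (see [summarize_days()]).
#' @param path Output path.
#' @param header_lines Optional character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_day_summaries <- function(summaries, path, header_lines = NULL) {
  summaries <- data.table::as.data.table(summaries)
  if (nrow(summaries) == 0L) stop("refusing to write an empty day-summary table")
  missing_cols <- setdiff(DAY_SUMMARY_COLS, names(summaries))
  if (length(missing_cols))
    stop("day-summary table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  out <- summaries[, DAY_SUMMARY_COLS, with = FALSE]
  # full precision for the cadence columns so the round-trip is exact
  write_csv_with_header(out, path, header_lines)
  invisible(path)
}

#' Read day summaries written by [write_day_summaries()]
#'
#' @param path Path to a day-summary CSV.
#' @return A `data.table` with the day-summary columns.
#' @export
read_day_summaries <- function(path) {
  stopifnot(file.exists(path))
  dt <- fread_skip_comments(path, colClasses = list(character = "patient_id"))
  missing_cols <- setdiff(DAY_SUMMARY_COLS, names(dt))
  if (length(missing_cols))
    stop("day-summary CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  dt[, date := data.table::as.IDate(date)]
  # stable column types regardless of what the values happen to look like
  for (col in c("day_post_op", "steps", "min_sedentary", "min_light",
                "min_moderate", "min_vigorous", "n_minutes_recorded",
                "n_outliers_removed"))
    data.table::set(dt, j = col, value = as.integer(dt[[col]]))
  for (col in c("p1m", "p6mc"))
    data.table::set(dt, j = col, value = as.numeric(dt[[col]]))
  data.table::setkeyv(dt, c("patient_id", "date"))
  dt[]
}

#' Write a minute-record table to CSV
#'
#' @inheritParams write_day_summaries
#' @param records Minute records as from [read_minute_csv()].
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(records, path, header_lines = NULL) {
  records <- data.table::as.data.table(records)
  write_csv_with_header(records[, MINUTE_COLS, with = FALSE], path,
                        header_lines)
  invisible(path)
}

#' Write patient metadata to CSV
#'
#' @inheritParams write_day_summaries
#' @param meta Patient metadata as from [read_metadata_csv()].
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(meta, path, header_lines = NULL) {
  meta <- data.table::as.data.table(meta)
  write_csv_with_header(meta[, META_COLS, with = FALSE], path, header_lines)
  invisible(path)
}
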