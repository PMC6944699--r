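#' Observed time-course dataset
#'
#' Container for the experimental design emulated throughout the package:
#' replicated viable-cell counts and bulk MGMT fold-changes at discrete
#' observation days under a known treatment schedule. MGMT may be missing
#' (`NA`) at some days; counts are mandatory and strictly positive.
#'
#' @param data a data.frame with columns `replicate_id` (character),
#'   `day` (days >= 0), `count` (cells > 0), `mgmt_fold` (unitless > 0 or
#'   `NA`).
#' @param schedule the `treatment_schedule` the cells experienced, or `NULL`.
#' @param provenance free-text record of origin (generator parameters,
#'   seed, file path, ...).
#' @return an object of class `time_course_dataset` (a data.frame).
#' @export
time_course_dataset <- function(data, schedule = NULL, provenance = "") {
  req <- c("replicate_id", "day", "count", "mgmt_fold")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[, req]
  data$replicate_id <- as.character(data$replicate_id)
  data$day <- as.numeric(data$day)
  data$count <- as.numeric(data$count)
  data$mgmt_fold <- as.numeric(data$mgmt_fold)
  validate_dataset_rows(data)
  structure(data,
            class = c("time_course_dataset", "data.frame"),
            schedule = schedule,
            provenance = provenance)
}

validate_dataset_rows <- function(data) {
  bad <- which(!is.finite(data$day) | data$day < 0)
  if (length(bad)) {
    stop("invalid day at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(data$count) | data$count <= 0)
  if (length(bad)) {
    stop("non-positive or missing count at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(data$mgmt_fold) & data$mgmt_fold <= 0)
  if (length(bad)) {
    stop("non-positive mgmt_fold at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (rep_id in unique(data$replicate_id)) {
    d <- data$day[data$replicate_id == rep_id]
    if (is.unsorted(d, strictly = TRUE)) {
      stop("days not strictly increasing within replicate '", rep_id, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.time_course_dataset <- function(x, ...) {
  cat(sprintf(
    "<time_course_dataset: %d rows, %d replicate(s), days {%s}>\n",
    nrow(x), length(unique(x$replicate_id)),
    paste(sort(unique(x$day)), collapse = ", ")))
  print.data.frame(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Dataset schedule and provenance accessors
#' @param dataset a `time_course_dataset`.
#' @return the attached `treatment_schedule` (or `NULL`), respectively the
#'   provenance record.
#' @export
dataset_schedule <- function(dataset) attr(dataset, "schedule")

#' @rdname dataset_schedule
#' @export
dataset_provenance <- function(dataset) attr(dataset, "provenance")

#' Read / write a time-course dataset as CSV
#'
#' The on-disk schema is `replicate_id,day,count,mgmt_fold` with an empty
#' cell for missing MGMT. Values are written at full double precision, so a
#' write/read round trip reproduces the numbers bit-exactly. Schema
#' violations (missing columns, non-positive counts, unsorted days) raise
#' errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param dataset a `time_course_dataset`.
#' @param schedule optional `treatment_schedule` to attach on read.
#' @return `read_dataset` returns a `time_course_dataset`; `write_dataset`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path, schedule = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(replicate_id = "character"))
  time_course_dataset(raw, schedule = schedule,
                      provenance = paste0("read from ", path))
}

#' @rdname read_dataset
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "time_course_dataset"))
  write_full_precision_csv(as.data.frame(dataset), path)
  invisible(path)
}
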