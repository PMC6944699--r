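# Internal constructor for simulated time courses. A trajectory is a
# data.frame with columns day, S, TR, R, total, mgmt plus optional
# age-density snapshots kept as an attribute.
new_trajectory <- function(day, S, TR, R, mgmt, model_id,
                           age_snapshots = NULL, params = NULL) {
  df <- data.frame(day = day, S = S, TR = TR, R = R,
                   total = S + TR + R, mgmt = mgmt)
  structure(df,
            class = c("trajectory", "data.frame"),
            model_id = model_id,
            age_snapshots = age_snapshots,
            params = params)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s model, %d time points, day %.3g to %.3g>\n",
              attr(x, "model_id") %||% "?", nrow(x), min(x$day), max(x$day)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE, ...)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Extract the age-density snapshots of an adaptive-model trajectory
#'
#' @param trajectory a trajectory produced by [simulate_adaptive()] with
#'   `snapshot_days` set.
#' @return a data.frame with columns `day`, `age`, `density`
#'   (cells per day of age), or `NULL` when no snapshots were recorded.
#' @export
age_snapshots <- function(trajectory) {
  attr(trajectory, "age_snapshots")
}

#' Write a trajectory to CSV
#'
#' Columns `day,S,TR,R,total,mgmt`, values at full double precision.
#'
#' @param trajectory a trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)[, c("day", "S", "TR", "R", "total", "mgmt")]
  write_full_precision_csv(df, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSV writer that preserves doubles bit-exactly (%.17g round-trips).
write_full_precision_csv <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- ""
      out
    } else {
      out <- as.character(col)
      out[is.na(col)] <- ""
      out
    }
  })
  mat <- do.call(cbind, fmt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(mat, 1L, paste, collapse = ","), con)
  invisible(path)
}
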