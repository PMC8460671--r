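# plain-text readers/writers for the pipeline's tidy containers

#' Read a time-volume curve from CSV
#'
#' Expects columns `t_norm` and `volume_ul` (one row per frame).
#'
#' @param file CSV path.
#' @param rr_ms cycle length in ms.
#' @param bw_g optional body weight in grams.
#' @return A [tvc()] object.
#' @export
read_tvc <- function(file, rr_ms, bw_g = NULL) {
  d <- read.csv(file)
  stop_if(!all(c("t_norm", "volume_ul") %in% names(d)),
          "CSV needs columns t_norm, volume_ul")
  tvc(d$t_norm, d$volume_ul, rr_ms = rr_ms, bw_g = bw_g)
}

#' Read myocardial point trajectories from CSV
#'
#' Expects long-format columns `point_id`, `frame`, `x`, `y`.
#'
#' @param file CSV path.
#' @return data.frame suitable for [strain_from_trajectories()].
#' @export
read_trajectories <- function(file) {
  d <- read.csv(file)
  stop_if(!all(c("point_id", "frame", "x", "y") %in% names(d)),
          "CSV needs columns point_id, frame, x, y")
  d
}

#' Read a glucose-tolerance curve from CSV
#'
#' Expects columns `time_min` and `glucose_mgdl`.
#'
#' @param file CSV path.
#' @return A `"gtt_curve"` data.frame.
#' @export
read_gtt <- function(file) {
  d <- read.csv(file)
  stop_if(!all(c("time_min", "glucose_mgdl") %in% names(d)),
          "CSV needs columns time_min, glucose_mgdl")
  structure(data.frame(time_min = d$time_min, glucose_mgdl = d$glucose_mgdl),
            class = c("gtt_curve", "data.frame"))
}

#' Write a delta-T1 course to CSV plus a JSON summary
#'
#' The CSV holds the course (`time_min`, `delta_t1_pct`); the JSON sidecar
#' holds `baseline_t1_ms` and `cumulative_delta_t1`.
#'
#' @param course a [delta_t1_course()] object.
#' @param csv_file,json_file output paths; either may be `NULL` to skip.
#' @return The course, invisibly.
#' @export
write_delta_t1_course <- function(course, csv_file, json_file = NULL) {
  stop_if(!inherits(course, "delta_t1_course"), "'course' must be a delta_t1_course")
  if (!is.null(csv_file))
    write.csv(data.frame(time_min = course$times_min,
                         delta_t1_pct = course$delta_t1_pct),
              csv_file, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(
      list(baseline_t1_ms = course$baseline_t1_ms,
           cumulative_delta_t1 = cumulative_delta_t1(course)),
      json_file, auto_unbox = TRUE, digits = NA)
  invisible(course)
}

#' Write a cohort report to JSON
#'
#' @param report a [build_report()] object.
#' @param file output path.
#' @return The report, invisibly.
#' @export
write_report_json <- function(report, file) {
  stop_if(!inherits(report, "cohort_report"), "'report' must be a cohort_report")
  jsonlite::write_json(report$table, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
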