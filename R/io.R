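#' Read a patient-level CEA dataset
#'
#' The on-disk format is delimited text: a main table with header columns
#' `patient_id`, `arm`, `followup`, `event` and either a cumulative `cost`
#' column or per-interval columns `cost_1 .. cost_K`, plus optional covariate
#' and `subgroup` columns; and an optional long-format quality-of-life
#' companion table with columns `patient_id`, `time`, `score`. Malformed
#' input produces an error naming the missing column or offending line.
#'
#' @param path Path to the main CSV table.
#' @param qol_path Optional path to the QoL long table.
#' @return An object of class `cea_data`: list with `records` (data frame)
#'   and `qol` (data frame or `NULL`).
#' @export
read_dataset <- function(path, qol_path = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "followup", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stopf("missing required column(s) in %s: %s", path,
           paste(miss, collapse = ", "))
  has_cost <- "cost" %in% names(records) ||
    any(grepl("^cost_[0-9]+$", names(records)))
  if (!has_cost)
    .stopf("missing cost column(s) in %s: need `cost` or `cost_1..cost_K`", path)
  bad <- which(!records$event %in% c(0, 1))
  if (length(bad))
    .stopf("invalid `event` value at data line(s) %s of %s (must be 0/1)",
           paste(utils::head(bad + 1L, 5), collapse = ", "), path)
  qol <- NULL
  if (!is.null(qol_path)) {
    if (!file.exists(qol_path)) .stopf("no such file: %s", qol_path)
    qol <- utils::read.csv(qol_path, stringsAsFactors = FALSE)
    qmiss <- setdiff(c("patient_id", "time", "score"), names(qol))
    if (length(qmiss))
      .stopf("missing required column(s) in %s: %s", qol_path,
             paste(qmiss, collapse = ", "))
  }
  structure(list(records = records, qol = qol), class = "cea_data")
}

#' Write a patient-level CEA dataset
#'
#' Inverse of [read_dataset()]; the round trip is lossless up to numeric
#' printing precision (15 significant digits).
#'
#' @param data A `cea_data` object, or a data frame of records.
#' @param path Path for the main table.
#' @param qol_path Optional path for the QoL long table.
#' @export
write_dataset <- function(data, path, qol_path = NULL) {
  records <- if (inherits(data, "cea_data")) data$records else data
  utils::write.csv(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(qol_path) && inherits(data, "cea_data") && !is.null(data$qol)) {
    utils::write.csv(format(data$qol, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     qol_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Quality-adjust the records of a dataset
#'
#' Builds adjusted records from a dataset with QoL trajectories: for each
#' patient the utility path is integrated to the quality-adjusted follow-up
#' time (and per-interval pieces when a grid is given).
#'
#' @param data A `cea_data` with a non-`NULL` `qol` table.
#' @param grid Optional [time_grid()].
#' @return The records data frame with columns `t_adj` (and matrix attribute
#'   `q` of per-interval pieces when a grid is given).
#' @export
adjusted_records <- function(data, grid = NULL) {
  stopifnot(inherits(data, "cea_data"))
  if (is.null(data$qol)) .stopf("dataset has no quality-of-life table")
  rec <- data$records
  qlist <- lapply(seq_len(nrow(rec)), function(i) {
    pid <- rec$patient_id[i]
    qi <- data$qol[data$qol$patient_id == pid, , drop = FALSE]
    if (nrow(qi) == 0L)
      .stopf("patient %s has no quality-of-life measurements", pid)
    traj <- qol_trajectory(qi$time, qi$score, rec$followup[i], rec$event[i])
    adjust_time(traj, grid)
  })
  rec$t_adj <- vapply(qlist, `[[`, numeric(1), "t_adj")
  if (!is.null(grid))
    attr(rec, "q") <- do.call(rbind, lapply(qlist, `[[`, "q"))
  rec
}
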