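#' Per-trial event table
#'
#' One row per trial: participant id, stimulus onset sample, response sample
#' (NA for trials without a response), RT in seconds, and the eight
#' behavioural measures (chosen value, unchosen value, value difference,
#' overall value, set salience, anxiety, liking, confidence). Additional
#' per-trial columns (e.g. construct scores) are carried through untouched.
#'
#' Invariants checked: `response_sample > stimulus_sample` where present;
#' `rt == (response_sample - stimulus_sample) / srate` within one sample;
#' `value_difference >= 0`.
#'
#' @param df data frame with at least `participant_id`, `stimulus_sample`,
#'   `response_sample`, `rt`.
#' @param srate sampling rate (Hz) the sample indices refer to.
#' @return data frame of class `event_table` with attribute `srate`.
#' @export
event_table <- function(df, srate) {
  need <- c("participant_id", "stimulus_sample", "response_sample", "rt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("event table misses columns: ",
                          paste(miss, collapse = ", "))
  has_resp <- !is.na(df$response_sample)
  if (any(df$response_sample[has_resp] <= df$stimulus_sample[has_resp]))
    stop2("response_sample must exceed stimulus_sample")
  rt_samp <- (df$response_sample - df$stimulus_sample) / srate
  bad <- has_resp & abs(rt_samp - df$rt) > 1 / srate + 1e-9
  if (any(bad))
    stop2(sum(bad), " trial(s) with rt inconsistent with sample indices")
  if ("value_difference" %in% names(df) &&
      any(df$value_difference < -1e-9, na.rm = TRUE))
    stop2("value_difference must be non-negative")
  structure(as.data.frame(df), srate = srate,
            class = c("event_table", "data.frame"))
}

measure_names <- function() {
  c("chosen_value", "unchosen_value", "value_difference", "overall_value",
    "set_salience", "anxiety", "liking", "confidence")
}

#' Write / read an event table as TSV
#'
#' Event times are stored both in samples and in seconds
#' (`stimulus_time`, `response_time`); on reading, the sample columns are
#' authoritative.
#'
#' @param events an [event_table()].
#' @param path file path.
#' @export
write_event_table <- function(events, path) {
  srate <- attr(events, "srate")
  out <- as.data.frame(events)
  out$stimulus_time <- out$stimulus_sample / srate
  out$response_time <- out$response_sample / srate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# srate=%s", format(srate)), con)
  write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# srate=", first)) stop2("missing '# srate=' header line")
  srate <- as.numeric(sub("^# srate=", "", first))
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  df$stimulus_time <- NULL; df$response_time <- NULL
  event_table(df, srate)
}
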