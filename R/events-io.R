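fmt_num <- function(x) {
  # %.17g round-trips doubles exactly, so write -> read -> write is
  # byte-identical
  sprintf("%.17g", x)
}

check_event_table <- function(t) {
  need <- c("event_id", "sample_id", "ref_intensity", "rep_intensity")
  if (!is.data.frame(t) || !all(need %in% names(t))) {
    stop("expected an event table with columns ",
         paste(need, collapse = ", "))
  }
  invisible(t)
}

#' Write an event table as CSV
#'
#' Plain CSV dialect: header
#' \code{event_id,sample_id,ref_intensity,rep_intensity}, UTF-8, '.'
#' decimal, no quoting. Intensities are written with 17 significant digits
#' so that [read_events()] round-trips bit-exactly.
#'
#' @param t event table (see [simulate_events()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(t, path) {
  check_event_table(t)
  lines <- c("event_id,sample_id,ref_intensity,rep_intensity",
             if (nrow(t)) paste(t$event_id, t$sample_id,
                                fmt_num(t$ref_intensity),
                                fmt_num(t$rep_intensity), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path file written by [write_events()] (or any CSV with the same
#'   header).
#' @return An event table data frame.
#' @export
read_events <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(event_id = "integer",
                                      sample_id = "character",
                                      ref_intensity = "numeric",
                                      rep_intensity = "numeric"))
  check_event_table(t)
}
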