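#' Write a synthetic cohort to plain-text files
#'
#' Emits the standard on-disk layout: `patients.csv`, `notes.csv` (note
#' manifest: note id, patient, ISO-8601 date, word count), `corpus.tsv`
#' (two columns: note id, space-separated words), `events.csv`
#' (`patient_id,event_date,system,code`), `truth.csv` and `gem.txt`
#' (tab-delimited crosswalk).
#'
#' @param cohort an `ehr_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  utils::write.csv(cohort$patients, f("patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$notes[, c("note_id", "patient_id", "note_date",
                                    "word_count")],
                   f("notes.csv"), row.names = FALSE)
  text <- vapply(cohort$tokens, function(ids) {
    paste(cohort$vocab[ids], collapse = " ")
  }, character(1))
  utils::write.table(data.frame(note_id = names(cohort$tokens), text = text),
                     f("corpus.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(cohort$events, f("events.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, f("truth.csv"), row.names = FALSE)
  write_gem_file(cohort$gem, f("gem.txt"))
  invisible(dir)
}

#' Read a structured event table
#'
#' @param path CSV with header `patient_id,event_date,system,code` and
#'   ISO-8601 dates.
#' @return data frame with `event_date` parsed as `Date`.
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       event_date = "character",
                                       system = "character",
                                       code = "character"))
  ev$event_date <- as.Date(ev$event_date)
  if (anyNA(ev$event_date)) stop("undated events in ", path, call. = FALSE)
  ev
}
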