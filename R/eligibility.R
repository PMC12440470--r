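#' Check cohort eligibility for a single patient
#'
#' Applies the case/control eligibility rules to one patient's dated events
#' and notes. Cases must have a first dementia diagnosis code after age 65
#' and at least two other note-bearing visits in each lookback year before
#' that first diagnosis. Controls must have no dementia code at all, no fill
#' of donepezil, galantamine, rivastigmine or memantine, and at least
#' `lookback_years` consecutive years ending at the index date each holding
#' two or more note-bearing visits, all after age 62.
#'
#' @param patient one-row data frame (or list) with `label`, `age_at_index`
#'   and `index_date`.
#' @param events data frame of this patient's events
#'   (`event_date`, `system`, `code`).
#' @param notes data frame of this patient's notes (`note_date`).
#' @param config a [cohort_config()] (supplies `lookback_years`).
#' @return a list with `pass` (logical), `reason` (character, `""` on pass)
#'   and `flags` (character vector; contains `"window_starts_before_65"`
#'   when the control lookback window opens before age 65).
#' @export
check_eligibility <- function(patient, events, notes, config) {
  if (nrow(events) > 0 && anyNA(events$event_date)) {
    stop("malformed input: undated events", call. = FALSE)
  }
  if (nrow(notes) > 0 && anyNA(notes$note_date)) {
    stop("malformed input: undated notes", call. = FALSE)
  }
  lb <- config$lookback_years
  dc <- dementia_codes()
  norm <- function(x) toupper(gsub("[.[:space:]]", "", x))
  dem9 <- norm(dc$icd9)
  dem10 <- norm(dc$icd10)
  is_dem <- (events$system == "ICD9" & norm(events$code) %in% dem9) |
    (events$system == "ICD10" & norm(events$code) %in% dem10)
  visit_dates <- unique(notes$note_date)
  flags <- character(0)

  fail <- function(reason) list(pass = FALSE, reason = reason, flags = flags)

  if (identical(patient$label, "case")) {
    if (!any(is_dem)) return(fail("case without dementia code"))
    d0 <- min(events$event_date[is_dem])
    age_d0 <- patient$age_at_index +
      as.numeric(d0 - patient$index_date) / 365.25
    if (age_d0 < 65) return(fail("first dementia code before age 65"))
    dem_dates <- unique(events$event_date[is_dem])
    ok_dates <- setdiff(visit_dates, dem_dates)
    for (j in seq_len(lb)) {
      lo <- d0 - j * 365L
      hi <- d0 - (j - 1L) * 365L
      nvis <- sum(ok_dates >= lo & ok_dates < hi)
      if (nvis < 2) {
        return(fail(sprintf("fewer than 2 qualifying visits in lookback year %d", j)))
      }
    }
    return(list(pass = TRUE, reason = "", flags = flags))
  }

  ## control
  if (any(is_dem)) return(fail("control with dementia code"))
  if (any(events$system == "MED" &
            toupper(trimws(events$code)) %in% excluded_medications())) {
    return(fail("control filled an excluded dementia medication"))
  }
  idx <- patient$index_date
  age_start <- patient$age_at_index - lb
  if (age_start < 62) return(fail("qualifying window starts before age 62"))
  if (age_start < 65) flags <- c(flags, "window_starts_before_65")
  for (j in seq_len(lb)) {
    lo <- idx - j * 365L
    hi <- idx - (j - 1L) * 365L
    nvis <- sum(visit_dates >= lo & visit_dates < hi)
    if (nvis < 2) {
      return(fail(sprintf("fewer than 2 note-bearing visits in lookback year %d", j)))
    }
  }
  list(pass = TRUE, reason = "", flags = flags)
}

#' Write a GEM-style crosswalk file
#'
#' Writes an ICD-9 to ICD-10 edge list as a headerless tab-delimited file
#' (`icd9<TAB>icd10`, one edge per line), mirroring the layout of the
#' CMS general equivalence mapping files. Duplicate edges are dropped
#' silently (with a message).
#'
#' @param group_spec data frame with columns `icd9` and `icd10`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gem_file <- function(group_spec, path) {
  stopifnot(is.data.frame(group_spec),
            all(c("icd9", "icd10") %in% names(group_spec)) ||
              nrow(group_spec) == 0)
  if (nrow(group_spec) == 0) {
    file.create(path)
    return(invisible(path))
  }
  edges <- group_spec[, c("icd9", "icd10")]
  dup <- duplicated(edges)
  if (any(dup)) {
    message(sum(dup), " duplicate GEM edge(s) dropped")
    edges <- edges[!dup, ]
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
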