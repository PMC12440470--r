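#' Binary structured-code indicators per patient
#'
#' Converts dated structured events into per-patient binary indicators over
#' the lookback window `[index - lookback, index)`: 1 if at least one
#' qualifying event of the code occurred in the window, 0 otherwise.
#' ICD-9/ICD-10 diagnosis events are first mapped through the crosswalk
#' groups (feature names `icd_group:<id>`); other systems keep their own
#' namespaces (`cpt:`, `med:`, `notetype:`). Events outside the window are
#' ignored (a message reports how many).
#'
#' @param events data frame (`patient_id`, `event_date`, `system`, `code`).
#' @param groups a [decompose_gem()] result for the diagnosis crosswalk.
#' @param patients data frame with `patient_id` and `index_date`;
#'   indicators are produced for exactly these patients, in this order.
#' @param lookback_years window length in years.
#' @return binary matrix (patients x observed features), column names
#'   namespaced, patient ids as row names.
#' @export
binarize_structured <- function(events, groups, patients,
                                lookback_years = 3) {
  stopifnot(all(c("patient_id", "index_date") %in% names(patients)))
  idx <- patients$index_date
  names(idx) <- patients$patient_id
  ev <- events[events$patient_id %in% patients$patient_id, , drop = FALSE]
  pidx <- idx[ev$patient_id]
  lo <- pidx - round(lookback_years * 365.25)
  in_window <- ev$event_date >= lo & ev$event_date < pidx
  if (any(!in_window)) {
    message(sum(!in_window), " event(s) outside the lookback window ignored")
  }
  ev <- ev[in_window, , drop = FALSE]

  feat <- character(nrow(ev))
  is_icd <- ev$system %in% c("ICD9", "ICD10")
  if (any(is_icd)) {
    feat[is_icd] <- paste0("icd_group:", map_events(ev[is_icd, ], groups))
  }
  other <- !is_icd
  if (any(other)) {
    feat[other] <- paste0(tolower(ev$system[other]), ":", ev$code[other])
  }

  cols <- sort(unique(feat))
  out <- matrix(0L, nrow(patients), length(cols),
                dimnames = list(patients$patient_id, cols))
  if (nrow(ev) > 0) {
    out[cbind(match(ev$patient_id, patients$patient_id), match(feat, cols))] <- 1L
  }
  out
}

#' Select structured features by training support
#'
#' Retains a structured binary feature iff it is present in at least
#' `min_support` patients of the training stratum. Selection is computed on
#' training data only; the retained column set then defines the schema for
#' any other sample. Topic and demographic features are not subject to this
#' filter (they are always kept by [assemble_features()]).
#'
#' @param binary_matrix training-stratum output of [binarize_structured()].
#' @param min_support minimum number of supporting patients (default 10).
#' @return character vector of retained feature names, sorted.
#' @export
select_features <- function(binary_matrix, min_support = 10) {
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  sort(colnames(binary_matrix)[colSums(binary_matrix) >= min_support])
}

#' Assemble the per-patient feature matrix
#'
#' Joins demographics (`demo:age`, standardised by the training mean/SD;
#' `demo:sex`, male = 1), stable-topic presence values (`topic:<id>`) and
#' the selected structured indicators into one numeric matrix, one row per
#' patient, columns sorted by namespace then name. Structured columns
#' missing for a patient sample (e.g. a validation sample lacking a
#' training-selected code) are imputed as 0. Columns that are identically
#' zero are dropped with a message, so the returned matrix never carries an
#' all-zero feature; the resulting column set is recorded and re-applied
#' when `schema` is supplied.
#'
#' @param patients data frame with `patient_id`, `age_at_index`, `sex`.
#' @param presences patients x topics matrix from [patient_topic_presence()].
#' @param binary patients x codes matrix from [binarize_structured()].
#' @param selection retained structured names from [select_features()].
#' @param age_stats `NULL` to standardise age by this sample's own mean/SD
#'   (training), or the `age_stats` attribute of a training feature matrix.
#' @param schema `NULL`, or the `feature_names` of a training feature
#'   matrix, to force an identical column set (validation).
#' @return numeric matrix with attributes `age_stats` and `feature_names`;
#'   class `feature_matrix`.
#' @export
assemble_features <- function(patients, presences, binary, selection,
                              age_stats = NULL, schema = NULL) {
  pid <- patients$patient_id
  if (!all(pid %in% rownames(presences))) {
    stop("patient missing topic presence vector", call. = FALSE)
  }
  presences <- presences[pid, , drop = FALSE]
  if (ncol(presences) > 0) {
    colnames(presences) <- paste0("topic:", colnames(presences))
  }

  if (is.null(age_stats)) {
    age_stats <- c(mean = mean(patients$age_at_index),
                   sd = stats::sd(patients$age_at_index))
    if (!is.finite(age_stats["sd"]) || age_stats["sd"] == 0) age_stats["sd"] <- 1
  }
  demo <- cbind(`demo:age` = (patients$age_at_index - age_stats["mean"]) / age_stats["sd"],
                `demo:sex` = as.numeric(patients$sex == "M"))
  rownames(demo) <- pid

  sel <- intersect(selection, colnames(binary))
  struct <- matrix(0, length(pid), length(selection),
                   dimnames = list(pid, selection))
  if (length(sel) > 0) {
    avail <- rownames(binary)[rownames(binary) %in% pid]
    struct[avail, sel] <- binary[avail, sel]
  }

  x <- cbind(demo, presences, struct)
  x <- x[, order(colnames(x)), drop = FALSE]

  if (is.null(schema)) {
    zero <- colSums(abs(x)) == 0
    if (any(zero)) {
      message(sum(zero), " all-zero feature column(s) dropped: ",
              paste(utils::head(colnames(x)[zero], 5), collapse = ", "))
      x <- x[, !zero, drop = FALSE]
    }
  } else {
    miss <- setdiff(schema, colnames(x))
    if (length(miss) > 0) {
      add <- matrix(0, length(pid), length(miss),
                    dimnames = list(pid, miss))
      x <- cbind(x, add)
    }
    x <- x[, schema, drop = FALSE]
  }
  structure(x, age_stats = age_stats, feature_names = colnames(x),
            class = c("feature_matrix", class(x)))
}

#' Feature counts per namespace
#'
#' @param x a [assemble_features()] matrix.
#' @return named integer vector of column counts by namespace; sums to
#'   `ncol(x)`.
#' @export
feature_counts <- function(x) {
  ns <- sub(":.*$", "", colnames(x))
  table(factor(ns))
}
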