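#' Configuration for the synthetic EHR cohort generator
#'
#' Bundles every knob of the synthetic cohort: sample sizes per race stratum,
#' the ICD-9 to ICD-10 transition date, the lookback window, the planted
#' topic model that generates note text, the latent undiagnosed-dementia
#' prevalence among validation controls, and the structured-code universe.
#'
#' The generator emulates a case-control phenotyping study: cases carry a
#' first dementia diagnosis code at their index date after age 65, controls
#' never carry one, and every patient has at least two note-bearing visits in
#' each year of the lookback window. Notes are drawn from a latent Dirichlet
#' allocation generative process over a shared vocabulary; notes of cases and
#' of latent-positive validation controls upweight the designated signal
#' topics, and their visits carry elevated probabilities of a configured set
#' of risk codes.
#'
#' @param n_cases number of training cases per race stratum.
#' @param n_controls number of training controls per race stratum.
#' @param n_validation_controls number of validation controls per race
#'   stratum; these receive a latent truth label used only for validation.
#' @param race_strata character vector of stratum labels; generation and all
#'   downstream modelling are run independently per stratum.
#' @param transition_date `Date`; diagnosis events strictly before this date
#'   are coded ICD-9, events on or after it ICD-10 (half-open convention).
#' @param lookback_years length of the feature window ending at (and
#'   excluding) the index date.
#' @param vocab_size,n_topics_true size of the synthetic vocabulary and
#'   number of planted topics.
#' @param signal_topic_ids indices (into the planted topics) of the
#'   dementia-signal topics enriched in cases and latent-positive controls.
#' @param latent_prevalence fraction of validation controls carrying the
#'   latent dementia signal.
#' @param notes_per_year mean note-bearing visits per patient-year (each year
#'   always gets at least 2, so eligibility holds by construction).
#' @param note_length_range inclusive range of note lengths in tokens.
#' @param prop_male probability a patient is male.
#' @param alpha_background,alpha_signal_neg,alpha_signal_pos Dirichlet prior
#'   weights for the per-note topic mixture: background topics always get
#'   `alpha_background`; signal topics get `alpha_signal_neg` in signal-free
#'   patients (dementia vocabulary essentially absent) and `alpha_signal_pos`
#'   in cases/latent positives.
#' @param topic_word_conc Dirichlet concentration for the planted topic-word
#'   distributions (small values give well-separated sparse topics).
#' @param n_icd_groups,n_cpt,n_med,n_notetype sizes of the structured-code
#'   universes (ICD groups are planted GEM components).
#' @param risk_icd_groups,risk_cpt,risk_med indices of the structured codes
#'   whose per-visit probability is elevated in signal patients.
#' @param p_risk_base,p_risk_elevated per-visit probability of each risk code
#'   in signal-free vs signal patients.
#' @param seed integer seed controlling all randomness in the generator.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_cases = 1000L,
                          n_controls = 1000L,
                          n_validation_controls = 2000L,
                          race_strata = "BA",
                          transition_date = as.Date("2015-10-01"),
                          lookback_years = 3L,
                          vocab_size = 500L,
                          n_topics_true = 20L,
                          signal_topic_ids = 1:3,
                          latent_prevalence = 0.04,
                          notes_per_year = 13,
                          note_length_range = c(50L, 200L),
                          prop_male = 0.97,
                          alpha_background = 0.3,
                          alpha_signal_neg = 0.01,
                          alpha_signal_pos = 1.0,
                          topic_word_conc = 0.05,
                          n_icd_groups = 60L,
                          n_cpt = 40L,
                          n_med = 30L,
                          n_notetype = 10L,
                          risk_icd_groups = 1:5,
                          risk_cpt = 1:3,
                          risk_med = 1:2,
                          p_risk_base = 0.02,
                          p_risk_elevated = 0.15,
                          seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_validation_controls = as.integer(n_validation_controls),
    race_strata = as.character(race_strata),
    transition_date = as.Date(transition_date),
    lookback_years = as.integer(lookback_years),
    vocab_size = as.integer(vocab_size),
    n_topics_true = as.integer(n_topics_true),
    signal_topic_ids = as.integer(signal_topic_ids),
    latent_prevalence = latent_prevalence,
    notes_per_year = notes_per_year,
    note_length_range = as.integer(note_length_range),
    prop_male = prop_male,
    alpha_background = alpha_background,
    alpha_signal_neg = alpha_signal_neg,
    alpha_signal_pos = alpha_signal_pos,
    topic_word_conc = topic_word_conc,
    n_icd_groups = as.integer(n_icd_groups),
    n_cpt = as.integer(n_cpt),
    n_med = as.integer(n_med),
    n_notetype = as.integer(n_notetype),
    risk_icd_groups = as.integer(risk_icd_groups),
    risk_cpt = as.integer(risk_cpt),
    risk_med = as.integer(risk_med),
    p_risk_base = p_risk_base,
    p_risk_elevated = p_risk_elevated,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot_config(cfg$n_cases > 0, "n_cases must be > 0")
  stopifnot_config(cfg$n_controls > 0, "n_controls must be > 0")
  stopifnot_config(cfg$n_validation_controls > 0,
                   "n_validation_controls must be > 0")
  stopifnot_config(length(cfg$race_strata) >= 1 &&
                     !anyDuplicated(cfg$race_strata),
                   "race_strata must be non-empty and unique")
  stopifnot_config(cfg$lookback_years >= 1, "lookback_years must be >= 1")
  stopifnot_config(cfg$latent_prevalence >= 0 && cfg$latent_prevalence <= 1,
                   "latent_prevalence must lie in [0, 1]")
  stopifnot_config(cfg$vocab_size >= 10, "vocab_size must be >= 10")
  stopifnot_config(cfg$n_topics_true >= 2, "n_topics_true must be >= 2")
  stopifnot_config(all(cfg$signal_topic_ids >= 1) &&
                     all(cfg$signal_topic_ids <= cfg$n_topics_true),
                   "signal_topic_ids out of range")
  stopifnot_config(cfg$notes_per_year >= 2,
                   "notes_per_year must be >= 2 for eligibility")
  stopifnot_config(length(cfg$note_length_range) == 2 &&
                     cfg$note_length_range[1] >= 1 &&
                     diff(cfg$note_length_range) >= 0,
                   "note_length_range must be an increasing pair")
  stopifnot_config(cfg$alpha_background > 0 && cfg$alpha_signal_neg > 0 &&
                     cfg$alpha_signal_pos > 0 && cfg$topic_word_conc > 0,
                   "Dirichlet parameters must be positive")
  stopifnot_config(all(cfg$risk_icd_groups <= cfg$n_icd_groups) &&
                     all(cfg$risk_cpt <= cfg$n_cpt) &&
                     all(cfg$risk_med <= cfg$n_med),
                   "risk code indices out of range")
  stopifnot_config(cfg$p_risk_base >= 0 && cfg$p_risk_base <= 1 &&
                     cfg$p_risk_elevated >= 0 && cfg$p_risk_elevated <= 1,
                   "risk probabilities must lie in [0, 1]")
  stopifnot_config(is.finite(cfg$seed), "seed must be a finite integer")
  invisible(cfg)
}

stopifnot_config <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid cohort configuration: ", msg, call. = FALSE)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  strata: %s | per stratum: %d cases, %d controls, %d validation controls\n",
              paste(x$race_strata, collapse = ", "),
              x$n_cases, x$n_controls, x$n_validation_controls))
  cat(sprintf("  lookback %d y ending at index; ICD transition %s\n",
              x$lookback_years, format(x$transition_date)))
  cat(sprintf("  topics: %d planted (signal: %s), vocab %d; latent prevalence %.3f\n",
              x$n_topics_true, paste(x$signal_topic_ids, collapse = ","),
              x$vocab_size, x$latent_prevalence))
  invisible(x)
}

# Medications whose fill excludes a patient from the control pool
# (cholinesterase inhibitors and memantine).
excluded_medications <- function() {
  c("DONEPEZIL", "GALANTAMINE", "RIVASTIGMINE", "MEMANTINE")
}

# Dementia diagnosis codes used by the generator and the eligibility check.
dementia_codes <- function() {
  list(icd9 = c("290.0", "290.40", "331.0"),
       icd10 = c("F01.50", "F03.90", "G30.9"))
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so the generator does not perturb the session.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
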