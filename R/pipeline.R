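#' Run the full phenotyping pipeline on a synthetic cohort
#'
#' End-to-end driver: generates (or accepts) a cohort, learns three
#' independently seeded LDA runs on a note subsample, infers topic loads for
#' every note, extracts stable topics and patient presence values, builds
#' the feature matrix (demographics + topic presences + supported structured
#' indicators), trains the race-stratified linear max-margin model with cost
#' selection by cross-validated AUC, and scores the validation controls with
#' percentiles on the full validation stratum.
#'
#' Run `r` of the three topic runs uses seed `seed + r`; topic learning uses
#' at most `learn_notes` notes sampled from the whole corpus (the inference
#' step then covers every note), mirroring the usual practice of learning
#' topics on a subsample of a large note corpus.
#'
#' @param config a [cohort_config()].
#' @param K number of topics per LDA run.
#' @param lda_iter Gibbs sweeps for topic learning.
#' @param learn_notes maximum number of notes used for topic learning.
#' @param infer_sweeps Gibbs sweeps per note at inference.
#' @param similarity_threshold cosine threshold for stable-topic matching.
#' @param params [presence_params()] for the presence function.
#' @param min_support structured-feature support filter (training stratum).
#' @param spec [svm_spec()] for cost selection.
#' @param cohort optionally, a pre-generated `ehr_cohort` (must match
#'   `config`); generated from `config` when `NULL`.
#' @return list with the `cohort`, the `stable` topics, and per-stratum
#'   results: `model`, `features_train`, `val_scores` (data frame with
#'   `patient_id`, `score`, `percentile`, `latent_truth`).
#' @export
run_phenotyping_pipeline <- function(config, K = 30, lda_iter = 150L,
                                     learn_notes = 20000L,
                                     infer_sweeps = 20L,
                                     similarity_threshold = 0.8,
                                     params = presence_params(),
                                     min_support = 10,
                                     spec = svm_spec(seed = config$seed),
                                     cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  corpus <- note_corpus(cohort$tokens, cohort$vocab)

  ## three topic runs on a learning subsample, inference on every note
  n_learn <- min(learn_notes, length(corpus$tokens))
  sub <- with_local_seed(derive_seed(config$seed, 7L), {
    sort(sample.int(length(corpus$tokens), n_learn))
  })
  learn_corpus <- note_corpus(corpus$tokens[sub], corpus$vocab)
  runs <- lapply(1:3, function(r) {
    learn_topics(learn_corpus, K = K, seed = config$seed + r,
                 n_iter = lda_iter)
  })
  loads <- lapply(1:3, function(r) {
    infer_loads(runs[[r]], corpus, n_sweeps = infer_sweeps,
                seed = derive_seed(config$seed, 10L + r))
  })
  stable <- extract_stable_topics(runs, similarity_threshold)
  if (nrow(stable$members) == 0) {
    stop("no stable topics extracted; lower similarity_threshold or raise lda_iter",
         call. = FALSE)
  }
  spwc <- stable_pwc(stable, loads)
  note_pid <- cohort$notes$patient_id[match(corpus$note_ids,
                                            cohort$notes$note_id)]
  presence_all <- patient_topic_presence(spwc, note_pid, params)

  groups <- decompose_gem(gem_graph(cohort$gem))

  strata <- unique(cohort$patients$race_stratum)
  per_stratum <- lapply(strata, function(st) {
    pats <- cohort$patients[cohort$patients$race_stratum == st, ]
    train <- pats[pats$cohort == "training", ]
    val <- pats[pats$cohort == "validation", ]

    bin_train <- binarize_structured(cohort$events, groups, train,
                                     config$lookback_years)
    selection <- select_features(bin_train, min_support)
    x_train <- assemble_features(train, presence_all, bin_train, selection)

    model <- train_risk_model(x_train, train$label, spec)

    bin_val <- binarize_structured(cohort$events, groups, val,
                                   config$lookback_years)
    x_val <- assemble_features(val, presence_all, bin_val, selection,
                               age_stats = attr(x_train, "age_stats"),
                               schema = attr(x_train, "feature_names"))
    s_val <- score_patients(model, x_val)
    val_scores <- data.frame(
      patient_id = val$patient_id,
      score = unname(s_val),
      percentile = score_percentile(s_val),
      latent_truth = val$latent_truth,
      stringsAsFactors = FALSE
    )
    list(stratum = st, model = model, features_train = x_train,
         train_scores = data.frame(patient_id = train$patient_id,
                                   score = unname(score_patients(model, x_train)),
                                   label = train$label,
                                   stringsAsFactors = FALSE),
         val_scores = val_scores)
  })
  names(per_stratum) <- strata

  list(cohort = cohort, runs = runs, stable = stable,
       presence = presence_all, groups = groups, strata = per_stratum)
}

#' Recovery of planted topics by the stable set
#'
#' For each planted (true) topic, the maximum cosine similarity between its
#' word distribution and any extracted stable topic.
#'
#' @param stable a [extract_stable_topics()] result.
#' @param topics_true planted topic-word matrix (e.g.
#'   `cohort$topics_true`).
#' @return numeric vector, one entry per planted topic.
#' @export
topic_recovery <- function(stable, topics_true) {
  if (nrow(stable$word_dist) == 0) return(rep(0, nrow(topics_true)))
  sims <- cosine_sim(topics_true, stable$word_dist)
  apply(sims, 1, max)
}
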