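#' Generate a synthetic EHR cohort
#'
#' Draws a complete case-control cohort — patients, dated tokenized clinical
#' notes, dated structured code events, a planted GEM crosswalk, and a latent
#' truth table for validation controls — with the statistical structure the
#' phenotyping pipeline assumes. Everything is deterministic given
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' Cases receive their first dementia diagnosis code at the index date (which
#' is excluded from the half-open feature window `[index - lookback, index)`)
#' and their notes, like those of latent-positive validation controls, are
#' drawn from a topic mixture that upweights the signal topics. Every patient
#' gets at least two note-bearing visits in each lookback year, so the whole
#' cohort passes [check_eligibility()] by construction.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `ehr_cohort`: a list with elements
#'   `patients`, `notes` (manifest), `tokens` (named list of integer word
#'   ids), `vocab`, `events`, `gem` (edge list with planted group ids),
#'   `truth` (latent truth for validation controls), `topics_true`
#'   (planted topic-word matrix) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config object", call. = FALSE)
  }
  with_local_seed(config$seed, {
    vocab <- sprintf("w%04d", seq_len(config$vocab_size))
    topics_true <- draw_true_topics(config)
    gem <- build_gem_spec(config)
    pools <- code_pools(config)

    strata <- lapply(seq_along(config$race_strata), function(si) {
      generate_stratum(config, config$race_strata[si], si, topics_true,
                       gem, pools)
    })
    patients <- do.call(rbind, lapply(strata, `[[`, "patients"))
    notes <- do.call(rbind, lapply(strata, `[[`, "notes"))
    events <- do.call(rbind, lapply(strata, `[[`, "events"))
    tokens <- do.call(c, lapply(strata, `[[`, "tokens"))
    rownames(patients) <- rownames(notes) <- rownames(events) <- NULL

    truth <- patients[patients$cohort == "validation",
                      c("patient_id", "race_stratum", "latent_truth")]
    rownames(truth) <- NULL

    out <- list(patients = patients, notes = notes, tokens = tokens,
                vocab = vocab, events = events, gem = gem, truth = truth,
                topics_true = topics_true, config = config)
    class(out) <- "ehr_cohort"
    out
  })
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>\n")
  cat(sprintf("  %d patients (%d cases / %d controls), %d notes, %d events\n",
              nrow(x$patients), sum(x$patients$label == "case"),
              sum(x$patients$label == "control"), nrow(x$notes),
              nrow(x$events)))
  cat(sprintf("  strata: %s; vocab %d; %d planted topics\n",
              paste(unique(x$patients$race_stratum), collapse = ", "),
              length(x$vocab), nrow(x$topics_true)))
  invisible(x)
}

draw_true_topics <- function(config) {
  K <- config$n_topics_true
  V <- config$vocab_size
  phi <- matrix(stats::rgamma(K * V, shape = config$topic_word_conc), K, V)
  bad <- rowSums(phi) == 0
  if (any(bad)) phi[bad, ] <- 1 / V
  phi / rowSums(phi)
}

# Planted GEM crosswalk: each group g is a small connected bipartite
# component (1-3 ICD-9 codes x 1-3 ICD-10 codes).
build_gem_spec <- function(config) {
  G <- config$n_icd_groups
  sizes9 <- sample(1:3, G, replace = TRUE, prob = c(0.55, 0.3, 0.15))
  sizes10 <- sample(1:3, G, replace = TRUE, prob = c(0.55, 0.3, 0.15))
  out <- vector("list", G)
  for (g in seq_len(G)) {
    i9 <- sprintf("%03d.%d", 99 + g, seq_len(sizes9[g]))
    i10 <- sprintf("A%02d.%d", g, seq_len(sizes10[g]))
    # star edges keep the component connected without being complete
    e <- unique(rbind(
      data.frame(icd9 = i9[1], icd10 = i10, stringsAsFactors = FALSE),
      data.frame(icd9 = i9, icd10 = i10[1], stringsAsFactors = FALSE)
    ))
    e$group <- g
    out[[g]] <- e
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

code_pools <- function(config) {
  list(cpt = sprintf("%05d", 10000 + seq_len(config$n_cpt)),
       med = sprintf("MED%03d", seq_len(config$n_med)),
       notetype = sprintf("NT%02d", seq_len(config$n_notetype)))
}

generate_stratum <- function(config, stratum, si, topics_true, gem, pools) {
  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  n_val <- config$n_validation_controls
  n <- n_case + n_ctrl + n_val

  role <- c(rep("case", n_case), rep("control_train", n_ctrl),
            rep("control_val", n_val))
  label <- ifelse(role == "case", "case", "control")
  cohort <- ifelse(role == "control_val", "validation", "training")

  # cases are older on average than controls, as in real dementia cohorts
  age <- ifelse(role == "case",
                65 + stats::rbeta(n, 1.5, 3) * 19.9,
                65 + stats::rbeta(n, 1.0, 4) * 19.9)
  sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
  index_date <- as.Date("2013-01-01") +
    sample.int(as.integer(as.Date("2018-09-12") - as.Date("2013-01-01")) + 1L,
               n, replace = TRUE) - 1L

  latent <- rep(NA_character_, n)
  latent[role == "control_train"] <- "none"
  is_val <- role == "control_val"
  latent[is_val] <- ifelse(stats::runif(sum(is_val)) < config$latent_prevalence,
                           "possible_probable", "none")

  patients <- data.frame(
    patient_id = sprintf("%s-%05d", stratum, seq_len(n)),
    race_stratum = stratum, sex = sex, age_at_index = round(age, 1),
    index_date = index_date, label = label, cohort = cohort,
    latent_truth = latent, stringsAsFactors = FALSE
  )
  signal_patient <- label == "case" | (!is.na(latent) & latent == "possible_probable")

  ## note-bearing visits: >=2 per lookback year by construction
  lb <- config$lookback_years
  lambda <- max(0, config$notes_per_year - 2)
  nv_year <- matrix(2L + stats::rpois(n * lb, lambda), n, lb)
  nv_year <- pmin(nv_year, 365L)
  visit_list <- vector("list", n)
  for (i in seq_len(n)) {
    offs <- unlist(lapply(seq_len(lb), function(j) {
      sample.int(365L, nv_year[i, j]) + (j - 1L) * 365L
    }))
    visit_list[[i]] <- sort(offs)
  }
  nv <- lengths(visit_list)
  visits <- data.frame(
    patient_id = rep(patients$patient_id, nv),
    date = rep(index_date, nv) - unlist(visit_list),
    signal = rep(signal_patient, nv),
    stringsAsFactors = FALSE
  )
  D <- nrow(visits)

  ## notes: one per visit, LDA generative process
  K <- config$n_topics_true
  alpha_neg <- rep(config$alpha_background, K)
  alpha_neg[config$signal_topic_ids] <- config$alpha_signal_neg
  alpha_pos <- rep(config$alpha_background, K)
  alpha_pos[config$signal_topic_ids] <- config$alpha_signal_pos
  shape <- matrix(rep(alpha_neg, each = D), D, K)
  if (any(visits$signal)) {
    shape[visits$signal, ] <- matrix(rep(alpha_pos, each = sum(visits$signal)),
                                     sum(visits$signal), K)
  }
  theta <- matrix(stats::rgamma(D * K, shape = shape), D, K)
  rs <- rowSums(theta)
  zero <- rs == 0
  if (any(zero)) { theta[zero, ] <- 1; rs[zero] <- K }
  theta <- theta / rs

  lens <- sample(seq(config$note_length_range[1], config$note_length_range[2]),
                 D, replace = TRUE)
  cseed <- derive_seed(config$seed, 100L + si)
  drawn <- cpp_sample_notes(theta, topics_true, lens,
                            config$signal_topic_ids, cseed)
  note_id <- sprintf("%s-N%07d", stratum, seq_len(D))
  tokens <- drawn$tokens
  names(tokens) <- note_id
  notes <- data.frame(
    note_id = note_id, patient_id = visits$patient_id,
    note_date = visits$date, word_count = lens,
    signal_tokens = drawn$signal_tokens, stringsAsFactors = FALSE
  )

  ## structured events
  events <- generate_events(config, patients, visits, gem, pools)

  list(patients = patients, notes = notes, tokens = tokens, events = events)
}

generate_events <- function(config, patients, visits, gem, pools) {
  D <- nrow(visits)
  G <- config$n_icd_groups
  tdate <- config$transition_date
  grp9 <- split(gem$icd9, gem$group)
  grp10 <- split(gem$icd10, gem$group)
  grp9 <- lapply(grp9, unique)
  grp10 <- lapply(grp10, unique)

  pick_icd <- function(gid, date) {
    era9 <- date < tdate
    code <- character(length(gid))
    for (i in seq_along(gid)) {
      pool <- if (era9[i]) grp9[[gid[i]]] else grp10[[gid[i]]]
      code[i] <- pool[sample.int(length(pool), 1L)]
    }
    data.frame(event_date = date,
               system = ifelse(era9, "ICD9", "ICD10"),
               code = code, stringsAsFactors = FALSE)
  }

  ev <- list()
  ## background diagnoses: 1 + Pois(0.6) uniform group draws per visit
  ndiag <- 1L + stats::rpois(D, 0.6)
  gid <- sample.int(G, sum(ndiag), replace = TRUE)
  dd <- rep(visits$date, ndiag)
  pid <- rep(visits$patient_id, ndiag)
  diag_bg <- cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
                   pick_icd(gid, dd))
  ev[[length(ev) + 1L]] <- diag_bg

  ## elevated risk diagnoses
  p_risk <- ifelse(visits$signal, config$p_risk_elevated, config$p_risk_base)
  for (g in config$risk_icd_groups) {
    hit <- stats::runif(D) < p_risk
    if (any(hit)) {
      ev[[length(ev) + 1L]] <- cbind(
        data.frame(patient_id = visits$patient_id[hit],
                   stringsAsFactors = FALSE),
        pick_icd(rep(g, sum(hit)), visits$date[hit]))
    }
  }

  flat_event <- function(pid, date, system, code) {
    data.frame(patient_id = pid, event_date = date, system = system,
               code = code, stringsAsFactors = FALSE)
  }

  ## procedures
  ncpt <- stats::rpois(D, 0.8)
  ev[[length(ev) + 1L]] <- flat_event(
    rep(visits$patient_id, ncpt), rep(visits$date, ncpt), "CPT",
    pools$cpt[sample.int(length(pools$cpt), sum(ncpt), replace = TRUE)])
  for (j in config$risk_cpt) {
    hit <- stats::runif(D) < p_risk
    if (any(hit)) {
      ev[[length(ev) + 1L]] <- flat_event(visits$patient_id[hit],
                                          visits$date[hit], "CPT",
                                          pools$cpt[j])
    }
  }

  ## medication fills (the control-excluding drugs are never generated)
  nmed <- stats::rpois(D, 0.3)
  ev[[length(ev) + 1L]] <- flat_event(
    rep(visits$patient_id, nmed), rep(visits$date, nmed), "MED",
    pools$med[sample.int(length(pools$med), sum(nmed), replace = TRUE)])
  for (j in config$risk_med) {
    hit <- stats::runif(D) < p_risk
    if (any(hit)) {
      ev[[length(ev) + 1L]] <- flat_event(visits$patient_id[hit],
                                          visits$date[hit], "MED",
                                          pools$med[j])
    }
  }

  ## note types: one per visit
  ev[[length(ev) + 1L]] <- flat_event(
    visits$patient_id, visits$date, "NOTETYPE",
    pools$notetype[sample.int(length(pools$notetype), D, replace = TRUE)])

  ## first dementia diagnosis at the index date (cases only; this event is
  ## outside the half-open feature window)
  cases <- patients[patients$label == "case", ]
  if (nrow(cases) > 0) {
    dc <- dementia_codes()
    era9 <- cases$index_date < tdate
    code <- ifelse(era9,
                   dc$icd9[sample.int(length(dc$icd9), nrow(cases), replace = TRUE)],
                   dc$icd10[sample.int(length(dc$icd10), nrow(cases), replace = TRUE)])
    ev[[length(ev) + 1L]] <- flat_event(cases$patient_id, cases$index_date,
                                        ifelse(era9, "ICD9", "ICD10"), code)
  }

  out <- do.call(rbind, ev)
  out <- out[order(out$patient_id, out$event_date, out$system, out$code), ]
  rownames(out) <- NULL
  out
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
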