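test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(n_cases = 10L, n_controls = 10L,
                       n_validation_controls = 10L, notes_per_year = 3,
                       note_length_range = c(20L, 40L), vocab_size = 80L,
                       n_topics_true = 5L, signal_topic_ids = 1:2,
                       n_icd_groups = 8L, n_cpt = 5L, n_med = 4L,
                       n_notetype = 3L, seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$notes, b$notes)
  expect_identical(a$tokens, b$tokens)
  expect_identical(a$events, b$events)
  expect_identical(a$gem, b$gem)
  expect_identical(a$topics_true, b$topics_true)
})

test_that("latent prevalence is honoured, including the degenerate case", {
  cfg0 <- tiny_config(seed = 3L, latent_prevalence = 0)
  co0 <- generate_cohort(cfg0)
  expect_true(all(co0$truth$latent_truth == "none"))

  cfg <- cohort_config(n_cases = 5L, n_controls = 5L,
                       n_validation_controls = 2000L,
                       notes_per_year = 2, note_length_range = c(20L, 30L),
                       vocab_size = 80L, n_topics_true = 5L,
                       signal_topic_ids = 1L, latent_prevalence = 0.5,
                       n_icd_groups = 6L, n_cpt = 4L, n_med = 4L,
                       n_notetype = 3L, seed = 11L)
  co <- generate_cohort(cfg)
  frac <- mean(co$truth$latent_truth == "possible_probable")
  # binomial oracle: 3 SDs around 0.5 at n = 2000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_cases = 0), "n_cases")
  expect_error(cohort_config(latent_prevalence = 1.2), "latent_prevalence")
  expect_error(cohort_config(lookback_years = 0), "lookback_years")
  expect_error(cohort_config(signal_topic_ids = 99), "signal_topic_ids")
})

test_that("every generated patient passes eligibility for its label", {
  co <- generate_cohort(tiny_config(seed = 21L))
  cfg <- co$config
  ev_by <- split(co$events, co$events$patient_id)
  nt_by <- split(co$notes, co$notes$patient_id)
  for (i in seq_len(nrow(co$patients))) {
    p <- co$patients[i, ]
    res <- check_eligibility(p, ev_by[[p$patient_id]], nt_by[[p$patient_id]],
                             cfg)
    expect_true(res$pass, info = paste(p$patient_id, res$reason))
  }
})

test_that("eligibility matches a brute-force oracle on a constructed toy set", {
  cfg <- cohort_config(n_cases = 2L, n_controls = 2L,
                       n_validation_controls = 2L, vocab_size = 50L,
                       n_topics_true = 4L, signal_topic_ids = 1L,
                       n_icd_groups = 4L, n_cpt = 3L, n_med = 3L,
                       n_notetype = 2L, risk_icd_groups = 1:2,
                       risk_cpt = 1L, risk_med = 1L, seed = 1L)
  idx <- as.Date("2016-06-01")
  mk_notes <- function(offsets) data.frame(note_date = idx - offsets)
  # Visit patterns per lookback year (days before index)
  good_offsets <- c(10, 200, 400, 600, 800, 1000)       # 2 per year
  sparse_offsets <- c(10, 400, 800)                     # 1 per year
  dem9 <- data.frame(patient_id = "x", event_date = idx, system = "ICD9",
                     code = "331.0", stringsAsFactors = FALSE)
  don <- data.frame(patient_id = "x", event_date = idx - 100,
                    system = "MED", code = "DONEPEZIL",
                    stringsAsFactors = FALSE)
  no_ev <- dem9[0, ]

  toy <- list(
    list(label = "case", age = 70, ev = dem9, notes = mk_notes(good_offsets)),
    list(label = "case", age = 70, ev = dem9, notes = mk_notes(sparse_offsets)),
    list(label = "case", age = 64, ev = dem9, notes = mk_notes(good_offsets)),
    list(label = "case", age = 70, ev = no_ev, notes = mk_notes(good_offsets)),
    list(label = "control", age = 70, ev = no_ev, notes = mk_notes(good_offsets)),
    list(label = "control", age = 70, ev = no_ev, notes = mk_notes(sparse_offsets)),
    list(label = "control", age = 70, ev = don, notes = mk_notes(good_offsets)),
    list(label = "control", age = 70, ev = dem9, notes = mk_notes(good_offsets)),
    list(label = "control", age = 64, ev = no_ev, notes = mk_notes(good_offsets)),
    list(label = "control", age = 66, ev = no_ev, notes = mk_notes(good_offsets)),
    list(label = "control", age = 70, ev = no_ev, notes = mk_notes(numeric(0))),
    list(label = "case", age = 66, ev = dem9, notes = mk_notes(good_offsets))
  )

  # independent brute-force application of the rules
  oracle <- function(p) {
    vis <- p$notes$note_date
    per_year <- vapply(1:3, function(j) {
      sum(vis >= idx - j * 365 & vis < idx - (j - 1) * 365)
    }, numeric(1))
    if (p$label == "case") {
      has_dem <- nrow(p$ev) > 0 && any(p$ev$code == "331.0")
      return(has_dem && p$age >= 65 && all(per_year >= 2))
    }
    has_dem <- nrow(p$ev) > 0 && any(p$ev$code == "331.0")
    has_don <- nrow(p$ev) > 0 && any(p$ev$code == "DONEPEZIL")
    !has_dem && !has_don && p$age - 3 >= 62 && all(per_year >= 2)
  }

  for (k in seq_along(toy)) {
    p <- toy[[k]]
    pat <- data.frame(label = p$label, age_at_index = p$age, index_date = idx)
    got <- check_eligibility(pat, p$ev, p$notes, cfg)
    expect_identical(got$pass, oracle(p), info = paste("toy patient", k))
  }
})

test_that("specific eligibility failures carry the expected reasons", {
  cfg <- tiny_config()
  idx <- as.Date("2016-06-01")
  pat <- data.frame(label = "control", age_at_index = 70, index_date = idx)
  one_per_year <- data.frame(note_date = idx - c(10, 400, 800))
  no_ev <- data.frame(patient_id = character(), event_date = as.Date(character()),
                      system = character(), code = character())
  r <- check_eligibility(pat, no_ev, one_per_year, cfg)
  expect_false(r$pass)
  expect_match(r$reason, "visits")

  don <- data.frame(patient_id = "x", event_date = idx - 50, system = "MED",
                    code = "DONEPEZIL")
  full <- data.frame(note_date = idx - c(10, 200, 400, 600, 800, 1000))
  r2 <- check_eligibility(pat, don, full, cfg)
  expect_false(r2$pass)
  expect_match(r2$reason, "medication")

  # age-62 boundary: window opening before 65 is flagged, not failed
  pat64 <- data.frame(label = "control", age_at_index = 66.5, index_date = idx)
  r3 <- check_eligibility(pat64, no_ev, full, cfg)
  expect_true(r3$pass)
  expect_true("window_starts_before_65" %in% r3$flags)

  expect_error(
    check_eligibility(pat, data.frame(patient_id = "x",
                                      event_date = as.Date(NA),
                                      system = "CPT", code = "1"),
                      full, cfg),
    "undated")
})

test_that("ICD events respect the transition-date era convention", {
  co <- generate_cohort(tiny_config(seed = 9L))
  td <- co$config$transition_date
  icd9 <- co$events[co$events$system == "ICD9", ]
  icd10 <- co$events[co$events$system == "ICD10", ]
  expect_true(all(icd9$event_date < td))
  expect_true(all(icd10$event_date >= td))
})

test_that("case and latent-positive notes are enriched in signal topics", {
  cfg <- cohort_config(n_cases = 100L, n_controls = 100L,
                       n_validation_controls = 50L, notes_per_year = 3,
                       note_length_range = c(40L, 80L), vocab_size = 150L,
                       n_topics_true = 8L, signal_topic_ids = 1:2,
                       n_icd_groups = 8L, n_cpt = 5L, n_med = 4L,
                       n_notetype = 3L, seed = 31L)
  co <- generate_cohort(cfg)
  share <- co$notes$signal_tokens / co$notes$word_count
  lab <- co$patients$label[match(co$notes$patient_id, co$patients$patient_id)]
  lat <- co$patients$latent_truth[match(co$notes$patient_id,
                                        co$patients$patient_id)]
  case_share <- share[lab == "case"]
  neg_share <- share[lab == "control" & lat == "none"]
  obs <- mean(case_share) - mean(neg_share)
  expect_gt(obs, 0)
  # permutation test on the mean difference
  set.seed(99)
  pool <- c(case_share, neg_share)
  n1 <- length(case_share)
  perm <- replicate(2000, {
    ix <- sample.int(length(pool), n1)
    mean(pool[ix]) - mean(pool[-ix])
  })
  pval <- (1 + sum(perm >= obs)) / 2001
  expect_lt(pval, 0.001)
})

test_that("GEM files round-trip and preserve planted components", {
  path <- withr::local_tempfile(fileext = ".txt")
  spec1 <- data.frame(icd9 = "123.4", icd10 = "A01.1")
  write_gem_file(spec1, path)
  expect_identical(length(readLines(path)), 1L)

  spec3 <- data.frame(icd9 = c("100.1", "100.2", "200.1", "300.1"),
                      icd10 = c("B01.1", "B01.1", "B02.1", "B03.1"))
  write_gem_file(spec3, path)
  groups <- decompose_gem(read_gem_file(path))
  expect_identical(length(unique(groups$group_id)), 3L)

  # duplicate edges dropped silently with a message
  expect_message(write_gem_file(rbind(spec1, spec1), path), "duplicate")
  expect_identical(length(readLines(path)), 1L)

  # empty spec -> empty file, zero groups
  write_gem_file(spec1[0, ], path)
  expect_identical(file.size(path), 0)
  expect_identical(nrow(decompose_gem(read_gem_file(path))), 0L)
})

test_that("cohorts round-trip through the plain-text layout", {
  co <- generate_cohort(tiny_config(seed = 13L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ev <- read_events_csv(file.path(dir, "events.csv"))
  expect_identical(nrow(ev), nrow(co$events))
  expect_s3_class(ev$event_date, "Date")
  corpus_lines <- readLines(file.path(dir, "corpus.tsv"))
  expect_identical(length(corpus_lines), nrow(co$notes))
  g <- read_gem_file(file.path(dir, "gem.txt"))
  expect_identical(nrow(g$edges), nrow(unique(co$gem[, c("icd9", "icd10")])))
})
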