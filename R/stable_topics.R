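#' Presence-function parameters
#'
#' The presence function maps a pseudo word count (PWC) to a bounded degree
#' of topic presence in a note: 0 below `lower`, `pwc / upper` between
#' `lower` and `upper` (closed interval), and 1 above `upper`.
#'
#' @param lower PWC below which a topic counts as absent (default 2.0).
#' @param upper PWC at which presence saturates at 1 (default 10.0).
#' @return an object of class `presence_params`.
#' @export
presence_params <- function(lower = 2.0, upper = 10.0) {
  if (!(lower > 0 && upper > lower)) {
    stop("presence parameters require 0 < lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "presence_params")
}

#' Topic presence in a note
#'
#' Piecewise presence of a topic given its pseudo word count:
#' `0` if `pwc < lower`, `pwc / upper` if `lower <= pwc <= upper`, and
#' `1` if `pwc > upper`. Vectorised over `pwc`.
#'
#' @param pwc non-negative pseudo word count(s).
#' @param params a [presence_params()].
#' @return value(s) in `[0, 1]`.
#' @export
presence <- function(pwc, params = presence_params()) {
  stopifnot(inherits(params, "presence_params"))
  if (any(pwc < 0, na.rm = TRUE)) {
    stop("pwc must be non-negative", call. = FALSE)
  }
  out <- pwc / params$upper
  out[pwc < params$lower] <- 0
  out[pwc > params$upper] <- 1
  out
}

#' Extract stable topics from three LDA runs
#'
#' A stable topic is a topic recovered consistently by all three
#' independently seeded runs: a triple of topics, one per run, that are
#' mutual best matches under cosine similarity between topic-word
#' distributions, with every pairwise similarity at or above
#' `similarity_threshold`. The stable topic's word distribution is the
#' average of its three members; topics without a qualifying triple are
#' dropped, and no topic joins more than one stable topic.
#'
#' @param runs list of exactly 3 `topic_run`s over the same vocabulary.
#' @param similarity_threshold minimum pairwise cosine similarity.
#' @return an object of class `stable_topics`: list with `word_dist`
#'   (stable x V matrix, rows sum to 1), `members` (stable x 3 matrix of
#'   member topic indices per run) and `min_similarity` per stable topic.
#' @export
extract_stable_topics <- function(runs, similarity_threshold = 0.8) {
  if (length(runs) != 3 || !all(vapply(runs, inherits, TRUE, "topic_run"))) {
    stop("runs must be a list of exactly 3 topic_run objects", call. = FALSE)
  }
  vocabs <- lapply(runs, function(r) colnames(r$topic_word))
  if (!all(vapply(vocabs[-1], identical, TRUE, vocabs[[1]]))) {
    stop("runs have mismatched vocabularies", call. = FALSE)
  }
  m1 <- runs[[1]]$topic_word
  m2 <- runs[[2]]$topic_word
  m3 <- runs[[3]]$topic_word
  s12 <- cosine_sim(m1, m2)
  s13 <- cosine_sim(m1, m3)
  s23 <- cosine_sim(m2, m3)

  best <- function(s) max.col(s, ties.method = "first")
  b12 <- best(s12); b21 <- best(t(s12))
  b13 <- best(s13); b31 <- best(t(s13))

  # Anchor on run 1: a triple needs mutual-best matches (1,2) and (1,3)
  # and all three pairwise similarities at the threshold. Requiring the
  # (2,3) pair to also be mutual-best is brittle when K exceeds the number
  # of real topics (duplicate topics divert best pointers), so only its
  # similarity is checked; mutual-best pairs are injective, so each topic
  # still joins at most one stable topic.
  members <- NULL
  minsim <- numeric(0)
  for (i in seq_len(nrow(m1))) {
    j <- b12[i]; k <- b13[i]
    if (b21[j] != i || b31[k] != i) next
    ms <- min(s12[i, j], s13[i, k], s23[j, k])
    if (ms < similarity_threshold) next
    members <- rbind(members, c(i, j, k))
    minsim <- c(minsim, ms)
  }
  if (is.null(members)) {
    members <- matrix(integer(), 0, 3)
  }
  colnames(members) <- c("run1", "run2", "run3")
  S <- nrow(members)
  wd <- matrix(0, S, ncol(m1), dimnames = list(NULL, colnames(m1)))
  if (S > 0) {
    wd <- (m1[members[, 1], , drop = FALSE] +
             m2[members[, 2], , drop = FALSE] +
             m3[members[, 3], , drop = FALSE]) / 3
    wd <- wd / rowSums(wd)
    rownames(wd) <- sprintf("stable%04d", seq_len(S))
    rownames(members) <- rownames(wd)
  }
  structure(list(word_dist = wd, members = members, min_similarity = minsim),
            class = "stable_topics")
}

#' @export
print.stable_topics <- function(x, ...) {
  cat(sprintf("<stable_topics> %d stable topics over %d words\n",
              nrow(x$word_dist), ncol(x$word_dist)))
  invisible(x)
}

cosine_sim <- function(a, b) {
  an <- a / sqrt(rowSums(a^2))
  bn <- b / sqrt(rowSums(b^2))
  tcrossprod(an, bn)
}

#' Per-note pseudo word counts for stable topics
#'
#' The PWC of a stable topic in a note is the median of the three member
#' topics' PWCs (one per run), making it invariant to run order.
#'
#' @param stable a [extract_stable_topics()] result.
#' @param loads list of 3 [infer_loads()] results, aligned with the runs
#'   that produced `stable` and covering the same notes in the same order.
#' @return matrix (notes x stable topics) of stable PWCs.
#' @export
stable_pwc <- function(stable, loads) {
  stopifnot(inherits(stable, "stable_topics"), length(loads) == 3)
  ids <- loads[[1]]$note_id
  if (!identical(loads[[2]]$note_id, ids) || !identical(loads[[3]]$note_id, ids)) {
    stop("note loads are not aligned across runs", call. = FALSE)
  }
  S <- nrow(stable$members)
  out <- matrix(0, length(ids), S,
                dimnames = list(ids, rownames(stable$word_dist)))
  for (s in seq_len(S)) {
    p1 <- loads[[1]]$pwc[, stable$members[s, 1]]
    p2 <- loads[[2]]$pwc[, stable$members[s, 2]]
    p3 <- loads[[3]]$pwc[, stable$members[s, 3]]
    ## elementwise median of three values
    out[, s] <- pmax(pmin(p1, p2), pmin(pmax(p1, p2), p3))
  }
  out
}

#' Patient-level topic presence
#'
#' A patient's presence value for a stable topic is the maximum presence
#' over all of the patient's notes.
#'
#' @param pwc_matrix notes x stable-topics matrix from [stable_pwc()].
#' @param note_patient character vector assigning each note (row) to a
#'   patient.
#' @param params a [presence_params()].
#' @return matrix (patients x stable topics) with entries in `[0, 1]`,
#'   rows ordered by patient id.
#' @export
patient_topic_presence <- function(pwc_matrix, note_patient,
                                   params = presence_params()) {
  if (nrow(pwc_matrix) != length(note_patient)) {
    stop("note_patient must label every row of pwc_matrix", call. = FALSE)
  }
  if (nrow(pwc_matrix) == 0) {
    stop("patient without notes: eligibility violated upstream", call. = FALSE)
  }
  pres <- presence(pwc_matrix, params)
  # presence() keeps matrix shape; max within patient per column
  pid <- factor(note_patient)
  idx <- split(seq_len(nrow(pwc_matrix)), pid)
  out <- matrix(0, length(idx), ncol(pwc_matrix),
                dimnames = list(names(idx), colnames(pwc_matrix)))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    if (length(rows) == 1L) {
      out[i, ] <- pres[rows, ]
    } else {
      out[i, ] <- do.call(pmax, lapply(rows, function(r) pres[r, ]))
    }
  }
  out
}

#' Top terms per stable topic
#'
#' @param stable a [extract_stable_topics()] result.
#' @param n number of terms per topic.
#' @return data frame with `stable_id`, `term`, `weight`.
#' @export
top_terms <- function(stable, n = 10) {
  wd <- stable$word_dist
  out <- lapply(seq_len(nrow(wd)), function(s) {
    ord <- order(wd[s, ], decreasing = TRUE)[seq_len(min(n, ncol(wd)))]
    data.frame(stable_id = rownames(wd)[s], term = colnames(wd)[ord],
               weight = wd[s, ord], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
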