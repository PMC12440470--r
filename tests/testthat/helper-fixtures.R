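# Shared fixtures and independent oracles used across test files.

# Small, fast cohort configuration for unit tests.
tiny_config <- function(seed = 7L, ...) {
  cohort_config(n_cases = 15L, n_controls = 15L, n_validation_controls = 20L,
                notes_per_year = 3, note_length_range = c(30L, 60L),
                n_icd_groups = 12L, n_cpt = 8L, n_med = 6L, n_notetype = 4L,
                vocab_size = 120L, n_topics_true = 6L, signal_topic_ids = 1:2,
                seed = seed, ...)
}

# Independent union-find over a bipartite edge list; the oracle for
# decompose_gem. Vertices are namespaced strings.
uf_components <- function(edges9, edges10, iso9 = character(),
                          iso10 = character()) {
  verts <- unique(c(paste0("ICD9:", c(edges9, iso9)),
                    paste0("ICD10:", c(edges10, iso10))))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges9)) {
    r1 <- find(paste0("ICD9:", edges9[i]))
    r2 <- find(paste0("ICD10:", edges10[i]))
    if (r1 != r2) parent[[r2]] <- r1
  }
  roots <- vapply(verts, find, character(1))
  split(verts, roots)
}

# Canonical form of a partition: sorted list of sorted member vectors,
# independent of group labels.
canonical_partition <- function(groups_list) {
  out <- unname(lapply(groups_list, function(g) sort(unname(g))))
  out[order(vapply(out, `[`, character(1), 1))]
}

# Canonical partition from a decompose_gem result.
partition_from_groups <- function(groups) {
  canonical_partition(split(paste0(groups$namespace, ":", groups$code),
                            groups$group_id))
}

# Deterministic synthetic LDA corpus with two disjoint-vocabulary topics.
two_topic_corpus <- function(n_docs = 60, len = 40, vocab_size = 40,
                             seed = 5) {
  stopifnot(vocab_size %% 2 == 0)
  half <- vocab_size / 2
  set.seed(seed)
  toks <- lapply(seq_len(n_docs), function(d) {
    if (d %% 2 == 0) sample.int(half, len, replace = TRUE)
    else half + sample.int(half, len, replace = TRUE)
  })
  names(toks) <- sprintf("doc%03d", seq_len(n_docs))
  note_corpus(toks, sprintf("w%03d", seq_len(vocab_size)))
}

# Same code normalization the reader applies, written out independently.
normalize_code_for_test <- function(x) toupper(gsub("[.[:space:]]", "", x))

# O(n^2) weighted pairwise-concordance oracle for the AUC.
auc_concordance_oracle <- function(scores, positive, weights) {
  ip <- which(positive)
  ineg <- which(!positive)
  num <- 0
  for (i in ip) {
    for (j in ineg) {
      cmp <- if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
      num <- num + weights[i] * weights[j] * cmp
    }
  }
  num / (sum(weights[ip]) * sum(weights[ineg]))
}

# Random reviewed-patient table for evaluation tests.
random_reviewed <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    score = round(rnorm(n), 2),
    stratum_id = sample(c("srs", "hi"), n, replace = TRUE),
    band = "p0_75",
    weight = runif(n, 0.5, 4),
    review_label = sample(c("none", "possible", "probable"), n,
                          replace = TRUE, prob = c(0.7, 0.15, 0.15)),
    stringsAsFactors = FALSE
  )
}
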