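#' Build a note corpus
#'
#' Packs tokenized notes (integer word ids into a shared vocabulary) into the
#' corpus object consumed by [learn_topics()] and [infer_loads()].
#'
#' @param tokens named list of integer vectors (1-based word ids); names are
#'   note ids.
#' @param vocab character vector; `tokens` index into it.
#' @return an object of class `note_corpus`.
#' @export
note_corpus <- function(tokens, vocab) {
  stopifnot(is.list(tokens), is.character(vocab))
  if (length(tokens) == 0) stop("empty corpus", call. = FALSE)
  if (is.null(names(tokens))) names(tokens) <- sprintf("note%06d", seq_along(tokens))
  lens <- lengths(tokens)
  if (any(lens == 0)) stop("corpus contains empty notes", call. = FALSE)
  rng <- range(unlist(lapply(tokens, range)))
  if (rng[1] < 1 || rng[2] > length(vocab)) {
    stop("token ids out of vocabulary range", call. = FALSE)
  }
  structure(list(tokens = tokens, vocab = vocab, note_ids = names(tokens)),
            class = "note_corpus")
}

#' Tokenize raw note texts
#'
#' Lower-cases, strips non-alphanumeric characters, drops tokens shorter
#' than `min_chars`, removes stopwords, and drops words seen in fewer than
#' `min_df` notes. Returns a [note_corpus()] over the induced vocabulary.
#' Notes left without any token are removed (with a message).
#'
#' @param texts named character vector of note texts.
#' @param min_chars minimum token length kept.
#' @param stopwords character vector of words to drop.
#' @param min_df minimum number of notes a word must appear in.
#' @return a [note_corpus()].
#' @export
tokenize_notes <- function(texts, min_chars = 2, stopwords = english_stopwords(),
                           min_df = 2) {
  toks <- lapply(texts, function(tx) {
    w <- strsplit(gsub("[^a-z0-9 ]", " ", tolower(tx)), "[[:space:]]+")[[1]]
    w <- w[nchar(w) >= min_chars & !(w %in% stopwords)]
    w
  })
  df <- table(unlist(lapply(toks, unique)))
  vocab <- sort(names(df)[df >= min_df])
  ids <- lapply(toks, function(w) {
    m <- match(w, vocab)
    m[!is.na(m)]
  })
  keep <- lengths(ids) > 0
  if (!all(keep)) message(sum(!keep), " note(s) empty after tokenization, dropped")
  if (!any(keep)) stop("no notes survive tokenization", call. = FALSE)
  note_corpus(lapply(ids[keep], as.integer), vocab)
}

english_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "has",
    "he", "her", "his", "in", "is", "it", "its", "no", "not", "of", "on",
    "or", "she", "that", "the", "their", "there", "they", "this", "to",
    "was", "were", "will", "with")
}

#' Learn an LDA topic model
#'
#' Fits latent Dirichlet allocation to the corpus by collapsed Gibbs
#' sampling with symmetric priors (document prior `alpha`, word prior
#' `beta`). Deterministic given `seed`.
#'
#' @param corpus a [note_corpus()].
#' @param K number of topics (at least 2, at most the vocabulary size).
#' @param seed integer seed for the sampler.
#' @param alpha symmetric document-topic prior; default `5 / K`.
#' @param beta symmetric topic-word prior.
#' @param n_iter Gibbs sweeps over the corpus.
#' @return an object of class `topic_run` with the `K x V` matrix
#'   `topic_word` (rows sum to 1), the priors and the seed.
#' @export
learn_topics <- function(corpus, K, seed, alpha = 5 / K, beta = 0.01,
                         n_iter = 1000L) {
  stopifnot(inherits(corpus, "note_corpus"))
  V <- length(corpus$vocab)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (K > V) stop("K exceeds the vocabulary size", call. = FALSE)
  lens <- lengths(corpus$tokens)
  flat <- unlist(corpus$tokens, use.names = FALSE) - 1L
  phi <- cpp_lda_fit(flat, as.integer(lens), as.integer(K), as.integer(V),
                     alpha, beta, as.integer(n_iter), as.integer(seed))
  phi <- phi / rowSums(phi)
  dimnames(phi) <- list(sprintf("topic%04d", seq_len(K)), corpus$vocab)
  structure(list(K = as.integer(K), topic_word = phi, alpha = alpha,
                 beta = beta, seed = as.integer(seed), n_iter = n_iter),
            class = "topic_run")
}

#' @export
print.topic_run <- function(x, ...) {
  cat(sprintf("<topic_run> K = %d, vocab = %d, seed = %d\n",
              x$K, ncol(x$topic_word), x$seed))
  invisible(x)
}

#' Infer per-note topic loads and pseudo word counts
#'
#' Infers topic proportions for each note under a fitted [learn_topics()]
#' run, then converts them to pseudo word counts (PWC): the proportion times
#' the note's total word count, i.e. the (generally non-integer) number of
#' words the topic accounts for. Notes whose tokens are all outside the
#' run's vocabulary get uniform proportions (with a message); empty notes
#' are an error.
#'
#' @param run a `topic_run`.
#' @param corpus a [note_corpus()]; its vocabulary may differ from the
#'   run's only by OOV tokens, which are ignored.
#' @param n_sweeps Gibbs sweeps per note (proportions averaged over the
#'   second half).
#' @param seed integer seed.
#' @return an object of class `note_loads`: list with `note_id`,
#'   `proportions` (notes x K), `word_count` and `pwc` (notes x K).
#' @export
infer_loads <- function(run, corpus, n_sweeps = 25L, seed = run$seed) {
  stopifnot(inherits(run, "topic_run"), inherits(corpus, "note_corpus"))
  word_count <- lengths(corpus$tokens)
  if (any(word_count == 0)) stop("empty note in corpus", call. = FALSE)

  vmatch <- match(corpus$vocab, colnames(run$topic_word))
  ids <- lapply(corpus$tokens, function(tk) {
    m <- vmatch[tk]
    m[!is.na(m)]
  })
  lens <- lengths(ids)
  oov_only <- lens == 0
  if (any(oov_only)) {
    message(sum(oov_only),
            " note(s) contain only out-of-vocabulary tokens; uniform proportions assigned")
    ids[oov_only] <- list(1L) # placeholder, overwritten below
    lens[oov_only] <- 1L
  }
  flat <- unlist(ids, use.names = FALSE) - 1L
  theta <- cpp_lda_infer(flat, as.integer(lens), run$topic_word, run$alpha,
                         as.integer(n_sweeps), as.integer(seed))
  theta <- theta / rowSums(theta)
  if (any(oov_only)) theta[oov_only, ] <- 1 / run$K
  dimnames(theta) <- list(corpus$note_ids, rownames(run$topic_word))
  pwc <- theta * word_count
  structure(list(note_id = corpus$note_ids, proportions = theta,
                 word_count = as.integer(word_count), pwc = pwc),
            class = "note_loads")
}
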