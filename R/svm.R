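#' Specification for the linear max-margin risk model
#'
#' @param C_grid positive cost values searched by cross-validation.
#' @param n_folds folds for stratified cross-validation (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return an object of class `svm_spec`.
#' @export
svm_spec <- function(C_grid = 10^(-4:2), n_folds = 5L, seed = 1L) {
  if (length(C_grid) == 0 || any(C_grid <= 0)) {
    stop("C_grid must be non-empty and positive", call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(list(C_grid = sort(C_grid), n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "svm_spec")
}

as_case_indicator <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- !(y %in% c("case", "control"))
    if (any(bad)) stop("labels must be 'case'/'control'", call. = FALSE)
    y <- y == "case"
  }
  as.logical(y)
}

#' Choose the SVM cost parameter by cross-validated AUC
#'
#' Runs stratified `n_folds`-fold cross-validation on the training data for
#' every cost in the grid, scoring held-out patients with the fold model's
#' decision values and averaging the per-fold AUC. The cost with the highest
#' mean CV AUC is chosen; exact ties break toward the smaller cost.
#' Deterministic given `spec$seed`.
#'
#' @param x training feature matrix.
#' @param y labels (`"case"`/`"control"`, logical, or 0/1 with 1 = case).
#' @param spec an [svm_spec()].
#' @return list with `chosen_C` and `cv_table` (data frame `C`, `cv_auc`).
#' @export
select_C <- function(x, y, spec = svm_spec()) {
  y <- as_case_indicator(y)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  folds <- with_local_seed(spec$seed, {
    f <- integer(length(y))
    for (cls in c(TRUE, FALSE)) {
      ids <- which(y == cls)
      f[ids] <- sample(rep_len(seq_len(spec$n_folds), length(ids)))
    }
    f
  })
  aucs <- matrix(NA_real_, length(spec$C_grid), spec$n_folds)
  for (k in seq_len(spec$n_folds)) {
    tr <- folds != k
    for (ci in seq_along(spec$C_grid)) {
      m <- fit_svm(x[tr, , drop = FALSE], y[tr], spec$C_grid[ci])
      s <- score_patients(m, x[!tr, , drop = FALSE])
      aucs[ci, k] <- weighted_auc(s, y[!tr])
    }
  }
  cv <- data.frame(C = spec$C_grid, cv_auc = rowMeans(aucs))
  list(chosen_C = spec$C_grid[which.max(cv$cv_auc)], cv_table = cv)
}

#' Fit the linear max-margin model at a fixed cost
#'
#' Fits a linear soft-margin SVM (hinge loss, L2 penalty; delegated to the
#' libsvm C-classifier in \pkg{e1071} with a linear kernel and no internal
#' scaling) and extracts the hyperplane so that a patient's risk score is
#' exactly `w . x + b`, oriented with higher scores more case-like.
#'
#' @param x numeric feature matrix (no all-zero columns; asserted).
#' @param y labels as in [select_C()].
#' @param C positive cost parameter.
#' @return object of class `risk_model`: list with named weight vector `w`,
#'   intercept `b` and `C`.
#' @export
fit_svm <- function(x, y, C) {
  y <- as_case_indicator(y)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (any(colSums(abs(x)) == 0)) {
    stop("all-zero feature column: selection invariant violated upstream",
         call. = FALSE)
  }
  yf <- factor(ifelse(y, "case", "control"), levels = c("case", "control"))
  m <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  ## libsvm orients decision values toward the first class it encounters;
  ## detect the orientation and flip so that case scores are high
  dv <- attr(stats::predict(m, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  pos_class <- strsplit(colnames(dv), "/")[[1]][1]
  if (pos_class != "case") {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  structure(list(w = w, b = b, C = C), class = "risk_model")
}

#' Train the risk model end to end (cost selection + final fit)
#'
#' @inheritParams select_C
#' @return a `risk_model` carrying `chosen_C` and the `cv_table`.
#' @export
train_risk_model <- function(x, y, spec = svm_spec()) {
  sel <- select_C(x, y, spec)
  m <- fit_svm(x, y, sel$chosen_C)
  m$cv_table <- sel$cv_table
  m
}

#' Risk scores: signed distance to the separating hyperplane
#'
#' @param model a `risk_model`.
#' @param x feature matrix whose columns match the model's features exactly.
#' @return named numeric vector of unbounded scores (`w . x + b`); higher
#'   scores indicate higher dementia likelihood.
#' @export
score_patients <- function(model, x) {
  stopifnot(inherits(model, "risk_model"))
  if (!identical(colnames(x), names(model$w))) {
    stop("feature names do not match the model schema", call. = FALSE)
  }
  drop(x %*% model$w + model$b)
}

#' Percentile of scores within a reference population
#'
#' @param scores scores to place.
#' @param reference the full validation-stratum scores defining the scale.
#' @return percentiles in `[0, 100]` (empirical CDF, ties share the value).
#' @export
score_percentile <- function(scores, reference = scores) {
  100 * stats::ecdf(reference)(scores)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d features, C = %g", length(x$w), x$C))
  if (!is.null(x$cv_table)) {
    cat(sprintf(", CV AUC = %.3f", max(x$cv_table$cv_auc)))
  }
  cat("\n")
  invisible(x)
}

#' Persist / restore a risk model as JSON-like plain text
#'
#' Writes feature names, weights, intercept and chosen cost to an RDS-free
#' CSV pair so models survive as text.
#'
#' @param model a `risk_model`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_risk_model <- function(model, path) {
  df <- data.frame(feature = c("(intercept)", "(cost)", names(model$w)),
                   value = c(model$b, model$C, unname(model$w)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  b <- df$value[df$feature == "(intercept)"]
  C <- df$value[df$feature == "(cost)"]
  keep <- !(df$feature %in% c("(intercept)", "(cost)"))
  w <- df$value[keep]
  names(w) <- df$feature[keep]
  structure(list(w = w, b = b, C = C), class = "risk_model")
}
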