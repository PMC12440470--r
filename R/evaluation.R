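#' Chart-review sampling design
#'
#' A two-phase verification design: a simple random sample of `n_srs`
#' patients from the full score frame, plus stratified draws from
#' score-percentile bands of the remaining frame. The default mirrors a
#' 600-review design on a 10,000-score frame: 200 by simple random
#' sampling, 100 from the (75, 90] percentile band and 30 from each of the
#' ten 1-percentile bands covering (90, 100].
#'
#' @param n_srs size of the simple random sample (phase 1); may be 0.
#' @param strata data frame with columns `lo`, `hi`, `n`: phase-2 percentile
#'   bands `(lo, hi]` and their sample sizes (0 to skip a band). Bands must
#'   not overlap.
#' @param seed integer seed used by [draw_review_sample()].
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(n_srs = 200L, strata = default_review_strata(),
                            seed = 1L) {
  stopifnot(is.data.frame(strata), all(c("lo", "hi", "n") %in% names(strata)))
  if (n_srs < 0 || any(strata$n < 0)) {
    stop("sample sizes must be non-negative", call. = FALSE)
  }
  if (n_srs + sum(strata$n) < 1) stop("empty design", call. = FALSE)
  if (any(strata$hi <= strata$lo)) stop("bands must satisfy lo < hi", call. = FALSE)
  o <- order(strata$lo)
  strata <- strata[o, ]
  if (nrow(strata) > 1 && any(strata$lo[-1] < strata$hi[-nrow(strata)])) {
    stop("percentile bands overlap", call. = FALSE)
  }
  strata$stratum_id <- sprintf("p%g_%g", strata$lo, strata$hi)
  rownames(strata) <- NULL
  structure(list(n_srs = as.integer(n_srs), strata = strata,
                 seed = as.integer(seed)),
            class = "sampling_design")
}

#' @rdname sampling_design
#' @export
default_review_strata <- function() {
  data.frame(lo = c(75, 90:99), hi = c(90, 91:100),
             n = c(100L, rep(30L, 10)))
}

#' Draw the chart-review verification sample
#'
#' Phase 1 draws a simple random sample from the full frame; phase 2 draws
#' the per-band samples from what remains of each percentile band. Every
#' sampled patient receives its inclusion probability under the two-phase
#' union convention `pi = 1 - (1 - pi_srs)(1 - pi_band)`, where `pi_band`
#' is the band's phase-2 draw fraction of its post-phase-1 frame (0 for
#' patients outside every band), and the weight `1 / pi`. Reproducible
#' given the design seed.
#'
#' @param scores data frame with `patient_id` and `score` for the full
#'   validation stratum (the sampling frame).
#' @param design a [sampling_design()].
#' @return data frame of reviewed patients: `patient_id`, `score`,
#'   `percentile`, `stratum_id` (the sampling stratum the patient was drawn
#'   in: `"srs"` for phase-1 draws, the band id for phase-2 draws; this is
#'   the resampling unit of [bootstrap_ci()]), `band` (the percentile band
#'   the patient's score falls in, `"p0_75"`-style for scores below the
#'   lowest band), `pi`, `weight`.
#' @export
draw_review_sample <- function(scores, design) {
  stopifnot(inherits(design, "sampling_design"),
            all(c("patient_id", "score") %in% names(scores)))
  n <- nrow(scores)
  pct <- 100 * rank(scores$score, ties.method = "average") / n
  band <- rep(NA_integer_, n)
  for (s in seq_len(nrow(design$strata))) {
    inb <- pct > design$strata$lo[s] & pct <= design$strata$hi[s]
    band[inb] <- s
  }
  pi_srs <- design$n_srs / n

  with_local_seed(design$seed, {
    srs_idx <- if (design$n_srs > 0) sample.int(n, design$n_srs) else integer()
    taken <- rep(FALSE, n)
    taken[srs_idx] <- TRUE
    pi_band <- rep(0, n)
    phase2 <- integer()
    for (s in seq_len(nrow(design$strata))) {
      members <- which(band == s)
      rem <- members[!taken[members]]
      ns <- design$strata$n[s]
      if (ns == 0) next
      if (length(rem) < ns) {
        stop(sprintf("stratum (%g, %g] has only %d unsampled patients for n = %d",
                     design$strata$lo[s], design$strata$hi[s], length(rem), ns),
             call. = FALSE)
      }
      draw <- rem[sample.int(length(rem), ns)]
      phase2 <- c(phase2, draw)
      pi_band[members] <- ns / length(rem)
    }
    route <- rep(NA_character_, n)
    route[srs_idx] <- "srs"
    route[phase2] <- design$strata$stratum_id[band[phase2]]
    sel <- sort(unique(c(srs_idx, phase2)))
    pi <- 1 - (1 - pi_srs) * (1 - pi_band[sel])
    lo0 <- if (nrow(design$strata) > 0) min(design$strata$lo) else 100
    out <- data.frame(
      patient_id = scores$patient_id[sel],
      score = scores$score[sel],
      percentile = pct[sel],
      stratum_id = route[sel],
      band = ifelse(is.na(band[sel]), sprintf("p0_%g", lo0),
                    design$strata$stratum_id[band[sel]]),
      pi = pi, weight = 1 / pi,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate the chart review of sampled patients
#'
#' Converts latent truth into reviewer labels (`"none"`, `"possible"`,
#' `"probable"`), optionally with imperfect reviewer sensitivity and
#' specificity. Detected latent positives split evenly between possible and
#' probable; false positives are labelled possible.
#'
#' @param latent character vector (`"possible_probable"` / `"none"`).
#' @param sensitivity,specificity reviewer operating characteristics.
#' @param seed integer seed.
#' @return character vector of review labels.
#' @export
simulate_review <- function(latent, sensitivity = 1, specificity = 1,
                            seed = 1L) {
  with_local_seed(seed, {
    out <- rep("none", length(latent))
    pos <- latent == "possible_probable"
    det <- pos & stats::runif(length(latent)) < sensitivity
    out[det] <- sample(c("possible", "probable"), sum(det), replace = TRUE)
    fp <- !pos & stats::runif(length(latent)) >= specificity
    out[fp] <- "possible"
    out
  })
}

#' Inverse-probability-weighted screening estimates at a cutoff
#'
#' Forms the weighted 2x2 table of review label (positive = possible or
#' probable) against flagging (score strictly above the cutoff percentile
#' of the full validation stratum, type-7 empirical quantile), with each
#' reviewed patient weighted by the reciprocal of its inclusion
#' probability, and derives prevalence, sensitivity, specificity, PPV, NPV
#' and accuracy. A rate whose weighted margin is zero is returned as `NA`
#' (with a message).
#'
#' @param reviewed output of [draw_review_sample()] with a `review_label`
#'   column added.
#' @param all_scores numeric scores of the full validation stratum
#'   (defines the percentile scale).
#' @param cutoff_percentile percentile cutoff (e.g. 90 flags scores above
#'   the 90th percentile).
#' @param positive_levels review labels counted as positive.
#' @return one-row data frame: `cutoff`, `cutoff_value`, `prevalence`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
ipw_estimates <- function(reviewed, all_scores, cutoff_percentile,
                          positive_levels = c("possible", "probable")) {
  stopifnot(all(c("review_label", "weight", "score") %in% names(reviewed)))
  if (any(!is.finite(reviewed$weight)) || any(reviewed$weight <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  cutoff_value <- stats::quantile(all_scores, cutoff_percentile / 100,
                                  type = 7, names = FALSE)
  flag <- reviewed$score > cutoff_value
  pos <- reviewed$review_label %in% positive_levels
  w <- reviewed$weight
  tp <- sum(w[pos & flag]); fn <- sum(w[pos & !flag])
  fp <- sum(w[!pos & flag]); tn <- sum(w[!pos & !flag])
  W <- tp + fn + fp + tn
  rate <- function(num, den, what) {
    if (den == 0) {
      message("zero weighted margin for ", what, "; returning NA")
      return(NA_real_)
    }
    num / den
  }
  data.frame(
    cutoff = cutoff_percentile,
    cutoff_value = cutoff_value,
    prevalence = rate(tp + fn, W, "prevalence"),
    sensitivity = rate(tp, tp + fn, "sensitivity"),
    specificity = rate(tn, tn + fp, "specificity"),
    ppv = rate(tp, tp + fp, "PPV"),
    npv = rate(tn, tn + fn, "NPV"),
    accuracy = rate(tp + tn, W, "accuracy")
  )
}

#' Area under the weighted empirical ROC curve
#'
#' Computes the IPW-weighted AUC as the weighted probability of
#' concordance: for a random positive-negative pair (drawn with the
#' patients' weights), the probability the positive scores higher, ties
#' counting one half. Equivalent to the trapezoidal area under the
#' weighted empirical ROC over all score thresholds.
#'
#' @param scores numeric scores.
#' @param positive logical (or review labels coercible via
#'   `positive_levels`).
#' @param weights positive weights (default unweighted).
#' @param positive_levels used when `positive` is character.
#' @return the AUC, or `NA` (with a message) if only one class is present.
#' @export
weighted_auc <- function(scores, positive, weights = rep(1, length(scores)),
                         positive_levels = c("possible", "probable")) {
  if (is.character(positive) || is.factor(positive)) {
    positive <- as.character(positive) %in% positive_levels
  }
  positive <- as.logical(positive)
  wp_tot <- sum(weights[positive])
  wn_tot <- sum(weights[!positive])
  if (wp_tot == 0 || wn_tot == 0) {
    message("weighted AUC undefined with a single class; returning NA")
    return(NA_real_)
  }
  o <- order(scores)
  s <- scores[o]; w <- weights[o]; p <- positive[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  wp <- tapply(w * p, grp, sum)
  wn <- tapply(w * !p, grp, sum)
  cum_wn <- c(0, cumsum(wn))[seq_along(wn)]
  concord <- sum(wp * cum_wn) + 0.5 * sum(wp * wn)
  unname(concord / (wp_tot * wn_tot))
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples the reviewed patients with replacement within each sampling
#' stratum at its realised size (keeping the verification design fixed),
#' recomputes the statistic, and returns the percentile interval.
#' Deterministic given `seed`.
#'
#' @param statistic function taking a reviewed-patient data frame and
#'   returning a scalar.
#' @param reviewed data frame with a `stratum_id` column.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `lower`, `upper`, `level`, `B` and the vector of
#'   bootstrap `replicates`.
#' @export
bootstrap_ci <- function(statistic, reviewed, B = 1000L, seed = 1L,
                         level = 0.95) {
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  idx_by_stratum <- split(seq_len(nrow(reviewed)), reviewed$stratum_id)
  reps <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      ids <- unlist(lapply(idx_by_stratum, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      statistic(reviewed[ids, , drop = FALSE])
    }, numeric(1))
  })
  reps_ok <- reps[is.finite(reps)]
  if (length(unique(reps_ok)) <= 1) {
    warning("degenerate statistic across bootstrap resamples; zero-width interval")
  }
  qs <- stats::quantile(reps_ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7, names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, B = B, replicates = reps)
}

#' Cohen's kappa for paired categorical ratings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the standard large-sample
#' standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`. If both raters
#' are constant and identical (`p_e = 1`), kappa is 1 by convention.
#'
#' @param a,b equal-length vectors of categorical ratings.
#' @param level confidence level for the reported interval.
#' @return list with `kappa`, `se`, `ci_lower`, `ci_upper`, `n`.
#' @export
cohens_kappa <- function(a, b, level = 0.95) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("need >= 2 paired ratings", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    message("both raters constant and equal; kappa = 1 by convention")
    return(list(kappa = 1, se = 0, ci_lower = 1, ci_upper = 1, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = kappa, se = se,
       ci_lower = max(-1, kappa - z * se),
       ci_upper = min(1, kappa + z * se), n = n)
}

#' Weighted prevalence by score-percentile band
#'
#' The per-band analogue of the overall IPW prevalence: for each score
#' percentile band of the review design (plus the below-band remainder),
#' the weighted fraction of reviewed patients labelled positive. Bands with
#' no reviewed patients are reported with `NA`.
#'
#' @inheritParams ipw_estimates
#' @param design optional [sampling_design()]; when given, every design
#'   band appears in the output even if empty.
#' @return data frame: `band`, `n_reviewed`, `prevalence`.
#' @export
prevalence_by_stratum <- function(reviewed, design = NULL,
                                  positive_levels = c("possible", "probable")) {
  ids <- unique(reviewed$band)
  if (!is.null(design)) {
    lo0 <- if (nrow(design$strata) > 0) min(design$strata$lo) else 100
    ids <- union(ids, c(sprintf("p0_%g", lo0), design$strata$stratum_id))
  }
  ids <- ids[order(as.numeric(sub("^p([0-9.]+)_.*$", "\\1", ids)))]
  pos <- reviewed$review_label %in% positive_levels
  out <- lapply(ids, function(s) {
    rows <- reviewed$band == s
    if (!any(rows)) {
      return(data.frame(band = s, n_reviewed = 0L, prevalence = NA_real_))
    }
    data.frame(band = s, n_reviewed = sum(rows),
               prevalence = sum(reviewed$weight[rows] * pos[rows]) /
                 sum(reviewed$weight[rows]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screening-test summary table across cutoffs
#'
#' Convenience wrapper producing a table of IPW estimates with stratified
#' bootstrap confidence intervals at several percentile cutoffs.
#'
#' @inheritParams ipw_estimates
#' @param cutoffs percentile cutoffs.
#' @param B,seed,level bootstrap settings (see [bootstrap_ci()]).
#' @return data frame in long format: `cutoff`, `metric`, `estimate`,
#'   `lower`, `upper`.
#' @export
screening_table <- function(reviewed, all_scores, cutoffs = c(50, 75, 90, 95),
                            positive_levels = c("possible", "probable"),
                            B = 1000L, seed = 1L, level = 0.95) {
  metrics <- c("prevalence", "sensitivity", "specificity", "ppv", "npv",
               "accuracy")
  out <- list()
  for (ct in cutoffs) {
    est <- ipw_estimates(reviewed, all_scores, ct, positive_levels)
    for (m in metrics) {
      ci <- bootstrap_ci(function(r) {
        suppressMessages(ipw_estimates(r, all_scores, ct, positive_levels)[[m]])
      }, reviewed, B = B, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        cutoff = ct, metric = m, estimate = est[[m]],
        lower = ci$lower, upper = ci$upper)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
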