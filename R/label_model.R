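# Generative label model over labeling-function votes, in the data
# programming tradition: the true note label y is latent, each labeling
# function j emits POSITIVE or abstains.  The emission model is one-sided:
# the function "considers" the note with probability propensity[j] and, when
# it does, its internal judgement matches y with probability accuracy[j];
# it emits POSITIVE only when the judgement is positive, so
#   P(POS | y = 1) = propensity * accuracy
#   P(POS | y = 0) = propensity * (1 - accuracy)
# and abstains otherwise.  Votes are conditionally independent given y.
# Fitting is plain EM on the observed vote matrix.

#' Label model parameters
#'
#' @param class_prior Probability that a note is truly positive, in (0,1).
#' @param accuracy Numeric vector (one per labeling function) in (0,1):
#'   probability that the function's non-abstain judgement matches the true
#'   label.
#' @param propensity Numeric vector in (0,1): probability the function does
#'   not abstain on a note whose label its judgement matches-or-misses.
#' @return An object of class `label_model_params`.
#' @export
label_model_params <- function(class_prior, accuracy, propensity) {
  stopifnot(length(class_prior) == 1L, length(accuracy) == length(propensity))
  if (class_prior <= 0 || class_prior >= 1 ||
      any(accuracy <= 0 | accuracy >= 1) ||
      any(propensity <= 0 | propensity >= 1)) {
    stop("label_model_params(): all parameters must lie strictly in (0, 1)")
  }
  structure(list(class_prior = class_prior, accuracy = accuracy,
                 propensity = propensity, converged = NA,
                 log_likelihood = NA_real_),
            class = "label_model_params")
}

#' @export
print.label_model_params <- function(x, ...) {
  cat(sprintf("<label_model_params: %d LFs, prior %.3f%s>\n",
              length(x$accuracy), x$class_prior,
              if (isFALSE(x$converged)) ", NOT converged" else ""))
  invisible(x)
}

# Accept either the data frame from assemble_vote_matrix() or a bare 0/1
# matrix; return the matrix plus note ids.
as_vote_matrix <- function(matrix) {
  if (is.data.frame(matrix)) {
    cols <- grep("^lf[0-9]+$", names(matrix), value = TRUE)
    v <- as.matrix(matrix[cols])
    ids <- if ("note_id" %in% names(matrix)) matrix$note_id else
      as.character(seq_len(nrow(matrix)))
  } else {
    v <- as.matrix(matrix)
    ids <- rownames(v) %||% as.character(seq_len(nrow(v)))
  }
  storage.mode(v) <- "double"
  if (any(!v %in% c(0, 1))) {
    stop("vote matrix entries must be 1 (POSITIVE) or 0 (ABSTAIN)")
  }
  list(votes = v, note_id = ids)
}

# Posterior P(y = 1 | votes) and the observed-data log-likelihood.
e_step <- function(v, prior, accuracy, propensity) {
  t1 <- propensity * accuracy        # P(POS | y = 1)
  t0 <- propensity * (1 - accuracy)  # P(POS | y = 0)
  l1 <- v %*% log(t1) + (1 - v) %*% log(1 - t1) + log(prior)
  l0 <- v %*% log(t0) + (1 - v) %*% log(1 - t0) + log(1 - prior)
  m <- pmax(l1, l0)
  ll <- sum(m + log(exp(l1 - m) + exp(l0 - m)))
  list(posterior = as.vector(1 / (1 + exp(l0 - l1))), log_likelihood = ll)
}

#' Fit the generative label model by EM
#'
#' Alternates the posterior computation (E-step, Bayes' rule with votes
#' conditionally independent given the latent label) with closed-form
#' re-estimation of the class prior, per-function accuracies and
#' propensities from posterior-weighted counts (M-step), until the mean
#' log-likelihood improves by less than `tol` or `max_iter` is reached.
#' Parameters are clamped to `[eps, 1 - eps]`.  The log-likelihood is
#' non-decreasing across iterations (up to the clamp).
#'
#' @param matrix Vote matrix from [assemble_vote_matrix()] (or a bare 0/1
#'   matrix, columns = labeling functions).
#' @param init Optional [label_model_params()] initialization.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the mean log-likelihood
#'   (default 1e-6).
#' @param seed Seed for the random initialization jitter (unused when
#'   `init` is supplied).
#' @param eps Parameter clamp (default 1e-3).
#' @return A [label_model_params()] with `converged`, `log_likelihood`,
#'   `ll_trace` and `n_iter` fields filled in.  Warns (and returns the best
#'   iterate) on non-convergence; errors when every vote abstains.
#' @export
fit_label_model <- function(matrix, init = NULL, max_iter = 500, tol = 1e-6,
                            seed = NULL, eps = 1e-3) {
  vm <- as_vote_matrix(matrix)
  v <- vm$votes
  n <- nrow(v)
  J <- ncol(v)
  if (sum(v) == 0) stop("fit_label_model(): degenerate matrix, every vote abstains")
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  if (is.null(init)) {
    jitter <- with_seed(seed, stats::runif(J, -0.05, 0.05))
    prior <- clamp(mean(rowSums(v) > 0))
    accuracy <- clamp(0.75 + jitter)
    propensity <- clamp(colMeans(v) / max(prior, eps))
  } else {
    prior <- init$class_prior
    accuracy <- init$accuracy
    propensity <- init$propensity
    stopifnot(length(accuracy) == J)
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- e_step(v, prior, accuracy, propensity)
    mu <- es$posterior
    ll_trace <- c(ll_trace, es$log_likelihood)
    # M-step: theta1 = E[POS | y=1], theta0 = E[POS | y=0]
    s1 <- sum(mu)
    s0 <- n - s1
    theta1 <- clamp(as.vector(crossprod(v, mu)) / max(s1, eps))
    theta0 <- clamp(as.vector(crossprod(v, 1 - mu)) / max(s0, eps))
    prior <- clamp(s1 / n)
    propensity <- clamp(theta1 + theta0)
    accuracy <- clamp(theta1 / (theta1 + theta0))
    if (it > 1L) {
      delta <- (ll_trace[it] - ll_trace[it - 1L]) / n
      if (abs(delta) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("fit_label_model(): EM did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  out <- label_model_params(prior, accuracy, propensity)
  out$converged <- converged
  out$log_likelihood <- ll_trace[length(ll_trace)]
  out$ll_trace <- ll_trace
  out$n_iter <- length(ll_trace)
  out
}

#' Posterior probabilistic labels
#'
#' One posterior probability of the positive class per note, from the fitted
#' model's E-step formula.  Deterministic given the parameters.
#'
#' @param params A [label_model_params()].
#' @param matrix A vote matrix.
#' @return Data frame with `note_id` and `p_positive`.
#' @export
predict_proba <- function(params, matrix) {
  vm <- as_vote_matrix(matrix)
  es <- e_step(vm$votes, params$class_prior, params$accuracy, params$propensity)
  data.frame(note_id = vm$note_id, p_positive = es$posterior,
             stringsAsFactors = FALSE)
}

#' Majority-vote baseline
#'
#' Fraction of non-abstain votes that are POSITIVE; rows where every
#' function abstains get the no-evidence default.
#'
#' @param matrix A vote matrix.
#' @param default Probability for all-abstain rows (default 0.5).
#' @return Data frame with `note_id` and `p_positive`.
#' @export
majority_vote <- function(matrix, default = 0.5) {
  vm <- as_vote_matrix(matrix)
  pos <- rowSums(vm$votes == 1)
  nonabs <- rowSums(vm$votes != 0)
  p <- ifelse(nonabs > 0, pos / nonabs, default)
  data.frame(note_id = vm$note_id, p_positive = p, stringsAsFactors = FALSE)
}

#' Simulate a vote matrix from known parameters
#'
#' Draws latent labels from the class prior and votes from the one-sided
#' emission model; the ground truth is returned so recovery can be checked.
#'
#' @param params A [label_model_params()].
#' @param n Number of notes.
#' @param seed Seed (required for reproducibility).
#' @return List with `votes` (n x J matrix of 1/0) and `y` (latent 0/1
#'   labels).
#' @export
simulate_votes <- function(params, n, seed) {
  J <- length(params$accuracy)
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, params$class_prior)
    p_pos <- outer(y, params$propensity * params$accuracy) +
      outer(1 - y, params$propensity * (1 - params$accuracy))
    votes <- matrix(stats::rbinom(n * J, 1L, as.vector(p_pos)), nrow = n,
                    dimnames = list(NULL, paste0("lf", seq_len(J))))
    list(votes = votes, y = y)
  })
}

#' Select a label model by stratified k-fold F1
#'
#' Candidate models (by convention, fits from different random
#' initializations) are scored on a gold-labeled evaluation set: the set is
#' partitioned into `k` stratified folds (seeded), each candidate's F1 with
#' labels hardened at `threshold` is averaged over folds, and the candidate
#' with the best mean F1 wins; ties break to the lowest candidate index.
#' Folds containing no positive note are skipped with a warning.
#'
#' @param candidates List of [label_model_params()].
#' @param matrix Vote matrix covering (at least) the gold notes.
#' @param gold Data frame with `note_id` and `gold_label`
#'   ("positive"/"negative"); needs at least `k` rows.
#' @param k Number of folds (default 10).
#' @param threshold Hardening threshold (default 0.5).
#' @param seed Seed for the fold assignment.
#' @return List with `best_index`, `best_model`, `mean_f1` (per candidate)
#'   and `fold_f1` (fold x candidate matrix).
#' @export
cv_select <- function(candidates, matrix, gold, k = 10, threshold = 0.5,
                      seed = 1L) {
  stopifnot(length(candidates) >= 1L, nrow(gold) >= k)
  vm <- as_vote_matrix(matrix)
  idx <- match(gold$note_id, vm$note_id)
  if (anyNA(idx)) stop("cv_select(): gold notes missing from matrix")
  truth <- gold$gold_label == "positive"
  folds <- with_seed(seed, {
    f <- integer(nrow(gold))
    for (cls in unique(truth)) {
      ids <- which(truth == cls)
      f[ids] <- sample(rep_len(seq_len(k), length(ids)))
    }
    f
  })
  probs <- lapply(candidates, function(p) {
    predict_proba(p, vm$votes[idx, , drop = FALSE])$p_positive
  })
  fold_f1 <- matrix(NA_real_, nrow = k, ncol = length(candidates))
  for (f in seq_len(k)) {
    in_fold <- folds == f
    if (!any(truth[in_fold])) {
      warning("cv_select(): fold ", f, " has no positives; skipped")
      next
    }
    for (c in seq_along(candidates)) {
      pred <- probs[[c]][in_fold] >= threshold
      fold_f1[f, c] <- binary_metrics(pred, truth[in_fold])$f1
    }
  }
  mean_f1 <- colMeans(fold_f1, na.rm = TRUE)
  best <- which.max(mean_f1)  # which.max returns the first (lowest index) max
  list(best_index = best, best_model = candidates[[best]],
       mean_f1 = mean_f1, fold_f1 = fold_f1)
}

#' Harden probabilistic labels
#'
#' @param labels Data frame with `note_id`, `p_positive`.
#' @param threshold Decision threshold (default 0.5); `p >= threshold` is
#'   positive.
#' @return The input with a `hard_label` column ("positive"/"negative").
#' @export
harden_labels <- function(labels, threshold = 0.5) {
  labels$hard_label <- ifelse(labels$p_positive >= threshold,
                              "positive", "negative")
  labels
}
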