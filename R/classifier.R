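# Noise-aware discriminative classifier: a weighted-loss ridge-logistic
# model over word n-gram features (1-3 grams, sublinear term frequency)
# trained on label-model output.  The interface (train on weighted hard
# labels, predict a probability from raw note text) is the one a
# transformer adapter would also satisfy; the original study's transformer
# optimizer settings are recorded in `transformer_reference_config()` for
# provenance only.

#' Reference transformer fine-tuning settings
#'
#' Provenance record of the full-scale configuration this package's linear
#' classifier stands behind: a long-input clinical transformer fine-tuned
#' with Adam, learning rate warming up to 1e-5 with linear decay over 3
#' epochs, 4096 subword-token input budget, snapshot selection by F1.
#' Nothing in this package consumes these values.
#'
#' @return Named list of settings.
#' @export
transformer_reference_config <- function() {
  list(model = "clinical long-input transformer",
       optimizer = "Adam", peak_learning_rate = 1e-5,
       schedule = "linear warmup then linear decay", epochs = 3,
       max_input_tokens = 4096, snapshot_selection = "best F1")
}

word_tokens <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))
}

ngram_list <- function(tokens, ngram_max = 3) {
  lapply(tokens, function(tk) {
    n <- length(tk)
    if (n == 0L) return(character(0))
    out <- tk
    if (ngram_max >= 2L && n >= 2L) {
      out <- c(out, paste(tk[-n], tk[-1L], sep = "_"))
    }
    if (ngram_max >= 3L && n >= 3L) {
      out <- c(out, paste(tk[1:(n - 2L)], tk[2:(n - 1L)], tk[3:n], sep = "_"))
    }
    out
  })
}

# Sparse document-term matrix with sublinear term frequency 1 + log(tf).
dtm_build <- function(grams, vocab) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(grams)) {
    idx <- match(grams[[d]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    tab <- tabulate(idx, nbins = length(vocab))
    nz <- which(tab > 0L)
    ii <- c(ii, rep.int(d, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, 1 + log(tab[nz]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(grams), length(vocab)))
}

#' Build a stratified weak-label training set
#'
#' Hardens probabilistic labels at `threshold`, then samples `size / 3`
#' positives and `2 * size / 3` negatives uniformly without replacement
#' (seeded), preserving the 1:2 positive-to-negative ratio.  Notes in
#' `exclusions` (test/development sets) are never sampled.  Each entry
#' carries a confidence weight: `p_positive` for positives, `1 -
#' p_positive` for negatives.
#'
#' @param labels Data frame with `note_id`, `p_positive`.
#' @param size Total requested size.
#' @param exclusions Note ids to exclude.
#' @param seed Seed.
#' @param threshold Hardening threshold (default 0.5).
#' @return Data frame `note_id`, `label`, `weight` of class
#'   `afwatch_training_set`.
#' @export
build_training_set <- function(labels, size, exclusions = character(0),
                               seed = 1L, threshold = 0.5) {
  stopifnot(size >= 3)
  labels <- labels[!labels$note_id %in% exclusions, , drop = FALSE]
  pos <- labels[labels$p_positive >= threshold, , drop = FALSE]
  neg <- labels[labels$p_positive < threshold, , drop = FALSE]
  n_pos <- round(size / 3)
  n_neg <- size - n_pos
  if (nrow(pos) < n_pos) {
    stop(sprintf("build_training_set(): need %d positives, only %d available",
                 n_pos, nrow(pos)))
  }
  if (nrow(neg) < n_neg) {
    stop(sprintf("build_training_set(): need %d negatives, only %d available",
                 n_neg, nrow(neg)))
  }
  with_seed(seed, {
    pos <- pos[sample.int(nrow(pos), n_pos), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg), n_neg), , drop = FALSE]
  })
  out <- data.frame(
    note_id = c(pos$note_id, neg$note_id),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    weight = c(pos$p_positive, 1 - neg$p_positive),
    stringsAsFactors = FALSE)
  class(out) <- c("afwatch_training_set", class(out))
  out
}

#' Train the noise-aware text classifier
#'
#' Ridge-penalized logistic regression (via glmnet) on 1-3 word-gram
#' features with sublinear term frequency, each example weighted by its
#' label-model confidence.  A seeded stratified validation split (default
#' 10%) is carved from the training set and the penalty on the
#' regularization path with the best validation F1 is kept - the desk-scale
#' analog of snapshot selection; the test set is never touched.
#' Deterministic given the seed.
#'
#' @param train Training set from [build_training_set()].
#' @param notes Note table supplying text for every training note.
#' @param seed Seed for the validation split.
#' @param ngram_max Longest n-gram (default 3).
#' @param min_count Minimum corpus frequency for a feature (default 2).
#' @param val_fraction Validation fraction for penalty selection
#'   (default 0.1).
#' @param threshold Decision threshold exposed by the model (default 0.5).
#' @param nlambda Length of the penalty path (default 40).
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 1e-5; the ridge path must descend far enough that the model
#'   can actually commit to the minority class).
#' @return An object of class `afwatch_classifier`.
#' @export
train_noise_aware <- function(train, notes, seed = 1L, ngram_max = 3,
                              min_count = 2, val_fraction = 0.1,
                              threshold = 0.5, nlambda = 40,
                              lambda_min_ratio = 1e-5) {
  if (nrow(train) == 0L) stop("train_noise_aware(): empty training set")
  if (length(unique(train$label)) < 2L) {
    stop("train_noise_aware(): training set has a single class")
  }
  train <- train[train$weight > 0, , drop = FALSE]  # weight zero = no loss
  if (length(unique(train$label)) < 2L) {
    stop("train_noise_aware(): training set has a single class")
  }
  text <- notes$text[match(train$note_id, notes$note_id)]
  if (anyNA(text)) stop("train_noise_aware(): missing note text")
  y <- as.integer(train$label == "positive")
  w <- train$weight
  grams <- ngram_list(word_tokens(text), ngram_max)
  counts <- table(unlist(grams))
  vocab <- names(counts)[counts >= min_count]
  x <- dtm_build(grams, vocab)

  n <- nrow(train)
  val <- if (val_fraction > 0) {
    with_seed(seed, {
      v <- logical(n)
      for (cls in c(0L, 1L)) {
        ids <- which(y == cls)
        k <- max(1L, round(length(ids) * val_fraction))
        v[sample(ids, k)] <- TRUE
      }
      v
    })
  } else {
    logical(n)
  }
  # guard: the carved split must keep both classes in the training part
  if (length(unique(y[!val])) < 2L) val[] <- FALSE
  use_val <- any(val)
  fit <- glmnet::glmnet(x[!val, , drop = FALSE], y[!val], family = "binomial",
                        weights = w[!val], alpha = 0,
                        nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                        standardize = FALSE)
  lam_idx <- if (use_val && sum(y[val]) > 0) {
    pv <- stats::predict(fit, x[val, , drop = FALSE], type = "response")
    f1s <- apply(pv, 2L, function(p) {
      binary_metrics(p >= threshold, y[val] == 1L)$f1
    })
    which.max(f1s)
  } else {
    length(fit$lambda)
  }
  beta <- as.numeric(fit$beta[, lam_idx])
  structure(list(vocab = vocab, beta = beta, intercept = fit$a0[[lam_idx]],
                 lambda = fit$lambda[lam_idx], ngram_max = ngram_max,
                 threshold = threshold, seed = seed,
                 n_train = sum(!val), n_val = sum(val)),
            class = "afwatch_classifier")
}

#' @export
print.afwatch_classifier <- function(x, ...) {
  cat(sprintf("<afwatch_classifier: %d features, lambda %.4g, threshold %.2f>\n",
              length(x$vocab), x$lambda, x$threshold))
  invisible(x)
}

#' Predict prediagnosis probabilities for notes
#'
#' @param object An `afwatch_classifier`.
#' @param notes Note table (or character vector of texts).
#' @param ... Unused.
#' @return Data frame with `note_id`, `p_positive`, `hard_label`.
#' @export
predict.afwatch_classifier <- function(object, notes, ...) {
  if (is.character(notes)) {
    notes <- data.frame(note_id = as.character(seq_along(notes)),
                        text = notes, stringsAsFactors = FALSE)
  }
  grams <- ngram_list(word_tokens(notes$text), object$ngram_max)
  x <- dtm_build(grams, object$vocab)
  eta <- as.numeric(x %*% object$beta) + object$intercept
  p <- stats::plogis(eta)
  data.frame(note_id = notes$note_id, p_positive = p,
             hard_label = ifelse(p >= object$threshold, "positive",
                                 "negative"),
             stringsAsFactors = FALSE)
}

#' Evaluate scores against gold labels
#'
#' Scalar metrics at the decision threshold (precision, recall, F1,
#' accuracy) plus ROC and precision-recall curves computed by sweeping
#' every distinct predicted probability, and the trapezoidal ROC area.
#'
#' @param scores Data frame with `note_id`, `p_positive`.
#' @param gold Data frame with `note_id`, `gold_label`; both classes must be
#'   present.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `precision`, `recall`, `f1`, `accuracy`, `auc`,
#'   `roc_points` (fpr, tpr, threshold), `pr_points` (recall, precision,
#'   threshold).
#' @export
evaluate_scores <- function(scores, gold, threshold = 0.5) {
  if (nrow(gold) == 0L) stop("evaluate_scores(): empty gold set")
  p <- scores$p_positive[match(gold$note_id, scores$note_id)]
  if (anyNA(p)) stop("evaluate_scores(): scores missing for some gold notes")
  truth <- gold$gold_label == "positive"
  if (!any(truth) || all(truth)) {
    stop("evaluate_scores(): gold set must contain both classes")
  }
  m <- binary_metrics(p >= threshold, truth)

  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  ts <- truth[ord]
  distinct <- which(!duplicated(ps, fromLast = TRUE))  # last index per value
  tp <- cumsum(ts)[distinct]
  fp <- cumsum(!ts)[distinct]
  P <- sum(truth)
  N <- sum(!truth)
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P),
                    threshold = c(Inf, ps[distinct]))
  pr <- data.frame(recall = tp / P, precision = tp / (tp + fp),
                   threshold = ps[distinct])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  c(m, list(auc = auc, roc_points = roc, pr_points = pr,
            threshold = threshold))
}

#' Evaluate a classifier on gold notes
#'
#' @param classifier An `afwatch_classifier`.
#' @param gold Gold label data frame.
#' @param notes Note table with text for the gold notes.
#' @param ... Passed to [evaluate_scores()].
#' @return As [evaluate_scores()].
#' @export
evaluate_classifier <- function(classifier, gold, notes, ...) {
  scores <- stats::predict(classifier,
                           notes[notes$note_id %in% gold$note_id, ,
                                 drop = FALSE])
  evaluate_scores(scores, gold, ...)
}

#' Classifier performance across training-set sizes
#'
#' For each requested size, trains `replicates` seeded classifiers on
#' stratified weak-label training sets and reports the mean of each metric
#' on the gold set, reproducing the training-size performance grid.
#'
#' @param labels Probabilistic labels for the full corpus.
#' @param gold Gold evaluation set (its notes are excluded from training).
#' @param notes Note table.
#' @param sizes Ascending training-set sizes (default
#'   `c(600, 5000, 10000, 15000)`).
#' @param replicates Runs per size (default 3).
#' @param seed Base seed; replicate r of size s uses `seed + 100 * s_index
#'   + r`.
#' @param ... Passed to [train_noise_aware()].
#' @return Data frame with one row per size: mean precision, recall, f1,
#'   accuracy, plus `replicates`.
#' @export
size_sweep <- function(labels, gold, notes,
                       sizes = c(600, 5000, 10000, 15000), replicates = 3,
                       seed = 1L, ...) {
  if (is.unsorted(sizes)) stop("size_sweep(): sizes must be ascending")
  rows <- lapply(seq_along(sizes), function(si) {
    mets <- vapply(seq_len(replicates), function(r) {
      s <- seed + 100L * si + r
      train <- build_training_set(labels, sizes[si],
                                  exclusions = gold$note_id, seed = s)
      clf <- train_noise_aware(train, notes, seed = s, ...)
      ev <- evaluate_classifier(clf, gold, notes)
      c(precision = ev$precision, recall = ev$recall, f1 = ev$f1,
        accuracy = ev$accuracy)
    }, numeric(4))
    data.frame(size = sizes[si], t(rowMeans(mets)), replicates = replicates)
  })
  do.call(rbind, rows)
}
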