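# small separable corpus shared by the classifier tests
make_clf_fixture <- function(n_pos = 60, n_neg = 120, seed = 17) {
  afwatch:::with_seed(seed, {
    pos <- sprintf("Vitals stable. %s %s %s. Plan reviewed.",
                   sample(c("Apple Watch", "Fitbit", "smartwatch"), n_pos, TRUE),
                   sample(c("notified", "alerted", "showed"), n_pos, TRUE),
                   sample(c("afib", "atrial fibrillation", "irregular rhythm"),
                          n_pos, TRUE))
    neg <- sprintf("Vitals stable. Patient %s today for %s. Plan reviewed.",
                   sample(c("seen", "evaluated", "followed"), n_neg, TRUE),
                   sample(c("knee pain", "cough", "headache", "rash"),
                          n_neg, TRUE))
    notes <- make_notes(c(pos, neg))
    labels <- data.frame(note_id = notes$note_id,
                         p_positive = c(rep(0.95, n_pos), rep(0.04, n_neg)))
    gold <- data.frame(note_id = notes$note_id,
                       gold_label = rep(c("positive", "negative"),
                                        c(n_pos, n_neg)))
    list(notes = notes, labels = labels, gold = gold)
  })
}

test_that("training sets keep the 1:2 ratio and exclude held-out notes", {
  fx <- make_clf_fixture()
  ts <- build_training_set(fx$labels, 90, exclusions = fx$notes$note_id[1:5],
                           seed = 2)
  expect_identical(sum(ts$label == "positive"), 30L)
  expect_identical(sum(ts$label == "negative"), 60L)
  expect_lte(abs(2 * sum(ts$label == "positive") -
                   sum(ts$label == "negative")), 2)
  expect_length(intersect(ts$note_id, fx$notes$note_id[1:5]), 0L)
  expect_false(anyDuplicated(ts$note_id) > 0)
  # weights are the label-model confidences
  expect_true(all(ts$weight[ts$label == "positive"] == 0.95))
  expect_true(all(ts$weight[ts$label == "negative"] == 0.96))
})

test_that("ratio arithmetic matches the published worked examples", {
  labels <- data.frame(note_id = as.character(1:45000),
                       p_positive = rep(c(0.9, 0.1), c(5829, 39171)))
  ts <- build_training_set(labels, 15000, seed = 1)
  expect_identical(sum(ts$label == "positive"), 5000L)
  expect_identical(sum(ts$label == "negative"), 10000L)
  ts600 <- build_training_set(labels, 600, seed = 1)
  expect_identical(sum(ts600$label == "positive"), 200L)
  expect_identical(sum(ts600$label == "negative"), 400L)
  few <- data.frame(note_id = as.character(1:1000),
                    p_positive = rep(c(0.9, 0.1), c(100, 900)))
  expect_error(build_training_set(few, 600, seed = 1), "200 positives")
})

test_that("the classifier separates a canonical corpus and is deterministic", {
  fx <- make_clf_fixture()
  ts <- build_training_set(fx$labels, 90, seed = 3)
  clf <- train_noise_aware(ts, fx$notes, seed = 3)
  preds <- predict(clf, fx$notes)
  m <- evaluate_scores(preds, fx$gold)
  expect_gte(m$accuracy, 0.95)
  # training-set accuracy on its own notes
  tr_gold <- data.frame(note_id = ts$note_id,
                        gold_label = ts$label)
  expect_gte(evaluate_scores(preds, tr_gold)$accuracy, 0.95)
  clf2 <- train_noise_aware(ts, fx$notes, seed = 3)
  expect_identical(predict(clf2, fx$notes)$p_positive, preds$p_positive)
  # duplicated note text scores identically at prediction time
  dup <- fx$notes[c(1, 1), ]
  dup$note_id <- c("d1", "d2")
  pd <- predict(clf, dup)
  expect_identical(pd$p_positive[1], pd$p_positive[2])
})

test_that("weight-zero examples do not influence the fit", {
  fx <- make_clf_fixture(n_pos = 40, n_neg = 80)
  ts <- build_training_set(fx$labels, 90, seed = 4)
  extra <- fx$labels[!fx$labels$note_id %in% ts$note_id, ][1:6, ]
  ts_aug <- rbind(ts, data.frame(note_id = extra$note_id,
                                 label = "positive", weight = 0))
  clf_a <- train_noise_aware(ts, fx$notes, seed = 5, val_fraction = 0)
  clf_b <- train_noise_aware(ts_aug, fx$notes, seed = 5, val_fraction = 0)
  pa <- predict(clf_a, fx$notes)$p_positive
  pb <- predict(clf_b, fx$notes)$p_positive
  expect_equal(pa, pb, tolerance = 1e-6)
})

test_that("degenerate training inputs are rejected", {
  fx <- make_clf_fixture(n_pos = 10, n_neg = 20)
  ts <- build_training_set(fx$labels, 9, seed = 1)
  ts_pos <- ts[ts$label == "positive", ]
  expect_error(train_noise_aware(ts_pos, fx$notes), "single class")
  expect_error(train_noise_aware(ts[0, ], fx$notes), "empty")
})

test_that("evaluation reproduces the perfect and uninformative limits", {
  gold <- data.frame(note_id = as.character(1:10),
                     gold_label = rep(c("positive", "negative"), 5))
  perfect <- data.frame(note_id = gold$note_id,
                        p_positive = ifelse(gold$gold_label == "positive",
                                            0.9, 0.1))
  m <- evaluate_scores(perfect, gold)
  expect_equal(c(m$precision, m$recall, m$f1, m$accuracy, m$auc),
               rep(1, 5))
  expect_true(any(m$roc_points$fpr == 0 & m$roc_points$tpr == 1))
  flat <- data.frame(note_id = gold$note_id, p_positive = rep(0.5, 10))
  m2 <- evaluate_scores(flat, gold)
  expect_equal(m2$auc, 0.5)
  expect_identical(nrow(m2$roc_points), 2L)  # (0,0) and (1,1) only
  one_class <- gold
  one_class$gold_label <- "positive"
  expect_error(evaluate_scores(perfect, one_class), "both classes")
})

test_that("curves match an exhaustive threshold-sweep oracle", {
  set.seed(23)
  n <- 200
  gold <- data.frame(note_id = as.character(1:n),
                     gold_label = sample(c("positive", "negative"), n, TRUE))
  scores <- data.frame(note_id = gold$note_id,
                       p_positive = round(runif(n), 2))  # force ties
  m <- evaluate_scores(scores, gold)
  truth <- gold$gold_label == "positive"
  for (i in seq_len(nrow(m$roc_points))) {
    th <- m$roc_points$threshold[i]
    pred <- scores$p_positive >= th
    expect_equal(m$roc_points$tpr[i], sum(pred & truth) / sum(truth))
    expect_equal(m$roc_points$fpr[i], sum(pred & !truth) / sum(!truth))
  }
  for (i in seq_len(nrow(m$pr_points))) {
    th <- m$pr_points$threshold[i]
    pred <- scores$p_positive >= th
    expect_equal(m$pr_points$recall[i], sum(pred & truth) / sum(truth))
    expect_equal(m$pr_points$precision[i],
                 sum(pred & truth) / sum(pred))
  }
  # ROC points are monotone in both coordinates
  expect_false(is.unsorted(m$roc_points$fpr))
  expect_false(is.unsorted(m$roc_points$tpr))
})

test_that("trapezoidal ROC area equals pairwise concordance", {
  set.seed(29)
  n <- 150
  gold <- data.frame(note_id = as.character(1:n),
                     gold_label = sample(c("positive", "negative"), n, TRUE))
  scores <- data.frame(note_id = gold$note_id,
                       p_positive = round(runif(n), 2))
  m <- evaluate_scores(scores, gold)
  truth <- gold$gold_label == "positive"
  pos <- scores$p_positive[truth]
  neg <- scores$p_positive[!truth]
  conc <- 0
  for (a in pos) for (b in neg) {
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  expect_equal(m$auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)
})

test_that("the size sweep emits one row per size with mean metrics", {
  fx <- make_clf_fixture(n_pos = 80, n_neg = 200, seed = 19)
  set.seed(1)
  gold_idx <- sample(seq_len(nrow(fx$notes)), 60)
  gold <- fx$gold[gold_idx, ]
  sw <- size_sweep(fx$labels, gold, fx$notes, sizes = c(30, 90),
                   replicates = 2, seed = 7)
  expect_identical(sw$size, c(30, 90))
  expect_identical(names(sw),
                   c("size", "precision", "recall", "f1", "accuracy",
                     "replicates"))
  expect_true(all(sw$f1 >= 0 & sw$f1 <= 1))
  # replicates = 1 equals a single training/evaluation pass
  sw1 <- size_sweep(fx$labels, gold, fx$notes, sizes = 60, replicates = 1,
                    seed = 7)
  ts <- build_training_set(fx$labels, 60, exclusions = gold$note_id,
                           seed = 7 + 100 + 1)
  clf <- train_noise_aware(ts, fx$notes, seed = 7 + 100 + 1)
  ev <- evaluate_classifier(clf, gold, fx$notes)
  expect_equal(sw1$f1, ev$f1)
  expect_error(size_sweep(fx$labels, gold, fx$notes, sizes = c(90, 30)),
               "ascending")
})

test_that("test-set isolation holds across sweep training sets", {
  fx <- make_clf_fixture(n_pos = 60, n_neg = 150, seed = 41)
  set.seed(2)
  gold <- fx$gold[sample(seq_len(nrow(fx$notes)), 50), ]
  for (s in c(1, 2)) {
    ts <- build_training_set(fx$labels, 60, exclusions = gold$note_id,
                             seed = s)
    expect_length(intersect(ts$note_id, gold$note_id), 0L)
  }
})
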