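test_that("make_split allocates 2:1 per class with largest-remainder rounding", {
  subjects <- data.frame(
    subject_id = c(sprintf("A%02d", 1:87), sprintf("C%02d", 1:74)),
    label = c(rep("AD", 87), rep("control", 74)))
  sp <- make_split(subjects, seed = 1)
  tr <- subjects$label[subjects$subject_id %in% sp$train_subjects]
  te <- subjects$label[subjects$subject_id %in% sp$test_subjects]
  expect_equal(sum(tr == "AD"), 58)
  expect_equal(sum(tr == "control"), 49)
  expect_equal(sum(te == "AD"), 29)
  expect_equal(sum(te == "control"), 25)

  # determinism and disjointness
  sp2 <- make_split(subjects, seed = 1)
  expect_identical(sp, sp2)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  for (f in sp$folds) {
    expect_length(intersect(f$fit, f$validation), 0)
    expect_true(all(c(f$fit, f$validation) %in% sp$train_subjects))
    expect_setequal(c(f$fit, f$validation), sp$train_subjects)
  }
  expect_error(make_split(data.frame(subject_id = "a", label = "AD")),
               "class")
})

test_that("the MLP separates well-separated classes and is deterministic", {
  set.seed(9)
  n <- 150
  X <- rbind(matrix(rnorm(n * 40), n, 40),
             matrix(rnorm(n * 40, mean = 6), n, 40))   # 6 SD apart
  y <- rep(c(0, 1), each = n)
  cfg <- mlp_config(max_epochs = 150, seed = 4)
  clf <- train_mlp(X, y, cfg)
  pr <- predict(clf, X)
  expect_gte(mean((pr$score >= 0.5) == (y == 1)) * 100, 99)
  expect_equal(evaluate(pr$score, y)$auc, 1.0)

  clf2 <- train_mlp(X, y, cfg)
  expect_identical(clf$weights, clf2$weights)
  expect_identical(predict(clf2, X)$score, pr$score)

  expect_error(train_mlp(X, rep(1, 2 * n), cfg), "single-class")
  expect_error(predict(clf, X[, 1:10]), "width")
})

test_that("permuted labels give chance-level validation accuracy", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(2 * n * 40), 2 * n, 40)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- sample(rep(c(0, 1), n))
    fit <- 1:round(1.6 * n); val <- (round(1.6 * n) + 1):(2 * n)
    clf <- train_mlp(X[fit, ], y[fit],
                     mlp_config(max_epochs = 100, patience = Inf, seed = s))
    pr <- predict(clf, X[val, ])
    mean((pr$score >= 0.5) == (y[val] == 1)) * 100
  }, numeric(1))
  expect_gt(mean(accs), 45)
  expect_lt(mean(accs), 55)
})

test_that("evaluate reproduces the metric identities and tie rule", {
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 9), 0.8)
  labels <- c(rep(1, 10), rep(0, 10))
  r <- evaluate(scores, labels)
  expect_equal(unname(r$confusion), c(8, 1, 9, 2))  # TP FP TN FN
  expect_equal(r$accuracy, 85)
  expect_equal(r$sensitivity, 80)
  expect_equal(r$specificity, 90)

  # score exactly 0.5 is assigned to the positive class
  r2 <- evaluate(c(0.5, 0.4), c(1, 0))
  expect_equal(unname(r2$confusion["TP"]), 1)

  # predictions invariant to row order
  o <- sample(20)
  r3 <- evaluate(scores[o], labels[o])
  expect_identical(r3$confusion, r$confusion)

  # perfect extreme scores give AUC 1
  expect_equal(evaluate(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)

  # subject-level aggregation averages scores within subject
  sid <- c(rep("s1", 10), rep("s2", 10))
  rs <- evaluate(scores, labels, level = "subject", subject_ids = sid)
  expect_equal(rs$n, 2)
  expect_equal(unname(rs$confusion["TP"]), 1)
})

test_that("rank AUC is 0.5 under label-independent scores and matches pROC", {
  set.seed(7)
  n <- 2000
  scores <- runif(2 * n)
  labels <- rep(c(0, 1), n)
  a <- evaluate(scores, labels)$auc
  expect_gt(a, 0.45); expect_lt(a, 0.55)
  skip_if_not_installed("pROC")
  a_small <- evaluate(scores[1:200], labels[1:200])$auc
  ref_small <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(labels[1:200], scores[1:200], direction = "<",
              levels = c(0, 1), quiet = TRUE))))
  expect_equal(a_small, ref_small, tolerance = 1e-12)
})

test_that("run_protocol keeps subjects on one side of every boundary", {
  f <- toy_features(n_subj_per_class = 6, rows_per_subj = 20, shift = 1.2,
                    seed = 8)
  subjects <- unique(f[, c("subject_id", "label")])
  sp <- make_split(subjects, seed = 2)
  rep_ <- run_protocol(f, sp, mlp_config(max_epochs = 80, seed = 3))
  expect_length(rep_$folds, 3)
  expect_equal(nrow(rep_$summary), 5)
  expect_identical(rep_$summary$stage,
                   c("fold1", "fold2", "fold3", "average", "holdout"))
  # average row is the mean of the fold rows
  expect_equal(rep_$summary$accuracy[4], mean(rep_$summary$accuracy[1:3]))
  # metric identities on every emitted confusion matrix
  for (r in c(rep_$folds, list(rep_$holdout))) {
    cm <- r$confusion
    expect_equal(r$accuracy, (cm["TP"] + cm["TN"]) / sum(cm) * 100,
                 ignore_attr = TRUE)
    expect_equal(r$sensitivity, cm["TP"] / (cm["TP"] + cm["FN"]) * 100,
                 ignore_attr = TRUE)
    expect_equal(r$specificity, cm["TN"] / (cm["TN"] + cm["FP"]) * 100,
                 ignore_attr = TRUE)
  }
  # strong shift: the protocol should separate the groups
  expect_gt(rep_$holdout$accuracy, 90)
  # determinism of the whole protocol
  rep2 <- run_protocol(f, sp, mlp_config(max_epochs = 80, seed = 3))
  expect_identical(rep_$summary, rep2$summary)
})
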