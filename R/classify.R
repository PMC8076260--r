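#' Subject-level MLP classification protocol
#'
#' Subjects are split 2:1 into training and hold-out sets (per class,
#' largest-remainder rounding). Within the training set, three repeated
#' random subject-level 80/20 splits provide the cross-validation folds.
#' A 5-layer perceptron (40 inputs, three hidden layers of 20 rectified
#' linear units, one sigmoid output) is fitted per fold and evaluated on
#' the fold's validation subjects; a final model fitted on all training
#' subjects is evaluated once on the held-out subjects. All splits are
#' by subject, never by row, so no subject ever contributes rows to both
#' sides of a fit/evaluation boundary.
#'
#' @name classify
NULL

# Per-class largest-remainder allocation of ratio*n subjects to training.
largest_remainder <- function(counts, ratio) {
  raw <- counts * ratio
  base <- floor(raw)
  total <- round(sum(raw))
  deficit <- total - sum(base)
  if (deficit > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(deficit)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Subject-level split plan
#'
#' @param subjects data.frame with columns `subject_id` and `label`.
#' @param ratio training fraction (default 2/3, i.e. a 2:1 split).
#' @param k number of cross-validation folds (default 3), each an
#'   independent seeded 80/20 subject draw within the training set,
#'   stratified by class.
#' @param fold_fraction fraction of training subjects assigned to the
#'   fit side of each fold (default 0.8).
#' @param seed integer seed; identical seeds give identical plans.
#' @return an object of class `split_plan`: `train_subjects`,
#'   `test_subjects`, `folds` (list of `list(fit, validation)`), `seed`.
#' @export
make_split <- function(subjects, ratio = 2 / 3, k = 3, fold_fraction = 0.8,
                       seed = 1) {
  subjects <- as.data.frame(subjects)
  stopifnot(all(c("subject_id", "label") %in% names(subjects)))
  subjects <- subjects[!duplicated(subjects$subject_id), ]
  classes <- sort(unique(subjects$label))
  counts <- vapply(classes, function(cl) sum(subjects$label == cl), integer(1))
  n_train <- largest_remainder(counts, ratio)
  if (any(counts - n_train < 1) || any(n_train < 1))
    stop("a class is too small for a nonempty train and test set")
  with_seed(seed, {
    train <- character(0)
    for (i in seq_along(classes)) {
      ids <- subjects$subject_id[subjects$label == classes[i]]
      train <- c(train, sample(ids, n_train[i]))
    }
    test <- setdiff(subjects$subject_id, train)
    folds <- lapply(seq_len(k), function(f) {
      fit <- character(0)
      for (cl in classes) {
        ids <- intersect(train, subjects$subject_id[subjects$label == cl])
        nf <- largest_remainder(length(ids), fold_fraction)
        fit <- c(fit, sample(ids, nf))
      }
      list(fit = sort(fit), validation = sort(setdiff(train, fit)))
    })
    structure(list(train_subjects = sort(train), test_subjects = sort(test),
                   folds = folds, ratio = ratio, k = k,
                   fold_fraction = fold_fraction, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test subjects, %d folds (%.0f/%.0f), seed %d\n",
              length(x$train_subjects), length(x$test_subjects), x$k,
              100 * x$fold_fraction, 100 * (1 - x$fold_fraction), x$seed))
  invisible(x)
}

#' MLP configuration
#'
#' Architecture per the protocol: 40 input nodes, three hidden layers of
#' 20 nodes, one output node. Hidden activations, optimizer and training
#' schedule are implementation choices exposed here.
#'
#' @param hidden hidden layer sizes (fixed-length 3 by default).
#' @param n_input input width (40 features).
#' @param learning_rate Adam step size.
#' @param max_epochs maximum full-batch epochs.
#' @param patience early-stopping patience (epochs without improvement
#'   of validation accuracy); `Inf` disables early stopping.
#' @param l2 L2 weight-decay coefficient (biases excluded).
#' @param seed weight-initialization seed.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(20, 20, 20), n_input = 40,
                       learning_rate = 0.01, max_epochs = 300,
                       patience = 50, l2 = 0, seed = 1) {
  structure(list(hidden = as.integer(hidden), n_input = as.integer(n_input),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 l2 = l2, seed = seed),
            class = "mlp_config")
}

mlp_forward <- function(W, X) {
  H <- list(X)
  nl <- length(W)
  for (l in seq_len(nl)) {
    Z <- H[[l]] %*% W[[l]]$W + matrix(W[[l]]$b, nrow(H[[l]]), length(W[[l]]$b),
                                      byrow = TRUE)
    H[[l + 1]] <- if (l < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  H
}

#' Train the multilayer perceptron
#'
#' Full-batch gradient descent with the adaptive-moment (Adam)
#' optimizer on the binary cross-entropy loss; rectified-linear hidden
#' units, sigmoid output; He-scaled Gaussian weight initialization from
#' the config seed. Deterministic for identical data, config and seed.
#'
#' @param X numeric matrix of normalized feature rows (n x 40).
#' @param y labels: logical/0-1 vector (1 or `TRUE` = positive class).
#' @param config an [mlp_config()].
#' @param X_val,y_val optional validation rows for early stopping and
#'   the accuracy history; when supplied, training stops after
#'   `patience` epochs without a new best validation accuracy and the
#'   best weights are restored.
#' @return an object of class `mlp_classifier`: weights, config, and a
#'   per-epoch `history` data.frame (loss, fit accuracy, validation
#'   accuracy when available).
#' @export
train_mlp <- function(X, y, config = mlp_config(), X_val = NULL, y_val = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != config$n_input)
    stop(sprintf("feature width %d != expected %d", ncol(X), config$n_input))
  if (length(unique(y)) < 2L) stop("single-class input: cannot train")
  sizes <- c(config$n_input, config$hidden, 1L)
  W <- with_seed(config$seed, lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  }))
  nl <- length(W)
  m <- lapply(W, function(w) list(W = w$W * 0, b = w$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; epsadam <- 1e-8
  lr <- config$learning_rate
  n <- nrow(X)
  best <- list(acc = -Inf, W = W, epoch = 0L)
  wait <- 0L
  hist <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    H <- mlp_forward(W, X)
    p <- H[[nl + 1]][, 1]
    p_ <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p_) + (1 - y) * log(1 - p_))
    delta <- matrix((p - y) / n, n, 1)                # dL/dz_out
    grads <- vector("list", nl)
    for (l in nl:1) {
      grads[[l]] <- list(W = crossprod(H[[l]], delta), b = colSums(delta))
      if (l > 1L)
        delta <- (delta %*% t(W[[l]]$W)) * (H[[l]] > 0)
    }
    for (l in seq_len(nl)) {
      for (nm in c("W", "b")) {
        g <- grads[[l]][[nm]]
        if (nm == "W" && (config$l2 %||% 0) > 0)
          g <- g + config$l2 * W[[l]]$W
        m[[l]][[nm]] <- b1 * m[[l]][[nm]] + (1 - b1) * g
        v[[l]][[nm]] <- b2 * v[[l]][[nm]] + (1 - b2) * g^2
        mhat <- m[[l]][[nm]] / (1 - b1^epoch)
        vhat <- v[[l]][[nm]] / (1 - b2^epoch)
        W[[l]][[nm]] <- W[[l]][[nm]] - lr * mhat / (sqrt(vhat) + epsadam)
      }
    }
    fit_acc <- mean((p >= 0.5) == (y == 1)) * 100
    val_acc <- NA_real_
    if (!is.null(X_val)) {
      pv <- mlp_forward(W, as.matrix(X_val))[[nl + 1]][, 1]
      val_acc <- mean((pv >= 0.5) == (as.numeric(y_val) == 1)) * 100
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, W = W, epoch = epoch)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist[[epoch]] <- c(epoch = epoch, loss = loss, fit_accuracy = fit_acc,
                       validation_accuracy = val_acc)
    if (!is.null(X_val) && is.finite(config$patience) && wait >= config$patience)
      break
  }
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
  if (!is.null(X_val) && best$epoch > 0L) W <- best$W
  structure(list(weights = W, config = config, history = hist,
                 best_epoch = if (!is.null(X_val)) best$epoch else nrow(hist)),
            class = "mlp_classifier")
}

#' Predict scores and labels
#'
#' @param object a trained [train_mlp()] classifier.
#' @param newdata numeric matrix of normalized feature rows (width 40).
#' @param ... unused.
#' @return data.frame with `score` in \[0, 1\] and `positive` (logical;
#'   score >= 0.5, ties assigned to the positive class).
#' @export
predict.mlp_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$config$n_input)
    stop(sprintf("row width %d != expected %d", ncol(X), object$config$n_input))
  p <- mlp_forward(object$weights, X)[[length(object$weights) + 1]][, 1]
  data.frame(score = p, positive = p >= 0.5)
}

# Rank-statistic AUC (Mann-Whitney; ties counted half).
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate classifier scores
#'
#' Builds the confusion matrix at threshold 0.5 (ties positive) and the
#' four summary metrics. In subject-level mode, each subject's rows are
#' aggregated by mean score before thresholding.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels true labels: logical/0-1 (1 = positive class, i.e. AD).
#' @param level `"pulse"` (per row, default) or `"subject"`.
#' @param subject_ids required for `level = "subject"`.
#' @return an object of class `evaluation_report`: `confusion`
#'   (TP, FP, TN, FN), `accuracy`, `sensitivity`, `specificity`
#'   (percent; `NA` when a class is absent), `auc`, `level`, `n`.
#' @export
evaluate <- function(scores, labels, level = c("pulse", "subject"),
                     subject_ids = NULL) {
  level <- match.arg(level)
  y <- as.numeric(labels) == 1
  s <- as.numeric(scores)
  if (level == "subject") {
    if (is.null(subject_ids)) stop("subject_ids required for subject-level evaluation")
    s <- tapply(s, subject_ids, mean)
    y <- as.logical(tapply(y, subject_ids, function(v) v[1]))
    s <- as.numeric(s)
  }
  pred <- s >= 0.5
  TP <- sum(pred & y); FP <- sum(pred & !y)
  TN <- sum(!pred & !y); FN <- sum(!pred & y)
  pct <- function(num, den) if (den == 0) NA_real_ else num / den * 100
  structure(list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 accuracy = pct(TP + TN, TP + TN + FP + FN),
                 sensitivity = pct(TP, TP + FN),
                 specificity = pct(TN, TN + FP),
                 auc = rank_auc(s, y), level = level, n = length(s)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> (%s level, n = %d)\n", x$level, x$n))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

report_row <- function(r) {
  c(accuracy = r$accuracy, sensitivity = r$sensitivity,
    specificity = r$specificity, auc = r$auc)
}

#' Run the full classification protocol
#'
#' For each cross-validation fold: fit the normalization model and the
#' MLP on the fold's fit subjects, evaluate on its validation subjects.
#' Then fit a final model on all training subjects and evaluate it once
#' on the held-out subjects. Every stage seed derives from the master
#' seed and is recorded in the report.
#'
#' @param features feature table ([assemble_features()] output, possibly
#'   several subjects bound together) with `subject_id` and `label`
#'   columns; *not* yet normalized (normalization is fitted inside each
#'   training boundary to avoid leakage).
#' @param split a [make_split()] plan for these subjects.
#' @param config an [mlp_config()]; per-stage weight seeds derive from
#'   `config$seed`.
#' @param positive_label label of the positive class (default `"AD"`).
#' @param level evaluation level, `"pulse"` (default) or `"subject"`.
#' @return an object of class `protocol_report`: `folds` (3 evaluation
#'   reports), `average` (mean of fold metrics), `holdout`, `seeds`,
#'   and a `summary` data.frame with one row per fold plus `average`
#'   and `holdout` rows.
#' @export
run_protocol <- function(features, split, config = mlp_config(),
                         positive_label = "AD",
                         level = c("pulse", "subject")) {
  level <- match.arg(level)
  features <- as.data.frame(features)
  stopifnot(all(c("subject_id", "label") %in% names(features)))
  fc <- feature_columns(config$n_input / 4)
  run_one <- function(fit_ids, eval_ids, stage, monitor = TRUE) {
    tr <- features[features$subject_id %in% fit_ids, , drop = FALSE]
    ev <- features[features$subject_id %in% eval_ids, , drop = FALSE]
    if (length(intersect(tr$subject_id, ev$subject_id)) > 0L)
      stop("subject-level integrity violated")   # asserted on every run
    nm <- normalize_fit(tr, fc)
    trn <- normalize_apply(nm, tr)
    evn <- normalize_apply(nm, ev)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, stage)
    # monitor = TRUE: the evaluation subjects are this stage's validation
    # set (the cross-validation folds), used for early stopping. The
    # hold-out stage must never see its evaluation subjects during
    # training, so the final model trains for the full schedule instead.
    clf <- train_mlp(as.matrix(trn[, fc]), trn$label == positive_label, cfg,
                     X_val = if (monitor) as.matrix(evn[, fc]),
                     y_val = if (monitor) evn$label == positive_label)
    pr <- predict(clf, as.matrix(evn[, fc]))
    list(report = evaluate(pr$score, evn$label == positive_label, level,
                           subject_ids = evn$subject_id),
         seed = cfg$seed, classifier = clf)
  }
  fold_out <- lapply(seq_along(split$folds), function(f)
    run_one(split$folds[[f]]$fit, split$folds[[f]]$validation,
            paste0("fold", f)))
  # final model: train on all training subjects for the cross-validated
  # epoch budget (mean of the folds' best epochs). Training the full
  # schedule instead overfits the subject clusters, and early-stopping
  # on the held-out subjects would leak their labels.
  best <- vapply(fold_out, function(f) f$classifier$best_epoch, numeric(1))
  config$max_epochs <- max(10L, as.integer(round(mean(pmax(best, 1)))))
  hold <- run_one(split$train_subjects, split$test_subjects, "holdout",
                  monitor = FALSE)
  fold_reports <- lapply(fold_out, `[[`, "report")
  avg <- colMeans(do.call(rbind, lapply(fold_reports, report_row)))
  summary <- as.data.frame(rbind(
    do.call(rbind, lapply(fold_reports, report_row)),
    avg, report_row(hold$report)))
  summary <- data.frame(stage = c(paste0("fold", seq_along(fold_reports)),
                                  "average", "holdout"), summary,
                        row.names = NULL)
  structure(list(folds = fold_reports, average = avg,
                 holdout = hold$report, summary = summary,
                 seeds = c(master = config$seed,
                           stats::setNames(vapply(fold_out, `[[`, numeric(1), "seed"),
                                           paste0("fold", seq_along(fold_out))),
                           holdout = hold$seed),
                 level = level, split = split),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> (%s level)\n", x$level))
  print(x$summary, digits = 4)
  invisible(x)
}
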