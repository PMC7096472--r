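#' Nonlinear SVM recursive feature elimination ranking
#'
#' Trains the kernel machine on all remaining features and scores each
#' feature f by the kernel-space criterion
#' \eqn{\Delta\|w\|^2_f = \|w\|^2 - \|w^{(-f)}\|^2}, where
#' \eqn{\|w^{(-f)}\|^2} re-evaluates the kernel with feature f removed and
#' the trained multipliers held fixed. The lowest-scoring feature is
#' eliminated; one per iteration. Correlation-bias mitigation: features
#' with pairwise |r| > `cor_threshold` are grouped, the group is scored
#' jointly (kernel without the whole group), and when a group scores worst
#' only its weakest member is eliminated.
#'
#' @param X feature matrix (samples x features), column names required.
#' @param y two-level labels.
#' @param C,gamma,kernel SVM hyperparameters (defaults C = 1,
#'   gamma = 1/m, RBF).
#' @param cor_threshold grouping threshold on |r| (default 0.95).
#' @param standardize z-score columns before ranking (default TRUE).
#' @return object of class `rfe_result`: `ranking` (feature names, best
#'   first), `elimination_order` (first eliminated first), `rank` (named
#'   integer vector, 1 = best).
#' @export
svm_rfe_rank <- function(X, y, C = 1, gamma = NULL,
                         kernel = c("rbf", "linear"),
                         cor_threshold = 0.95, standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  check_that(!is.null(colnames(X)), "X must have column names")
  check_that(ncol(X) >= 2L, "need at least 2 features")
  check_that(length(unique(y)) == 2L, "both classes must be present")
  if (standardize) {
    mu <- colMeans(X); sdv <- apply(X, 2L, sd); sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  remaining <- colnames(X)
  eliminated <- character(0)
  lv <- sort(unique(as.character(y)))
  yy <- ifelse(as.character(y) == lv[2], 1, -1)

  kmat <- function(cols) {
    A <- X[, cols, drop = FALSE]
    if (kernel == "rbf") rbf_kernel(A, A, gamma) else linear_kernel(A, A)
  }
  while (length(remaining) > 1L) {
    fit <- svm_train(X[, remaining, drop = FALSE], y, C = C, gamma = gamma,
                     kernel = kernel, max_passes = 5L)
    a <- fit$alpha
    w2 <- svm_wnorm2(a, yy, kmat(remaining))
    indiv <- vapply(remaining, function(f) {
      w2 - svm_wnorm2(a, yy, kmat(setdiff(remaining, f)))
    }, numeric(1))
    # correlation groups among remaining features
    groups <- correlation_groups(X[, remaining, drop = FALSE], cor_threshold)
    unit_scores <- vapply(groups, function(g) {
      if (length(g) == 1L) indiv[[g]]
      else w2 - svm_wnorm2(a, yy, kmat(setdiff(remaining, g)))
    }, numeric(1))
    worst_unit <- groups[[which.min(unit_scores)]]
    drop_feat <- worst_unit[which.min(indiv[worst_unit])]
    eliminated <- c(eliminated, drop_feat)
    remaining <- setdiff(remaining, drop_feat)
  }
  eliminated <- c(eliminated, remaining)
  ranking <- rev(eliminated)
  rk <- setNames(seq_along(ranking), ranking)
  structure(list(ranking = ranking, elimination_order = eliminated,
                 rank = rk, kernel = kernel, C = C, gamma = gamma),
            class = "rfe_result")
}

# Partition features into groups of pairwise |r| > threshold (greedy union).
correlation_groups <- function(X, threshold) {
  m <- ncol(X)
  nm <- colnames(X)
  if (m == 1L) return(list(nm))
  cm <- suppressWarnings(abs(stats::cor(X)))
  cm[is.na(cm)] <- 0
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    if (cm[i, j] > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(m), find, integer(1))
  unname(lapply(split(seq_len(m), roots), function(ix) nm[ix]))
}

#' Leave-one-subject-out evaluation with per-fold RFE
#'
#' For each left-out subject: standardize on the training folds, rank
#' features by [svm_rfe_rank()] on training data only, then evaluate the
#' left-out subject at every feature-subset size. Ranks are aggregated by
#' summation across folds (ties broken by mean elimination round, then
#' column order); the confusion matrix is reported at the subset size with
#' the best pooled balanced accuracy.
#'
#' @param X feature matrix with column names.
#' @param y two-level labels.
#' @param subjects subject identifier per row (>= 3 unique).
#' @param C,gamma,kernel SVM settings.
#' @param cor_threshold RFE grouping threshold.
#' @return object of class `loso_result`: `aggregate_ranking`,
#'   `rank_sums`, `curve` (data.frame n_features / balanced_accuracy),
#'   `best_size`, `report` (from [report_confusion()]), `fold_rankings`.
#' @export
loso_evaluate <- function(X, y, subjects, C = 1, gamma = NULL,
                          kernel = c("rbf", "linear"), cor_threshold = 0.95) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.character(y)
  subj <- as.character(subjects)
  # canonical row order: results must not depend on how subjects were listed
  ord <- order(subj, y)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; subj <- subj[ord]
  us <- unique(subj)
  check_that(length(us) >= 3L, "need at least 3 subjects")
  m <- ncol(X)
  feats <- colnames(X)
  if (is.null(gamma)) gamma <- 1 / m

  rank_sums <- setNames(numeric(m), feats)
  elim_round <- setNames(numeric(m), feats)
  fold_rankings <- list()
  preds <- vector("list", m)  # predictions per subset size, pooled

  for (s in us) {
    tr <- subj != s; te <- !tr
    if (length(unique(y[tr])) < 2L) next
    if (length(unique(y[te])) < 2L)
      message(sprintf("subject %s has a single class in test fold", s))
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, sd); sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    rfe <- svm_rfe_rank(Xtr, y[tr], C = C, gamma = gamma, kernel = kernel,
                        cor_threshold = cor_threshold, standardize = FALSE)
    fold_rankings[[s]] <- rfe$ranking
    rank_sums <- rank_sums + rfe$rank[feats]
    elim_round <- elim_round + match(feats, rfe$elimination_order)
    for (k in seq_len(m)) {
      top <- rfe$ranking[seq_len(k)]
      fit <- svm_train(Xtr[, top, drop = FALSE], y[tr], C = C, gamma = gamma,
                       kernel = kernel, max_passes = 5L)
      ph <- predict(fit, Xte[, top, drop = FALSE])
      preds[[k]] <- rbind(preds[[k]],
                          data.frame(subject = s, truth = y[te], pred = ph))
    }
  }
  bacc <- vapply(preds, function(d) {
    if (is.null(d)) return(NA_real_)
    balanced_accuracy(d$pred, d$truth)
  }, numeric(1))
  curve <- data.frame(n_features = seq_len(m), balanced_accuracy = bacc)
  best <- which.max(bacc)
  report <- report_confusion(preds[[best]]$pred, preds[[best]]$truth)
  # tie-break: lower rank sum first, later mean elimination (better) first,
  # then column order
  aggregate_ranking <- feats[order(rank_sums, -elim_round, seq_len(m))]
  structure(list(aggregate_ranking = aggregate_ranking,
                 rank_sums = rank_sums, curve = curve,
                 best_size = best, report = report,
                 fold_rankings = fold_rankings,
                 predictions = preds[[best]]),
            class = "loso_result")
}

balanced_accuracy <- function(pred, truth) {
  lv <- sort(unique(truth))
  mean(vapply(lv, function(l) mean(pred[truth == l] == l), numeric(1)))
}

#' Confusion matrix report
#'
#' Row-normalized percentage confusion matrix, balanced accuracy (mean of
#' per-class recalls, i.e. the diagonal mean), and positive/negative
#' predictive values.
#'
#' @param predictions predicted labels.
#' @param labels true labels (same length, same level set).
#' @return object of class `classification_report`: `confusion` (rows sum
#'   to 100), `balanced_accuracy` (%), `ppv`, `npv` (%).
#' @export
report_confusion <- function(predictions, labels) {
  check_that(length(predictions) > 0L, "empty predictions")
  check_that(length(predictions) == length(labels), "length mismatch")
  lv <- sort(unique(as.character(labels)))
  check_that(all(as.character(predictions) %in% lv),
             "predictions contain labels outside the truth set")
  cm <- table(factor(labels, lv), factor(predictions, lv))
  pc <- 100 * prop.table(cm, 1L)
  bacc <- mean(diag(pc))
  # treat the second (sorted) level as the positive class
  tp <- cm[2, 2]; fp <- cm[1, 2]; tn <- cm[1, 1]; fn <- cm[2, 1]
  ppv <- if ((tp + fp) > 0) 100 * tp / (tp + fp) else NA_real_
  npv <- if ((tn + fn) > 0) 100 * tn / (tn + fn) else NA_real_
  structure(list(confusion = pc, balanced_accuracy = bacc,
                 ppv = ppv, npv = npv, positive = lv[2]),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Confusion matrix (% of true class):\n")
  print(round(unclass(x$confusion), 2))
  cat(sprintf("Balanced accuracy: %.2f%% | PPV %.2f%% | NPV %.2f%% (positive = %s)\n",
              x$balanced_accuracy, x$ppv, x$npv, x$positive))
  invisible(x)
}
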