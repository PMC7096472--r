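# Kernel matrix helpers ------------------------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

linear_kernel <- function(A, B) tcrossprod(A, B)

#' Soft-margin SVM trained by sequential minimal optimization
#'
#' Deterministic SMO (full pass over examples, partner chosen by maximum
#' error difference) solving the C-SVC dual for an RBF or linear kernel.
#' Intended for the small sample sizes of per-subject feature tables.
#'
#' @param X numeric matrix (samples x features).
#' @param y labels; any two-level vector (mapped to -1/+1 by sorted order).
#' @param C box constraint (default 1).
#' @param gamma RBF width; default `1/ncol(X)`.
#' @param kernel `"rbf"` or `"linear"`.
#' @param tol KKT tolerance.
#' @param max_passes passes without change before stopping.
#' @return object of class `svm_model` with `alpha`, `b`, `X`, `y`,
#'   `levels`, kernel settings.
#' @export
svm_train <- function(X, y, C = 1, gamma = NULL, kernel = c("rbf", "linear"),
                      tol = 1e-3, max_passes = 10L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  lv <- sort(unique(as.character(y)))
  check_that(length(lv) == 2L, "exactly two classes required")
  yy <- ifelse(as.character(y) == lv[2], 1, -1)
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- if (kernel == "rbf") rbf_kernel(X, X, gamma) else linear_kernel(X, X)

  alpha <- numeric(n); b <- 0
  fcache <- function() as.numeric(K %*% (alpha * yy)) + b
  passes <- 0L; iter <- 0L; max_iter <- 200L * n
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    E <- fcache() - yy
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * yy) + b - yy[i]
      if ((yy[i] * Ei < -tol && alpha[i] < C) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        Ej_all <- as.numeric(K %*% (alpha * yy)) + b - yy
        j <- which.max(abs(Ej_all - Ei) + ifelse(seq_len(n) == i, -Inf, 0))
        Ej <- Ej_all[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yy[i] != yy[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yy[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
          yy[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
          yy[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
      iter <- iter + 1L
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  structure(list(alpha = alpha, b = b, X = X, y = yy, levels = lv,
                 kernel = kernel, gamma = gamma, C = C),
            class = "svm_model")
}

#' @param object an `svm_model`.
#' @param newdata matrix of samples to classify.
#' @param ... unused.
#' @return predicted labels (original level values).
#' @rdname svm_train
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Kx <- if (object$kernel == "rbf")
    rbf_kernel(newdata, object$X, object$gamma)
  else linear_kernel(newdata, object$X)
  f <- as.numeric(Kx %*% (object$alpha * object$y)) + object$b
  object$levels[ifelse(f >= 0, 2L, 1L)]
}

# ||w||^2 in feature space for a trained machine, on a given kernel matrix.
svm_wnorm2 <- function(alpha, y, K) {
  ay <- alpha * y
  as.numeric(t(ay) %*% K %*% ay)
}
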