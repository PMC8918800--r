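#' Evaluate a categorizer under the repeated random-split protocol
#'
#' Each iteration draws an independent random 75/25 train/test split,
#' standardizes the features with training-fold statistics only, trains
#' the classifier on the training fold and scores it on the held-out
#' fold; the protocol result is the mean success over iterations. Labels
#' may be true object categories or a fish's behavioural choices — the
#' protocol is agnostic.
#'
#' @param X numeric feature matrix (rows = images) or data.frame of
#'   numeric columns.
#' @param y two-level label vector, one per row.
#' @param train_frac fraction of rows in the training fold.
#' @param iterations number of independent splits.
#' @param classifier `"svm"` (soft-margin linear SVM, cost 1) or `"knn"`
#'   (k-nearest-neighbour, `k = 5`).
#' @param seed integer seed driving all splits.
#' @return list of class `protocol_result`: `mean_success`,
#'   `per_iteration`, `n_images`, `seed`, `classifier`.
#' @export
evaluate_protocol <- function(X, y, train_frac = 0.75, iterations = 20,
                              classifier = c("svm", "knn"), seed = 1L) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  if (nrow(X) < 8) stop("need at least 8 rows", call. = FALSE)
  if (nlevels(droplevels(y)) != 2)
    stop("labels must have exactly two classes", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  n <- nrow(X)
  n_train <- max(2L, round(train_frac * n))
  per <- with_local_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      repeat {
        tr <- sample.int(n, n_train)
        if (nlevels(droplevels(y[tr])) == 2 &&
            nlevels(droplevels(y[-tr])) == 2) break
      }
      mu <- colMeans(X[tr, , drop = FALSE])
      sdev <- apply(X[tr, , drop = FALSE], 2, sd)
      sdev[sdev < 1e-12] <- 1
      Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
      pred <- fit_predict(Z[tr, , drop = FALSE], y[tr],
                          Z[-tr, , drop = FALSE], classifier)
      mean(pred == y[-tr])
    }, numeric(1))
  })
  structure(list(mean_success = mean(per), per_iteration = per,
                 n_images = n, seed = as.integer(seed),
                 classifier = classifier),
            class = "protocol_result")
}

fit_predict <- function(Ztr, ytr, Zte, classifier) {
  if (classifier == "svm") {
    fit <- e1071::svm(Ztr, ytr, kernel = "linear", cost = 1, scale = FALSE)
    predict(fit, Zte)
  } else {
    class::knn(Ztr, Zte, ytr, k = 5)
  }
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("protocol result: %s on %d images, %d iterations\n",
              x$classifier, x$n_images, length(x$per_iteration)))
  cat(sprintf("  mean success %.3f (sd %.3f)\n", x$mean_success,
              sd(x$per_iteration)))
  invisible(x)
}

#' Greedy forward feature ordering
#'
#' Step 1 evaluates every feature alone under the split protocol and
#' keeps the best; each later step adds the remaining feature that
#' maximizes the protocol success of the augmented set. Candidates
#' within a step share the same split seed, so comparisons are paired;
#' ties break towards the lower feature index. The ordering runs to all
#' features so the saturation curve can be plotted. Greedy selection is
#' a lower bound on exhaustive best-subset performance.
#'
#' @inheritParams evaluate_protocol
#' @param iterations splits per protocol evaluation.
#' @return list of class `greedy_trace`: `ordered_features`,
#'   `success_at_step`, `seed`, `classifier`.
#' @export
greedy_feature_selection <- function(X, y, classifier = c("svm", "knn"),
                                     seed = 1L, iterations = 20) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  remaining <- seq_len(ncol(X))
  chosen <- integer(0)
  success <- numeric(0)
  for (step in seq_len(ncol(X))) {
    step_seed <- derive_seed(seed, paste0("greedy_step", step))
    scores <- vapply(remaining, function(j) {
      evaluate_protocol(X[, c(chosen, j), drop = FALSE], y,
                        iterations = iterations, classifier = classifier,
                        seed = step_seed)$mean_success
    }, numeric(1))
    best <- remaining[which.max(scores)]  # which.max: first max, lowest index
    chosen <- c(chosen, best)
    success <- c(success, max(scores))
    remaining <- setdiff(remaining, best)
  }
  structure(list(ordered_features = colnames(X)[chosen],
                 success_at_step = success, seed = as.integer(seed),
                 classifier = classifier),
            class = "greedy_trace")
}

#' @export
print.greedy_trace <- function(x, ...) {
  cat("greedy feature ordering (", x$classifier, "):\n", sep = "")
  for (k in seq_along(x$ordered_features))
    cat(sprintf("  %2d. %-22s %.3f\n", k, x$ordered_features[k],
                x$success_at_step[k]))
  invisible(x)
}

#' Raw-pixel classification baseline
#'
#' The same split protocol applied to flattened image thumbnails instead
#' of extracted features. Exists to reproduce the qualitative ordering
#' that feature-based classification beats raw pixels on shape-dominant
#' material.
#'
#' @param imgs list of grayscale image matrices.
#' @param y two-level labels.
#' @param thumb thumbnail side in pixels.
#' @inheritParams evaluate_protocol
#' @return a `protocol_result`.
#' @export
raw_pixel_baseline <- function(imgs, y, seed = 1L, thumb = 32,
                               iterations = 20,
                               classifier = c("svm", "knn")) {
  classifier <- match.arg(classifier)
  P <- t(vapply(imgs, function(im) {
    as.vector(EBImage::imageData(EBImage::resize(EBImage::Image(im),
                                                 w = thumb, h = thumb)))
  }, numeric(thumb * thumb)))
  evaluate_protocol(P, y, iterations = iterations, classifier = classifier,
                    seed = seed)
}
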