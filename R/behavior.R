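#' Decide between two stimuli from classifier outputs
#'
#' The two-branch decision rule of the behavioural model: each stimulus
#' is classified independently; if exactly one prediction matches the
#' rewarded category the decision follows it, and if the two predictions
#' agree the choice is a fair coin.
#'
#' @param pred_a,pred_b predicted category labels for side A and B
#'   (vectorized).
#' @param rewarded the rewarded category label.
#' @return character vector of `"A"` / `"B"` choices. Uses the current
#'   RNG stream for coin flips.
#' @export
decide_pair <- function(pred_a, pred_b, rewarded) {
  stopifnot(length(pred_a) == length(pred_b))
  n <- length(pred_a)
  a_hit <- pred_a == rewarded
  b_hit <- pred_b == rewarded
  out <- ifelse(a_hit & !b_hit, "A", ifelse(b_hit & !a_hit, "B", NA))
  tie <- is.na(out)
  out[tie] <- ifelse(runif(sum(tie)) < 0.5, "A", "B")
  out
}

#' Calibrate execution-noise flip probability
#'
#' Execution noise flips the decided response with probability
#' `flip_prob`, taking an error-free rate `model_rate` down to the
#' behavioural `target_rate`:
#' `target = model (1 - flip) + (1 - model) flip`, whose unique solution
#' is `flip = (model - target) / (2 model - 1)`. Noise can only pull
#' performance towards chance, so the target must lie between 0.5 and
#' the model rate.
#'
#' @param model_rate classifier/decision success rate before noise,
#'   above 0.5.
#' @param target_rate desired post-noise success rate in
#'   `[0.5, model_rate]`.
#' @return list of class `noise_model`: `flip_prob`, `target_rate`,
#'   `model_rate`.
#' @export
calibrate_flip_probability <- function(model_rate, target_rate) {
  if (model_rate <= 0.5)
    stop("model_rate must exceed 0.5 (flip probability unidentifiable)",
         call. = FALSE)
  if (target_rate > model_rate)
    stop("execution noise cannot raise accuracy above the model rate",
         call. = FALSE)
  if (target_rate < 0.5)
    stop("target_rate below chance is not reachable with flip_prob <= 0.5",
         call. = FALSE)
  flip <- (model_rate - target_rate) / (2 * model_rate - 1)
  structure(list(flip_prob = flip, target_rate = target_rate,
                 model_rate = model_rate), class = "noise_model")
}

#' Apply execution noise to a correctness sequence
#'
#' Independently flips each trial outcome with the calibrated
#' probability, emulating response noise downstream of the perceptual
#' decision.
#'
#' @param correct logical vector of trial correctness.
#' @param noise a [calibrate_flip_probability()] result, or a bare
#'   flip probability.
#' @return logical vector of noisy correctness. Uses the current RNG
#'   stream.
#' @export
apply_execution_noise <- function(correct, noise) {
  flip <- if (inherits(noise, "noise_model")) noise$flip_prob else noise
  stopifnot(flip >= 0, flip <= 0.5)
  xor(correct, runif(length(correct)) < flip)
}

#' Simulate a paired-presentation categorization experiment
#'
#' Full generative loop of the behavioural model: on each trial one
#' stimulus from each category is drawn, both are classified by the
#' trained model, the decision rule picks a side, and execution noise
#' flips the outcome with the calibrated probability. With a
#' near-perfect classifier the success rate converges to the noise
#' target.
#'
#' @param features data.frame with columns `id`, `label` and feature
#'   columns (as from [extract_features()]).
#' @param model a fitted classifier with a `predict` method on the
#'   standardized feature matrix, as returned by [train_categorizer()].
#' @param rewarded rewarded category label.
#' @param noise a `noise_model` (or bare flip probability; 0 = no noise).
#' @param n_trials number of simulated trials.
#' @param seed integer seed.
#' @param fish_id identifier stored in the trial records.
#' @return data.frame of trial records: stimulus_a, stimulus_b,
#'   category_a, category_b, chosen, correct, fish_id, session.
#' @export
simulate_experiment <- function(features, model, rewarded, noise = 0,
                                n_trials = 200, seed = 1L,
                                fish_id = "sim01") {
  stopifnot(all(c("id", "label") %in% names(features)))
  labs <- unique(features$label)
  stopifnot(length(labs) == 2, rewarded %in% labs)
  other <- setdiff(labs, rewarded)
  pred <- predict_categorizer(model, features)
  with_local_seed(seed, {
    ia <- sample(which(features$label == rewarded), n_trials, replace = TRUE)
    ib <- sample(which(features$label == other), n_trials, replace = TRUE)
    swap <- runif(n_trials) < 0.5  # rewarded stimulus on either side
    a <- ifelse(swap, ib, ia)
    b <- ifelse(swap, ia, ib)
    chosen <- decide_pair(pred[a], pred[b], rewarded)
    chosen_cat <- ifelse(chosen == "A", features$label[a],
                         features$label[b])
    correct <- apply_execution_noise(chosen_cat == rewarded, noise)
    # noise flips the executed response, so the chosen side flips with it
    flipped <- correct != (chosen_cat == rewarded)
    chosen[flipped] <- ifelse(chosen[flipped] == "A", "B", "A")
    data.frame(stimulus_a = features$id[a], stimulus_b = features$id[b],
               category_a = features$label[a],
               category_b = features$label[b],
               chosen = chosen, correct = correct,
               fish_id = fish_id,
               session = rep(seq_len(ceiling(n_trials / 20)),
                             each = 20)[seq_len(n_trials)])
  })
}

#' Train a categorizer on a feature table
#'
#' Standardizes the feature columns (whole-table statistics) and fits the
#' requested classifier on all rows; used as the frozen perception stage
#' inside behavioural simulations, where no further protocol splitting
#' happens.
#'
#' @param features data.frame with `label` and feature columns.
#' @param classifier `"svm"` or `"knn"`.
#' @param feature_cols which feature columns to use; default all 18.
#' @return list of class `categorizer` with the fit and the
#'   standardization constants.
#' @export
train_categorizer <- function(features, classifier = c("svm", "knn"),
                              feature_cols = feature_names()) {
  classifier <- match.arg(classifier)
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  y <- factor(features$label)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  fit <- if (classifier == "svm")
    e1071::svm(Z, y, kernel = "linear", cost = 1, scale = FALSE)
  else list(train = Z, y = y)
  structure(list(fit = fit, mu = mu, sdev = sdev, classifier = classifier,
                 feature_cols = feature_cols), class = "categorizer")
}

#' @rdname train_categorizer
#' @param model a `categorizer`.
#' @export
predict_categorizer <- function(model, features) {
  stopifnot(inherits(model, "categorizer"))
  X <- as.matrix(features[, model$feature_cols, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sdev, "/")
  if (model$classifier == "svm") as.character(predict(model$fit, Z))
  else as.character(class::knn(model$fit$train, Z, model$fit$y, k = 5))
}

#' Fish-versus-model independence table
#'
#' Joint outcome proportions of {fish correct/incorrect} x {model
#' correct/incorrect}, the proportions expected under independence (the
#' product of the marginals), and their difference. Agreement between
#' observed and expected indicates the fish's errors are not tied to the
#' images the model finds hard.
#'
#' @param fish_correct,model_correct aligned logical outcome vectors.
#' @return list with `observed`, `expected` and `difference` 2x2
#'   matrices (rows: fish, cols: model) and `max_deviation`.
#' @export
independence_analysis <- function(fish_correct, model_correct) {
  if (!length(fish_correct) || length(fish_correct) != length(model_correct))
    stop("need equal-length non-empty outcome vectors", call. = FALSE)
  f <- factor(fish_correct, levels = c(TRUE, FALSE))
  m <- factor(model_correct, levels = c(TRUE, FALSE))
  obs <- table(fish = f, model = m) / length(f)
  exp_ <- outer(table(f) / length(f), table(m) / length(m))
  obs <- matrix(obs, 2, 2, dimnames = list(fish = c("correct", "error"),
                                           model = c("correct", "error")))
  exp_ <- matrix(exp_, 2, 2, dimnames = dimnames(obs))
  list(observed = obs, expected = exp_, difference = obs - exp_,
       max_deviation = max(abs(obs - exp_)))
}
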