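#' Convert mode/concentration to beta shape parameters
#'
#' The hierarchical model parameterizes the group-level beta distribution
#' by its mode `omega` and concentration `kappa`:
#' `a = omega (kappa - 2) + 1`, `b = (1 - omega)(kappa - 2) + 1`, so that
#' Beta(a, b) has mode `omega` for `kappa > 2` and `kappa = 2` gives the
#' uniform.
#'
#' @param omega mode in (0, 1).
#' @param kappa concentration, >= 2.
#' @return numeric vector `c(a, b)`.
#' @export
mode_conc_to_shapes <- function(omega, kappa) {
  stopifnot(omega > 0, omega < 1)
  if (kappa < 2) stop("kappa must be >= 2", call. = FALSE)
  c(a = omega * (kappa - 2) + 1, b = (1 - omega) * (kappa - 2) + 1)
}

#' Fit the hierarchical beta-binomial model
#'
#' Per-fish success counts are binomial with rate `p_fish`; the `p_fish`
#' come from a beta distribution with mode `omega` and concentration
#' `kappa`; priors are broad and uniform (`omega ~ U(0,1)`,
#' `kappa - 2 ~ U(0, kappa_max - 2)`). Sampling alternates exact
#' conjugate Gibbs draws of each `p_fish` given (`omega`, `kappa`) with
#' random-walk Metropolis updates of `logit(omega)` and
#' `log(kappa - 2)`; step sizes adapt towards a 40% acceptance rate
#' during burn-in only. Either hyperparameter can be clamped, which
#' reduces the model to independent conjugate beta posteriors (used as
#' an exactness oracle).
#'
#' @param data data.frame with columns `n_trials` and `n_successes`
#'   (optionally `fish_id`), one row per fish.
#' @param chains number of independent chains.
#' @param samples retained draws per chain (after burn-in).
#' @param burn_in adaptation/warm-up iterations per chain, discarded.
#' @param seed integer seed.
#' @param omega_fixed,kappa_fixed optional clamped hyperparameter values.
#' @param kappa_max upper bound of the uniform prior on `kappa`.
#' @return object of class `fishcat_posterior`: arrays `omega`, `kappa`
#'   (`samples x chains`) and `p` (`samples x chains x n_fish`), the
#'   data, and split R-hat diagnostics per parameter. A warning is
#'   raised if any split R-hat is 1.1 or more.
#' @export
fit_hierarchical <- function(data, chains = 3, samples = 10000,
                             burn_in = 2000, seed = 1L,
                             omega_fixed = NULL, kappa_fixed = NULL,
                             kappa_max = 1002) {
  stopifnot(all(c("n_trials", "n_successes") %in% names(data)),
            nrow(data) >= 1, chains >= 1)
  k <- data$n_successes
  n <- data$n_trials
  if (any(n <= 0)) stop("every fish needs at least one trial", call. = FALSE)
  if (any(k < 0 | k > n)) stop("invalid success counts", call. = FALSE)
  n_fish <- length(k)
  omega_draws <- matrix(NA_real_, samples, chains)
  kappa_draws <- matrix(NA_real_, samples, chains)
  p_draws <- array(NA_real_, c(samples, chains, n_fish))
  for (ch in seq_len(chains)) {
    res <- with_local_seed(derive_seed(seed, paste0("chain", ch)), {
      run_chain(k, n, samples, burn_in, omega_fixed, kappa_fixed, kappa_max)
    })
    omega_draws[, ch] <- res$omega
    kappa_draws[, ch] <- res$kappa
    p_draws[, ch, ] <- res$p
  }
  rh <- if (chains >= 2)
    c(omega = rhat(omega_draws), kappa = rhat(kappa_draws),
      stats::setNames(vapply(seq_len(n_fish),
                             function(i) rhat(p_draws[, , i, drop = FALSE]
                                              [, , 1]),
                             numeric(1)),
                      paste0("p_", seq_len(n_fish))))
  else
    stats::setNames(rep(NA_real_, 2 + n_fish),
                    c("omega", "kappa", paste0("p_", seq_len(n_fish))))
  free <- c(is.null(omega_fixed), is.null(kappa_fixed), rep(TRUE, n_fish))
  if (any(rh[free] >= 1.1, na.rm = TRUE))
    warning("chains have not converged: split R-hat >= 1.1 for ",
            paste(names(rh)[free & !is.na(rh) & rh >= 1.1], collapse = ", "),
            call. = FALSE)
  structure(list(omega = omega_draws, kappa = kappa_draws, p = p_draws,
                 data = data, rhat = rh, seed = as.integer(seed),
                 fixed = list(omega = omega_fixed, kappa = kappa_fixed)),
            class = "fishcat_posterior")
}

run_chain <- function(k, n, samples, burn_in, omega_fixed, kappa_fixed,
                      kappa_max) {
  n_fish <- length(k)
  omega <- if (is.null(omega_fixed)) runif(1, 0.2, 0.8) else omega_fixed
  kappa <- if (is.null(kappa_fixed)) runif(1, 5, 50) else kappa_fixed
  step <- c(omega = 0.5, kappa = 0.5)  # RW sd on logit/log scale
  out_o <- numeric(samples)
  out_k <- numeric(samples)
  out_p <- matrix(NA_real_, samples, n_fish)
  total <- burn_in + samples
  acc <- c(omega = 0L, kappa = 0L)
  for (it in seq_len(total)) {
    ab <- mode_conc_to_shapes(omega, kappa)
    p <- rbeta(n_fish, ab[1] + k, ab[2] + n - k)
    # guard against underflow at extreme shapes
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    if (is.null(omega_fixed)) {
      eta <- stats::qlogis(omega)
      eta_new <- eta + rnorm(1, 0, step["omega"])
      om_new <- stats::plogis(eta_new)
      lr <- hyper_loglik(p, om_new, kappa) - hyper_loglik(p, omega, kappa) +
        log(om_new * (1 - om_new)) - log(omega * (1 - omega))
      if (is.finite(lr) && log(runif(1)) < lr) {
        omega <- om_new
        acc["omega"] <- acc["omega"] + 1L
      }
    }
    if (is.null(kappa_fixed)) {
      zeta <- log(kappa - 2)
      zeta_new <- zeta + rnorm(1, 0, step["kappa"])
      ka_new <- 2 + exp(zeta_new)
      if (ka_new <= kappa_max) {
        lr <- hyper_loglik(p, omega, ka_new) - hyper_loglik(p, omega, kappa) +
          zeta_new - zeta
        if (is.finite(lr) && log(runif(1)) < lr) {
          kappa <- ka_new
          acc["kappa"] <- acc["kappa"] + 1L
        }
      }
    }
    if (it <= burn_in && it %% 50 == 0) {
      rate <- acc / 50
      step <- step * exp(0.5 * (rate - 0.4))
      step <- pmin(pmax(step, 0.01), 5)
      acc[] <- 0L
    }
    if (it > burn_in) {
      out_o[it - burn_in] <- omega
      out_k[it - burn_in] <- kappa
      out_p[it - burn_in, ] <- p
    }
  }
  list(omega = out_o, kappa = out_k, p = out_p)
}

hyper_loglik <- function(p, omega, kappa) {
  ab <- mode_conc_to_shapes(omega, kappa)
  sum(dbeta(p, ab[1], ab[2], log = TRUE))
}

#' Highest density interval from posterior draws
#'
#' Shortest contiguous interval containing `mass` of the sorted draws;
#' ties in width break towards the lower start. For a unimodal posterior
#' this is the HDI.
#'
#' @param draws numeric vector of posterior draws (at least 1000).
#' @param mass interval probability mass.
#' @return object of class `hdi_interval`: `lower`, `upper`, `mass`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  stopifnot(mass > 0, mass <= 1)
  if (length(draws) < 1000)
    stop("need at least 1000 draws for a stable HDI", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) {
    iv <- c(x[1], x[n])
  } else {
    starts <- seq_len(n - m + 1)
    widths <- x[starts + m - 1] - x[starts]
    s <- starts[which.min(widths)]
    iv <- c(x[s], x[s + m - 1])
  }
  structure(list(lower = iv[1], upper = iv[2], mass = mass),
            class = "hdi_interval")
}

#' @export
print.hdi_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI: [%.4f, %.4f]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Compare an HDI against a region of practical equivalence
#'
#' Classifies the interval against the ROPE `[center - halfwidth,
#' center + halfwidth]`: `"above"` when the whole interval lies above the
#' ROPE, `"below"` symmetric, `"within"` when contained in it, and
#' `"overlapping"` otherwise. A success rate is credibly different from
#' chance only when its HDI is wholly outside the ROPE.
#'
#' @param interval an [hdi()] result (or `c(lower, upper)`).
#' @param center ROPE center (0.5 = chance in a two-alternative task).
#' @param halfwidth ROPE half-width.
#' @return one of `"above"`, `"below"`, `"within"`, `"overlapping"`.
#' @export
rope_assessment <- function(interval, center = 0.5, halfwidth = 0.05) {
  if (inherits(interval, "hdi_interval"))
    interval <- c(interval$lower, interval$upper)
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (interval[1] > hi) "above"
  else if (interval[2] < lo) "below"
  else if (interval[1] >= lo && interval[2] <= hi) "within"
  else "overlapping"
}

#' Difference of success rates between two conditions
#'
#' Draw-wise differences of group-level mode draws (or any two matched
#' draw vectors), summarized by an HDI and a ROPE decision around zero.
#'
#' @param samples_1,samples_2 `fishcat_posterior` objects (the
#'   group-level mode draws are compared) or numeric draw vectors of
#'   equal length.
#' @param mass HDI mass.
#' @param halfwidth ROPE half-width around zero.
#' @return list: `hdi` (of the difference 1 - 2), `decision`, `mean_diff`.
#' @export
compare_success_rates <- function(samples_1, samples_2, mass = 0.95,
                                  halfwidth = 0.05) {
  d1 <- if (inherits(samples_1, "fishcat_posterior"))
    as.numeric(samples_1$omega) else as.numeric(samples_1)
  d2 <- if (inherits(samples_2, "fishcat_posterior"))
    as.numeric(samples_2$omega) else as.numeric(samples_2)
  if (length(d1) != length(d2))
    stop("draw vectors must be matched (equal length)", call. = FALSE)
  diff_draws <- d1 - d2
  if (all(abs(diff_draws) < 1e-15)) {
    iv <- structure(list(lower = 0, upper = 0, mass = mass),
                    class = "hdi_interval")
    return(list(hdi = iv, decision = "within", mean_diff = 0))
  }
  iv <- hdi(diff_draws, mass)
  list(hdi = iv,
       decision = rope_assessment(iv, center = 0, halfwidth = halfwidth),
       mean_diff = mean(diff_draws))
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical R-hat computed over the
#' split halves; values near 1 indicate the chains agree.
#'
#' @param chains matrix of draws, `iterations x chains` (at least 2
#'   columns, or 1 column which is then split in two).
#' @return numeric R-hat (NA if the draws are constant).
#' @export
rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2)
    stop("split R-hat needs at least 2 chains", call. = FALSE)
  half <- floor(nrow(chains) / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j) {
    cbind(chains[seq_len(half), j], chains[half + seq_len(half), j])
  }))
  m <- ncol(split)
  n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize a fitted posterior
#'
#' @param fit a `fishcat_posterior`.
#' @param mass HDI mass.
#' @param rope_center,rope_halfwidth ROPE used for the per-parameter
#'   decision.
#' @return data.frame: parameter, mean, hdi_lower, hdi_upper, rhat,
#'   rope_decision.
#' @export
posterior_summary <- function(fit, mass = 0.95, rope_center = 0.5,
                              rope_halfwidth = 0.05) {
  stopifnot(inherits(fit, "fishcat_posterior"))
  n_fish <- dim(fit$p)[3]
  ids <- if (!is.null(fit$data$fish_id)) as.character(fit$data$fish_id)
         else paste0("fish", seq_len(n_fish))
  one <- function(draws, name, rh) {
    iv <- hdi(as.numeric(draws), mass)
    data.frame(parameter = name, mean = mean(draws),
               hdi_lower = iv$lower, hdi_upper = iv$upper, rhat = rh,
               rope_decision = rope_assessment(iv, rope_center,
                                               rope_halfwidth))
  }
  rows <- list(one(fit$omega, "omega", fit$rhat["omega"]))
  for (i in seq_len(n_fish))
    rows[[i + 1]] <- one(fit$p[, , i], ids[i],
                         fit$rhat[paste0("p_", i)])
  kap <- hdi(as.numeric(fit$kappa), mass)
  rows[[length(rows) + 1]] <-
    data.frame(parameter = "kappa", mean = mean(fit$kappa),
               hdi_lower = kap$lower, hdi_upper = kap$upper,
               rhat = fit$rhat["kappa"], rope_decision = NA)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
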