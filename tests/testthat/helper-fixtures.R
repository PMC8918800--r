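# shared fixtures, built once per test run and memoized
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small shape-dominant stimulus set + feature table used across modules
fx_set <- function() fx("set", function() {
  gen_stimulus_set(15, size_levels = c(10000, 50000),
                   separation_profile = "shape_dominant", seed = 42)
})

fx_feats <- function() fx("feats", function() {
  s <- fx_set()
  extract_features(s$images, labels = s$manifest$category)
})

fx_tex_set <- function() fx("tex_set", function() {
  gen_stimulus_set(15, size_levels = c(10000, 50000),
                   separation_profile = "texture_dominant", seed = 43)
})

# accuracy of the best single-feature threshold classifier
threshold_accuracy <- function(x, labels, positive = "animal") {
  cuts <- sort(unique(x))
  max(vapply(cuts, function(t) {
    acc <- mean((x >= t) == (labels == positive))
    max(acc, 1 - acc)
  }, numeric(1)))
}

# independent convex-hull oracle: gift-wrapping (Jarvis march) + shoelace
oracle_hull_area <- function(points) {
  pts <- unique(points)
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 2] + pts[, 1] * 1e-9)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cand == cur || cr > 0 ||
          (abs(cr) < 1e-12 &&
           sum((pts[j, ] - pts[cur, ])^2) > sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  poly <- pts[hull, , drop = FALSE]
  u <- poly[, 1]; v <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(u * v[j] - u[j] * v)) / 2
}

# independent corner counter: turning angle of the smoothed contour over a
# fixed arc window, counting circular runs above a fixed angle threshold
oracle_corner_count <- function(mask, window = 40, min_turn = pi / 6) {
  ct <- trace_contour(mask)
  p <- ct$smooth_points
  n <- nrow(p)
  d <- rbind(diff(p), p[1, ] - p[nrow(p), ])
  step <- sqrt(rowSums(d^2))
  k <- max(3L, round(window / mean(step)))
  idx <- function(i) ((i - 1) %% n) + 1
  turn <- vapply(seq_len(n), function(i) {
    a <- p[idx(i + k), ] - p[i, ]
    b <- p[i, ] - p[idx(i - k), ]
    ang <- atan2(a[1], a[2]) - atan2(b[1], b[2])
    abs(atan2(sin(ang), cos(ang)))
  }, numeric(1))
  flag <- turn > min_turn
  if (!any(flag)) return(0L)
  if (all(flag)) return(1L)
  prev <- flag[c(n, seq_len(n - 1))]
  sum(flag & !prev)
}

# dense-grid HDI oracle for a Beta(a, b) posterior: minimize the interval
# width over the lower tail probability
oracle_beta_hdi <- function(a, b, mass = 0.95, grid = 20000) {
  u <- seq(1e-7, 1 - mass - 1e-7, length.out = grid)
  width <- qbeta(u + mass, a, b) - qbeta(u, a, b)
  s <- u[which.min(width)]
  c(qbeta(s, a, b), qbeta(s + mass, a, b))
}

# exhaustive best-subset protocol success for subset sizes 1 and 2
exhaustive_best <- function(X, y, size, seed, iterations = 10) {
  combos <- utils::combn(ncol(X), size, simplify = FALSE)
  best <- -Inf
  for (cc in combos) {
    s <- evaluate_protocol(X[, cc, drop = FALSE], y,
                           iterations = iterations, seed = seed)$mean_success
    if (s > best) best <- s
  }
  best
}

# synthetic feature matrix: one informative column among noise
informative_matrix <- function(n = 120, p = 5, informative = 1, gap = 3,
                               seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    y <- rep(c("a", "b"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, informative] <- ifelse(y == "a", gap, -gap) + rnorm(n)
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = y)
  })
}
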