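#' Derive a stage seed from a top-level seed
#'
#' Expands one user-facing seed into independent per-stage seeds so that
#' pipeline stages can be re-run in isolation and still reproduce their
#' output bit-for-bit. The stage name is hashed with a small polynomial
#' rolling hash; the result stays within R's 32-bit integer range.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name, e.g. `"stimuli"` or `"mcmc"`.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

assert_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  rng <- range(img)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  invisible(mask)
}

#' Read / write grayscale stimulus images
#'
#' Thin wrappers around the png package that enforce the package's image
#' convention: numeric `[row, col]` matrix, intensities in `[0, 1]`,
#' written as 8-bit grayscale PNG.
#'
#' @param path file path of a PNG image.
#' @param img numeric matrix in `[0, 1]`.
#' @return `read_stimulus()` returns a numeric matrix; `write_stimulus()`
#'   returns `path` invisibly.
#' @export
read_stimulus <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  assert_gray_image(px)
}

#' @rdname read_stimulus
#' @export
write_stimulus <- function(img, path) {
  assert_gray_image(img)
  png::writePNG(round(img * 255) / 255, path)
  invisible(path)
}
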