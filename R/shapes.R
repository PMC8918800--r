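#' Render analytic reference shapes
#'
#' Binary masks and grayscale images of ideal geometric shapes (disc,
#' rectangle, ellipse, regular star, polygon). These are the analytic
#' ground truth used to validate the feature extractors: a disc has
#' roundness 1 and eccentricity 0, a 2:1 ellipse has eccentricity
#' sqrt(3)/2, and so on.
#'
#' All renderers place the shape centred on a white square canvas and
#' return either a logical mask or a grayscale image (object intensity
#' `fg` on background 1).
#'
#' @param r disc radius in pixels.
#' @param side canvas side in pixels; default leaves a safe white margin.
#' @param a,b ellipse semi-axes (rows, cols) in pixels.
#' @param h,w rectangle height and width in pixels.
#' @param rotation rotation of the shape in degrees (counter-clockwise).
#' @name render_shapes
NULL

pixel_grid <- function(side) {
  c0 <- (side + 1) / 2
  list(r = matrix(seq_len(side) - c0, side, side),
       c = matrix(seq_len(side) - c0, side, side, byrow = TRUE))
}

#' @rdname render_shapes
#' @export
render_disc_mask <- function(r, side = ceiling(2 * r) + 21) {
  g <- pixel_grid(side)
  g$r^2 + g$c^2 <= r^2
}

#' @rdname render_shapes
#' @export
render_rect_mask <- function(h, w, side = max(h, w) + 20) {
  m <- matrix(FALSE, side, side)
  r0 <- floor((side - h) / 2); c0 <- floor((side - w) / 2)
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

#' @rdname render_shapes
#' @export
render_ellipse_mask <- function(a, b, rotation = 0,
                                side = 2 * max(a, b) + 21) {
  g <- pixel_grid(side)
  th <- rotation * pi / 180
  u <- cos(th) * g$r + sin(th) * g$c
  v <- -sin(th) * g$r + cos(th) * g$c
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a filled polygon mask by even-odd scanline fill
#'
#' @param vertices two-column matrix of (row, col) vertex coordinates.
#' @param side canvas side, or a length-2 vector `c(rows, cols)`.
#' @rdname render_shapes
#' @export
render_polygon_mask <- function(vertices, side) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  dims <- if (length(side) == 1) c(side, side) else side
  m <- matrix(FALSE, dims[1], dims[2])
  vr <- vertices[, 1]; vc <- vertices[, 2]
  n <- length(vr)
  jj <- c(n, seq_len(n - 1))
  for (row in seq_len(dims[1])) {
    y <- row
    crosses <- which((vr > y) != (vr[jj] > y))
    if (!length(crosses)) next
    xs <- vc[crosses] + (y - vr[crosses]) /
      (vr[jj][crosses] - vr[crosses]) * (vc[jj][crosses] - vc[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      if (hi >= lo) m[row, max(1, lo):min(dims[2], hi)] <- TRUE
    }
  }
  m
}

#' @param n_points number of star points.
#' @param r_outer,r_inner outer and inner vertex radii of the star.
#' @rdname render_shapes
#' @export
render_star_mask <- function(n_points = 5, r_outer, r_inner = r_outer * 0.4,
                             rotation = 0, side = 2 * r_outer + 21) {
  k <- seq_len(2 * n_points)
  ang <- -pi / 2 + (k - 1) * pi / n_points + rotation * pi / 180
  rad <- ifelse(k %% 2 == 1, r_outer, r_inner)
  c0 <- (side + 1) / 2
  v <- cbind(c0 + rad * sin(ang), c0 + rad * cos(ang))
  render_polygon_mask(v, side)
}

#' @param mask logical matrix to paint.
#' @param fg object intensity in `[0, 1)`.
#' @rdname render_shapes
#' @export
mask_to_image <- function(mask, fg = 0) {
  assert_mask(mask)
  img <- matrix(1, nrow(mask), ncol(mask))
  img[mask] <- fg
  img
}
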