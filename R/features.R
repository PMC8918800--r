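#' Names of the 18 object descriptors
#'
#' Order is fixed and used everywhere a feature matrix is built: area,
#' hull area, hull ratio, perimeter and roundness (compactness); number
#' and mean curvature of sharp contour sections; eccentricity of the
#' object and of its convex hull; entropy, standard deviation and
#' skewness of object intensities; checkerboard and star template
#' correlations; grayscale and silhouette mirror symmetry; mean and total
#' energy of the inverted bounding box.
#'
#' @return character vector of length 18.
#' @export
feature_names <- function() {
  c("area", "hull_area", "hull_ratio", "perimeter", "roundness",
    "n_sharp_curves", "mean_sharp_curvature",
    "eccentricity", "hull_eccentricity",
    "entropy", "intensity_std", "skewness",
    "checker_corr", "star_corr",
    "gray_symmetry", "silhouette_symmetry",
    "mean_energy", "total_energy")
}

# convex hull of the object's boundary-pixel corners: every mask pixel's
# unit square lies inside this polygon, so hull_area >= area always holds.
hull_polygon <- function(contour_points) {
  p <- contour_points
  corners <- rbind(p + rep(c(-0.5, -0.5), each = nrow(p)),
                   p + rep(c(-0.5,  0.5), each = nrow(p)),
                   p + rep(c( 0.5, -0.5), each = nrow(p)),
                   p + rep(c( 0.5,  0.5), each = nrow(p)))
  corners[chull(corners[, 2], corners[, 1]), , drop = FALSE]
}

shoelace_area <- function(poly) {
  u <- poly[, 1]; v <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(u * v[j] - u[j] * v)) / 2
}

#' Compactness descriptors (f1-f5)
#'
#' Area (filled mask pixel count), convex hull area, their ratio
#' (reciprocal solidity; > 1 signals concavities such as limbs), perimeter
#' and roundness = perimeter^2 / (4 pi area), which equals 1 for a disc by
#' the isoperimetric inequality and grows with boundary complexity.
#'
#' @param mask logical object mask (holes filled).
#' @param contour a [trace_contour()] result for `mask`.
#' @return named numeric vector: area, hull_area, hull_ratio, perimeter,
#'   roundness.
#' @export
compactness_features <- function(mask, contour) {
  area <- sum(mask)
  if (area == 0) stop("zero-area mask", call. = FALSE)
  hull <- hull_polygon(contour$points)
  hull_area <- shoelace_area(hull)
  per <- contour$perimeter
  c(area = area, hull_area = hull_area, hull_ratio = hull_area / area,
    perimeter = per, roundness = per^2 / (4 * pi * area))
}

#' Contour curvature descriptors (f6-f7)
#'
#' The smoothed contour is scanned with arc-length windows of
#' `section_px` pixels advanced by `stride` (overlapping, so a corner is
#' always near the centre of some window rather than split across a
#' section boundary). Each window is rotated so its endpoint chord is
#' horizontal and a quadratic is fitted; the window's curvature is twice
#' the magnitude of the leading coefficient (the second derivative of the
#' fit). A window is sharp when its curvature exceeds the spread
#' criterion over all windows; because neighbouring windows overlap, one
#' corner lights up a contiguous run of windows, and `n_sharp_curves`
#' counts maximal circular runs while `mean_sharp_curvature` averages the
#' curvature of sharp windows (0 when none). When the curvatures are
#' uniform up to estimation noise — relative spread below
#' `degenerate_cv`, as on a disc — the object is treated as having
#' constant curvature and no sharp curves.
#'
#' @param contour a [trace_contour()] result.
#' @param section_px target section arc length in pixels.
#' @param threshold `"literal"` flags sections with curvature above the
#'   standard deviation of all section curvatures; `"mean_plus_sd"` flags
#'   those above mean + sd.
#' @param degenerate_cv relative-spread floor below which no section is
#'   flagged.
#' @return named numeric vector: n_sharp_curves, mean_sharp_curvature.
#' @export
curvature_features <- function(contour, section_px = 100,
                               threshold = c("literal", "mean_plus_sd"),
                               degenerate_cv = 0.05,
                               stride = section_px / 4) {
  threshold <- match.arg(threshold)
  pts <- contour$smooth_points
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  arc <- cumsum(sqrt(rowSums(d^2)))
  total <- arc[length(arc)]
  pos <- c(0, arc[-length(arc)])
  if (total <= section_px) {
    return(c(n_sharp_curves = 0, mean_sharp_curvature = 0))
  }
  n_win <- max(1L, as.integer(floor(total / stride)))
  starts <- (seq_len(n_win) - 1) * stride
  curv <- vapply(starts, function(s0) {
    lo <- s0; hi <- s0 + section_px
    sel <- if (hi <= total) pos >= lo & pos < hi else pos >= lo | pos < hi - total
    p <- pts[sel, , drop = FALSE]
    if (hi > total) {  # wrapped window: restore point order along the arc
      first <- pos[sel] >= lo
      p <- rbind(pts[sel, , drop = FALSE][first, , drop = FALSE],
                 pts[sel, , drop = FALSE][!first, , drop = FALSE])
    }
    if (nrow(p) < 5) return(NA_real_)
    section_curvature(p)
  }, numeric(1))
  ok <- is.finite(curv)
  curv <- curv[ok]
  if (!length(curv)) return(c(n_sharp_curves = 0, mean_sharp_curvature = 0))
  mu <- mean(curv); sdev <- if (length(curv) > 1) sd(curv) else 0
  if (sdev < degenerate_cv * mu)
    return(c(n_sharp_curves = 0, mean_sharp_curvature = 0))
  cut <- if (threshold == "literal") sdev else mu + sdev
  sharp <- curv > cut
  if (!any(sharp)) return(c(n_sharp_curves = 0, mean_sharp_curvature = 0))
  # windows overlap, so one corner lights up several consecutive windows:
  # count maximal circular runs of sharp windows, not windows themselves
  runs <- count_circular_runs(sharp)
  c(n_sharp_curves = runs, mean_sharp_curvature = mean(curv[sharp]))
}

count_circular_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(1L)
  if (!any(flag)) return(0L)
  prev <- flag[c(n, seq_len(n - 1))]
  sum(flag & !prev)
}

# parametric quadratic fit along arc length; curvature = |(r''(s), c''(s))|.
# Equivalent to the chord-aligned scalar fit for shallow sections, but still
# well defined when a sharp corner makes the section steep or folded.
section_curvature <- function(p) {
  d <- diff(p)
  s <- c(0, cumsum(sqrt(rowSums(d^2))))
  if (s[length(s)] < 4) return(NA_real_)
  s <- s - mean(s)
  fit <- stats::lm.fit(cbind(1, s, s^2), p)
  2 * sqrt(sum(fit$coefficients[3, ]^2))
}

# central second moments of TRUE pixels
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  rc <- r - mean(r); cc <- c - mean(c)
  # 1/12 term: each pixel is a unit square, not a point
  list(mu20 = mean(rc^2) + 1 / 12, mu02 = mean(cc^2) + 1 / 12,
       mu11 = mean(rc * cc),
       centroid = c(mean(r), mean(c)))
}

moments_to_ecc <- function(mu20, mu02, mu11) {
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- max(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  if (l1 <= 0) stop("degenerate mask: zero spatial extent", call. = FALSE)
  if (l2 <= 0) return(1 - 1e-9)
  sqrt(max(0, 1 - l2 / l1))
}

# area, centroid and central second moments of a polygon via Green's theorem
polygon_moments <- function(poly) {
  u <- poly[, 1]; v <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  a <- u * v[j] - u[j] * v
  A <- sum(a) / 2
  cu <- sum((u + u[j]) * a) / (6 * A)
  cv <- sum((v + v[j]) * a) / (6 * A)
  iuu <- sum((u^2 + u * u[j] + u[j]^2) * a) / 12
  ivv <- sum((v^2 + v * v[j] + v[j]^2) * a) / 12
  iuv <- sum((u * v[j] + 2 * u * v + 2 * u[j] * v[j] + u[j] * v) * a) / 24
  list(area = abs(A),
       mu20 = iuu / A - cu^2, mu02 = ivv / A - cv^2,
       mu11 = iuv / A - cu * cv)
}

#' Eccentricity descriptors (f8-f9)
#'
#' Eccentricity of the best-fit (second-moment) ellipse of the object and
#' of its convex hull: the distance between the foci divided by the major
#' axis length, i.e. sqrt(1 - (b/a)^2); 0 for a disc, approaching 1 for
#' elongated shapes.
#'
#' @inheritParams compactness_features
#' @return named numeric vector: eccentricity, hull_eccentricity.
#' @export
eccentricity_features <- function(mask, contour = NULL) {
  if (sum(mask) < 4) stop("degenerate mask", call. = FALSE)
  mm <- mask_moments(mask)
  e <- moments_to_ecc(mm$mu20, mm$mu02, mm$mu11)
  if (is.null(contour)) contour <- trace_contour(mask)
  hm <- polygon_moments(hull_polygon(contour$points))
  eh <- moments_to_ecc(hm$mu20, hm$mu02, hm$mu11)
  c(eccentricity = e, hull_eccentricity = eh)
}

#' Texture descriptors (f10-f12)
#'
#' Shannon entropy (base 2, 256 equal-width bins on `[0, 1]`), population
#' standard deviation, and skewness (normalized third central moment,
#' defined as 0 for a constant object) of the object pixel intensities.
#' Statistics are over object pixels only; background never contributes.
#'
#' @param img grayscale image.
#' @param mask logical object mask.
#' @return named numeric vector: entropy, intensity_std, skewness.
#' @export
texture_features <- function(img, mask) {
  v <- img[mask]
  bins <- tabulate(pmin(floor(v * 256) + 1L, 256L), nbins = 256L)
  p <- bins[bins > 0] / length(v)
  H <- -sum(p * log2(p))
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  skew <- if (m2 < 1e-12) 0 else m3 / m2^1.5
  c(entropy = H, intensity_std = sqrt(m2), skewness = skew)
}

bbox_of <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

checker_template <- function(h, w, k) {
  ri <- floor((seq_len(h) - 1) * k / h)
  ci <- floor((seq_len(w) - 1) * k / w)
  t <- outer(ri, ci, function(a, b) (a + b) %% 2)
  1 - 2 * t  # +1 on even cells, -1 on odd
}

star_template <- function(h, w, n_points = 5, inner_frac = 0.4) {
  k <- seq_len(2 * n_points)
  ang <- -pi / 2 + (k - 1) * pi / n_points
  rad <- ifelse(k %% 2 == 1, 1, inner_frac)
  vr <- rad * sin(ang); vc <- rad * cos(ang)
  # inscribe: affinely map the star's own bounding box onto the full h x w box
  v <- cbind(1 + (vr - min(vr)) / diff(range(vr)) * (h - 1),
             1 + (vc - min(vc)) / diff(range(vc)) * (w - 1))
  m <- render_polygon_mask(v, c(h, w))
  ifelse(m, 1, -1)
}

#' Template-correlation descriptors (f13-f14)
#'
#' The object (cropped to its bounding box, intensities mapped to
#' `2 I - 1` so black is -1 and white is +1) is correlated with +/-1
#' templates resized to the bounding box: checkerboards with 4, 6, 8, 10
#' and 12 checkers per row (the maximum over sizes is reported) and an
#' upright filled five-pointed star. Correlation is the absolute dot
#' product over object pixels divided by the object pixel count, so phase
#' is irrelevant and a balanced template scores ~0 on a constant object.
#'
#' @inheritParams texture_features
#' @param checker_sizes checkers per row for the checkerboard bank.
#' @return named numeric vector: checker_corr, star_corr.
#' @export
template_correlations <- function(img, mask,
                                  checker_sizes = c(4, 6, 8, 10, 12)) {
  bb <- bbox_of(mask)
  s <- 2 * img[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE] - 1
  m <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  n <- sum(m)
  h <- nrow(s); w <- ncol(s)
  cc <- max(vapply(checker_sizes, function(k) {
    t <- checker_template(h, w, k)
    abs(sum(s[m] * t[m])) / n
  }, numeric(1)))
  st <- star_template(h, w)
  c(checker_corr = cc, star_corr = abs(sum(s[m] * st[m])) / n)
}

# bilinear rotation about a center, white background
rotate_bilinear <- function(img, angle_rad, center) {
  h <- nrow(img); w <- ncol(img)
  out_r <- matrix(seq_len(h), h, w) - center[1]
  out_c <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  src_r <- ca * out_r - sa * out_c + center[1]
  src_c <- sa * out_r + ca * out_c + center[2]
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    v <- matrix(1, h, w)
    v[ok] <- img[cbind(rr[ok], cc[ok])]
    v
  }
  v <- at(r0, c0) * (1 - fr) * (1 - fc) + at(r0 + 1, c0) * fr * (1 - fc) +
    at(r0, c0 + 1) * (1 - fr) * fc + at(r0 + 1, c0 + 1) * fr * fc
  pmin(pmax(v, 0), 1)
}

mask_orientation <- function(mask) {
  mm <- mask_moments(mask)
  0.5 * atan2(2 * mm$mu11, mm$mu02 - mm$mu20)
}

rms_mirror <- function(box) {
  h <- nrow(box); w <- ncol(box)
  kh <- floor(h / 2); kw <- floor(w / 2)
  d_h <- if (kh >= 1)
    sqrt(mean((box[seq_len(kh), , drop = FALSE] -
               box[h + 1 - seq_len(kh), , drop = FALSE])^2)) else 0
  d_v <- if (kw >= 1)
    sqrt(mean((box[, seq_len(kw), drop = FALSE] -
               box[, w + 1 - seq_len(kw), drop = FALSE])^2)) else 0
  mean(c(d_h, d_v))
}

#' Mirror-symmetry descriptors (f15-f16)
#'
#' The image is rotated so the major axis of the object's best-fit
#' ellipse lies along the horizontal, then cropped to the object bounding
#' box. For each axis, one half is mirrored onto the other and the
#' root-mean-square intensity difference taken (Euclidean distance
#' normalized by the square root of the pixel count); the feature is the
#' mean over the two axes. `gray_symmetry` uses the grayscale values,
#' `silhouette_symmetry` the binary mask, so a shape-symmetric object
#' with asymmetric texture separates the two.
#'
#' @inheritParams texture_features
#' @return named numeric vector: gray_symmetry, silhouette_symmetry.
#' @export
symmetry_features <- function(img, mask, blur_sigma = 1.5,
                              work_side = 256) {
  if (sum(mask) < 4) stop("degenerate mask", call. = FALSE)
  # the measure is resolution-invariant, so work at a bounded resolution:
  # crop to the object and downscale the largest objects
  bb0 <- bbox_of(mask)
  img <- img[bb0[1]:bb0[2], bb0[3]:bb0[4], drop = FALSE]
  mask <- mask[bb0[1]:bb0[2], bb0[3]:bb0[4], drop = FALSE]
  if (max(dim(img)) > work_side) {
    f <- work_side / max(dim(img))
    h <- max(8L, round(nrow(img) * f)); w <- max(8L, round(ncol(img) * f))
    img <- pmin(pmax(EBImage::imageData(
      EBImage::resize(EBImage::Image(img), w = h, h = w)), 0), 1)
    dim(img) <- c(h, w)
    soft <- EBImage::imageData(
      EBImage::resize(EBImage::Image(mask * 1), w = h, h = w))
    dim(soft) <- c(h, w)
    mask <- soft >= 0.5
  }
  img <- pad_white(img, 4L)
  mpadded <- matrix(FALSE, nrow(img), ncol(img))
  mpadded[4L + seq_len(nrow(mask)), 4L + seq_len(ncol(mask))] <- mask
  mask <- mpadded
  th <- mask_orientation(mask)
  ctr <- mask_moments(mask)$centroid
  # pad so rotation cannot clip the object
  pad <- ceiling(max(dim(img)) * 0.25) + 2L
  rot <- rotate_bilinear(pad_white(img, pad), -th, ctr + pad)
  # soft mask: rotate the 0/1 mask with interpolation and keep it soft, so
  # boundary rasterization noise does not dominate the silhouette distance
  mpad <- matrix(0, nrow(rot), ncol(rot))
  mpad[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
  brot <- 1 - rotate_bilinear(1 - mpad, -th, ctr + pad)
  hard <- brot >= 0.5
  if (!any(hard)) stop("degenerate mask after rotation", call. = FALSE)
  bb <- bbox_of(hard)
  blur <- function(x) {
    if (blur_sigma <= 0) return(x)
    EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = blur_sigma))
  }
  g <- blur(rot)[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  b <- blur(brot)[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  c(gray_symmetry = rms_mirror(g), silhouette_symmetry = rms_mirror(b))
}

#' Energy descriptors (f17-f18)
#'
#' Mean and total value of the inverted image (`1 - I`) over the object's
#' bounding box, so that energy measures dark object content rather than
#' the white background: an all-white box scores 0, a black box filling
#' its bounding box scores mean 1.
#'
#' @inheritParams texture_features
#' @return named numeric vector: mean_energy, total_energy.
#' @export
energy_features <- function(img, mask) {
  bb <- bbox_of(mask)
  inv <- 1 - img[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  c(mean_energy = mean(inv), total_energy = sum(inv))
}

#' Extract the full 18-descriptor vector of one stimulus
#'
#' Runs mask extraction, contour tracing and every descriptor family on
#' one object-on-white grayscale image. Deterministic: the same image
#' always yields the same vector.
#'
#' @param img grayscale image matrix in `[0, 1]`.
#' @param curvature_threshold `"literal"` or `"mean_plus_sd"`, see
#'   [curvature_features()].
#' @return named numeric vector of length 18 (see [feature_names()]).
#' @export
extract_all <- function(img, curvature_threshold = "literal") {
  mask <- extract_object_mask(img)
  contour <- trace_contour(mask)
  out <- c(compactness_features(mask, contour),
           curvature_features(contour, threshold = curvature_threshold),
           eccentricity_features(mask, contour),
           texture_features(img, mask),
           template_correlations(img, mask),
           symmetry_features(img, mask),
           energy_features(img, mask))
  stopifnot(identical(names(out), feature_names()), all(is.finite(out)))
  out
}

#' Extract features for a list of stimuli into a data frame
#'
#' @param imgs named list of grayscale image matrices.
#' @param labels optional vector of class labels, recycled alongside
#'   `imgs`.
#' @param ... passed to [extract_all()].
#' @return data.frame with columns `id`, optionally `label`, and the 18
#'   descriptors.
#' @export
extract_features <- function(imgs, labels = NULL, ...) {
  stopifnot(is.list(imgs), length(imgs) >= 1)
  mat <- t(vapply(imgs, extract_all, numeric(18), ...))
  ids <- if (is.null(names(imgs))) as.character(seq_along(imgs))
         else names(imgs)
  out <- data.frame(id = ids, mat, row.names = NULL)
  if (!is.null(labels)) out <- cbind(out[1], label = labels, out[-1])
  out
}
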