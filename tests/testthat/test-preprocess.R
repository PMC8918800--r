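test_that("mask extraction is contrast-invariant and fills holes", {
  disc <- render_disc_mask(100)
  expect_lt(abs(sum(extract_object_mask(mask_to_image(disc))) /
                  (pi * 100^2) - 1), 0.01)
  # low-contrast version of the same disc: identical mask
  expect_identical(extract_object_mask(mask_to_image(disc, fg = 0.5)),
                   extract_object_mask(mask_to_image(disc, fg = 0)))
  expect_error(extract_object_mask(matrix(1, 50, 50)), "no object")

  # interior holes are filled ("pixels within the perimeter")
  ring <- disc & !render_disc_mask(60, side = ncol(disc))
  expect_equal(sum(extract_object_mask(mask_to_image(ring))), sum(disc))

  # corner-touching components are one 8-connected object
  ck <- matrix(1, 60, 60)
  ck[11:30, 11:30] <- 0
  ck[31:50, 31:50] <- 0
  expect_gte(sum(extract_object_mask(ck)), 800)
})

test_that("contour tracing recovers analytic perimeters", {
  sq <- trace_contour(render_rect_mask(100, 100))
  expect_lt(abs(sq$perimeter / 400 - 1), 0.02)
  dc <- trace_contour(render_disc_mask(100))
  expect_lt(abs(dc$perimeter / (2 * pi * 100) - 1), 0.03)
  expect_true(all(diff(dc$arc_lengths) > 0))
  # closed: first and last points are neighbours
  n <- nrow(dc$points)
  expect_lte(max(abs(dc$points[n, ] - dc$points[1, ])), 1)

  tiny <- matrix(FALSE, 5, 5)
  tiny[3, 3] <- TRUE
  expect_error(trace_contour(tiny), "degenerate")
})

test_that("mask extraction is idempotent on rendered masks", {
  for (mask in list(render_disc_mask(40), render_star_mask(5, 45),
                    render_ellipse_mask(50, 20, rotation = 30))) {
    expect_identical(extract_object_mask(mask_to_image(mask)), mask)
  }
})

test_that("contour polygon area agrees with pixel count for convex shapes", {
  for (mask in list(render_disc_mask(60), render_ellipse_mask(70, 35),
                    render_rect_mask(60, 90))) {
    ct <- trace_contour(mask)
    poly <- ct$points
    u <- poly[, 1]; v <- poly[, 2]
    j <- c(seq_len(nrow(poly))[-1], 1)
    a <- abs(sum(u * v[j] - u[j] * v)) / 2
    expect_lt(abs(a / sum(mask) - 1), 0.03)
  }
})

test_that("area normalization hits its target and preserves aspect", {
  img <- mask_to_image(render_disc_mask(113))  # ~40100 px
  out <- normalize_object_area(img, 10000)
  expect_true(sum(extract_object_mask(out)) %in% 9800:10200)
  m <- extract_object_mask(out)
  bb <- which(m, arr.ind = TRUE)
  aspect <- diff(range(bb[, 1])) / diff(range(bb[, 2]))
  expect_lt(abs(aspect - 1), 0.05)

  # identity: already at target
  expect_identical(normalize_object_area(img, sum(extract_object_mask(img))),
                   img)

  up <- normalize_object_area(mask_to_image(render_disc_mask(57)), 300000)
  expect_lt(abs(sum(extract_object_mask(up)) / 300000 - 1), 0.02)

  expect_error(normalize_object_area(img, 10), "floor")
})

test_that("silhouettes keep the mask and kill texture", {
  img <- gen_animal_stimulus(stimulus_params("animal", target_area = 10000,
                                             seed = 21))
  sil <- make_silhouette(img)
  expect_identical(extract_object_mask(sil), extract_object_mask(img))
  tf <- texture_features(sil, extract_object_mask(sil))
  expect_equal(unname(tf), c(0, 0, 0))
  # idempotent
  expect_identical(make_silhouette(sil), sil)
})

test_that("area normalization and silhouette commute", {
  img <- gen_animal_stimulus(stimulus_params("animal", target_area = 10000,
                                             seed = 22))
  a <- extract_object_mask(make_silhouette(normalize_object_area(img, 20000)))
  b <- extract_object_mask(normalize_object_area(make_silhouette(img), 20000))
  # canvases differ by padding, so compare mask statistics, not pixels
  expect_lt(abs(sum(a) / sum(b) - 1), 0.015)
  ha <- compactness_features(a, trace_contour(a))[["hull_ratio"]]
  hb <- compactness_features(b, trace_contour(b))[["hull_ratio"]]
  expect_lt(abs(ha / hb - 1), 0.02)
})

test_that("texture patches share a carrier and preserve the histogram", {
  p1 <- stimulus_params("animal", target_area = 10000, seed = 31)
  p2 <- stimulus_params("plant", target_area = 10000, seed = 32,
                        texture_amplitude = 0.18)
  i1 <- gen_animal_stimulus(p1)
  i2 <- gen_plant_stimulus(p2)
  t1 <- make_texture_patch(i1)
  t2 <- make_texture_patch(i2)
  # same carrier: shape features agree although source shapes differ
  for (tp in list(t1, t2)) {
    m <- extract_object_mask(tp)
    cf <- compactness_features(m, trace_contour(m))
    expect_lt(abs(cf[["hull_ratio"]] - 1), 0.02)
    expect_lt(abs(sum(m) / 10000 - 1), 0.02)
    expect_lt(eccentricity_features(m)[["eccentricity"]], 0.1)
  }
  # histogram-derived statistics survive the re-arrangement
  src <- texture_features(i1, extract_object_mask(i1))
  dst <- texture_features(t1, extract_object_mask(t1))
  expect_lt(abs(src[["intensity_std"]] - dst[["intensity_std"]]), 0.01)
  expect_lt(abs(src[["entropy"]] - dst[["entropy"]]), 0.1)

  # constant object -> zero spread
  sil <- make_silhouette(i1)
  expect_equal(texture_features(make_texture_patch(sil),
                                extract_object_mask(make_texture_patch(sil)))
               [["intensity_std"]], 0)
})
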