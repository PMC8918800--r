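test_that("compactness descriptors match analytic shapes", {
  disc <- render_disc_mask(100)
  cf <- compactness_features(disc, trace_contour(disc))
  expect_lt(abs(cf[["roundness"]] - 1), 0.05)
  expect_lt(abs(cf[["hull_ratio"]] - 1), 0.02)

  sq <- render_rect_mask(100, 100)
  cfs <- compactness_features(sq, trace_contour(sq))
  expect_lt(abs(cfs[["roundness"]] / (4 / pi) - 1), 0.05)

  # plus-pentomino of five 100x100 squares: hull 70000 over area 50000
  plus <- matrix(FALSE, 320, 320)
  plus[111:210, 11:310] <- TRUE
  plus[11:310, 111:210] <- TRUE
  cfp <- compactness_features(plus, trace_contour(plus))
  expect_equal(cfp[["area"]], 50000)
  expect_lt(abs(cfp[["hull_ratio"]] / 1.4 - 1), 0.03)
})

test_that("hull area matches a gift-wrapping + shoelace oracle", {
  set.seed(99)
  for (i in 1:10) {
    mask <- matrix(FALSE, 64, 64)
    ctr <- c(32, 32) + round(runif(2, -6, 6))
    r <- runif(1, 8, 20)
    g <- pixel_grid(64)
    rr <- g$r + 32.5 - ctr[1]
    cc <- g$c + 32.5 - ctr[2]
    k <- sample(2:5, 1)
    rad <- r * (1 + 0.3 * cos(k * atan2(rr, cc)))
    mask <- sqrt(rr^2 + cc^2) <= rad
    ct <- trace_contour(mask)
    mine <- compactness_features(mask, ct)[["hull_area"]]
    corners <- rbind(ct$points + rep(c(-0.5, -0.5), each = nrow(ct$points)),
                     ct$points + rep(c(-0.5, 0.5), each = nrow(ct$points)),
                     ct$points + rep(c(0.5, -0.5), each = nrow(ct$points)),
                     ct$points + rep(c(0.5, 0.5), each = nrow(ct$points)))
    expect_lt(abs(mine / oracle_hull_area(corners) - 1), 0.01)
  }
})

test_that("sharp-curve counts follow contour geometry", {
  expect_equal(curvature_features(trace_contour(render_disc_mask(200)))
               [["n_sharp_curves"]], 0)

  star <- render_star_mask(5, 400, r_inner = 150)
  nf <- curvature_features(trace_contour(star))[["n_sharp_curves"]]
  oracle <- oracle_corner_count(star)
  expect_equal(oracle, 10)
  expect_lte(abs(nf - oracle), 2)

  ell <- trace_contour(render_ellipse_mask(200, 50))
  cv <- curvature_features(ell)
  expect_lte(cv[["n_sharp_curves"]], 2)
  expect_gte(cv[["n_sharp_curves"]], 1)
  # sharp sections sit at the high-curvature ends: mean sharp curvature is
  # well above the ellipse's minimum curvature b/a^2
  expect_gt(cv[["mean_sharp_curvature"]], 5 * (50 / 200^2))
})

test_that("eccentricity matches moment ellipses", {
  expect_lt(eccentricity_features(render_disc_mask(80))[["eccentricity"]],
            0.1)
  e <- eccentricity_features(render_ellipse_mask(100, 50))
  expect_lt(abs(e[["eccentricity"]] / sqrt(0.75) - 1), 0.02)
  # convex shape: hull eccentricity equals shape eccentricity
  expect_lt(abs(e[["hull_eccentricity"]] / e[["eccentricity"]] - 1), 0.02)
})

test_that("texture statistics hit closed-form values", {
  img <- matrix(1, 120, 120)
  img[11:110, 11:110] <- 0.4
  m <- extract_object_mask(img)
  expect_equal(unname(texture_features(img, m)), c(0, 0, 0))

  img[11:110, 11:110] <- rep(c(0.2, 0.8), length.out = 10000)
  tf <- texture_features(img, m)
  expect_equal(tf[["entropy"]], 1, tolerance = 1e-9)
  expect_equal(tf[["intensity_std"]], 0.3, tolerance = 1e-9)
  expect_lt(abs(tf[["skewness"]]), 1e-6)

  img[11:110, 11:110] <- rep(c(0.2, 0.2, 0.2, 0.8), length.out = 10000)
  expect_equal(texture_features(img, m)[["entropy"]],
               -0.75 * log2(0.75) - 0.25 * log2(0.25), tolerance = 1e-9)
})

test_that("template correlations respond to matching structure", {
  # checkerboard object at full contrast vs its own template size
  board <- fishcat:::checker_template(160, 160, 8)
  img <- fishcat:::pad_white((board + 1) / 2, 10)
  m <- extract_object_mask(img)
  tc <- template_correlations(img, m)
  expect_gte(tc[["checker_corr"]], 0.9)

  # constant object: balanced template scores ~0
  disc <- mask_to_image(render_disc_mask(80), fg = 0.3)
  expect_lte(template_correlations(disc, extract_object_mask(disc))
             [["checker_corr"]], 0.05)

  # star silhouette in canonical pose matches the star template
  star <- mask_to_image(render_star_mask(5, 100))
  expect_gte(template_correlations(star, extract_object_mask(star))
             [["star_corr"]], 0.8)
})

test_that("symmetry is rotation-invariant and texture-sensitive", {
  ell <- render_ellipse_mask(100, 50)
  s0 <- symmetry_features(mask_to_image(ell, 0.3), ell)
  expect_lte(s0[["gray_symmetry"]], 0.02)
  expect_lte(s0[["silhouette_symmetry"]], 0.02)

  e37 <- render_ellipse_mask(100, 50, rotation = 37)
  s37 <- symmetry_features(mask_to_image(e37, 0.3), e37)
  expect_lt(max(abs(s37 - s0)), 0.02)

  # shape-symmetric object with split texture
  hb <- matrix(1, 140, 140)
  hb[21:120, 21:70] <- 0
  hb[21:120, 71:120] <- 0.9
  sh <- symmetry_features(hb, extract_object_mask(hb))
  expect_gte(sh[["gray_symmetry"]], 0.4)
  expect_lte(sh[["silhouette_symmetry"]], 0.02)
})

test_that("energy measures inverted object content", {
  sq <- render_rect_mask(80, 80)
  en <- energy_features(mask_to_image(sq), sq)
  expect_equal(en[["mean_energy"]], 1)
  # doubling area at fixed intensity doubles total energy
  sq2 <- render_rect_mask(80, 160, side = 200)
  en2 <- energy_features(mask_to_image(sq2), sq2)
  expect_lt(abs(en2[["total_energy"]] / (2 * en[["total_energy"]]) - 1),
            0.03)
})

test_that("extract_all is deterministic and ordered as documented", {
  img <- gen_animal_stimulus(stimulus_params("animal", target_area = 10000,
                                             seed = 51))
  v1 <- extract_all(img)
  expect_identical(v1, extract_all(img))
  expect_identical(names(v1), feature_names())

  disc <- mask_to_image(render_disc_mask(90), fg = 0.2)
  fv <- extract_all(disc)
  expect_lt(abs(fv[["hull_ratio"]] - 1), 0.02)
  expect_lt(abs(fv[["roundness"]] - 1), 0.05)
  expect_lt(fv[["eccentricity"]], 0.1)
  expect_equal(fv[["n_sharp_curves"]], 0)

  # animals are less compact than plants by construction
  plant <- gen_plant_stimulus(stimulus_params("plant", target_area = 10000,
                                              seed = 52))
  fp <- extract_all(plant)
  expect_gt(v1[["hull_ratio"]], fp[["hull_ratio"]])
  expect_gt(v1[["roundness"]], fp[["roundness"]])
})

test_that("shape features are scale-stable and size features scale", {
  base <- stimulus_params("animal", target_area = 10000, seed = 61)
  fvs <- lapply(c(10000, 50000, 100000), function(a) {
    p <- base
    p$target_area <- a
    extract_all(gen_animal_stimulus(p))
  })
  stable <- c("hull_ratio", "roundness", "eccentricity", "entropy",
              "gray_symmetry", "intensity_std")
  for (nm in stable) {
    vals <- vapply(fvs, `[[`, numeric(1), nm)
    spread <- diff(range(vals)) / max(abs(mean(vals)), 0.1)
    expect_lt(spread, 0.12)
  }
  # skewness hovers near 0: the texture field is redrawn per resolution,
  # so only an absolute band is meaningful
  skews <- vapply(fvs, `[[`, numeric(1), "skewness")
  expect_lt(diff(range(skews)), 0.3)
  for (pair in list(c("area", 2), c("hull_area", 2), c("perimeter", 1),
                    c("total_energy", 2))) {
    v1 <- fvs[[1]][[pair[1]]]
    v3 <- fvs[[3]][[pair[1]]]
    expected <- (100000 / 10000)^(as.numeric(pair[2]) / 2)
    expect_lt(abs((v3 / v1) / expected - 1), 0.06)
  }
})

test_that("halving contrast leaves mask-derived features unchanged", {
  p <- stimulus_params("animal", target_area = 10000, seed = 71,
                       contrast = 1)
  p2 <- p
  p2$contrast <- 0.5
  f1 <- extract_all(gen_animal_stimulus(p))
  f2 <- extract_all(gen_animal_stimulus(p2))
  mask_feats <- c("area", "hull_area", "hull_ratio", "perimeter",
                  "roundness", "n_sharp_curves", "mean_sharp_curvature",
                  "eccentricity", "hull_eccentricity",
                  "silhouette_symmetry")
  expect_identical(f1[mask_feats], f2[mask_feats])
})

test_that("generated stimuli respect the isoperimetric floor", {
  feats <- fx_feats()
  expect_true(all(feats$roundness >= 0.95))
  expect_true(all(feats$hull_ratio >= 1))
  expect_true(all(feats$entropy >= 0))
  expect_true(all(is.finite(as.matrix(feats[, feature_names()]))))
})
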