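test_that("animal stimuli have limb-driven concavities and exact areas", {
  p <- stimulus_params("animal", n_appendages = 8,
                       appendage_length_ratio = 1.5,
                       target_area = 50000, seed = 1)
  img <- gen_animal_stimulus(p)
  mask <- extract_object_mask(img)
  cf <- compactness_features(mask, trace_contour(mask))
  expect_gt(cf[["hull_ratio"]], 1.3)
  expect_lt(abs(cf[["area"]] / 50000 - 1), 0.02)
  # same params, same seed: bit-identical
  expect_identical(img, gen_animal_stimulus(p))
})

test_that("animal generator rejects invalid appendage counts", {
  p <- stimulus_params("animal", target_area = 50000, seed = 1)
  p$n_appendages <- 0
  expect_error(gen_animal_stimulus(p), "appendages")
  expect_error(gen_animal_stimulus(stimulus_params("plant", seed = 1)),
               "animal")
})

test_that("plant stimuli are near-convex with controllable eccentricity", {
  img <- gen_plant_stimulus(stimulus_params("plant", target_area = 100000,
                                            seed = 2))
  mask <- extract_object_mask(img)
  cf <- compactness_features(mask, trace_contour(mask))
  expect_lt(abs(cf[["area"]] / 100000 - 1), 0.02)
  expect_lte(cf[["hull_ratio"]], 1.15)

  # ellipse mode, 2:1 axes -> e = sqrt(1 - 1/4)
  pe <- stimulus_params("plant", axis_ratio = 2, boundary_smoothness = 0,
                        target_area = 50000, seed = 3)
  me <- extract_object_mask(gen_plant_stimulus(pe))
  expect_lt(abs(eccentricity_features(me)[["eccentricity"]] / 0.8660 - 1),
            0.02)

  # zero boundary jitter -> convex: hull/area ratio 1 within 2%
  p0 <- stimulus_params("plant", boundary_smoothness = 0,
                        target_area = 50000, seed = 4)
  m0 <- extract_object_mask(gen_plant_stimulus(p0))
  hr <- compactness_features(m0, trace_contour(m0))[["hull_ratio"]]
  expect_lt(abs(hr - 1), 0.02)
})

test_that("area normalization holds across the five study levels", {
  for (lev in c(10000, 100000, 300000)) {
    img <- gen_animal_stimulus(stimulus_params("animal", target_area = lev,
                                               seed = lev %% 97 + 1))
    expect_lt(abs(sum(extract_object_mask(img)) / lev - 1), 0.02)
  }
})

test_that("stimulus sets are balanced, unique and profile-separated", {
  tiny <- gen_stimulus_set(1, size_levels = 10000, seed = 9)
  expect_length(tiny$images, 2)
  expect_setequal(tiny$manifest$category, c("animal", "plant"))
  expect_error(gen_stimulus_set(5, size_levels = numeric(0), seed = 1),
               "size_levels")

  s <- fx_set()
  expect_equal(sum(s$manifest$category == "animal"), 15)
  expect_false(any(duplicated(s$manifest$seed)))
  hr <- vapply(s$images, function(im) {
    m <- extract_object_mask(im)
    compactness_features(m, trace_contour(m))[["hull_ratio"]]
  }, numeric(1))
  expect_gte(threshold_accuracy(hr, s$manifest$category), 0.9)

  st <- fx_tex_set()
  hrt <- vapply(st$images, function(im) {
    m <- extract_object_mask(im)
    compactness_features(m, trace_contour(m))[["hull_ratio"]]
  }, numeric(1))
  expect_lte(threshold_accuracy(hrt, st$manifest$category), 0.7)
})

test_that("shape-separation dial monotonically improves shape threshold", {
  accs <- vapply(c(0.15, 0.5, 1), function(sep) {
    s <- gen_stimulus_set(12, size_levels = 10000, seed = 77,
                          shape_sep = sep)
    hr <- vapply(s$images, function(im) {
      m <- extract_object_mask(im)
      compactness_features(m, trace_contour(m))[["hull_ratio"]]
    }, numeric(1))
    threshold_accuracy(hr, s$manifest$category)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("simulated cohorts match beta-binomial closed forms", {
  coh <- simulate_fish_cohort(0.75, 52, n_fish = 1000,
                              n_trials_per_fish = 200, seed = 5)
  expect_lt(abs(mean(coh$n_successes / coh$n_trials) - 38.5 / 52), 0.02)

  # kappa = 2 is the uniform on (0,1)
  u <- simulate_fish_cohort(0.6, 2, n_fish = 1000,
                            n_trials_per_fish = 100, seed = 6)
  expect_lt(abs(mean(u$p_true) - 0.5), 0.02)

  expect_error(simulate_fish_cohort(0.7, 1.5, 10, 100), "kappa")
  expect_identical(simulate_fish_cohort(0.7, 30, 10, 100, seed = 3),
                   simulate_fish_cohort(0.7, 30, 10, 100, seed = 3))
})

test_that("cohort p_fish moments match Beta(a, b) at large n", {
  ab <- mode_conc_to_shapes(0.7, 30)
  coh <- simulate_fish_cohort(0.7, 30, n_fish = 10000,
                              n_trials_per_fish = 10, seed = 8)
  m_true <- ab[1] / sum(ab)
  v_true <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
  expect_lt(abs(mean(coh$p_true) - m_true), 3 * sqrt(v_true / 10000) + 0.003)
  expect_lt(abs(var(coh$p_true) / v_true - 1), 0.1)
})

test_that("stimulus sets round-trip through PNG and manifest files", {
  dir <- withr::local_tempdir()
  s <- gen_stimulus_set(1, size_levels = 10000, seed = 12)
  write_stimulus_set(s, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(man$id, s$manifest$id)
  img <- read_stimulus(file.path(dir, paste0(man$id[1], ".png")))
  # 8-bit quantization only
  expect_lt(max(abs(img - s$images[[man$id[1]]])), 1 / 255)
})
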