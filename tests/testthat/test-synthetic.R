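test_that("generation is bit-reproducible by seed", {
  a <- generate_env(20, 20, seed = 5)
  b <- generate_env(20, 20, seed = 5)
  c <- generate_env(20, 20, seed = 6)
  expect_identical(a$layers, b$layers)
  expect_identical(a$latents, b$latents)
  expect_false(identical(a$layers, c$layers))
  expect_equal(length(a$layers), 29)  # 19 climate + 10 edaphic by default
  expect_equal(length(a$latents), 4)
})

test_that("two noiseless mixes of one latent factor are perfectly correlated", {
  v <- generate_env(20, 20, n_climate = 2, n_edaphic = 0, latent_dim = 1,
                    noise_sd = 0, seed = 3)
  r <- cor(as.vector(v$layers$bio01), as.vector(v$layers$bio02))
  expect_equal(abs(r), 1, tolerance = 1e-12)
})

test_that("climate PCA concentrates variance in the latent subspace", {
  v <- generate_env(50, 50, seed = 11, noise_sd = 0.3)
  clim <- subset_layers(v, grep("^bio", names(v$layers), value = TRUE))
  fit <- fit_pca(clim, n_axes = 6)
  expect_gt(sum(fit$transform$eigenvalue_proportions[1:4]), 0.85)
})

test_that("scenario shifts move climate only, by the stated sd amounts", {
  v <- generate_env(20, 20, seed = 7)
  zero <- scenario_shift(setNames(rep(0, 19), v$climate_names), "same")
  same <- apply_shift(v, zero)
  expect_identical(same$layers, v$layers)
  one <- scenario_shift(setNames(c(1, rep(0, 18)), v$climate_names), "plus")
  fut <- apply_shift(v, one)
  expect_equal(mean(fut$layers$bio01) - mean(v$layers$bio01),
               sd(v$layers$bio01), tolerance = 1e-12)
  for (nm in c(v$climate_names[-1], v$edaphic_names))
    expect_identical(fut$layers[[nm]], v$layers[[nm]])
})

test_that("latent shifts keep ground truth computable and consistent", {
  v <- generate_env(30, 30, seed = 9)
  sp <- strong_species()
  sh <- latent_shift(v, c(-0.5, -0.25, 0, 0), "fut")
  fut <- apply_shift(v, sh)
  # direct evaluation of the shifted logistic equals the stack's truth
  eta <- sp$intercept
  for (k in 1:4) eta <- eta + sp$weights[k] * (v$latents[[k]] + sh$latent_delta[k])
  expect_equal(true_suitability(sp, fut), plogis(eta), tolerance = 1e-12)
  # a non-latent shift invalidates the ground truth
  manual <- apply_shift(v, scenario_shift(setNames(c(1, rep(0, 18)),
                                                   v$climate_names), "m"))
  expect_error(true_suitability(sp, manual), "latent")
})

test_that("presence sampling is deterministic and tracks suitability", {
  v <- generate_env(25, 25, seed = 13)
  sp <- strong_species()
  o1 <- sample_presences(sp, v, 10, seed = 21)
  o2 <- sample_presences(sp, v, 10, seed = 21)
  expect_identical(o1$records, o2$records)
  # drawn cells concentrate in suitable habitat
  suit <- true_suitability(sp, v)
  th <- thin_to_cells(o1, v$grid)
  drawn <- suit[cbind(th$cells$row, th$cells$col)]
  expect_gt(mean(drawn), mean(suit))
  expect_error(sample_presences(sp, v, 1e6, seed = 1), "exceeds")
})

test_that("uniform suitability yields uniform cell frequencies", {
  v <- generate_env(12, 12, n_climate = 2, n_edaphic = 0, latent_dim = 2,
                    seed = 2)
  flat <- virtual_species_spec(c(0, 0), 0)
  counts <- integer(144)
  for (i in 1:700) {
    occ <- sample_presences(flat, v, 5, seed = i)
    rc <- lonlat_to_cell(v$grid, occ$records$longitude, occ$records$latitude)
    idx <- (rc$col - 1) * 12 + rc$row
    counts[idx] <- counts[idx] + 1
  }
  expect_gt(chisq.test(counts)$p.value, 1e-3)
})

test_that("true suitable area honours the cutoff and the valid mask", {
  v <- generate_env(20, 20, seed = 15)
  flat <- null_species()  # suitability exactly 0.5 everywhere
  all_area <- suitable_area_km2(binary_map(matrix(1, 20, 20), v$grid))
  expect_equal(true_suitable_area(flat, v, cutoff = 0.5), all_area)
  expect_equal(true_suitable_area(flat, v, cutoff = 0.500001), 0)
  expect_equal(true_suitable_area(strong_species(), v, cutoff = 1 + 1e-9), 0)
})

test_that("shift_for_loss hits the requested fractional area loss", {
  v <- generate_env(40, 40, seed = 23)
  sp <- strong_species()
  for (f in c(0.3, 0.7)) {
    sh <- shift_for_loss(sp, v, f)
    fut <- apply_shift(v, sh)
    achieved <- 1 - true_suitable_area(sp, fut) / true_suitable_area(sp, v)
    expect_equal(achieved, f, tolerance = 0.02)
  }
})
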