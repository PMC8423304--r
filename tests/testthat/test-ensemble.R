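toy_table <- function() {
  # linearly separable six-point toy problem on one predictor
  grid <- toy_grid(2, 3)
  stack <- env_stack(list(climPC1 = matrix(c(-3, -2, -1, 1, 2, 3), 2, 3)),
                     grid)
  build_training_table(data.frame(row = c(2, 1, 2), col = c(2, 3, 3)),
                       data.frame(row = c(1, 2, 1), col = c(1, 1, 2)),
                       stack)
}

test_that("training tables refuse duplicates, single classes, non-finite", {
  tab <- toy_table()
  expect_s3_class(tab, "training_table")
  expect_equal(tab$response, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(sum(attr(tab, "weights")[tab$response == 1]),
               sum(attr(tab, "weights")[tab$response == 0]))
  grid <- toy_grid(2, 3)
  stack <- env_stack(list(climPC1 = matrix(1:6 + 0, 2, 3)), grid)
  expect_error(build_training_table(data.frame(row = 1, col = 1),
                                    data.frame(row = 1, col = 1), stack),
               "duplicated cell")
  expect_error(fit_learner(structure(data.frame(response = c(1L, 1L),
                                                climPC1 = c(0, 1)),
                                     class = c("training_table", "data.frame")),
                           "GLM"),
               "single class")
})

test_that("a GLM-family fit is monotone on separable one-predictor data", {
  tab <- toy_table()
  m <- fit_learner(tab, "GLM", seed = 1)
  p <- predict_learner(m, matrix(seq(-3, 3, by = 0.5),
                                 dimnames = list(NULL, "climPC1")))
  expect_true(all(diff(p) >= -1e-12))
  expect_lt(p[1], p[length(p)])
})

test_that("every registered family is deterministic given the seed", {
  venv <- generate_env(20, 20, seed = 8)
  ss <- score_stack_of(venv, 3, 2)
  occ <- thin_to_cells(sample_presences(strong_species(), venv, 8, seed = 2),
                       venv$grid)
  b <- presence_distance_bounds(occ, venv$grid)
  pa <- sample_disk_pas(venv$grid, occ, 40, b, seed = 5, mask = venv$mask)
  tab <- build_training_table(occ$cells, pa$cells, ss)
  newx <- stack_matrix(ss)[1:50, ]
  for (fam in registered_learners()) {
    m1 <- suppressWarnings(fit_learner(tab, fam, seed = 33))
    m2 <- suppressWarnings(fit_learner(tab, fam, seed = 33))
    expect_identical(predict_learner(m1, newx), predict_learner(m2, newx),
                     info = fam)
  }
})

test_that("each family ranks truly suitable cells above unsuitable ones", {
  venv <- generate_env(30, 30, seed = 12)
  sp <- strong_species()
  ss <- score_stack_of(venv)
  suit <- true_suitability(sp, venv)
  occ <- thin_to_cells(sample_presences(sp, venv, 15, seed = 3), venv$grid)
  b <- presence_distance_bounds(occ, venv$grid)
  pa_m <- sample_disk_pas(venv$grid, occ, nrow(occ$cells), b, seed = 5,
                          mask = venv$mask)
  pa_l <- sample_disk_pas(venv$grid, occ, 500, b, seed = 6, mask = venv$mask)
  hi <- suit >= 0.8 & venv$mask
  lo <- suit <= 0.2 & venv$mask
  for (fam in registered_learners()) {
    pa <- if (fam %in% c("GBM", "CTA", "RF")) pa_m else pa_l
    tab <- build_training_table(occ$cells, pa$cells, ss)
    m <- suppressWarnings(fit_learner(tab, fam, seed = 4))
    s <- predict_surface(m, ss)
    expect_gt(mean(s$values[hi]), mean(s$values[lo]), label = fam)
  }
})

test_that("predict_surface propagates NoData and stays in [0, 1]", {
  venv <- generate_env(15, 15, seed = 21)
  ss <- score_stack_of(venv, 3, 2)
  ss$mask[1:10] <- FALSE
  for (nm in names(ss$layers)) ss$layers[[nm]][1:10] <- NA
  occ <- thin_to_cells(sample_presences(strong_species(), venv, 5, seed = 2),
                       venv$grid)
  b <- presence_distance_bounds(occ, venv$grid)
  pa <- sample_disk_pas(venv$grid, occ, 30, b, seed = 5, mask = ss$mask)
  tab <- build_training_table(occ$cells, pa$cells, ss)
  m <- suppressWarnings(fit_learner(tab, "MAXENT", seed = 1))
  s <- predict_surface(m, ss)
  expect_true(all(is.na(s$values[1:10])))
  v <- s$values[!is.na(s$values)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("ensemble_mean is the per-cell unweighted mean within member bounds", {
  grid <- toy_grid(4, 4)
  m1 <- suitability_map(matrix(0.2, 4, 4), grid, provenance = "a")
  m2 <- suitability_map(matrix(0.4, 4, 4), grid, provenance = "b")
  em <- ensemble_mean(list(m1, m2))
  expect_equal(em$values, matrix(0.3, 4, 4))
  expect_setequal(em$provenance, c("a", "b"))
  expect_equal(ensemble_mean(list(m1))$values, m1$values)
  set.seed(99)
  maps <- lapply(1:5, function(i)
    suitability_map(matrix(runif(16), 4, 4), grid, provenance = letters[i]))
  em <- ensemble_mean(maps)
  lo <- Reduce(pmin, lapply(maps, `[[`, "values"))
  hi <- Reduce(pmax, lapply(maps, `[[`, "values"))
  expect_true(all(em$values >= lo - 1e-12 & em$values <= hi + 1e-12))
})

test_that("calibrate_replicate counts families x sets x runs models", {
  venv <- generate_env(20, 20, seed = 31)
  ss <- score_stack_of(venv, 3, 2)
  occ <- thin_to_cells(sample_presences(strong_species(), venv, 6, seed = 1),
                       venv$grid)
  b <- presence_distance_bounds(occ, venv$grid)
  mk <- function(n, seed) sample_disk_pas(venv$grid, occ, n, b, seed = seed,
                                          mask = venv$mask)
  cal <- suppressWarnings(calibrate_replicate(
    occ$cells, list(mk(6, 1), mk(6, 2)), list(mk(200, 3), mk(200, 4)),
    list(current = ss), families = c("CTA", "MAXENT"),
    n_runs = 2, seed_base = 7))
  expect_equal(cal$n_models, 8)
  expect_length(cal$provenance, 8)
  v <- cal$ensembles$current$values[venv$mask]
  expect_true(all(v >= 0 & v <= 1))
})
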