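test_that("maxsensspec threshold separates the worked examples", {
  r <- maxsensspec_threshold(c(0.9, 0.8, 0.7), c(0.2, 0.3, 0.6))
  expect_equal(r$threshold, 0.65)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # perfectly separated classes reach sens + spec = 2
  r2 <- maxsensspec_threshold(runif(20, 0.6, 1), runif(30, 0, 0.4))
  expect_equal(r2$sensitivity + r2$specificity, 2)
  # coincident single scores: best achievable sum is 1
  r3 <- maxsensspec_threshold(0.5, 0.5)
  expect_equal(r3$sensitivity + r3$specificity, 1)
  expect_error(maxsensspec_threshold(numeric(0), 0.5), "non-empty")
})

test_that("presence proportion is area-weighted by the spherical band form", {
  g <- toy_grid(1, 10)
  expect_equal(area_weighted_presence_proportion(
    binary_map(matrix(1, 1, 10), g)), 1)
  expect_equal(area_weighted_presence_proportion(
    binary_map(matrix(rep(c(1, 0), 5), 1, 10), g)), 0.5)
  # one-cell rows at 60N and at the equator: high-latitude cells weigh less
  g2 <- niche_grid(xmin = 0, ymax = 60, cellsize = 1 / 12,
                   nrow = 720, ncol = 1)
  v <- matrix(NA_real_, 720, 1)
  v[1] <- 1    # top cell: band [60 - 1/12, 60]
  v[720] <- 0  # bottom cell: band [0, 1/12]
  p <- area_weighted_presence_proportion(binary_map(v, g2))
  d <- pi / 180 / 12
  a60 <- sin(60 * pi / 180) - sin(60 * pi / 180 - d)
  a0 <- sin(d)
  expect_equal(p, a60 / (a60 + a0), tolerance = 1e-12)
  expect_equal(p, 0.334, tolerance = 5e-3)
})

test_that("poisson binomial tail matches hand enumeration", {
  expect_equal(poisson_binomial_pvalue(c(0.2, 0.9, 0.4), 0), 1)
  expect_equal(poisson_binomial_pvalue(c(0.3, 0.3), 2), 0.09)
  expect_equal(poisson_binomial_pvalue(rep(0.5, 4), 2), 11 / 16)
  expect_equal(poisson_binomial_pvalue(rep(1, 5), 5), 1)
  p <- c(0.1, 0.5, 0.8)
  expect_equal(poisson_binomial_pvalue(p, 3), prod(p))
  pv <- vapply(0:3, function(D) poisson_binomial_pvalue(p, D), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
  expect_error(poisson_binomial_pvalue(c(0.5, 0.5), 3), "D must lie")
  expect_error(poisson_binomial_pvalue(c(0.5, 1.2), 1), "in \\[0, 1\\]")
})

test_that("jackknife produces one replicate per presence cell, no leakage", {
  venv <- generate_env(25, 25, seed = 17)
  sp <- strong_species()
  occ <- thin_to_cells(sample_presences(sp, venv, 5, seed = 8), venv$grid)
  ss <- score_stack_of(venv)
  cfg <- read_run_config(list(families = "MAXENT", n_runs = 1,
                              pa = list(n_sets = 2), seed = 99))
  rep <- suppressWarnings(jackknife_run(occ, list(current = ss), cfg))
  expect_s3_class(rep, "jackknife_report")
  expect_equal(rep$n, nrow(occ$cells))
  expect_equal(nrow(rep$replicates), rep$n)
  expect_equal(rep$D, sum(rep$replicates$success))
  expect_equal(rep$p_value,
               poisson_binomial_pvalue(rep$replicates$presence_proportion,
                                       rep$D))
  expect_true(all(rep$replicates$presence_proportion >= 0 &
                    rep$replicates$presence_proportion <= 1))
  # each replicate's left-out cell is one of the presence cells, each once
  expect_setequal(paste(rep$replicates$left_out_row,
                        rep$replicates$left_out_col),
                  paste(occ$cells$row, occ$cells$col))
  expect_error(jackknife_run(occ_from_cells(data.frame(row = 1:2, col = 1:2),
                                            venv$grid),
                             list(current = ss), cfg),
               ">= 3 unique presence cells")
})

test_that("homogeneous binomial option uses the mean predicted proportion", {
  venv <- generate_env(25, 25, seed = 18)
  occ <- thin_to_cells(sample_presences(strong_species(), venv, 5, seed = 9),
                       venv$grid)
  ss <- score_stack_of(venv)
  cfg <- read_run_config(list(families = "MAXENT", n_runs = 1,
                              pa = list(n_sets = 2), seed = 7,
                              test = "binomial"))
  rep <- suppressWarnings(jackknife_run(occ, list(current = ss), cfg))
  expect_equal(rep$p_value,
               pbinom(rep$D - 1, rep$n,
                      mean(rep$replicates$presence_proportion),
                      lower.tail = FALSE))
})

test_that("report round-trips through its CSV and JSON exports", {
  venv <- generate_env(25, 25, seed = 19)
  occ <- thin_to_cells(sample_presences(strong_species(), venv, 6, seed = 3),
                       venv$grid)
  ss <- score_stack_of(venv)
  cfg <- read_run_config(list(families = "CTA", n_runs = 1,
                              pa = list(n_sets = 2), seed = 5))
  rep <- suppressWarnings(jackknife_run(occ, list(current = ss), cfg))
  dir <- withr::local_tempdir()
  write_jackknife_report(rep, file.path(dir, "jk.csv"),
                         file.path(dir, "jk.json"))
  rows <- read.csv(file.path(dir, "jk.csv"))
  expect_equal(nrow(rows), rep$n)
  expect_equal(sum(rows$success), rep$D)
  js <- jsonlite::read_json(file.path(dir, "jk.json"))
  expect_equal(js$D, rep$D)
  expect_equal(js$p_value, rep$p_value, tolerance = 1e-12)
})
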