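test_that("noise calibration matches the variance-decomposition closed form", {
  # perfect correlation forces zero noise
  expect_identical(calibrate_noise_sd(1.193, 31.75, 1), 0)
  # R^2 = 1/2 <=> signal variance equals noise variance
  expect_equal(calibrate_noise_sd(2, 1, 1 / sqrt(2)), 2)
  # closed form sigma = |b1| sd_x sqrt(1/R^2 - 1)
  sd_x <- 110 / sqrt(12)
  expect_equal(calibrate_noise_sd(1.193, sd_x, 0.265),
               1.193 * sd_x * sqrt(1 / 0.265^2 - 1))
  expect_error(calibrate_noise_sd(1.193, sd_x, 0), class = "aavrange_config_error")
  expect_error(calibrate_noise_sd(1.193, sd_x, 1.2), class = "aavrange_config_error")
  expect_error(calibrate_noise_sd(0, sd_x, 0.5), class = "aavrange_config_error")
})

test_that("calibrated noise reproduces the target correlation in large samples", {
  # round-trip over a parameter grid: sample R within 3 Monte-Carlo SEs
  set.seed(101)
  grid <- expand.grid(slope = c(0.077, 1.193, -2), R = c(0.1, 0.265, 0.7))
  for (g in seq_len(nrow(grid))) {
    slope <- grid$slope[g]; R <- grid$R[g]
    n <- 1e5
    sd_x <- 110 / sqrt(12)
    sigma <- calibrate_noise_sd(slope, sd_x, R)
    x <- runif(n, 0, 110)
    y <- 200 + slope * x + rnorm(n, 0, sigma)
    mc_se <- (1 - R^2) / sqrt(n)
    expect_lt(abs(abs(cor(x, y)) - R), 3 * mc_se,
              label = sprintf("sample |R| deviation (slope %.3f, R %.3f)", slope, R))
  }
})

test_that("the generator is deterministic given a seed", {
  cfg <- synthetic_config(seed = 42)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(a, b)
  # and written tables are byte-identical
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_cell_table(a, fa); write_cell_table(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  # different seed, different table
  expect_false(identical(a, simulate_cells(synthetic_config(seed = 43))))
})

test_that("zero noise collapses areas onto the generating line", {
  cfg <- synthetic_config(noise_sd = 0, seed = 5)
  cells <- simulate_cells(cfg)
  neg <- cells[!cells$gfp_positive, ]
  expect_equal(neg$area_um2, 202.723 + 1.193 * neg$distance_um)
  # GFP+ cells sit at the intercept (distance zero from an infected cell)
  pos <- cells[cells$gfp_positive, ]
  expect_true(all(pos$area_um2 == 202.723))
  expect_true(all(is.na(pos$distance_um)))
})

test_that("cell records respect their invariants", {
  cfg <- synthetic_config(seed = 11, n_animals = 4, cells_per_animal = 50)
  cells <- simulate_cells(cfg)
  expect_equal(nrow(cells), 200)
  expect_true(all(cells$area_um2 >= cfg$area_floor))
  expect_true(all(is.na(cells$distance_um[cells$gfp_positive])))
  expect_true(all(!is.na(cells$distance_um[!cells$gfp_positive])))
  expect_true(all(cells$gfp_intensity[cells$gfp_positive] > 0))
  expect_true(all(cells$gfp_intensity[!cells$gfp_positive] == 0))
  expect_equal(length(unique(cells$animal_id)), 4)
  # flooring events are counted
  expect_gte(attr(cells, "n_floored"), 0)
  noisy <- simulate_cells(synthetic_config(noise_sd = 500, seed = 1))
  expect_gt(attr(noisy, "n_floored"), 0)
  expect_message(simulate_cells(synthetic_config(noise_sd = 500, seed = 1),
                                verbose = TRUE), "clamped")
  # sham cells carry no infection annotation
  sham <- simulate_cells(synthetic_config(arm = "sham", seed = 2))
  expect_true(all(!sham$gfp_positive))
  expect_true(all(is.na(sham$distance_um)))
})

test_that("per-animal GFP+ fractions recover the infection rate", {
  cfg <- synthetic_config(seed = 77, n_animals = 20, cells_per_animal = 200,
                          infection_rate = 0.388)
  cells <- simulate_cells(cfg)
  frac <- tapply(cells$gfp_positive, cells$animal_id, mean)
  # binomial SE of the grand mean over 20 x 200 cells
  se <- sqrt(0.388 * 0.612 / (20 * 200))
  expect_lt(abs(mean(frac) - 0.388), 3 * se)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(n_animals = 0), class = "aavrange_config_error")
  expect_error(synthetic_config(cells_per_animal = -5), class = "aavrange_config_error")
  expect_error(synthetic_config(distance_min = 50, distance_max = 50),
               class = "aavrange_config_error")
  expect_error(synthetic_config(infection_rate = 0), class = "aavrange_config_error")
  expect_error(synthetic_config(infection_rate = 1.2), class = "aavrange_config_error")
  expect_error(synthetic_config(noise_sd = -1), class = "aavrange_config_error")
})

test_that("cell tables round-trip through CSV with the documented header", {
  cells <- simulate_cells(synthetic_config(seed = 9, n_animals = 2,
                                           cells_per_animal = 10))
  path <- tempfile(fileext = ".csv")
  write_cell_table(cells, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header, c("cell_id", "animal_id", "arm", "gfp_positive",
                             "gfp_intensity", "area_um2", "distance_um"))
  back <- read_cell_table(path)
  expect_equal(back$area_um2, cells$area_um2)
  expect_identical(back$gfp_positive, cells$gfp_positive)
  expect_equal(back$distance_um, cells$distance_um)
  expect_error(read_cell_table(tempfile()), class = "aavrange_data_error")
})

test_that("the AAC control preset carries the pressure-overload line", {
  cfg <- aac_control_config(seed = 1)
  expect_equal(cfg$true_slope, 0.077)
  expect_equal(cfg$true_intercept, 326.868)
  expect_equal(cfg$target_R, 0.022)
  expect_equal(cfg$infection_rate, 0.363)
  expect_identical(cfg$arm, "aac_control")
  # overrides still apply
  expect_equal(aac_control_config(infection_rate = 0.2)$infection_rate, 0.2)
})

test_that("hypertrophic-area draws honour mean, SD and the positivity floor", {
  set.seed(123)
  x <- simulate_hypertrophic_areas(2e4)
  expect_true(all(x >= 1))
  expect_lt(abs(mean(x) - 332.2), 3)   # small clamp lift (~+0.4) allowed
  expect_lt(abs(sd(x) - 138.6), 3)
  expect_gte(attr(x, "n_floored"), 0)
})
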