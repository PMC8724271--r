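#' Configuration for the synthetic morphometry generator
#'
#' Bundles every parameter of the per-cell generator: the true distance--area
#' line, the distance sampling window, the noise level (or the target Pearson
#' correlation it is calibrated from), the hypertrophic-area population, and
#' the per-animal infection rate.
#'
#' Defaults are the treated (miR-133 overexpression) arm: line
#' 202.723 + 1.193 X with correlation 0.265, distances uniform on 0--110
#' micrometres, 5 animals of 105 cells, infection rate 38.8%. The pressure
#' -overload control arm preset is [aac_control_config()].
#'
#' @param arm Experimental arm: `"treated"`, `"aac_control"` or `"sham"`.
#' @param n_animals Number of animals (biological replicates).
#' @param cells_per_animal Cells measured per animal.
#' @param true_slope Slope of the generating line (um^2 per um).
#' @param true_intercept Intercept of the generating line (um^2).
#' @param distance_min,distance_max Distance sampling window (um); distances
#'   are drawn uniformly on this interval for uninfected cells.
#' @param noise_sd Residual SD of cell area about the line (um^2), or
#'   `"auto"` to calibrate it from `target_R` via [calibrate_noise_sd()].
#' @param target_R Target population Pearson correlation between distance and
#'   area, in (0, 1]; used only when `noise_sd = "auto"`.
#' @param hypertrophic_mean,hypertrophic_sd Mean and SD (um^2) of the
#'   hypertrophic cell-area population used for the area threshold.
#' @param infection_rate Per-cell probability of being GFP+ (transduced),
#'   in (0, 1).
#' @param area_floor Smallest admissible cell area (um^2); generated areas
#'   below it are clamped and the number of clamped cells recorded.
#' @param seed Integer seed making [simulate_cells()] deterministic, or
#'   `NULL` to use the current RNG state.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [simulate_cells()], [aac_control_config()]
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg$noise_sd_value
#' @export
synthetic_config <- function(arm = c("treated", "aac_control", "sham"),
                             n_animals = 5,
                             cells_per_animal = 105,
                             true_slope = 1.193,
                             true_intercept = 202.723,
                             distance_min = 0,
                             distance_max = 110,
                             noise_sd = "auto",
                             target_R = 0.265,
                             hypertrophic_mean = 332.2,
                             hypertrophic_sd = 138.6,
                             infection_rate = 0.388,
                             area_floor = 1,
                             seed = NULL) {
  arm <- match.arg(arm)
  if (!is.numeric(n_animals) || n_animals < 1 || n_animals != round(n_animals))
    stop_config("n_animals must be a positive integer")
  if (!is.numeric(cells_per_animal) || cells_per_animal < 1 ||
      cells_per_animal != round(cells_per_animal))
    stop_config("cells_per_animal must be a positive integer")
  if (!is.numeric(distance_min) || !is.numeric(distance_max) ||
      distance_min < 0 || distance_max <= distance_min)
    stop_config("need distance_max > distance_min >= 0")
  if (!is.numeric(infection_rate) || infection_rate <= 0 || infection_rate >= 1)
    stop_config("infection_rate must be in (0, 1)")
  if (!is.numeric(hypertrophic_sd) || hypertrophic_sd < 0)
    stop_config("hypertrophic_sd must be >= 0")
  if (!is.numeric(area_floor) || area_floor <= 0)
    stop_config("area_floor must be > 0")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || seed != round(seed)) stop_config("seed must be an integer")
    seed <- as.integer(seed)
  }

  sd_x <- (distance_max - distance_min) / sqrt(12)
  if (identical(noise_sd, "auto")) {
    noise_sd_value <- calibrate_noise_sd(true_slope, sd_x, target_R)
  } else {
    if (!is.numeric(noise_sd) || noise_sd < 0)
      stop_config("noise_sd must be >= 0 or \"auto\"")
    noise_sd_value <- noise_sd
  }

  structure(
    list(arm = arm, n_animals = as.integer(n_animals),
         cells_per_animal = as.integer(cells_per_animal),
         true_slope = true_slope, true_intercept = true_intercept,
         distance_min = distance_min, distance_max = distance_max,
         noise_sd = noise_sd, noise_sd_value = noise_sd_value,
         target_R = if (identical(noise_sd, "auto")) target_R else NA_real_,
         hypertrophic_mean = hypertrophic_mean,
         hypertrophic_sd = hypertrophic_sd,
         infection_rate = infection_rate, area_floor = area_floor,
         seed = seed),
    class = "synthetic_config")
}

#' Pressure-overload (AAC) control arm preset
#'
#' The abdominal-aortic-constriction control arm: cell area is essentially
#' independent of the distance to an infected cell (line 326.868 + 0.077 X,
#' correlation 0.022) because the control virus carries no therapeutic
#' cargo; the infection rate observed in control hearts is 36.3%.
#'
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
aac_control_config <- function(...) {
  args <- list(arm = "aac_control", true_slope = 0.077,
               true_intercept = 326.868, target_R = 0.022,
               infection_rate = 0.363)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic morphometry config (", x$arm, " arm)\n", sep = "")
  cat(sprintf("  %d animals x %d cells, infection rate %.3f\n",
              x$n_animals, x$cells_per_animal, x$infection_rate))
  cat(sprintf("  area = %.3f + %.3f * distance + N(0, %.1f^2) um^2\n",
              x$true_intercept, x$true_slope, x$noise_sd_value))
  if (!is.na(x$target_R))
    cat(sprintf("  (noise calibrated to Pearson R = %.3f; X ~ U(%g, %g) um)\n",
                x$target_R, x$distance_min, x$distance_max))
  cat(sprintf("  hypertrophic areas ~ N(%.1f, %.1f^2) um^2\n",
              x$hypertrophic_mean, x$hypertrophic_sd))
  invisible(x)
}

#' Calibrate the residual SD from a target Pearson correlation
#'
#' For the linear model `Y = b0 + b1 X + e`, `e ~ N(0, sigma^2)`, the
#' population correlation between X and Y satisfies
#' `R^2 = b1^2 Var(X) / (b1^2 Var(X) + sigma^2)`. Inverting gives
#' `sigma = |b1| sd(X) sqrt(1 / R^2 - 1)`, the residual SD that makes the
#' generated data reproduce a printed correlation.
#'
#' @param slope Generating slope `b1` (um^2 per um); must be non-zero for
#'   `target_R < 1`.
#' @param sd_x Standard deviation of the distance distribution (um); for a
#'   uniform window of width w this is `w / sqrt(12)`.
#' @param target_R Target population correlation in (0, 1]. `target_R = 1`
#'   forces zero noise; `target_R = 0` is impossible for a non-zero slope
#'   (it would need infinite noise).
#'
#' @return The residual SD sigma (um^2), a non-negative scalar.
#' @examples
#' calibrate_noise_sd(1.193, 110 / sqrt(12), 0.265)
#' calibrate_noise_sd(2, 1, 1 / sqrt(2))  # signal variance == noise variance
#' @export
calibrate_noise_sd <- function(slope, sd_x, target_R) {
  if (!is.numeric(sd_x) || sd_x <= 0) stop_config("sd_x must be > 0")
  if (!is.numeric(target_R) || target_R <= 0 || target_R > 1)
    stop_config("target_R must be in (0, 1]: R = 0 with a non-zero slope needs infinite noise")
  if (target_R == 1) return(0)
  if (!is.numeric(slope) || slope == 0)
    stop_config("slope must be non-zero when target_R < 1")
  abs(slope) * sd_x * sqrt(1 / target_R^2 - 1)
}

#' Draw replicate points from the linear distance--area model
#'
#' The core linear-Gaussian sampler behind the generator: distances uniform
#' on the configured window, areas `b0 + b1 X + N(0, sigma^2)` with no
#' positivity clamp. This is the sampler used for parameter-recovery
#' simulations (the clamp applied by [simulate_cells()] truncates the
#' Gaussian tail and would bias recovered coefficients; see the methods
#' vignette for the quantified bias).
#'
#' @param n Number of points.
#' @param slope,intercept Generating line.
#' @param noise_sd Residual SD (um^2).
#' @param distance_min,distance_max Uniform distance window (um).
#' @return A data.frame with columns `distance_um`, `area_um2`.
#' @export
simulate_regression_points <- function(n, slope = 1.193, intercept = 202.723,
                                       noise_sd = calibrate_noise_sd(slope, (distance_max - distance_min) / sqrt(12), 0.265),
                                       distance_min = 0, distance_max = 110) {
  if (!is.numeric(n) || n < 1) stop_config("n must be a positive integer")
  x <- stats::runif(n, distance_min, distance_max)
  y <- intercept + slope * x + stats::rnorm(n, 0, noise_sd)
  data.frame(distance_um = x, area_um2 = y)
}

#' Simulate a per-cell morphometry table
#'
#' Generates one cell record per row for every animal in the configured arm.
#' GFP status is Bernoulli at the configured infection rate. Uninfected
#' (GFP-) cells in the treated and control arms receive a distance to the
#' nearest infected cell, uniform on the configured window, and an area on
#' the arm's line plus Gaussian noise. GFP+ cells sit at distance zero from
#' an infected cell (themselves), so their distance is recorded as missing
#' and their area is drawn at the line's intercept; sham cells have no
#' infected neighbours at all. GFP intensity is lognormal for GFP+ cells and
#' zero otherwise; only the boolean is used downstream.
#'
#' Areas are clamped at `config$area_floor` (positivity guard); the number
#' of clamped cells is recorded in the `n_floored` attribute and reported
#' when `verbose = TRUE`.
#'
#' @param config A [synthetic_config()].
#' @param verbose Report the number of floored areas, if any.
#' @return A data.frame with columns `cell_id`, `animal_id`, `arm`,
#'   `gfp_positive`, `gfp_intensity`, `area_um2`, `distance_um`, and
#'   attribute `n_floored`. Deterministic given `config$seed`.
#' @examples
#' cells <- simulate_cells(synthetic_config(seed = 1))
#' head(cells)
#' @export
simulate_cells <- function(config, verbose = FALSE) {
  if (!inherits(config, "synthetic_config"))
    stop_config("config must be a synthetic_config")
  if (!is.null(config$seed)) set.seed(config$seed)

  n_total <- config$n_animals * config$cells_per_animal
  animal <- rep(sprintf("%s_animal_%02d", config$arm, seq_len(config$n_animals)),
                each = config$cells_per_animal)

  if (config$arm == "sham") {
    gfp <- rep(FALSE, n_total)
  } else {
    gfp <- stats::runif(n_total) < config$infection_rate
  }
  distance <- rep(NA_real_, n_total)
  needs_dist <- !gfp & config$arm != "sham"
  distance[needs_dist] <- stats::runif(sum(needs_dist), config$distance_min,
                                       config$distance_max)

  mu <- config$true_intercept + config$true_slope * ifelse(is.na(distance), 0, distance)
  area_raw <- mu + stats::rnorm(n_total, 0, config$noise_sd_value)
  floored <- area_raw < config$area_floor
  area <- pmax(area_raw, config$area_floor)

  intensity <- numeric(n_total)
  intensity[gfp] <- stats::rlnorm(sum(gfp), meanlog = log(500), sdlog = 0.5)

  cells <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(n_total)),
    animal_id = animal,
    arm = config$arm,
    gfp_positive = gfp,
    gfp_intensity = intensity,
    area_um2 = area,
    distance_um = distance,
    stringsAsFactors = FALSE)
  attr(cells, "n_floored") <- sum(floored)
  if (verbose && any(floored))
    message(sum(floored), " cell area(s) clamped at the ", config$area_floor,
            " um^2 floor")
  cells
}

#' Simulate a hypertrophic cell-area sample
#'
#' Draws cross-sectional areas of hypertrophic (pressure-overloaded,
#' untreated) cardiomyocytes from a Gaussian population, clamped at a small
#' positive floor. The default population (mean 332.2, SD 138.6 um^2)
#' reproduces a lower 95% confidence bound of the mean near 304.7 um^2 at
#' n = 100.
#'
#' @param n Sample size.
#' @param mean,sd Population mean and SD (um^2).
#' @param area_floor Positivity clamp (um^2).
#' @return Numeric vector of areas with attribute `n_floored`.
#' @export
simulate_hypertrophic_areas <- function(n, mean = 332.2, sd = 138.6,
                                        area_floor = 1) {
  if (!is.numeric(n) || n < 1) stop_config("n must be a positive integer")
  raw <- stats::rnorm(n, mean, sd)
  out <- pmax(raw, area_floor)
  attr(out, "n_floored") <- sum(raw < area_floor)
  out
}

#' Write / read a cell table as CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `cell_id, animal_id, arm, gfp_positive, gfp_intensity, area_um2, distance_um`,
#' one row per cell, missing distances empty.
#'
#' @param cells A cell table from [simulate_cells()].
#' @param path File path.
#' @return `write_cell_table()` returns `path` invisibly; `read_cell_table()`
#'   returns the cell table.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such cell table: ", path))
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "arm", "gfp_positive", "area_um2", "distance_um")
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop_data(paste0("cell table lacks column(s): ", paste(missing, collapse = ", ")))
  cells$gfp_positive <- as.logical(cells$gfp_positive)
  if (any(!is.na(cells$area_um2) & cells$area_um2 <= 0))
    stop_data("cell areas must be positive")
  cells
}
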