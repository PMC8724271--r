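#' Per-animal infection and morphometry summaries
#'
#' Aggregates a cell table to one row per animal: cell count, GFP+ fraction
#' (the estimated infection rate), and mean/SD of cell area. The animal --
#' not the cell -- is the replication unit for infection-rate estimates, so
#' the attribute `group_stats` reports the mean and SD of the per-animal
#' fractions within each arm.
#'
#' @param cells A cell table ([simulate_cells()] / [read_cell_table()]).
#' @return A data.frame of class `animal_summary` with columns `animal_id`,
#'   `arm`, `n_cells`, `infected_fraction`, `mean_area`, `sd_area`, and
#'   attribute `group_stats`.
#' @export
summarize_animals <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) == 0)
    stop_data("empty cell table")
  if (!all(c("animal_id", "gfp_positive", "area_um2") %in% names(cells)))
    stop_data("cell table needs animal_id, gfp_positive, area_um2")
  arm <- if ("arm" %in% names(cells)) cells$arm else "unspecified"

  key <- split(seq_len(nrow(cells)), cells$animal_id)
  out <- do.call(rbind, lapply(names(key), function(a) {
    idx <- key[[a]]
    data.frame(animal_id = a,
               arm = as.character(arm[idx[1]]),
               n_cells = length(idx),
               infected_fraction = mean(cells$gfp_positive[idx]),
               mean_area = mean(cells$area_um2[idx]),
               sd_area = stats::sd(cells$area_um2[idx]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$animal_id), ]
  rownames(out) <- NULL

  gs <- do.call(rbind, lapply(split(out, out$arm), function(g)
    data.frame(arm = g$arm[1], n_animals = nrow(g),
               mean_fraction = mean(g$infected_fraction),
               sd_fraction = stats::sd(g$infected_fraction),
               stringsAsFactors = FALSE)))
  rownames(gs) <- NULL
  attr(out, "group_stats") <- gs
  class(out) <- c("animal_summary", "data.frame")
  out
}

#' Welch comparison of two cell-area groups
#'
#' Two-sided Welch (unequal-variance) t test with Welch--Satterthwaite
#' degrees of freedom, plus Cohen's d on the pooled SD. The sign of
#' `mean_diff` is `mean(a) - mean(b)`.
#'
#' @param areas_a,areas_b Cell areas (um^2) of the two groups, each n >= 2.
#' @param group_a,group_b Labels.
#' @return An object of class `group_comparison` with fields `group_a`,
#'   `group_b`, `mean_diff`, `welch_t`, `df`, `p_value`, `cohens_d`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(areas_a, areas_b, group_a = "a", group_b = "b") {
  a <- as.numeric(areas_a[!is.na(areas_a)])
  b <- as.numeric(areas_b[!is.na(areas_b)])
  if (length(a) < 2 || length(b) < 2)
    stop_data("each group needs at least 2 observations")

  md <- mean(a) - mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: both groups constant
    tt <- if (md == 0) 0 else sign(md) * Inf
    df <- length(a) + length(b) - 2
    p <- if (md == 0) 1 else 0
  } else {
    w <- stats::t.test(a, b, var.equal = FALSE)
    tt <- unname(w$statistic)
    df <- unname(w$parameter)
    p <- w$p.value
  }
  sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
             (length(a) + length(b) - 2))
  d <- if (sp == 0) { if (md == 0) 0 else sign(md) * Inf } else md / sp

  structure(list(group_a = group_a, group_b = group_b, mean_diff = md,
                 welch_t = tt, df = df, p_value = p, cohens_d = d,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: mean diff %.1f um^2, Welch t = %.2f (df %.1f), p = %.4g, d = %.2f\n",
              x$group_a, x$group_b, x$mean_diff, x$welch_t, x$df,
              x$p_value, x$cohens_d))
  invisible(x)
}

#' Compare cell areas between arms / GFP strata of a cell table
#'
#' Convenience wrapper extracting two area vectors from a cell table and
#' delegating to [compare_groups()]. The default unit pools cells across
#' animals (matching the >20-cells-per-animal pooling of the morphometry);
#' `unit = "animal"` compares per-animal mean areas instead.
#'
#' @param cells A cell table (possibly rbind-ed across arms).
#' @param arm_a,arm_b Arms to compare.
#' @param gfp Optional logical: restrict both groups to GFP+ (`TRUE`) or
#'   GFP- (`FALSE`) cells.
#' @param unit `"cell"` (pooled) or `"animal"` (per-animal means).
#' @return A `group_comparison`.
#' @export
compare_arms <- function(cells, arm_a, arm_b, gfp = NULL,
                         unit = c("cell", "animal")) {
  unit <- match.arg(unit)
  pick <- function(arm) {
    sel <- cells$arm == arm
    if (!is.null(gfp)) sel <- sel & cells$gfp_positive == gfp
    sub <- cells[sel, , drop = FALSE]
    if (nrow(sub) == 0) stop_data(paste0("no cells in arm ", arm))
    if (unit == "cell") sub$area_um2
    else vapply(split(sub$area_um2, sub$animal_id), mean, numeric(1))
  }
  lab <- function(arm) paste0(arm, if (is.null(gfp)) "" else
    if (gfp) " GFP+" else " GFP-")
  compare_groups(pick(arm_a), pick(arm_b), lab(arm_a), lab(arm_b))
}

#' Benjamini--Hochberg adjustment across a set of comparisons
#'
#' Off by default in the pipeline (panels are reported with per-panel
#' significance); apply when several [compare_groups()] results are read
#' together.
#'
#' @param comparisons List of `group_comparison` objects.
#' @param method Adjustment method (see [stats::p.adjust()]).
#' @return A data.frame with one row per comparison and columns `group_a`,
#'   `group_b`, `p_value`, `p_adjusted`.
#' @export
adjust_comparisons <- function(comparisons, method = "BH") {
  p <- vapply(comparisons, function(x) x$p_value, numeric(1))
  data.frame(group_a = vapply(comparisons, `[[`, "", "group_a"),
             group_b = vapply(comparisons, `[[`, "", "group_b"),
             p_value = p,
             p_adjusted = stats::p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

#' Non-cell-autonomy index
#'
#' Scalar summary of the paracrine (bystander) effect: the relative area
#' reduction of \emph{uninfected} (GFP-) cells in the treated arm versus
#' uninfected cells in the control arm,
#' `1 - mean(treated GFP-) / mean(control GFP-)`. Positive values indicate
#' non-cell-autonomous attenuation of hypertrophy; the index is invariant
#' to rescaling both groups by a common positive factor.
#'
#' @param gfp_neg_treated,gfp_neg_control Areas (um^2) of GFP- cells.
#' @return A fraction in (-Inf, 1].
#' @examples
#' non_cell_autonomy_index(rep(250, 5), rep(332.2, 5))
#' @export
non_cell_autonomy_index <- function(gfp_neg_treated, gfp_neg_control) {
  t <- as.numeric(gfp_neg_treated[!is.na(gfp_neg_treated)])
  c0 <- as.numeric(gfp_neg_control[!is.na(gfp_neg_control)])
  if (!length(t) || !length(c0)) stop_data("both groups must be non-empty")
  mc <- mean(c0)
  if (mc == 0) stop_data("control mean area is zero")
  1 - mean(t) / mc
}
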