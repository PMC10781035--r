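# Cutoff-scan pipeline: optimize a cluster size over a grid of
# polarization-cutoff radii, compare each truncated-model minimum to the
# full-potential reference, and tabulate energies, structural RMSD,
# coordination counts and percent energy deviations.

#' Full-potential reference minimum
#'
#' Basin hopping at a reference cutoff large enough to include every
#' molecule pair (default 20 Angstrom), verified a posteriori:
#' `r_ref >= d_max` of the result must hold, and the energy is re-evaluated
#' with the truncation disabled to confirm exact equality.
#'
#' @param n cluster size.
#' @param params a [dc_params()] object (its `cutoff` is replaced by
#'   `r_ref`).
#' @param settings a [bh_settings()].
#' @param r_ref reference cutoff radius, Angstrom.
#' @return a `bhopt` object with an extra `uncutoff_check` field (absolute
#'   energy difference vs the untruncated evaluation, kcal/mol).
#' @export
reference_minimum <- function(n, params = dc_params(),
                              settings = bh_settings(), r_ref = 20) {
  params$cutoff <- r_ref
  fit <- basin_hopping(n, params, settings)
  if (fit$d_max > r_ref)
    warning(sprintf("reference cutoff %.1f A is below d_max = %.2f A", r_ref,
                    fit$d_max))
  free <- total_energy(fit$best, params, cutoff = Inf)
  fit$uncutoff_check <- abs(free$e_total - fit$energy$e_total)
  fit
}

#' Percent energy deviation from a reference
#'
#' `100 |E - E_ref| / |E_ref|`.
#'
#' @param e energy (kcal/mol) or an `energy_breakdown`.
#' @param reference reference energy or `energy_breakdown`; must be
#'   nonzero.
#' @return deviation in percent.
#' @export
energy_deviation <- function(e, reference) {
  if (inherits(e, "energy_breakdown")) e <- e$e_total
  if (inherits(reference, "energy_breakdown")) reference <- reference$e_total
  if (reference == 0) stop("reference energy must be nonzero")
  100 * abs(e - reference) / abs(reference)
}

#' Scan the polarization cutoff radius
#'
#' For each radius in `r_grid`, runs an independent basin-hopping search
#' (with a seed derived from the settings seed and the radius) under the
#' potential truncated at that radius, and records the energy breakdown of
#' the best minimum, its permutation-minimized O--O RMSD to the
#' full-potential reference, the average interacting count at that radius,
#' the percent energy deviation and d_max.  The default grid (1 to 8
#' Angstrom in 0.5 steps plus the 20 Angstrom reference radius) resolves
#' the first-coordination-shell radius near 3 Angstrom and the
#' intermediate-shell region around 4 Angstrom.
#'
#' @param n cluster size.
#' @param r_grid cutoff radii, Angstrom.
#' @param params a [dc_params()] object.
#' @param settings a [bh_settings()]; `n_steps`/`n_trajectories` set the
#'   per-radius search budget.
#' @param reference optional `bhopt` from [reference_minimum()]; computed
#'   (at the largest grid radius) when missing.
#' @param reference_settings settings for the reference search when it is
#'   computed here (defaults to `settings`).
#' @return An object of class `cutoff_scan`: a data.frame with one row per
#'   radius and columns `n, r, e_lj, e_coulomb, e_pol, e_total,
#'   rmsd_to_reference, avg_interacting, energy_deviation, d_max, seed`,
#'   plus attributes `reference`, `params`, `settings`.
#' @export
scan_cutoffs <- function(n, r_grid = c(seq(1, 8, by = 0.5), 20),
                         params = dc_params(), settings = bh_settings(),
                         reference = NULL,
                         reference_settings = settings) {
  stopifnot(length(r_grid) >= 1, all(r_grid > 0))
  r_grid <- sort(unique(r_grid))
  seed <- settings$seed
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  settings$seed <- seed
  if (is.null(reference)) {
    reference_settings$seed <- traj_seed(seed, 777L)
    reference <- reference_minimum(n, params, reference_settings,
                                   r_ref = max(r_grid, 20))
  }
  ref_d <- oo_distances(reference$best)
  rows <- vector("list", length(r_grid))
  fits <- vector("list", length(r_grid))
  for (i in seq_along(r_grid)) {
    r <- r_grid[i]
    p <- params; p$cutoff <- r
    s <- settings; s$seed <- traj_seed(seed, round(1000 * r))
    fit <- basin_hopping(n, p, s)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      n = n, r = r,
      e_lj = fit$energy$e_lj, e_coulomb = fit$energy$e_coulomb,
      e_pol = fit$energy$e_pol, e_total = fit$energy$e_total,
      rmsd_to_reference = permutation_rmsd(ref_d, oo_distances(fit$best)),
      avg_interacting = avg_interacting(fit$best, r),
      energy_deviation = energy_deviation(fit$energy, reference$energy),
      d_max = fit$d_max, seed = s$seed)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_scan", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "fits") <- fits
  attr(out, "params") <- params
  attr(out, "settings") <- settings
  out
}

#' Coordination-shell parametric table
#'
#' Re-expresses a cutoff scan as (average interacting count, percent
#' energy deviation) pairs in radius order: the parametric view in which
#' the first-shell sufficiency (deviation within ~5% once the first
#' coordination shell is complete) is visible directly.
#'
#' @param scan a `cutoff_scan`.
#' @return data.frame with columns `r`, `avg_interacting`,
#'   `energy_deviation`.
#' @export
shell_parametric_table <- function(scan) {
  stopifnot(inherits(scan, "cutoff_scan"))
  data.frame(r = scan$r, avg_interacting = scan$avg_interacting,
             energy_deviation = scan$energy_deviation)
}

#' @export
print.cutoff_scan <- function(x, ...) {
  ref <- attr(x, "reference")
  cat(sprintf("Cutoff scan: N = %d, %d radii, reference E = %.5f kcal/mol\n",
              x$n[1], nrow(x), ref$energy$e_total))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Plot a cutoff scan
#'
#' Four qualitative panels: the energy contributions vs cutoff radius, the
#' average interacting count vs radius, the structural RMSD vs radius, and
#' the energy deviation vs interacting count (parametric view).
#'
#' @param x a `cutoff_scan`.
#' @param ... passed to the energy panel.
#' @export
plot.cutoff_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(c(x$e_lj, x$e_coulomb, x$e_pol, x$e_total))
  graphics::plot(x$r, x$e_total, type = "b", pch = 4, col = "red",
                 ylim = rng, xlab = "cutoff r (A)",
                 ylab = "energy (kcal/mol)", main = "energy terms", ...)
  graphics::lines(x$r, x$e_lj, type = "b", pch = 1, col = "blue")
  graphics::lines(x$r, x$e_coulomb, type = "b", pch = 0, col = "orange")
  graphics::lines(x$r, x$e_pol, type = "b", pch = 2, col = "darkgreen")
  graphics::legend("bottomright", c("total", "LJ", "Coulomb", "polarization"),
                   col = c("red", "blue", "orange", "darkgreen"),
                   pch = c(4, 1, 0, 2), cex = 0.7)
  graphics::plot(x$r, x$avg_interacting, type = "s", xlab = "cutoff r (A)",
                 ylab = expression(group("<", N[i], ">")),
                 main = "interacting molecules")
  graphics::plot(x$r, x$rmsd_to_reference, type = "b", xlab = "cutoff r (A)",
                 ylab = "RMSD (A)", main = "structural deviation")
  graphics::plot(x$avg_interacting, x$energy_deviation, type = "b",
                 xlab = expression(group("<", N[i], ">")),
                 ylab = "energy deviation (%)", main = "parametric view")
  graphics::abline(h = 5, lty = 2)
  invisible(x)
}

#' Write a scan table and its run manifest
#'
#' Writes the scan records as CSV (documented header = the column names of
#' the `cutoff_scan` data.frame) and a JSON manifest with the settings,
#' seeds and potential parameters.
#'
#' @param scan a `cutoff_scan`.
#' @param csv_path output CSV path.
#' @param manifest_path optional JSON manifest path.
#' @return `csv_path`, invisibly.
#' @export
write_scan <- function(scan, csv_path, manifest_path = NULL) {
  stopifnot(inherits(scan, "cutoff_scan"))
  write.csv(as.data.frame(scan), csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    params <- attr(scan, "params")
    manifest <- list(
      n = scan$n[1], r_grid = scan$r, seeds = scan$seed,
      settings = unclass(attr(scan, "settings")),
      params = c(unclass(params)[c("epsilon", "sigma", "q_h", "q_m",
                                   "alpha", "cutoff", "mutual",
                                   "coulomb_k")],
                 unclass(params$geom)),
      reference_energy = attr(scan, "reference")$energy$e_total)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}
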