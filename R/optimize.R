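# Basin-hopping global optimization of rigid water clusters in angle-axis
# coordinates: random starts, Monte Carlo moves on all molecules, L-BFGS
# quenches, Metropolis acceptance on quenched energies, and per-block
# step-size adaptation toward a target acceptance ratio.

#' Basin-hopping settings
#'
#' Defaults follow the standard protocol for polarizable water clusters:
#' an optimization temperature of k_B T = 3 kcal/mol, alternating blocks
#' of 100 translational and 200 angular moves adapted toward a 20%
#' acceptance ratio, and four independent trajectories.  The per-trajectory
#' step count defaults to 1e4 (a desk-scale budget; raise to 1e5 for
#' production searches of larger clusters).
#'
#' @param n_steps basin-hopping steps per trajectory.
#' @param n_trajectories independent trajectories (each from its own
#'   random start and derived seed).
#' @param temperature Metropolis temperature k_B T, kcal/mol.
#' @param translational_block,angular_block moves per adaptation block.
#' @param target_acceptance acceptance ratio the step sizes are adapted
#'   toward (multiply by 1.05 if the measured block acceptance is above
#'   target, by 0.95 otherwise, clamped to sane bounds).
#' @param initial_translation_step Angstrom (moves are uniform in a cube
#'   of this half-width, applied to every molecule).
#' @param initial_rotation_step radians (uniform-in-cube rotation-vector
#'   perturbations of every molecule).
#' @param seed integer seed; `NULL` draws one from the session RNG.  Given
#'   the seed, runs are exactly reproducible.
#' @param minimizer_tolerance quench convergence threshold on the gradient
#'   max-norm, kcal/mol/Angstrom (and /rad).
#' @param minimizer_maxit L-BFGS iteration cap per quench.
#' @param guard_radius Angstrom: quenched configurations whose O--O graph
#'   at this radius is disconnected (an evaporated molecule) are rejected.
#' @return An object of class `bh_settings`.
#' @export
bh_settings <- function(n_steps = 10000, n_trajectories = 4,
                        temperature = 3, translational_block = 100,
                        angular_block = 200, target_acceptance = 0.2,
                        initial_translation_step = 1.2,
                        initial_rotation_step = 1.2, seed = NULL,
                        minimizer_tolerance = 1e-2, minimizer_maxit = 200,
                        guard_radius = 5) {
  stopifnot(n_steps >= 1, n_trajectories >= 1, temperature > 0,
            translational_block >= 1, angular_block >= 1,
            target_acceptance > 0, target_acceptance < 1,
            initial_translation_step > 0, initial_rotation_step > 0,
            minimizer_tolerance > 0, minimizer_maxit >= 1, guard_radius > 0)
  structure(list(n_steps = as.integer(n_steps),
                 n_trajectories = as.integer(n_trajectories),
                 temperature = temperature,
                 translational_block = as.integer(translational_block),
                 angular_block = as.integer(angular_block),
                 target_acceptance = target_acceptance,
                 initial_translation_step = initial_translation_step,
                 initial_rotation_step = initial_rotation_step,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 minimizer_tolerance = minimizer_tolerance,
                 minimizer_maxit = as.integer(minimizer_maxit),
                 guard_radius = guard_radius),
            class = "bh_settings")
}

#' Local minimization (quench) of a cluster
#'
#' L-BFGS descent on the rigid-body coordinates using the analytic
#' gradient.  The returned energy never exceeds the starting energy; on a
#' line-search breakdown or dipole non-convergence the best point found is
#' returned with `converged = FALSE`.
#'
#' @param config starting `water_cluster` (no hard overlaps).
#' @param params a [dc_params()] object.
#' @param settings a [bh_settings()] (only the minimizer fields are used).
#' @param gtol,maxit optional overrides of the settings.
#' @return list with `cluster`, `energy` (an `energy_breakdown`), `gmax`,
#'   `iterations`, `converged`.
#' @export
local_minimize <- function(config, params = dc_params(),
                           settings = bh_settings(),
                           gtol = settings$minimizer_tolerance,
                           maxit = settings$minimizer_maxit) {
  res <- cpp_minimize(pose_matrix(config), cpp_par(params), gtol, maxit)
  b <- res$breakdown
  if (!isTRUE(b$ok)) check_eval(b)
  list(cluster = cluster_from_pose(res$x),
       energy = structure(list(e_lj = b$e_lj, e_coulomb = b$e_coulomb,
                               e_pol = b$e_pol, e_total = b$e_total,
                               converged = b$converged,
                               iterations = b$iterations),
                          class = "energy_breakdown"),
       gmax = res$gmax, iterations = res$iterations,
       converged = isTRUE(res$converged))
}

#' Propose a Monte Carlo move
#'
#' Translational moves perturb every molecule's position by an independent
#' uniform-in-cube vector of half-width `step`; angular moves perturb
#' every orientation vector the same way.  The input configuration is not
#' modified.  Uses the session RNG (seed with `set.seed` for
#' reproducibility).
#'
#' @param config a `water_cluster`.
#' @param kind `"translational"` or `"angular"`.
#' @param step maximum per-component perturbation (Angstrom or radians).
#' @return a new `water_cluster`.
#' @export
propose_move <- function(config, kind = c("translational", "angular"), step) {
  kind <- match.arg(kind)
  stopifnot(step >= 0)
  m <- pose_matrix(config)
  n <- nrow(m)
  cols <- if (kind == "translational") 1:3 else 4:6
  m[, cols] <- m[, cols] + matrix(runif(3 * n, -step, step), n, 3)
  cluster_from_pose(m)
}

traj_seed <- function(seed, k) as.integer((seed + 1000003 * k) %% 2147483647L)

#' Basin-hopping search for the putative global minimum
#'
#' Runs `n_trajectories` independent basin-hopping trajectories of
#' `n_steps` steps each, starting from random clusters
#' ([random_cluster()]), and returns the lowest minimum found.  Each step
#' perturbs all molecules (alternating blocks of translational and
#' angular moves), quenches with L-BFGS, rejects dissociated
#' configurations, and applies a Metropolis accept/reject on the quenched
#' energies at the optimization temperature.  Step sizes adapt per block
#' toward the target acceptance ratio.  Fully reproducible given the seed
#' (per-trajectory seeds are derived from it).
#'
#' @param n cluster size (>= 2).
#' @param params a [dc_params()] object (its `cutoff` defines the
#'   truncation of the polarization term during the whole search).
#' @param settings a [bh_settings()].
#' @param start optional list of starting `water_cluster`s, one per
#'   trajectory (defaults to seeded random clusters).
#' @return An object of class `bhopt`: list with `best` (the minimum-energy
#'   `water_cluster`), `energy` (`energy_breakdown`), `n`, `d_max`,
#'   per-trajectory diagnostics (`trajectories`), `settings`, `seed`,
#'   `n_minimizations`.
#' @examples
#' \donttest{
#' p <- dc_params(cutoff = 20)
#' fit <- basin_hopping(3, p, bh_settings(n_steps = 200, n_trajectories = 1,
#'                                        seed = 1))
#' fit
#' }
#' @export
basin_hopping <- function(n, params = dc_params(),
                          settings = bh_settings(), start = NULL) {
  stopifnot(n >= 2)
  seed <- settings$seed
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  par <- cpp_par(params)
  trajs <- vector("list", settings$n_trajectories)
  best <- NULL
  n_min <- 0L
  for (k in seq_len(settings$n_trajectories)) {
    set.seed(traj_seed(seed, k))
    x0 <- if (!is.null(start)) pose_matrix(start[[k]])
          else pose_matrix(random_start(n))
    res <- cpp_basin_hopping(x0, par, settings$n_steps,
                             settings$temperature,
                             settings$translational_block,
                             settings$angular_block,
                             settings$target_acceptance,
                             settings$initial_translation_step,
                             settings$initial_rotation_step,
                             settings$minimizer_tolerance,
                             settings$minimizer_maxit,
                             settings$guard_radius)
    n_min <- n_min + res$n_minimizations
    trajs[[k]] <- list(best_energy = res$best$e_total,
                       best_step = res$best_step,
                       acceptance = res$acceptance,
                       step_trans = res$step_trans,
                       step_rot = res$step_rot,
                       best_history = res$best_history,
                       seed = traj_seed(seed, k))
    if (is.null(best) || res$best$e_total < best$best$e_total) best <- res
  }
  # final polish of the overall best at tight tolerance
  pol <- cpp_minimize(best$best_x, par, 1e-6, 2000L)
  n_min <- n_min + 1L
  b <- pol$breakdown
  cl <- cluster_from_pose(pol$x)
  structure(list(best = cl,
                 energy = structure(list(e_lj = b$e_lj,
                                         e_coulomb = b$e_coulomb,
                                         e_pol = b$e_pol,
                                         e_total = b$e_total,
                                         converged = b$converged,
                                         iterations = b$iterations),
                                    class = "energy_breakdown"),
                 n = n, d_max = d_max(cl), trajectories = trajs,
                 settings = settings, seed = seed, params = params,
                 n_minimizations = n_min),
            class = "bhopt")
}

# random start for basin hopping; grows the container if the default
# density cannot be placed (placement failure is an error for the
# user-facing fixture, but a trajectory start must not abort a search)
random_start <- function(n) {
  r <- 1.5 * n^(1/3)
  for (i in 1:6) {
    cl <- tryCatch(random_cluster(n, container_radius = r),
                   error = function(e) NULL)
    if (!is.null(cl)) return(cl)
    r <- 1.25 * r
  }
  stop("could not place a random starting cluster")
}

#' @export
print.bhopt <- function(x, ...) {
  cat(sprintf("Basin-hopping result: N = %d, cutoff r = %.2f A\n",
              x$n, x$params$cutoff))
  cat(sprintf("  best energy: %.5f kcal/mol (LJ %.4f, Coulomb %.4f, pol %.4f)\n",
              x$energy$e_total, x$energy$e_lj, x$energy$e_coulomb,
              x$energy$e_pol))
  cat(sprintf("  d_max = %.3f A; %d trajectories x %d steps (seed %d)\n",
              x$d_max, x$settings$n_trajectories, x$settings$n_steps,
              x$seed))
  invisible(x)
}

#' @export
summary.bhopt <- function(object, ...) {
  print(object)
  eb <- vapply(object$trajectories, function(t) t$best_energy, 0)
  cat(sprintf("  trajectory best energies: %s kcal/mol\n",
              paste(sprintf("%.4f", eb), collapse = ", ")))
  acc <- unlist(lapply(object$trajectories, function(t) t$acceptance))
  cat(sprintf("  mean block acceptance: %.3f (target %.2f)\n",
              mean(acc), object$settings$target_acceptance))
  cat(sprintf("  quenches: %d\n", object$n_minimizations))
  invisible(object)
}

#' @export
plot.bhopt <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$trajectories[[1]]$best_history
  graphics::plot(seq_along(h), h, type = "s", xlab = "block",
                 ylab = "best energy (kcal/mol)",
                 main = "running best (trajectory 1)", ...)
  acc <- x$trajectories[[1]]$acceptance
  graphics::plot(seq_along(acc), acc, type = "l", xlab = "block",
                 ylab = "acceptance", main = "block acceptance")
  graphics::abline(h = x$settings$target_acceptance, lty = 2)
  invisible(x)
}

#' Write a basin-hopping checkpoint
#'
#' Serializes a search result to JSON: settings, seed, cluster size, the
#' best-so-far configuration and energy, and the step counters.  A later
#' run can resume from it by passing the checkpointed configuration as a
#' start (see [read_checkpoint()]).
#'
#' @param fit a `bhopt` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "bhopt"))
  jsonlite::write_json(list(
    n = fit$n, seed = fit$seed,
    settings = unclass(fit$settings),
    best_pose = as.matrix(fit$best),
    best_energy = unclass(fit$energy)[c("e_lj", "e_coulomb", "e_pol",
                                        "e_total")],
    n_minimizations = fit$n_minimizations,
    steps_done = fit$settings$n_steps * fit$settings$n_trajectories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a basin-hopping checkpoint
#'
#' @param path JSON path written by [write_checkpoint()].
#' @return list with `n`, `seed`, `settings` (a [bh_settings()]), `best`
#'   (a `water_cluster`), `best_energy`, `n_minimizations`, `steps_done`.
#'   Resume a search with
#'   `basin_hopping(ck$n, params, settings, start = rep(list(ck$best), settings$n_trajectories))`.
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- ck$settings
  sets <- sets[intersect(names(sets), names(formals(bh_settings)))]
  list(n = ck$n, seed = ck$seed, settings = do.call(bh_settings, sets),
       best = cluster_from_pose(matrix(unlist(ck$best_pose), ck$n, 6)),
       best_energy = ck$best_energy,
       n_minimizations = ck$n_minimizations, steps_done = ck$steps_done)
}
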