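#' Parameters of the rigid polarizable water potential
#'
#' Assembles the full parameter set of the 4-site polarizable potential:
#' an O--O Lennard-Jones term, Coulomb interactions between partial charges
#' on the hydrogens and the M site, and a many-body polarization term from
#' an isotropic point polarizability on the M site.  Only the polarization
#' term is subject to the cutoff radius; the pairwise terms never are.
#'
#' The defaults are the Dang--Chang polarizable water model, transcribed
#' from Dang & Chang, J. Chem. Phys. 106, 8149 (1997): they reproduce the
#' gas-phase monomer dipole of 1.85 D.  The same parameter set ships as a
#' YAML file in `system.file("extdata", "dc_params.yaml", package =
#' "dcwater")`; see [read_water_params()].
#'
#' @param epsilon Lennard-Jones well depth (O--O), kcal/mol.
#' @param sigma Lennard-Jones diameter (O--O), Angstrom.
#' @param q_h partial charge on each hydrogen, e.
#' @param q_m partial charge on the M site, e; must equal `-2 * q_h`
#'   (neutral molecule).
#' @param alpha isotropic molecular polarizability on the M site, Angstrom^3.
#' @param geom rigid monomer geometry, a [water_geometry()].
#' @param cutoff polarization cutoff radius r, Angstrom: molecule pairs
#'   with O--O distance greater than `cutoff` are excluded from the static
#'   field and from the dipole-dipole couplings (and only from those).
#' @param mutual logical: include the mutual dipole-dipole coupling in the
#'   self-consistency (full linear response, the standard Dang--Chang
#'   formulation).  `FALSE` gives the charges-only induction
#'   `mu_i = alpha * E_i^0`, provided for sensitivity analysis.
#' @param scf_tol convergence tolerance of the fixed-point dipole
#'   iteration (max component change, e Angstrom).
#' @param scf_maxit iteration cap for the fixed-point solver.
#' @param coulomb_k Coulomb conversion constant, kcal mol^-1 Angstrom e^-2.
#' @param overlap_floor hard O--O floor, Angstrom; configurations with a
#'   closer contact are rejected as degenerate.
#' @return An object of class `water_params`.
#' @examples
#' p <- dc_params(cutoff = 20)
#' p
#' @export
dc_params <- function(epsilon = 0.1825, sigma = 3.234,
                      q_h = 0.519, q_m = -2 * q_h, alpha = 1.444,
                      geom = water_geometry(), cutoff = 20,
                      mutual = TRUE, scf_tol = 1e-10, scf_maxit = 2000,
                      coulomb_k = 332.0637, overlap_floor = 0.1) {
  stopifnot(epsilon > 0, sigma > 0, alpha >= 0, cutoff > 0,
            scf_tol > 0, scf_maxit >= 1, coulomb_k > 0, overlap_floor > 0)
  if (abs(q_m + 2 * q_h) > 1e-12)
    stop("q_m must equal -2 * q_h (molecular neutrality)")
  if (!inherits(geom, "water_geometry")) geom <- do.call(water_geometry, geom)
  structure(list(epsilon = epsilon, sigma = sigma, q_h = q_h, q_m = q_m,
                 alpha = alpha, geom = geom, cutoff = cutoff,
                 mutual = isTRUE(mutual), scf_tol = scf_tol,
                 scf_maxit = as.integer(scf_maxit), coulomb_k = coulomb_k,
                 overlap_floor = overlap_floor),
            class = "water_params")
}

#' @export
print.water_params <- function(x, ...) {
  cat("Rigid polarizable 4-site water potential\n")
  cat(sprintf("  LJ (O-O):      epsilon = %.4f kcal/mol, sigma = %.3f A\n",
              x$epsilon, x$sigma))
  cat(sprintf("  charges:       q_H = %+.4f e, q_M = %+.4f e\n", x$q_h, x$q_m))
  cat(sprintf("  polarizability: alpha = %.3f A^3 (M site), %s induction\n",
              x$alpha, if (x$mutual) "mutual" else "charges-only"))
  cat(sprintf("  polarization cutoff: r = %.2f A (O-O, hard)\n", x$cutoff))
  print(x$geom)
  invisible(x)
}

# flat list for the C++ layer, with optional cutoff override
cpp_par <- function(params, cutoff = NULL) {
  stopifnot(inherits(params, "water_params"))
  p <- unclass(params)
  if (!is.null(cutoff)) p$cutoff <- cutoff
  if (!is.finite(p$cutoff)) p$cutoff <- 1e12  # "no cutoff"
  p$geom <- list(r_oh = params$geom$r_oh, theta_hoh = params$geom$theta_hoh,
                 r_om = params$geom$r_om)
  p
}

#' Read potential parameters from a YAML file
#'
#' The file is a flat key-value mapping using the argument names of
#' [dc_params()] (geometry keys `r_oh`, `theta_hoh`, `r_om` at top level
#' or under `geom:`).  Keys not present fall back to the packaged
#' Dang--Chang defaults.  Units are as in [dc_params()].
#'
#' @param path YAML file path.
#' @return A `water_params` object.
#' @export
read_water_params <- function(path) {
  y <- yaml::read_yaml(path)
  gk <- c("r_oh", "theta_hoh", "r_om")
  g <- if (!is.null(y$geom)) y$geom else y[intersect(gk, names(y))]
  y <- y[setdiff(names(y), c("geom", gk))]
  args <- y[intersect(names(y), names(formals(dc_params)))]
  if (length(g)) args$geom <- do.call(water_geometry, g[intersect(gk, names(g))])
  do.call(dc_params, args)
}

#' Write potential parameters to a YAML file
#'
#' @param params a `water_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_water_params <- function(params, path) {
  stopifnot(inherits(params, "water_params"))
  y <- unclass(params)
  y$geom <- unclass(y$geom)
  yaml::write_yaml(y, path)
  invisible(path)
}
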