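# Synthetic starting configurations and idealized closed-form geometries.
# Random clusters seed the basin-hopping trajectories; the ideal solids
# (cube, trigonal prism) have exactly known O-O distance multisets and are
# used as geometric oracles in tests.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Haar-uniform random rotation as an angle-axis vector, via a uniform
# unit quaternion
random_orientation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  th <- 2 * acos(max(-1, min(1, q[1])))
  s <- sqrt(max(0, 1 - q[1]^2))
  if (s < 1e-12) return(c(0, 0, 0))
  q[2:4] / s * th
}

#' Random non-overlapping starting cluster
#'
#' O positions are sampled uniformly in a sphere and rejection-sampled to
#' keep every O--O pair at least `min_separation` apart; orientations are
#' Haar-uniform random rotations.  The defaults (separation 2.2 Angstrom,
#' container radius `1.5 N^(1/3)` Angstrom) give starting densities close
#' enough to bind on quenching while avoiding close contacts that would
#' make the dipole self-consistency diverge.
#'
#' @param n number of molecules.
#' @param seed optional integer seed (calls `set.seed`); with the same
#'   seed the configuration is bit-identical across calls.
#' @param container_radius sphere radius for the O positions, Angstrom.
#' @param min_separation minimum pairwise O--O distance, Angstrom.
#' @return a `water_cluster`.
#' @export
random_cluster <- function(n, seed = NULL,
                           container_radius = 1.5 * n^(1/3),
                           min_separation = 2.2) {
  stopifnot(n >= 1, container_radius > 0, min_separation > 0)
  with_seed(seed, {
    for (restart in 1:60) {
      pos <- matrix(NA_real_, n, 3)
      placed <- 0L
      tries <- 0L
      while (placed < n && tries < 2000L) {
        tries <- tries + 1L
        x <- runif(3, -container_radius, container_radius)
        if (sum(x^2) > container_radius^2) next
        if (placed > 0L) {
          dd <- sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - x)^2))
          if (any(dd < min_separation)) next
        }
        placed <- placed + 1L
        pos[placed, ] <- x
      }
      if (placed == n) {
        ori <- t(vapply(seq_len(n), function(i) random_orientation(),
                        numeric(3)))
        return(water_cluster(pos, ori))
      }
    }
    stop("random_cluster: container too small for the requested separation")
  })
}

#' Ideal cubic octamer
#'
#' Eight O sites on the vertices of a cube; orientations are random but
#' seeded.  The O--O distance multiset is exactly 12 edges, 12 face
#' diagonals and 4 body diagonals, which makes the cube a convenient
#' closed-form oracle for distance-based metrics (the cube motif is also
#' the characteristic oxygen frame of minimum-energy water octamers).
#'
#' @param edge cube edge length, Angstrom.
#' @param seed optional integer seed for the orientations.
#' @return a `water_cluster` with 8 molecules.
#' @export
ideal_cube <- function(edge, seed = NULL) {
  stopifnot(edge > 0)
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  colnames(v) <- NULL
  with_seed(seed, {
    ori <- t(vapply(1:8, function(i) random_orientation(), numeric(3)))
    water_cluster(v, ori)
  })
}

#' Ideal trigonal-prism hexamer
#'
#' Six O sites on the vertices of a trigonal prism (two parallel
#' equilateral triangles of side `edge` separated by `height`): the oxygen
#' frame of the minimum-energy polarizable-water hexamer.
#'
#' @param edge triangle side, Angstrom.
#' @param height distance between the triangle planes, Angstrom.
#' @param seed optional integer seed for the orientations.
#' @return a `water_cluster` with 6 molecules.
#' @export
ideal_prism <- function(edge, height, seed = NULL) {
  stopifnot(edge > 0, height > 0)
  rr <- edge / sqrt(3)  # circumradius of the triangle
  ang <- 2 * pi * (0:2) / 3
  tri <- cbind(rr * cos(ang), rr * sin(ang), 0)
  v <- rbind(tri, sweep(tri, 2, c(0, 0, height), "+"))
  with_seed(seed, {
    ori <- t(vapply(1:6, function(i) random_orientation(), numeric(3)))
    water_cluster(v, ori)
  })
}
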