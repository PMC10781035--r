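# Structural observables: O-O distance multisets, permutation-minimized
# distance RMSD, largest O-O distance, coordination counting.

#' O--O distance multiset of a cluster
#'
#' @param config a `water_cluster` with at least two molecules.
#' @return numeric vector of the N(N-1)/2 unordered O--O pair distances
#'   (Angstrom), with attribute `n` = cluster size.
#' @export
oo_distances <- function(config) {
  n <- cluster_size(config)
  if (n < 2) stop("oo_distances requires at least 2 molecules")
  d <- as.numeric(dist(o_positions(config)))
  attr(d, "n") <- n
  d
}

dset <- function(x) {
  if (inherits(x, "water_cluster")) return(oo_distances(x))
  as.numeric(x)
}

#' Permutation-minimized O--O distance RMSD between two clusters
#'
#' The structural deviation between a cluster and a reference is measured
#' on the O--O distance multisets: the RMSD minimized over all pairings of
#' the distances,
#' `min_pi sqrt( sum_i (R_i - r_pi(i))^2 / P )`,
#' which makes the metric invariant under molecule relabeling and global
#' rigid motions.  The minimizing pairing for squared loss is obtained by
#' sorting both multisets and pairing in order (rearrangement inequality);
#' an exhaustive search over all P! pairings is retained as a check for
#' small clusters.
#'
#' @param reference,test `water_cluster` objects of equal size, or their
#'   [oo_distances()] vectors.
#' @param normalization `"ndist"` (default) divides by the number of
#'   distances P = N(N-1)/2, giving a per-distance RMS in Angstrom;
#'   `"n"` divides by the cluster size N instead.
#' @param method `"sorted"` (default) or `"brute"` (exhaustive, only for
#'   P <= 8).
#' @return RMSD in Angstrom.
#' @export
permutation_rmsd <- function(reference, test,
                             normalization = c("ndist", "n"),
                             method = c("sorted", "brute")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  a <- dset(reference); b <- dset(test)
  if (length(a) != length(b))
    stop("distance sets must come from clusters of equal size")
  p <- length(a)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  denom <- if (normalization == "ndist") p else n
  if (method == "sorted") {
    return(sqrt(sum((sort(a) - sort(b))^2) / denom))
  }
  if (p > 8) stop("brute-force pairing is limited to 8 distances")
  perms <- all_permutations(p)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    s <- sum((a - b[perms[i, ]])^2)
    if (s < best) best <- s
  }
  sqrt(best / denom)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Largest O--O distance in a cluster
#'
#' `d_max` is the smallest cutoff radius at which the truncated
#' polarization term equals the full many-body term exactly.
#'
#' @param config a `water_cluster` with at least two molecules.
#' @return distance in Angstrom.
#' @export
d_max <- function(config) max(oo_distances(config))

#' Average number of interacting molecules
#'
#' For each molecule, counts the molecules within O--O distance `r`
#' including the molecule itself (an isolated molecule counts 1), and
#' averages over the cluster.  This is the mean number of molecules
#' coupled by the polarization term at cutoff `r`: it equals 1 below the
#' nearest-neighbor distance and N once `r >= d_max`, and in between it is
#' a non-decreasing step function whose plateaus mark complete
#' coordination shells (e.g. 4 for the three-coordinated molecules of a
#' cubic octamer, 5 for tetrahedral bulk-like coordination).
#'
#' @param config a `water_cluster`.
#' @param r cutoff radius, Angstrom.  Ties at exactly `r` count as
#'   interacting (closed ball).
#' @return average count (dimensionless).
#' @export
avg_interacting <- function(config, r) {
  stopifnot(r > 0)
  n <- cluster_size(config)
  if (n == 1) return(1)
  d <- as.matrix(dist(o_positions(config)))
  mean(colSums(d <= r))  # diagonal is 0 <= r, so the self-count is included
}

#' Radii of complete coordination shells
#'
#' Detects the cutoff radii at which the average interacting count has a
#' plateau (a complete shell): maximal gaps in the sorted O--O distance
#' multiset wider than `gap` are reported by their midpoints.
#'
#' @param config a `water_cluster`.
#' @param gap minimal gap width, Angstrom.
#' @return numeric vector of radii (possibly empty), increasing.
#' @export
shell_radii <- function(config, gap = 0.3) {
  d <- sort(dset(config))
  dd <- diff(d)
  mid <- (d[-length(d)] + d[-1]) / 2
  mid[dd > gap]
}
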