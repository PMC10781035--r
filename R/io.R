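# XYZ serialization of clusters.  Molecules are written as contiguous
# O,H,H(,M) blocks in pose order; the comment line carries key=value
# metadata (e.g. the energy and the cutoff used).  Reading reconstructs
# rigid-body poses by fitting each block to the reference frame and
# validates rigidity.

stop_xyz <- function(class, msg) {
  stop(structure(class = c(class, "xyz_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write a cluster to an XYZ file
#'
#' Standard XYZ dialect: first line the atom count, second line a comment
#' with `key=value` metadata pairs, then `SYMBOL x y z` with coordinates
#' in Angstrom printed to 6 decimals.
#'
#' @param config a `water_cluster`.
#' @param path output file path.
#' @param geom a [water_geometry()] used to expand the sites.
#' @param include_m also write the massless M site (symbol `M`).
#' @param metadata named list of scalar metadata written into the comment
#'   line (e.g. `list(e_total = -41.5, cutoff = 20)`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path, geom = water_geometry(),
                      include_m = FALSE, metadata = list()) {
  s <- all_sites(config, geom)
  n <- length(s)
  per <- if (include_m) 4L else 3L
  lines <- character(2 + per * n)
  lines[1] <- as.character(per * n)
  lines[2] <- paste(vapply(names(metadata), function(k)
    sprintf("%s=%.10g", k, as.numeric(metadata[[k]])), ""), collapse = " ")
  r <- 3L
  syms <- c("O", "H", "H", "M")
  for (i in seq_len(n)) {
    for (a in seq_len(per)) {
      lines[r] <- sprintf("%-2s %12.6f %12.6f %12.6f", syms[a],
                          s[[i]][a, 1], s[[i]][a, 2], s[[i]][a, 3])
      r <- r + 1L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

parse_xyz_comment <- function(line) {
  line <- trimws(line)
  if (!nzchar(line)) return(list())
  toks <- strsplit(line, "\\s+")[[1]]
  toks <- toks[grepl("=", toks)]
  out <- list()
  for (t in toks) {
    kv <- strsplit(t, "=", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(kv[2]))
    out[[kv[1]]] <- if (is.na(v)) kv[2] else v
  }
  out
}

# best-fit rotation (Kabsch) mapping body-frame offsets B to observed
# offsets X (both k x 3)
kabsch <- function(B, X) {
  s <- svd(t(B) %*% X)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Read a cluster from an XYZ file
#'
#' Expects molecules serialized as contiguous O,H,H (optionally followed
#' by M) blocks.  Each block is fit to the rigid reference frame: the pose
#' position is the O position and the orientation the best-fit rotation.
#' Blocks deviating from the rigid geometry by more than `tol` are
#' rejected.  The two hydrogens are interchangeable (C2v symmetry); the
#' labeling giving the smaller rotation angle is kept, so symmetry-
#' equivalent poses compare equal.
#'
#' @param path XYZ file path.
#' @param geom the expected [water_geometry()].
#' @param tol rigidity tolerance, Angstrom.
#' @return a `water_cluster`; comment-line metadata is attached as
#'   attribute `metadata`.
#' @export
read_xyz <- function(path, geom = water_geometry(), tol = 1e-3) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_xyz("xyz_malformed", "file too short")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 1) stop_xyz("xyz_malformed", "bad atom count line")
  if (length(lines) < 2 + nat)
    stop_xyz("xyz_malformed", "fewer atom lines than the declared count")
  meta <- parse_xyz_comment(lines[2])
  toks <- strsplit(trimws(lines[3:(2 + nat)]), "\\s+")
  bad <- vapply(toks, length, 0L) < 4
  if (any(bad)) stop_xyz("xyz_malformed", "atom line with fewer than 4 fields")
  sym <- toupper(vapply(toks, `[[`, "", 1))
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop_xyz("xyz_malformed", "non-numeric coordinates")
  if (!all(sym %in% c("O", "H", "M")))
    stop_xyz("xyz_unknown_symbol",
             paste("unknown atom symbols:",
                   paste(unique(setdiff(sym, c("O", "H", "M"))), collapse = ", ")))
  per <- if (any(sym == "M")) 4L else 3L
  if (nat %% per != 0)
    stop_xyz("xyz_malformed",
             sprintf("atom count %d is not a multiple of %d", nat, per))
  n <- nat %/% per
  want <- rep(if (per == 4L) c("O", "H", "H", "M") else c("O", "H", "H"), n)
  if (!all(sym == want))
    stop_xyz("xyz_malformed", "atoms are not in O,H,H(,M) molecule blocks")

  B <- body_frame(geom)
  pos <- matrix(0, n, 3)
  ori <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    blk <- xyz[((i - 1) * per + 1):(i * per), , drop = FALSE]
    o <- blk[1, ]
    obs <- sweep(blk[-1, , drop = FALSE], 2, o)  # H1,H2(,M) offsets
    fits <- list(obs, obs[c(2, 1, seq_len(per - 3) + 2), , drop = FALSE])
    best <- NULL
    for (X in fits) {
      Bref <- B[2:per, , drop = FALSE]
      R <- kabsch(Bref, X)
      resid <- sqrt(max(rowSums((X - t(R %*% t(Bref)))^2)))
      p <- angle_axis_from_rotation(R)
      if (is.null(best) || resid < best$resid - 1e-12 ||
          (abs(resid - best$resid) <= 1e-12 &&
           sum(p^2) < sum(best$p^2))) {
        best <- list(R = R, resid = resid, p = p)
      }
    }
    if (best$resid > tol)
      stop_xyz("xyz_nonrigid",
               sprintf("molecule %d deviates from the rigid geometry by %.2g A",
                       i, best$resid))
    pos[i, ] <- o
    ori[i, ] <- best$p
  }
  out <- water_cluster(pos, ori)
  attr(out, "metadata") <- meta
  out
}
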