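#' Decoy clustering and convergence analysis
#'
#' Decoy ensembles are clustered by an iterative neighbor-count procedure
#' in the spirit of the classic structure-decoy clustering tools: the decoy
#' with the most neighbors within an RMSD cutoff seeds the first cluster,
#' its members are removed, and the process repeats (up to five clusters).
#' The largest cluster's relative size and tightness give the convergence
#' density Dc used in the folding confidence score.
#'
#' @name decoy_analysis
NULL

#' Optimal-superposition Ca RMSD between two conformations
#'
#' Least root-mean-square deviation after rigid superposition (Kabsch
#' rotation via SVD, with reflection guard).
#'
#' @param a,b `ChainConformation`s (or n x 3 coordinate matrices) of equal
#'   length.
#' @return RMSD in A.
#' @export
pairwise_rmsd <- function(a, b) {
  xa <- if (inherits(a, "ChainConformation")) a$ca else as.matrix(a)
  xb <- if (inherits(b, "ChainConformation")) b$ca else as.matrix(b)
  if (nrow(xa) != nrow(xb)) {
    cf_abort("cf_length_mismatch_error",
             "conformations differ in length (%d vs %d)", nrow(xa), nrow(xb))
  }
  superposed_sq_dev(xa, xb)$rmsd
}

# Kabsch superposition of xb onto xa; returns rmsd and rotated coordinates.
superposed_sq_dev <- function(xa, xb, sub = NULL) {
  if (!is.null(sub)) {
    ca <- colMeans(xa[sub, , drop = FALSE])
    cb <- colMeans(xb[sub, , drop = FALSE])
    h <- crossprod(sweep(xb[sub, , drop = FALSE], 2, cb),
                   sweep(xa[sub, , drop = FALSE], 2, ca))
  } else {
    ca <- colMeans(xa); cb <- colMeans(xb)
    h <- crossprod(sweep(xb, 2, cb), sweep(xa, 2, ca))
  }
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xb_fit <- sweep(sweep(xb, 2, cb) %*% t(r), 2, ca, `+`)
  dev <- xa - xb_fit
  list(rmsd = sqrt(mean(rowSums(dev * dev))), fitted = xb_fit)
}

#' Pairwise RMSD matrix of a decoy ensemble
#'
#' @param ens a `DecoyEnsemble` or list of conformations.
#' @return symmetric matrix of [pairwise_rmsd()] values.
#' @export
rmsd_matrix <- function(ens) {
  decoys <- if (inherits(ens, "DecoyEnsemble")) ens$decoys else ens
  m <- length(decoys)
  dm <- matrix(0, m, m)
  if (m < 2) return(dm)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      dm[i, j] <- dm[j, i] <- pairwise_rmsd(decoys[[i]], decoys[[j]])
    }
  }
  dm
}

cluster_at_cutoff <- function(dm, cutoff, max_clusters = 5L) {
  m <- nrow(dm)
  remaining <- seq_len(m)
  solutions <- list()
  while (length(remaining) > 0 && length(solutions) < max_clusters) {
    sub <- dm[remaining, remaining, drop = FALSE]
    neigh <- rowSums(sub <= cutoff) - 1L
    seed_local <- which.max(neigh)          # ties: lowest index wins
    members_local <- which(sub[seed_local, ] <= cutoff)
    members <- remaining[members_local]
    centroid <- remaining[seed_local]
    rmsds <- dm[centroid, members]
    solutions[[length(solutions) + 1L]] <- structure(
      list(members = members, M = length(members),
           centroid_index = centroid,
           mean_rmsd_to_centroid = mean(rmsds),
           rmsd_cutoff = cutoff),
      class = "ClusterSolution")
    remaining <- setdiff(remaining, members)
  }
  solutions
}

#' Cluster a decoy ensemble by neighbor counting
#'
#' With `cutoff = "auto"` the RMSD cutoff is adapted on a 0.5 A grid over
#' [3.5, 12] A, choosing the smallest cutoff whose top cluster holds
#' between 10% and 70% of the decoys (falling back to the grid end when no
#' cutoff qualifies).
#'
#' @param ens a `DecoyEnsemble` or list of conformations.
#' @param cutoff `"auto"` or a fixed RMSD cutoff in A.
#' @param max_clusters maximum clusters extracted (default 5).
#' @param cutoff_range adaptation bounds in A (default `c(3.5, 12)`).
#' @return list of `ClusterSolution`s, largest-first extraction order.
#' @export
spicker_cluster <- function(ens, cutoff = "auto", max_clusters = 5L,
                            cutoff_range = c(3.5, 12)) {
  decoys <- if (inherits(ens, "DecoyEnsemble")) ens$decoys else ens
  if (length(decoys) == 0L) {
    cf_abort("cf_domain_error", "empty decoy ensemble")
  }
  dm <- rmsd_matrix(decoys)
  m <- nrow(dm)
  if (identical(cutoff, "auto")) {
    grid <- seq(cutoff_range[1], cutoff_range[2], by = 0.5)
    frac <- vapply(grid, function(cc) {
      sol <- cluster_at_cutoff(dm, cc, 1L)
      sol[[1]]$M / m
    }, numeric(1))
    ok <- which(frac >= 0.1 & frac <= 0.7)
    cutoff <- if (length(ok)) grid[ok[1]]
      else if (all(frac < 0.1)) cutoff_range[2]
      else cutoff_range[1]
  }
  cluster_at_cutoff(dm, cutoff, max_clusters)
}

#' @export
print.ClusterSolution <- function(x, ...) {
  cat(sprintf("ClusterSolution: M = %d, centroid decoy %d, <R> = %.2f A (cutoff %.1f A)\n",
              x$M, x$centroid_index, x$mean_rmsd_to_centroid, x$rmsd_cutoff))
  invisible(x)
}

#' Convergence density Dc of a cluster
#'
#' `Dc = (M / M_tot) / <R>`, the fraction of decoys captured by the cluster
#' divided by their mean RMSD to the centroid. `<R>` is floored at 0.5 A so
#' a degenerate single-point cluster cannot send Dc to infinity.
#'
#' @param sol a `ClusterSolution`.
#' @param M_tot total number of decoys in the simulation (> 0).
#' @param r_floor minimum `<R>` used (default 0.5 A).
#' @return Dc (scalar).
#' @export
convergence_density <- function(sol, M_tot, r_floor = 0.5) {
  if (M_tot <= 0) cf_abort("cf_domain_error", "M_tot must be > 0")
  (sol$M / M_tot) / max(sol$mean_rmsd_to_centroid, r_floor)
}

#' First-model selection
#'
#' The centroid decoy of the cluster with the most members is the first
#' model (ties broken by extraction order). Refinement of the centroid is
#' an identity step in this implementation.
#'
#' @param solutions list of `ClusterSolution`s.
#' @param ens the `DecoyEnsemble` (or decoy list) they index into.
#' @return the centroid `ChainConformation`.
#' @export
select_first_model <- function(solutions, ens) {
  if (length(solutions) == 0L) {
    cf_abort("cf_domain_error", "no clusters supplied")
  }
  decoys <- if (inherits(ens, "DecoyEnsemble")) ens$decoys else ens
  sizes <- vapply(solutions, function(s) s$M, numeric(1))
  best <- solutions[[which.max(sizes)]]
  decoys[[best$centroid_index]]
}

#' Cluster report table
#'
#' @param solutions list of `ClusterSolution`s.
#' @param M_tot total decoy count.
#' @return data.frame with columns `cluster`, `M`, `mean_rmsd`, `Dc`.
#' @export
cluster_report <- function(solutions, M_tot) {
  data.frame(
    cluster = seq_along(solutions),
    M = vapply(solutions, function(s) s$M, numeric(1)),
    mean_rmsd = vapply(solutions, function(s) s$mean_rmsd_to_centroid,
                       numeric(1)),
    Dc = vapply(solutions, convergence_density, numeric(1), M_tot = M_tot)
  )
}
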