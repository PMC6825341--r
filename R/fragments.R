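#' Fragment libraries and distance profiles
#'
#' Fragment assembly draws short backbone pieces (1-20 residues) from a
#' position-indexed library and splices their internal geometry into the
#' chain. The same library yields pairwise distance profiles: histograms of
#' Cb-Cb distances observed across the fragments covering a residue pair,
#' converted to a knowledge-based energy term `-w * ln(p(d) + eps)`.
#'
#' @name fragments
NULL

# --- internal (pseudo-bond) coordinates of a Ca trace ----------------------

# Returns list(l, theta, tau): l[i] = |p_i - p_{i-1}| (i >= 2),
# theta[i] = angle at p_{i-1} over (p_{i-2}, p_{i-1}, p_i) (i >= 3),
# tau[i] = dihedral (p_{i-3}, p_{i-2}, p_{i-1}, p_i) (i >= 4).
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

internal_coords <- function(ca) {
  n <- nrow(ca)
  b <- diff(ca)                       # (n-1) x 3 bond vectors
  l <- c(NA, sqrt(rowSums(b * b)))
  theta <- rep(NA_real_, n)
  tau <- rep(NA_real_, n)
  if (n >= 3) {
    u <- b / sqrt(rowSums(b * b))
    cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
    theta[3:n] <- acos(clamp(-cosang, -1, 1))  # angle at the middle atom
  }
  if (n >= 4) {
    b1 <- b[1:(n - 3), , drop = FALSE]
    b2 <- b[2:(n - 2), , drop = FALSE]
    b3 <- b[3:(n - 1), , drop = FALSE]
    n1 <- row_cross(b1, b2)
    n2 <- row_cross(b2, b3)
    u2 <- b2 / sqrt(rowSums(b2 * b2))
    m1 <- row_cross(n1, u2)
    tau[4:n] <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
  }
  list(l = l, theta = theta, tau = tau)
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitize(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Place the next atom from the three preceding ones (NeRF construction).
# Scalar arithmetic throughout: this sits in the Monte Carlo hot loop.
nerf_place <- function(a, b, c, l, theta, tau) {
  bc1 <- c[1] - b[1]; bc2 <- c[2] - b[2]; bc3 <- c[3] - b[3]
  bn <- sqrt(bc1 * bc1 + bc2 * bc2 + bc3 * bc3)
  bc1 <- bc1 / bn; bc2 <- bc2 / bn; bc3 <- bc3 / bn
  ab1 <- b[1] - a[1]; ab2 <- b[2] - a[2]; ab3 <- b[3] - a[3]
  n1 <- ab2 * bc3 - ab3 * bc2
  n2 <- ab3 * bc1 - ab1 * bc3
  n3 <- ab1 * bc2 - ab2 * bc1
  nn <- sqrt(n1 * n1 + n2 * n2 + n3 * n3)
  if (nn < 1e-9) {
    p <- perp_unit(c(bc1, bc2, bc3)); n1 <- p[1]; n2 <- p[2]; n3 <- p[3]
  } else {
    n1 <- n1 / nn; n2 <- n2 / nn; n3 <- n3 / nn
  }
  m1 <- n2 * bc3 - n3 * bc2          # cross(n, bc)
  m2 <- n3 * bc1 - n1 * bc3
  m3 <- n1 * bc2 - n2 * bc1
  st <- l * sin(theta); d1 <- -l * cos(theta)
  d2 <- st * cos(tau); d3 <- st * sin(tau)
  c(c[1] + d1 * bc1 + d2 * m1 + d3 * n1,
    c[2] + d1 * bc2 + d2 * m2 + d3 * n2,
    c[3] + d1 * bc3 + d2 * m3 + d3 * n3)
}

# Rebuild Cartesian coordinates ca[from..n] from internal coordinates,
# keeping ca[1..from-1] fixed. `from` must be >= 2.
rebuild_from <- function(ca, ic, from) {
  n <- nrow(ca)
  for (i in from:n) {
    if (i == 2) {
      dir <- unitize(ca[2, ] - ca[1, ])
      ca[2, ] <- ca[1, ] + ic$l[2] * dir
    } else if (i == 3) {
      # no dihedral defined yet: use a fixed virtual reference atom
      a <- ca[1, ] + perp_unit(ca[2, ] - ca[1, ])
      ca[3, ] <- nerf_place(a, ca[1, ], ca[2, ], ic$l[3], ic$theta[3],
                            ifelse(is.na(ic$tau[3]), 0, ic$tau[3]))
    } else {
      ca[i, ] <- nerf_place(ca[i - 3, ], ca[i - 2, ], ca[i - 1, ],
                            ic$l[i], ic$theta[i], ic$tau[i])
    }
  }
  ca
}

#' Construct a fragment library object
#'
#' @param fragments list (indexed by start position) of lists of fragment
#'   Ca coordinate matrices.
#' @param n_res chain length the library covers.
#' @param top_n nominal per-position capacity (default 200).
#' @return a `FragmentLibrary`.
#' @export
fragment_library <- function(fragments, n_res, top_n = 200) {
  lens <- unlist(lapply(fragments, function(fl) vapply(fl, nrow, 1L)))
  if (length(lens) && (min(lens) < 1L || max(lens) > 20L)) {
    cf_abort("cf_domain_error", "fragment lengths must lie in [1, 20]")
  }
  if (any(vapply(fragments, length, 1L) > top_n)) {
    cf_abort("cf_domain_error", "per-position fragment count exceeds top_n")
  }
  structure(list(fragments = fragments, n_res = as.integer(n_res),
                 top_n = as.integer(top_n)),
            class = "FragmentLibrary")
}

#' Distance profile of a residue pair from a fragment library
#'
#' Tallies the Cb-Cb distance between residues `i` and `j` across every
#' fragment that covers both within a single piece, into bins of
#' `bin_width` A. Pairs never covered yield an empty profile that
#' contributes zero energy.
#'
#' @param frags a `FragmentLibrary`.
#' @param i,j residue indices (i < j; coverage requires `j - i` < fragment
#'   length).
#' @param bin_width histogram bin width in A (default 0.5).
#' @return a `DistanceProfile`: list with `i`, `j`, `breaks`, `counts`,
#'   `n_obs`.
#' @export
build_distance_profile <- function(frags, i, j, bin_width = 0.5) {
  stopifnot(inherits(frags, "FragmentLibrary"), i < j)
  dists <- numeric(0)
  for (p in seq_along(frags$fragments)) {
    if (p > i) next
    for (f in frags$fragments[[p]]) {
      last <- p + nrow(f) - 1L
      if (last < j) next
      cb <- virtual_cbeta(f)
      dists <- c(dists, vnorm(cb[i - p + 1L, ] - cb[j - p + 1L, ]))
    }
  }
  if (length(dists) == 0L) {
    return(structure(list(i = i, j = j, breaks = numeric(0),
                          counts = integer(0), n_obs = 0L),
                     class = "DistanceProfile"))
  }
  top <- ceiling(max(dists) / bin_width) * bin_width
  breaks <- seq(0, top, by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  counts <- as.integer(table(cut(dists, breaks, include.lowest = TRUE)))
  structure(list(i = i, j = j, breaks = breaks, counts = counts,
                 n_obs = length(dists)),
            class = "DistanceProfile")
}

#' Profile energy of a pairwise distance
#'
#' `-ln(p(d) + eps)` with `p` the normalized histogram mass of the bin
#' containing `d` (0 outside the histogram range). Empty profiles return 0.
#'
#' @param profile a `DistanceProfile`.
#' @param d distance in A.
#' @param eps regularizer (default 1e-3).
#' @return energy value.
#' @export
profile_energy <- function(profile, d, eps = 1e-3) {
  if (profile$n_obs == 0L) return(0)
  p <- 0
  k <- findInterval(d, profile$breaks, rightmost.closed = TRUE)
  if (k >= 1 && k <= length(profile$counts)) {
    p <- profile$counts[k] / profile$n_obs
  }
  -log(p + eps)
}

# Precompiled profile set for fast evaluation inside the MC loop:
# matrix of -log(p + eps) per (pair, bin), shared breaks.
compile_profiles <- function(profiles, eps = 1e-3) {
  profiles <- Filter(function(pr) pr$n_obs > 0, profiles)
  if (length(profiles) == 0L) return(NULL)
  bw <- profiles[[1]]$breaks[2] - profiles[[1]]$breaks[1]
  maxbin <- max(vapply(profiles, function(pr) length(pr$counts), 1L))
  mat <- matrix(-log(eps), length(profiles), maxbin)
  ij <- matrix(0L, length(profiles), 2)
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    mat[k, seq_along(pr$counts)] <- -log(pr$counts / pr$n_obs + eps)
    ij[k, ] <- c(pr$i, pr$j)
  }
  list(ij = ij, mat = mat, bin_width = bw, floor_e = -log(eps))
}

eval_profile_set <- function(compiled, cb) {
  if (is.null(compiled)) return(0)
  dv <- cb[compiled$ij[, 1], , drop = FALSE] - cb[compiled$ij[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dv * dv))
  bin <- floor(d / compiled$bin_width) + 1
  ok <- bin >= 1 & bin <= ncol(compiled$mat)
  e <- rep(compiled$floor_e, length(d))
  e[ok] <- compiled$mat[cbind(which(ok), bin[ok])]
  sum(e)
}

#' Build distance profiles for all nearby residue pairs
#'
#' Convenience wrapper over [build_distance_profile()] covering every pair
#' with sequence separation in `sep_range` (fragment pieces are at most 20
#' residues, so separations above 19 are never covered).
#'
#' @param frags a `FragmentLibrary`.
#' @param sep_range separation range, default `c(3, 12)`.
#' @param bin_width histogram bin width in A.
#' @return list of `DistanceProfile` objects.
#' @export
build_profile_set <- function(frags, sep_range = c(3, 12), bin_width = 0.5) {
  out <- list()
  for (i in seq_len(frags$n_res)) {
    for (s in sep_range[1]:sep_range[2]) {
      j <- i + s
      if (j > frags$n_res) break
      pr <- build_distance_profile(frags, i, j, bin_width)
      if (pr$n_obs > 0) out[[length(out) + 1L]] <- pr
    }
  }
  out
}
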