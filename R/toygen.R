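#' Synthetic fixture generation
#'
#' Generates everything the pipeline needs without external databases:
#' idealized toy folds (helix bundles, beta hairpins, mixed topologies)
#' with valid chain geometry, their true contact maps, predictor-like
#' corrupted contact lists at controlled precision, fragment libraries
#' derived from the native fold, and alignments tuned to a requested
#' effective sequence count. All generators are deterministic per seed.
#'
#' @name toygen
NULL

#' Default precision of the four synthetic predictor tiers
#' @return named numeric vector.
#' @export
default_tier_precisions <- function() {
  c(very_high = 0.8, high = 0.65, medium = 0.5, low = 0.35)
}

# Equal-chord arc between points p and q: n_bonds chords of length `bond`,
# bulging toward unit vector w. Returns the n_bonds - 1 interior points.
arc_bridge <- function(p, q, n_bonds, w, bond = BOND_IDEAL) {
  g <- vnorm(q - p)
  if (n_bonds < 2) cf_abort("cf_domain_error", "arc needs >= 2 bonds")
  if (g >= n_bonds * bond) {
    cf_abort("cf_infeasible_error", "gap %.2f too wide for %d bonds", g, n_bonds)
  }
  e1 <- unitize(q - p)
  w <- unitize(w - sum(w * e1) * e1)
  if (g < 1e-9) cf_abort("cf_infeasible_error", "coincident arc endpoints")
  # solve chord ratio g/bond = sin(A/2) / sin(A/(2n)) for total arc angle A
  f <- function(a) sin(a / 2) / sin(a / (2 * n_bonds)) - g / bond
  a_tot <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6), tol = 1e-10)$root
  rho <- g / (2 * sin(a_tot / 2))
  mid <- (p + q) / 2
  centre <- mid - rho * cos(a_tot / 2) * w
  u <- unitize(p - centre)
  # second in-plane axis chosen so the arc apex (angle A/2) sits along +w;
  # this stays correct when the arc angle exceeds pi
  u2 <- unitize((w - cos(a_tot / 2) * u) / sin(a_tot / 2))
  ang <- a_tot * seq_len(n_bonds - 1) / n_bonds
  t(vapply(ang, function(a) centre + rho * (cos(a) * u + sin(a) * u2),
           numeric(3)))
}

# Ideal alpha-helix Ca trace: radius 2.3 A, rise 1.5 A, 100 deg per residue.
helix_trace <- function(n, centre_xy, z0, direction = 1, phase = 0) {
  t <- seq_len(n) - 1
  ang <- phase + direction * (100 * pi / 180) * t
  cbind(centre_xy[1] + 2.3 * cos(ang),
        centre_xy[2] + 2.3 * sin(ang),
        z0 + direction * 1.5 * t)
}

# Pleated beta-strand Ca trace along direction dirx in x (bond 3.80 A).
strand_trace <- function(n, x0, y0, z0, dirx = 1) {
  t <- seq_len(n) - 1
  cbind(x0 + dirx * 3.679 * t, y0 + 0.95 * (t %% 2), rep(z0, n))
}

# Bonds needed to bridge gap g with gently curved arcs (chord ~ 88% of
# the straight-line allotment keeps the sagitta small).
loop_bonds <- function(g, bond = BOND_IDEAL) {
  max(2L, as.integer(ceiling(g / (bond * 0.88))))
}

build_helix_bundle <- function(n_res) {
  n_h <- if (n_res >= 45) 3L else 2L
  centres <- if (n_h == 3) {
    rb <- 5.8
    lapply(0:2, function(k) rb * c(cos(2 * pi * k / 3), sin(2 * pi * k / 3)))
  } else {
    list(c(-4.8, 0), c(4.8, 0))
  }
  assemble <- function(lens) {
    ca <- NULL
    for (k in seq_len(n_h)) {
      dir <- if (k %% 2 == 1) 1 else -1
      z0 <- if (dir == 1) 0 else (lens[k] - 1) * 1.5
      h <- helix_trace(lens[k], centres[[k]], z0, dir, phase = 2.1 * k)
      if (!is.null(ca)) {
        p <- ca[nrow(ca), ]
        q <- h[1, ]
        out_xy <- unitize(c((p[1] + q[1]) / 2, (p[2] + q[2]) / 2, 0))
        zsign <- if (k %% 2 == 0) 1 else -1  # loop sits past the helix ends
        nb <- loop_bonds(vnorm(q - p))
        # try a few bulge tilts; keep the first arc clear of both helices
        # bonded neighbours (arc endpoints) are excluded from the check
        context <- rbind(utils::tail(ca[-nrow(ca), , drop = FALSE], 12),
                         utils::head(h[-1, , drop = FALSE], 12))
        arc <- NULL; best <- -Inf
        for (nb_try in nb + 0:2) {        # extra bonds buy steeper departures
          for (rot in c(0, 25, -25, 50) * pi / 180) {
            rz <- rotation_matrix(c(0, 0, 1), rot)
            for (tilt in c(1.2, 1.8, 0.8, 2.6, 0.5)) {
              w <- unitize(as.vector(rz %*% out_xy) + c(0, 0, zsign * tilt))
              cand <- arc_bridge(p, q, nb_try, w)
              dmin <- min(as.matrix(stats::dist(rbind(cand, context)))[
                seq_len(nrow(cand)), -seq_len(nrow(cand))])
              if (dmin > best) { arc <- cand; best <- dmin }
              if (best >= 3.5) break
            }
            if (best >= 3.5) break
          }
          if (best >= 3.5) break
        }
        ca <- rbind(ca, arc, h)
      } else {
        ca <- h
      }
    }
    ca
  }
  base <- max(5L, (n_res - 3L * (n_h - 1L)) %/% n_h)
  lens <- rep(base, n_h)
  turn <- 0L
  for (it in 1:60) {
    ca <- assemble(lens)
    delta <- n_res - nrow(ca)
    if (delta == 0L) return(ca)
    # nudge one helix at a time: loop sizes react to endpoint geometry, so
    # small steps converge where bulk redistribution can oscillate
    k <- turn %% n_h + 1L
    lens[k] <- max(4L, lens[k] + sign(delta) * min(abs(delta), 2L))
    turn <- turn + 1L
  }
  cf_abort("cf_infeasible_error",
           "could not allocate %d residues over %d helices", n_res, n_h)
}

build_beta_hairpin <- function(n_res) {
  turn_int <- 2L                      # tight two-residue beta turn
  n_s2 <- (n_res - turn_int) %/% 2L
  n_s1 <- n_res - turn_int - n_s2
  s1 <- strand_trace(n_s1, 0, 0, 0, dirx = 1)
  x_end <- s1[nrow(s1), 1]
  s2 <- strand_trace(n_s2, x_end - 1.8, 0, 5.0, dirx = -1)
  p <- s1[nrow(s1), ]
  q <- s2[1, ]
  rbind(s1, arc_bridge(p, q, turn_int + 1L, unitize(c(1, 0.3, 0.5))), s2)
}

# Helix with its axis along +x.
helix_trace_x <- function(n, x0, y0, z0, phase = 0) {
  t <- seq_len(n) - 1
  ang <- phase + (100 * pi / 180) * t
  cbind(x0 + 1.5 * t, y0 + 2.3 * cos(ang), z0 + 2.3 * sin(ang))
}

build_mixed <- function(n_res) {
  turn_int <- 2L; loop_int <- 3L
  n_rest <- n_res - turn_int - loop_int
  n_s <- max(5L, floor(n_rest * 0.27))
  n_hel <- n_rest - 2L * n_s
  s1 <- strand_trace(n_s, 0, 0, 0, dirx = 1)
  x_end <- s1[nrow(s1), 1]
  s2 <- strand_trace(n_s, x_end - 1.8, 0, 5.0, dirx = -1)
  turn <- arc_bridge(s1[nrow(s1), ], s2[1, ], turn_int + 1L,
                     unitize(c(1, 0.3, 0.5)))
  hel <- helix_trace_x(n_hel, x0 = 1.0, y0 = 0, z0 = 11.2, phase = 0.4)
  loop <- arc_bridge(s2[nrow(s2), ], hel[1, ], loop_int + 1L,
                     unitize(c(-1, 0.4, 0.8)))
  rbind(s1, turn, s2, loop, hel)
}

#' Generate an idealized toy fold
#'
#' Deterministic per seed; a small seeded coordinate jitter (0.03 A sd)
#' decorrelates repeated topologies without breaking the chain-geometry
#' invariants.
#'
#' @param topology one of `"helix_bundle"`, `"beta_hairpin"`, `"mixed"`.
#' @param n_res chain length in `[20, 120]`.
#' @param seed RNG seed.
#' @return a `ChainConformation` passing [validate_geometry()].
#' @export
make_toy_structure <- function(topology = c("helix_bundle", "beta_hairpin",
                                            "mixed"),
                               n_res, seed = 1) {
  topology <- match.arg(topology)
  if (n_res < 20 || n_res > 120) {
    cf_abort("cf_infeasible_error",
             "n_res must lie in [20, 120] (got %d)", n_res)
  }
  ca <- switch(topology,
               helix_bundle = build_helix_bundle(n_res),
               beta_hairpin = build_beta_hairpin(n_res),
               mixed = build_mixed(n_res))
  stopifnot(nrow(ca) == n_res)
  with_seed(seed, {
    ca <- ca + matrix(stats::rnorm(length(ca), 0, 0.03), ncol = 3)
    seq_aa <- paste(sample(c("A", "L", "V", "I", "F", "S", "T", "E", "K",
                             "D", "R", "N", "Q", "G"),
                           n_res, replace = TRUE), collapse = "")
    conf <- chain_conformation(ca, seq_aa)
    if (!validate_geometry(conf)) {
      cf_abort("cf_infeasible_error",
               "generated %s of %d residues violates chain geometry",
               topology, n_res)
    }
    conf
  })
}

#' True contact map of a structure
#'
#' All residue pairs with Cb-Cb distance at or below `threshold` and
#' sequence separation of at least `min_sep`, with unit restraint weight.
#'
#' @param conf a `ChainConformation`.
#' @param threshold contact distance in A (default 8).
#' @param min_sep minimum sequence separation (default 6).
#' @return a `ConsensusContactSet` with `u = 1` everywhere.
#' @export
true_contacts <- function(conf, threshold = 8, min_sep = 6) {
  n <- conf$n_res
  dm <- as.matrix(stats::dist(conf$cb))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1] >= min_sep) &
    dm[idx] <= threshold
  df <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                   u = rep(1, sum(keep)))
  df$sep_class <- if (nrow(df)) separation_class(df$i, df$j) else character(0)
  new_consensus_set(df, n)
}

#' Corrupt a true contact map into a predictor-like ranked list
#'
#' Produces a ranked list of the tier's nominal length whose fraction of
#' true pairs equals `precision` (to rounding). False pairs are drawn
#' uniformly from non-contact pairs at the same minimum separation. True
#' pairs are biased toward the top of the ranking; `ranking_noise` controls
#' how much the two populations interleave. Confidences decrease with rank.
#'
#' @param truth a `ConsensusContactSet` of true contacts.
#' @param precision fraction of true pairs in `(0, 1]`.
#' @param category tier controlling the list length via [top_count()].
#' @param L sequence length.
#' @param ranking_noise interleaving strength in `[0, 1]` (default 0.6).
#' @param seed RNG seed.
#' @param predictor_name identifier for the output.
#' @param min_sep separation floor for sampled false pairs (default 6).
#' @return a `PredictorOutput` of the requested category.
#' @export
corrupt_contacts <- function(truth, precision, category, L,
                             ranking_noise = 0.6, seed = 1,
                             predictor_name = paste0("synthetic_", category),
                             min_sep = 6) {
  if (!(precision > 0 && precision <= 1)) {
    cf_abort("cf_domain_error", "precision must be in (0, 1]")
  }
  n_list <- top_count(category, L)
  with_seed(seed, {
    tdf <- truth$contacts
    n_true <- min(round_half_up(precision * n_list), nrow(tdf))
    n_false <- n_list - n_true
    pick_true <- tdf[sample.int(nrow(tdf), n_true), c("i", "j")]
    all_i <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    sep_ok <- all_i[, 2] - all_i[, 1] >= min_sep
    cand <- all_i[sep_ok, , drop = FALSE]
    truth_key <- paste(tdf$i, tdf$j)
    cand <- cand[!paste(cand[, 1], cand[, 2]) %in% truth_key, , drop = FALSE]
    if (nrow(cand) < n_false) {
      cf_abort("cf_infeasible_error",
               "only %d non-contact pairs available, need %d",
               nrow(cand), n_false)
    }
    pick_false <- cand[sample.int(nrow(cand), n_false), , drop = FALSE]
    q <- c(stats::runif(n_true, 1 - ranking_noise, 1),
           stats::runif(n_false, 0, min(1, 0.4 + ranking_noise / 2)))
    ord <- order(-q)
    ij <- rbind(as.matrix(pick_true), pick_false)[ord, , drop = FALSE]
    conf <- sort(clamp(seq(0.9, 0.25, length.out = n_list) +
                         stats::rnorm(n_list, 0, 0.02), 0.01, 1),
                 decreasing = TRUE)
    predictor_output(predictor_name,
                     data.frame(i = ij[, 1], j = ij[, 2], confidence = conf),
                     category = category, L = L)
  })
}

#' Synthesize an alignment with a requested effective sequence count
#'
#' Sequences descend from a random ancestor; a fraction of rows duplicate
#' earlier rows (block-copy structure) and every row is point-mutated at a
#' rate tuned by bisection until [effective_count()] lands within 10% of
#' `target_nf`. The mutation randomness is frozen per seed so the Nf is a
#' monotone function of the rate and the bisection is well behaved.
#'
#' @param L sequence length.
#' @param n number of rows.
#' @param target_nf requested Nf, within `[1/sqrt(L), n/sqrt(L)]`.
#' @param seed RNG seed.
#' @param tol relative tolerance (default 0.1).
#' @return an `AlignedSequenceSet` with attribute `realized_nf`.
#' @export
synth_msa <- function(L, n, target_nf, seed = 1, tol = 0.1) {
  lo_nf <- 1 / sqrt(L); hi_nf <- n / sqrt(L)
  if (target_nf < lo_nf - 1e-9 || target_nf > hi_nf + 1e-9) {
    cf_abort("cf_infeasible_error",
             "target Nf %.3f outside attainable [%.3f, %.3f]",
             target_nf, lo_nf, hi_nf)
  }
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(seed, {
    anc <- sample(alphabet, L, replace = TRUE)
    parent_of <- c(NA, vapply(2:n, function(i) {
      if (i > 2 && stats::runif(1) < 0.3) sample.int(i - 1, 1) else 1L
    }, 1L))
    u <- matrix(stats::runif(n * L), n, L)
    repl <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
    build <- function(mu) {
      rows <- matrix("", n, L)
      rows[1, ] <- anc
      for (i in 2:n) {
        base <- rows[parent_of[i], ]
        mut <- u[i, ] < mu
        base[mut] <- repl[i, mut]
        rows[i, ] <- base
      }
      aligned_set(c("query", paste0("seq", 2:n)),
                  apply(rows, 1, paste, collapse = ""),
                  query_id = "query")
    }
    nf_of <- function(mu) effective_count(build(mu))$nf
    lo <- 0; hi <- 0.75
    best_mu <- NA; best_nf <- NA
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      nf <- nf_of(mid)
      if (is.na(best_nf) || abs(nf - target_nf) < abs(best_nf - target_nf)) {
        best_mu <- mid; best_nf <- nf
      }
      if (abs(nf - target_nf) <= tol * target_nf) break
      if (nf < target_nf) lo <- mid else hi <- mid
    }
    if (abs(best_nf - target_nf) > tol * target_nf) {
      # endpoints may beat the bisection interior for extreme targets
      for (mu in c(0, 0.75)) {
        nf <- nf_of(mu)
        if (abs(nf - target_nf) < abs(best_nf - target_nf)) {
          best_mu <- mu; best_nf <- nf
        }
      }
    }
    if (abs(best_nf - target_nf) > tol * target_nf) {
      cf_abort("cf_infeasible_error",
               "could not reach Nf %.3f (best %.3f)", target_nf, best_nf)
    }
    msa <- build(best_mu)
    attr(msa, "realized_nf") <- best_nf
    attr(msa, "mutation_rate") <- best_mu
    msa
  })
}

#' Fragment library derived from a native structure
#'
#' Cuts native segments at every start position, applies seeded coordinate
#' jitter, and re-regularizes pseudo-bond lengths so every fragment
#' satisfies the chain-geometry invariants.
#'
#' @param conf the native `ChainConformation`.
#' @param min_len,max_len fragment length range (within `[1, 20]`;
#'   defaults 3-12: shorter pieces carry no internal geometry, longer ones
#'   add little for toy-scale chains).
#' @param per_position fragments per start position (default 200).
#' @param jitter coordinate noise sd in A (default 0.05).
#' @param seed RNG seed.
#' @return a `FragmentLibrary`.
#' @export
make_fragment_library <- function(conf, min_len = 3, max_len = 12,
                                  per_position = 200, jitter = 0.05,
                                  seed = 1) {
  stopifnot(min_len >= 1, max_len <= 20, min_len <= max_len)
  n <- conf$n_res
  with_seed(seed, {
    frags <- vector("list", n)
    for (p in seq_len(n)) {
      avail <- min(max_len, n - p + 1L)
      if (avail < min_len) {
        frags[[p]] <- list()
        next
      }
      lens <- sample(min_len:avail, per_position, replace = TRUE)
      frags[[p]] <- lapply(lens, function(l) {
        f <- conf$ca[p:(p + l - 1L), , drop = FALSE]
        if (jitter > 0 && l >= 2) {
          f <- f + matrix(stats::rnorm(length(f), 0, jitter), ncol = 3)
          if (l >= 3) {
            ic <- internal_coords(f)
            ic$l <- clamp(ic$l, BOND_MIN + 0.05, BOND_MAX - 0.05)
            f <- rebuild_from(f, ic, 2L)
          }
        }
        f
      })
    }
    fragment_library(frags, n, top_n = max(per_position, 200L))
  })
}
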