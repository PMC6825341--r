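#' Replica-exchange Monte Carlo fragment assembly
#'
#' The folding engine assembles a full-length Ca/Cb chain under the
#' contact-restraint potential plus a minimal generic chain force field
#' (harmonic pseudo-bond around 3.8 A, soft-sphere excluded volume at
#' 3.4 A, optional fragment-derived distance-profile term). A ladder of
#' replicas at geometrically spaced temperatures runs Metropolis Monte
#' Carlo with fragment-substitution, pivot and crankshaft moves; adjacent
#' replicas attempt configuration swaps at fixed intervals, and decoys are
#' harvested from the coldest replicas.
#'
#' @name folding_engine
NULL

#' Simulation configuration
#'
#' @param n_replicas number of replicas (default 8).
#' @param t_min,t_max temperature ladder endpoints (geometric spacing).
#' @param steps_per_replica Monte Carlo steps per replica.
#' @param swap_interval steps between replica-exchange sweeps.
#' @param snapshot_interval steps between decoy harvests from the cold
#'   replicas.
#' @param n_cold number of coldest replicas harvested (default 2).
#' @param seed mandatory RNG seed.
#' @param weights named list of energy-term weights (`contact`, `bond`,
#'   `clash`, `profile`).
#' @param move_probs probabilities of the fragment / pivot / crankshaft
#'   moves (renormalized; fragment mass is reassigned when no library is
#'   supplied).
#' @param max_retries resampling attempts before a proposal degrades to the
#'   identity move.
#' @param energy_check_interval accepted-move interval at which the running
#'   energy is validated against a full recomputation.
#' @param soft_radius soft-sphere radius of the excluded-volume energy term
#'   in A (default 4.5; the hard geometric floor stays at 3.4).
#' @param burn_in fraction of each replica's trajectory discarded before
#'   decoy harvesting starts (default 0.3).
#' @param greedy_init_steps downhill-only moves applied to each replica's
#'   starting coil before the Monte Carlo proper (default 0).
#' @param quench_steps downhill-only moves applied to each cold replica
#'   after the Monte Carlo proper (default 1500); quenched snapshots are
#'   harvested every 50 steps so clusters form around basin floors.
#' @param use_profiles build and apply fragment distance profiles inside
#'   [run_folding()] when a library is supplied (default TRUE).
#' @return a `SimulationConfig`.
#' @export
simulation_config <- function(n_replicas = 8, t_min = 0.15, t_max = 15,
                              steps_per_replica = 5000, swap_interval = 50,
                              snapshot_interval = 250, n_cold = 2,
                              seed = NULL,
                              weights = list(contact = 2, bond = 1,
                                             clash = 1, profile = 0.05),
                              move_probs = c(fragment = 0.5, pivot = 0.25,
                                             crankshaft = 0.25),
                              max_retries = 20,
                              energy_check_interval = 1000,
                              soft_radius = 4.5, use_profiles = TRUE,
                              burn_in = 0.4, greedy_init_steps = 0,
                              quench_steps = 1500) {
  if (n_replicas < 1 || steps_per_replica < 0 || swap_interval < 1 ||
      snapshot_interval < 1 || n_cold < 1) {
    cf_abort("cf_domain_error", "simulation counts must be positive")
  }
  if (!(t_min > 0 && t_max >= t_min)) {
    cf_abort("cf_domain_error", "need 0 < t_min <= t_max")
  }
  ladder <- if (n_replicas == 1) t_min else
    exp(seq(log(t_min), log(t_max), length.out = n_replicas))
  if (n_replicas > 1 && any(diff(ladder) <= 0)) {
    cf_abort("cf_domain_error", "temperature ladder must be increasing")
  }
  structure(list(n_replicas = n_replicas, temperatures = ladder,
                 steps_per_replica = steps_per_replica,
                 swap_interval = swap_interval,
                 snapshot_interval = snapshot_interval,
                 n_cold = min(n_cold, n_replicas), seed = seed,
                 weights = weights, move_probs = move_probs,
                 max_retries = max_retries,
                 energy_check_interval = energy_check_interval,
                 soft_radius = soft_radius, use_profiles = use_profiles,
                 burn_in = burn_in, greedy_init_steps = greedy_init_steps,
                 quench_steps = quench_steps),
            class = "SimulationConfig")
}

#' Total energy of a conformation
#'
#' Weighted sum of the contact-restraint term, a harmonic pseudo-bond term
#' around 3.8 A, a soft-sphere excluded-volume penalty below 3.4 A, and an
#' optional mean distance-profile term.
#'
#' @param conf a `ChainConformation`.
#' @param cs a `ConsensusContactSet` (may be empty).
#' @param profiles optional list of `DistanceProfile`s or a compiled set.
#' @param config a [simulation_config()] (supplies the weights).
#' @param params restraint parameters (default: length-derived d2).
#' @return total energy (scalar).
#' @export
total_energy <- function(conf, cs, profiles = NULL,
                         config = simulation_config(),
                         params = restraint_params(L = conf$n_res)) {
  w <- config$weights
  compiled <- if (is.null(profiles) || is.null(profiles$mat %||% NULL)) {
    if (is.list(profiles) && length(profiles) &&
        inherits(profiles[[1]], "DistanceProfile")) {
      compile_profiles(profiles)
    } else profiles
  } else profiles
  e_contact <- restraint_energy(conf, cs, params)
  b <- bond_lengths(conf$ca)
  e_bond <- sum((b - BOND_IDEAL)^2)
  n <- conf$n_res
  dv <- attr(conf, "dist_ca")       # cached by propose_move when available
  if (is.null(dv)) {
    dv <- as.vector(stats::dist(conf$ca))
    i <- seq_len(n - 1)
    dv[(i - 1) * n - i * (i - 1) / 2 + 1] <- Inf  # bonded neighbours
  }
  # soft-sphere radius ~4.5 A (typical nonbonded Ca-Ca floor); the hard
  # geometric invariant stays at 3.4 A
  soft <- config$soft_radius %||% 4.5
  e_clash <- sum(pmax(0, soft - dv)^2)
  e_profile <- eval_profile_set(compiled, conf$cb)
  w$contact * e_contact + w$bond * e_bond + w$clash * e_clash +
    (w$profile %||% 0) * e_profile
}

# --- move set --------------------------------------------------------------

move_fragment <- function(ca, frags) {
  starts <- which(lengths(frags$fragments) > 0)
  if (length(starts) == 0L) return(NULL)
  p <- sample(starts, 1L)
  fl <- frags$fragments[[p]]
  f <- fl[[sample.int(length(fl), 1L)]]
  len <- nrow(f)
  if (p + len - 1L > nrow(ca) || len < 3L) return(NULL)
  ic <- internal_coords(ca)
  fic <- internal_coords(f)
  idx <- p:(p + len - 1L)
  # splice fragment-internal degrees of freedom only
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (k >= 2 && i >= 2) ic$l[i] <- fic$l[k]
    if (k >= 3 && i >= 3) ic$theta[i] <- fic$theta[k]
    if (k >= 4 && i >= 4) ic$tau[i] <- fic$tau[k]
  }
  rebuild_from(ca, ic, max(2L, p + 1L))
}

move_pivot <- function(ca, angle_sd = 0.4) {
  n <- nrow(ca)
  k <- sample(2:(n - 1), 1L)
  axis <- unitize(stats::rnorm(3))
  ang <- stats::rnorm(1, 0, angle_sd)
  if (abs(ang) < 1e-12) return(ca)
  r <- rotation_matrix(axis, ang)
  tail_idx <- (k + 1):n
  shifted <- sweep(ca[tail_idx, , drop = FALSE], 2, ca[k, ])
  ca[tail_idx, ] <- sweep(shifted %*% t(r), 2, ca[k, ], `+`)
  ca
}

move_crankshaft <- function(ca, angle_sd = 0.6) {
  n <- nrow(ca)
  if (n < 4) return(ca)
  k1 <- sample(1:(n - 3), 1L)
  k2 <- min(n, k1 + sample(3:min(10, n - k1), 1L))
  axis <- ca[k2, ] - ca[k1, ]
  if (vnorm(axis) < 1e-9) return(ca)
  ang <- stats::rnorm(1, 0, angle_sd)
  r <- rotation_matrix(axis, ang)
  idx <- (k1 + 1):(k2 - 1)
  shifted <- sweep(ca[idx, , drop = FALSE], 2, ca[k1, ])
  ca[idx, ] <- sweep(shifted %*% t(r), 2, ca[k1, ], `+`)
  ca
}

#' Propose a Monte Carlo move
#'
#' Applies one of fragment substitution, pivot, or crankshaft (drawn from
#' `config$move_probs`). Proposals violating the bonded-geometry or
#' excluded-volume invariants are resampled up to `config$max_retries`
#' times, after which the identity move is returned. Consumes the global
#' RNG stream (seed it for reproducibility).
#'
#' @param conf a `ChainConformation`.
#' @param frags optional `FragmentLibrary`.
#' @param config a [simulation_config()].
#' @param scale move-size multiplier for the rotation moves; replicas pass
#'   a temperature-dependent value so cold, compact states take smaller
#'   steps.
#' @return a valid `ChainConformation`.
#' @export
propose_move <- function(conf, frags = NULL, config = simulation_config(),
                         scale = 1) {
  probs <- config$move_probs
  if (is.null(frags)) probs["fragment"] <- 0
  if (sum(probs) <= 0) probs <- c(fragment = 0, pivot = 0.5, crankshaft = 0.5)
  probs <- probs / sum(probs)
  n <- conf$n_res
  for (try in seq_len(config$max_retries)) {
    kind <- sample(names(probs), 1L, prob = probs)
    ca_new <- switch(kind,
      fragment = move_fragment(conf$ca, frags),
      pivot = move_pivot(conf$ca, angle_sd = 0.4 * scale),
      crankshaft = move_crankshaft(conf$ca, angle_sd = 0.6 * scale))
    if (is.null(ca_new)) next
    b <- bond_lengths(ca_new)
    if (any(b < BOND_MIN - 1e-9 | b > BOND_MAX + 1e-9)) next
    dv <- as.vector(stats::dist(ca_new))
    i <- seq_len(n - 1)
    dv[(i - 1) * n - i * (i - 1) / 2 + 1] <- Inf
    if (any(dv < CLASH_DIST)) next
    out <- chain_conformation(ca_new, conf$sequence)
    attr(out, "dist_ca") <- dv      # reused by total_energy's clash term
    return(out)
  }
  conf
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-delta_E / T))`. Consumes one
#' uniform variate from the global RNG stream only when `delta_E > 0`.
#'
#' @param delta_E energy change of the proposal.
#' @param temperature replica temperature (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_E, temperature) {
  if (temperature <= 0) cf_abort("cf_domain_error", "temperature must be > 0")
  if (is.nan(delta_E)) return(FALSE)
  if (delta_E <= 0) return(TRUE)
  if (!is.finite(delta_E)) return(FALSE)
  stats::runif(1) < exp(-delta_E / temperature)
}

#' One replica-exchange sweep
#'
#' Proposes swaps between adjacent temperature slots, pairing (1,2), (3,4),
#' ... on even sweeps and (2,3), (4,5), ... on odd sweeps. A swap of the
#' configurations in slots a < b is accepted with probability
#' `min(1, exp((1/T_a - 1/T_b) * (E_a - E_b)))`.
#'
#' @param replicas list of lists with elements `conf`, `energy`.
#' @param temperatures increasing temperature ladder.
#' @param sweep_index integer used to alternate the pairing parity.
#' @return the (possibly swapped) replica list.
#' @export
replica_exchange_sweep <- function(replicas, temperatures, sweep_index = 0L) {
  r <- length(replicas)
  if (r < 2) return(replicas)
  if (any(diff(temperatures) < 0)) {
    cf_abort("cf_domain_error", "temperature ladder must be increasing")
  }
  first <- if (sweep_index %% 2 == 0) 1L else 2L
  a <- first
  while (a + 1 <= r) {
    b <- a + 1L
    ea <- replicas[[a]]$energy; eb <- replicas[[b]]$energy
    logp <- (1 / temperatures[a] - 1 / temperatures[b]) * (ea - eb)
    if (logp >= 0 || stats::runif(1) < exp(logp)) {
      tmp <- replicas[[a]]; replicas[[a]] <- replicas[[b]]; replicas[[b]] <- tmp
    }
    a <- a + 2L
  }
  replicas
}

extended_chain <- function(sequence) {
  n <- nchar(sequence)
  # gentle zigzag keeps the trace non-collinear so Cb placement is stable
  i <- seq_len(n)
  ca <- cbind(3.63 * i, 1.1 * (i %% 2), 0.3 * ((i %/% 2) %% 2))
  chain_conformation(ca, sequence)
}

# Compact self-avoiding random coil: keeps restrained pairs inside the
# gradient region of the contact well (which is flat beyond 80 A).
# Consumes the global RNG stream.
random_coil <- function(sequence, max_restarts = 50) {
  n <- nchar(sequence)
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(0, n, 3)
    ca[2, ] <- c(BOND_IDEAL, 0, 0)
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in 1:30) {
        dir_prev <- unitize(ca[i - 1, ] - ca[i - 2, ])
        ang <- stats::runif(1, 75, 130) * pi / 180
        axis <- unitize(stats::rnorm(3))
        axis <- unitize(axis - sum(axis * dir_prev) * dir_prev)
        dir_new <- as.vector(rotation_matrix(axis, ang) %*% dir_prev)
        # weak bias back toward the centroid keeps the coil compact
        cen <- colMeans(ca[1:(i - 1), , drop = FALSE])
        pull <- unitize(cen - ca[i - 1, ])
        dir_new <- unitize(dir_new + 0.3 * pull)
        cand <- ca[i - 1, ] + BOND_IDEAL * dir_new
        dd <- sqrt(rowSums((ca[1:(i - 2), , drop = FALSE] -
                              matrix(cand, i - 2, 3, byrow = TRUE))^2))
        if (all(dd >= CLASH_DIST + 0.05)) {
          ca[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(chain_conformation(ca, sequence))
  }
  extended_chain(sequence)
}

#' Run a replica-exchange folding simulation
#'
#' Replicas start from perturbed extended chains; decoys are harvested from
#' the `n_cold` coldest slots every `snapshot_interval` steps (and once at
#' step zero). Deterministic for a fixed `config$seed`.
#'
#' @param sequence amino-acid string.
#' @param cs a `ConsensusContactSet` of restraints.
#' @param frags optional `FragmentLibrary`.
#' @param config a [simulation_config()] (its `seed` must be set).
#' @param profiles optional list of `DistanceProfile`s.
#' @return a `DecoyEnsemble`: list with `decoys`, `energies`, `M_tot`,
#'   `log` (per-sweep energy trace) and `bookkeeping_error` (max drift of
#'   the running energy vs. full recomputation).
#' @export
run_folding <- function(sequence, cs, frags = NULL,
                        config = simulation_config(), profiles = NULL) {
  if (is.null(config$seed)) {
    cf_abort("cf_domain_error", "config$seed is mandatory for folding runs")
  }
  with_seed(config$seed, {
    if (is.null(profiles) && !is.null(frags) &&
        isTRUE(config$use_profiles)) {
      profiles <- build_profile_set(frags)
    }
    compiled <- if (!is.null(profiles)) compile_profiles(profiles) else NULL
    params <- restraint_params(L = nchar(sequence))
    energy_of <- function(conf) {
      total_energy(conf, cs, compiled, config, params)
    }
    replicas <- lapply(seq_len(config$n_replicas), function(r) {
      conf <- if (config$steps_per_replica > 0) random_coil(sequence)
              else extended_chain(sequence)
      e <- energy_of(conf)
      if (config$steps_per_replica > 0) {
        for (g in seq_len(config$greedy_init_steps %||% 0)) {
          cand <- propose_move(conf, frags, config)
          e_cand <- energy_of(cand)
          if (e_cand < e) { conf <- cand; e <- e_cand }
        }
      }
      list(conf = conf, energy = e)
    })
    decoys <- list(); energies <- numeric(0)
    harvest <- function(rep) {
      decoys[[length(decoys) + 1L]] <<- rep$conf
      energies[[length(energies) + 1L]] <<- rep$energy
    }
    for (r in seq_len(config$n_cold)) harvest(replicas[[r]])

    n_sweeps <- if (config$swap_interval > 0)
      ceiling(config$steps_per_replica / config$swap_interval) else 0L
    log_rows <- list()
    accepted <- 0L
    bookkeeping_error <- 0
    step_global <- 0L
    if (config$steps_per_replica > 0) {
      for (sweep in seq_len(n_sweeps)) {
        steps <- min(config$swap_interval,
                     config$steps_per_replica - (sweep - 1L) * config$swap_interval)
        for (r in seq_len(config$n_replicas)) {
          rep <- replicas[[r]]
          temp <- config$temperatures[r]
          mscale <- clamp(sqrt(temp / max(config$temperatures)), 0.3, 1)
          for (s in seq_len(steps)) {
            prop <- propose_move(rep$conf, frags, config, scale = mscale)
            e_new <- energy_of(prop)
            if (metropolis_accept(e_new - rep$energy, temp)) {
              rep$conf <- prop
              rep$energy <- rep$energy + (e_new - rep$energy)
              accepted <- accepted + 1L
              if (accepted %% config$energy_check_interval == 0L) {
                drift <- abs(rep$energy - energy_of(rep$conf))
                bookkeeping_error <- max(bookkeeping_error, drift)
              }
            }
            if (r <= config$n_cold) {
              step_this <- (sweep - 1L) * config$swap_interval + s
              if (step_this %% config$snapshot_interval == 0L &&
                  step_this > config$burn_in * config$steps_per_replica) {
                harvest(rep)
              }
            }
          }
          replicas[[r]] <- rep
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(sweep = sweep, replica = r, temperature = temp,
                       energy = rep$energy)
        }
        replicas <- replica_exchange_sweep(replicas, config$temperatures,
                                           sweep_index = sweep)
      }
    }
    if (config$steps_per_replica > 0 && (config$quench_steps %||% 0) > 0) {
      for (r in seq_len(config$n_cold)) {
        rep <- replicas[[r]]
        for (g in seq_len(config$quench_steps)) {
          cand <- propose_move(rep$conf, frags, config, scale = 0.4)
          e_cand <- energy_of(cand)
          if (e_cand < rep$energy) {
            rep$conf <- cand; rep$energy <- e_cand
          }
          if (g %% 50 == 0) harvest(rep)
        }
        replicas[[r]] <- rep
      }
    }
    structure(list(decoys = decoys, energies = energies,
                   M_tot = length(decoys),
                   log = if (length(log_rows)) do.call(rbind, log_rows)
                         else data.frame(),
                   accepted = accepted,
                   bookkeeping_error = bookkeeping_error),
              class = "DecoyEnsemble")
  })
}

#' @export
print.DecoyEnsemble <- function(x, ...) {
  cat(sprintf("DecoyEnsemble: %d decoys (best energy %.2f)\n",
              x$M_tot, if (x$M_tot) min(x$energies) else NA_real_))
  invisible(x)
}
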