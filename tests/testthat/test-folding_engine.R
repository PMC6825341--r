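tiny_system <- function(n = 30, seed = 5) {
  s <- make_toy_structure("helix_bundle", n, seed = seed)
  tc <- true_contacts(s)
  fl <- make_fragment_library(s, per_position = 8, seed = seed + 1)
  list(native = s, cs = tc, frags = fl)
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(n_replicas = 2, steps_per_replica = 120, swap_interval = 30,
         snapshot_interval = 60, burn_in = 0, quench_steps = 0, seed = 99),
    list(...))
  do.call(simulation_config, args)
}

test_that("distance profiles tally fragment distances exactly", {
  sys <- tiny_system()
  pr <- build_distance_profile(sys$frags, 5, 9)
  expect_gt(pr$n_obs, 0)
  # naive per-fragment tally
  manual <- 0
  for (p in seq_along(sys$frags$fragments)) {
    if (p > 5) next
    for (f in sys$frags$fragments[[p]]) {
      if (p + nrow(f) - 1 < 9) next
      manual <- manual + 1
    }
  }
  expect_equal(pr$n_obs, manual)
  expect_equal(sum(pr$counts), pr$n_obs)   # histogram mass = contributors

  # jitter-0 library: profile peaks at the native distance
  fl0 <- make_fragment_library(sys$native, per_position = 10, jitter = 0,
                               seed = 3)
  pr0 <- build_distance_profile(fl0, 5, 9)
  d_native <- sqrt(sum((sys$native$cb[5, ] - sys$native$cb[9, ])^2))
  peak_bin <- which.max(pr0$counts)
  expect_lte(abs((pr0$breaks[peak_bin] + 0.25) - d_native), 0.5)

  # uncovered pair: empty profile contributes zero energy
  pr_far <- build_distance_profile(sys$frags, 1, 30)
  expect_equal(pr_far$n_obs, 0)
  expect_equal(profile_energy(pr_far, 6), 0)
})

test_that("total_energy is the sum of its independently computed terms", {
  sys <- tiny_system()
  cfg <- fast_config()
  dec <- random_decoy(sys$native, sd = 0.8)
  params <- restraint_params(L = dec$n_res)
  profs <- build_profile_set(sys$frags)
  e <- total_energy(dec, sys$cs, profs, cfg, params)

  e_contact <- restraint_energy(dec, sys$cs, params)
  b <- sqrt(rowSums(diff(dec$ca)^2))
  e_bond <- sum((b - 3.8)^2)
  dm <- as.matrix(dist(dec$ca)); diag(dm) <- Inf
  for (i in seq_len(dec$n_res - 1)) { dm[i, i + 1] <- Inf; dm[i + 1, i] <- Inf }
  e_clash <- sum(pmax(0, cfg$soft_radius - dm[upper.tri(dm)])^2)
  e_prof <- sum(vapply(profs, function(pr) {
    d <- sqrt(sum((dec$cb[pr$i, ] - dec$cb[pr$j, ])^2))
    profile_energy(pr, d)
  }, numeric(1)))
  manual <- cfg$weights$contact * e_contact + cfg$weights$bond * e_bond +
    cfg$weights$clash * e_clash + cfg$weights$profile * e_prof
  expect_equal(e, manual, tolerance = 1e-9)
})

test_that("ideal-geometry chain has near-zero generic terms", {
  sys <- tiny_system()
  cfg <- fast_config(weights = list(contact = 0, bond = 1, clash = 1,
                                    profile = 0))
  empty <- structure(list(contacts = data.frame(i = integer(0), j = integer(0),
                                                u = numeric(0),
                                                sep_class = character(0)),
                          L = sys$native$n_res), class = "ConsensusContactSet")
  expect_lt(total_energy(sys$native, empty, NULL, cfg), 2)

  # two Ca at 1 A: positive clash penalty
  ca <- sys$native$ca
  ca[10, ] <- ca[25, ] + c(1, 0, 0)
  squashed <- list(n_res = nrow(ca), ca = ca, cb = ca,
                   sequence = sys$native$sequence)
  class(squashed) <- "ChainConformation"
  expect_gt(total_energy(squashed, empty, NULL, cfg), 5)
})

test_that("propose_move preserves chain geometry and is seeded", {
  sys <- tiny_system()
  cfg <- fast_config()
  set.seed(1)
  conf <- sys$native
  for (k in 1:50) {
    conf <- propose_move(conf, sys$frags, cfg)
    b <- sqrt(rowSums(diff(conf$ca)^2))
    expect_true(all(b >= 3.6 - 1e-9 & b <= 4.0 + 1e-9))
  }
  # same seed, same trajectory
  set.seed(77); c1 <- propose_move(sys$native, sys$frags, cfg)
  set.seed(77); c2 <- propose_move(sys$native, sys$frags, cfg)
  expect_equal(c1$ca, c2$ca)
})

test_that("metropolis_accept implements the standard criterion", {
  expect_true(metropolis_accept(-5, 1))
  expect_true(metropolis_accept(0, 1))
  expect_false(metropolis_accept(Inf, 1))
  expect_error(metropolis_accept(1, 0), class = "cf_domain_error")

  # empirical acceptance at delta = T ln 2 is 1/2
  set.seed(12)
  acc <- mean(replicate(10000, metropolis_accept(log(2) * 2, 2)))
  expect_lt(abs(acc - 0.5), 0.02)
})

test_that("replica exchange matches its closed-form swap probability", {
  # equal energies or equal temperatures: always swap
  reps <- list(list(conf = 1, energy = 3), list(conf = 2, energy = 3))
  out <- replica_exchange_sweep(reps, c(1, 2), 0)
  expect_equal(out[[1]]$conf, 2)

  set.seed(21)
  ta <- 1; tb <- 3; ea <- 2; eb <- -1
  p_theory <- min(1, exp((1 / ta - 1 / tb) * (ea - eb)))
  swaps <- replicate(10000, {
    r <- replica_exchange_sweep(list(list(conf = "a", energy = ea),
                                     list(conf = "b", energy = eb)),
                                c(ta, tb), 0)
    r[[1]]$conf == "b"
  })
  expect_lt(abs(mean(swaps) - p_theory), 0.02)
})

test_that("run_folding is reproducible and honours zero steps", {
  sys <- tiny_system()
  cfg <- fast_config()
  e1 <- run_folding(sys$native$sequence, sys$cs, sys$frags, cfg)
  e2 <- run_folding(sys$native$sequence, sys$cs, sys$frags, cfg)
  expect_equal(e1$energies, e2$energies)
  expect_equal(e1$decoys[[e1$M_tot]]$ca, e2$decoys[[e2$M_tot]]$ca)

  cfg0 <- fast_config(steps_per_replica = 0)
  e0 <- run_folding(sys$native$sequence, sys$cs, sys$frags, cfg0)
  expect_equal(e0$M_tot, cfg0$n_cold)   # initial conformations only

  cfg_ns <- fast_config(); cfg_ns$seed <- NULL
  expect_error(run_folding(sys$native$sequence, sys$cs, sys$frags, cfg_ns),
               class = "cf_domain_error")
})

test_that("harvested decoys satisfy the chain-geometry invariants and the
           running energy matches recomputation", {
  sys <- tiny_system()
  cfg <- fast_config(energy_check_interval = 25)
  ens <- run_folding(sys$native$sequence, sys$cs, sys$frags, cfg)
  expect_lt(ens$bookkeeping_error, 1e-6)
  for (d in ens$decoys) expect_true(validate_geometry(d))
  # stored energies match full recomputation
  profs <- build_profile_set(sys$frags)
  for (k in seq_len(ens$M_tot)) {
    expect_equal(ens$energies[k],
                 total_energy(ens$decoys[[k]], sys$cs, profs, cfg),
                 tolerance = 1e-6)
  }
})

test_that("two-state toy system approaches Boltzmann occupancy", {
  # single particle on a 1D two-level energy ladder sampled with the same
  # metropolis_accept: long-run frequencies must match Boltzmann weights
  set.seed(31)
  temp <- 1.3; e_hi <- 1.1
  state <- 0; n_hi <- 0; n_tot <- 20000
  for (k in seq_len(n_tot)) {
    proposal <- 1 - state
    de <- (proposal - state) * e_hi
    if (metropolis_accept(de, temp)) state <- proposal
    n_hi <- n_hi + state
  }
  p_hi <- exp(-e_hi / temp) / (1 + exp(-e_hi / temp))
  se <- sqrt(p_hi * (1 - p_hi) / n_tot)
  expect_lt(abs(n_hi / n_tot - p_hi), 5 * se)  # allows autocorrelation
})
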