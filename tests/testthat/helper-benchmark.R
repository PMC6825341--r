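# Shared desk-scale benchmark harness for the folding acceptance criteria.
# Settings here are the stated desk-scale world: three 40-60 residue toy
# targets at contact precision 0.8 for fold recovery, and a 30-target
# precision sweep for the C-score calibration property.

# Fold one toy target end-to-end; returns the quantities the acceptance
# criteria are stated in.
fold_toy_target <- function(topology, n_res, seed, precision = 0.8,
                            nf = 100, sim_args = list()) {
  s <- make_toy_structure(topology, n_res, seed = seed)
  tc <- true_contacts(s)
  tiers <- c("very_high", "high", "medium")
  pos <- lapply(seq_along(tiers), function(k) {
    corrupt_contacts(tc, precision, tiers[k], n_res, seed = seed + k,
                     predictor_name = paste0("synth", k))
  })
  cs <- build_consensus(pos, L = n_res, nf = nf)
  fl <- make_fragment_library(s, per_position = 25, seed = seed + 9)
  cfg <- do.call(simulation_config, c(list(seed = seed + 5), sim_args))
  ens <- run_folding(s$sequence, cs, fl, cfg)
  sols <- spicker_cluster(ens)
  top <- sols[[which.max(vapply(sols, `[[`, 0, "M"))]]
  first <- select_first_model(sols, ens)

  lt <- long_range_subset(tc, top = 10 * n_res)$contacts
  d <- sqrt(rowSums((first$cb[lt$i, , drop = FALSE] -
                       first$cb[lt$j, , drop = FALSE])^2))
  true_lr_sat <- if (nrow(lt)) mean(d <= 8) else NA_real_

  baseline <- with_seed(seed + 77, contactfold:::random_coil(s$sequence))

  sr <- suppressWarnings(satisfaction_rate(first, cs))
  dc <- convergence_density(top, ens$M_tot)
  list(native = s, consensus = cs, ensemble = ens, first_model = first,
       true_lr_sat = true_lr_sat,
       tm = tm_score(first, s),
       tm_baseline = tm_score(baseline, s),
       sr = sr, dc = dc, nf = nf,
       c_score = suppressWarnings(c_score(nf, sr, dc)))
}

# The three fold-recovery targets: one per topology, 40-60 residues.
fold_recovery_targets <- function() {
  list(list(topology = "beta_hairpin", n_res = 44),
       list(topology = "helix_bundle", n_res = 48),
       list(topology = "mixed", n_res = 56))
}

# Calibration benchmark design: alignment depth spans the Nf range the
# modelled families cover (~15-736); contact precision grows with ln(Nf)
# plus noise, mirroring the depth -> contact-accuracy premise.
calibration_design <- function(n_targets = 30, seed = 1) {
  with_seed(seed, {
    topo <- rep(c("beta_hairpin", "helix_bundle", "mixed"),
                length.out = n_targets)
    n_res <- rep(c(40, 44, 48), length.out = n_targets)
    lnf <- runif(n_targets, log(15), log(736))
    prec <- 0.25 + 0.6 * (lnf - log(15)) / (log(736) - log(15)) +
      rnorm(n_targets, 0, 0.05)
    data.frame(topology = topo, n_res = n_res, nf = exp(lnf),
               precision = pmin(0.95, pmax(0.2, prec)),
               seed = sample.int(1e6, n_targets))
  })
}

# Reduced-cost simulation settings for the 30-target calibration sweep.
calibration_sim_args <- function() {
  list(n_replicas = 5, steps_per_replica = 2000, snapshot_interval = 200,
       quench_steps = 500, n_cold = 2)
}
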