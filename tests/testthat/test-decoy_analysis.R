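test_that("pairwise_rmsd is superposition-invariant and symmetric", {
  s <- make_toy_structure("mixed", 30, seed = 4)
  expect_equal(pairwise_rmsd(s, s), 0)

  r <- contactfold:::rotation_matrix(c(1, 2, 0.5), 1.1)
  moved <- chain_conformation(sweep(s$ca %*% t(r), 2, c(5, -3, 8), `+`),
                              s$sequence)
  expect_lt(pairwise_rmsd(s, moved), 1e-9)

  set.seed(2)
  a <- random_decoy(s); b <- random_decoy(s)
  expect_equal(pairwise_rmsd(a, b), pairwise_rmsd(b, a))
  expect_error(pairwise_rmsd(s$ca, s$ca[1:10, ]),
               class = "cf_length_mismatch_error")
})

test_that("pairwise_rmsd matches an exhaustive rotation-grid oracle", {
  # tabulated 4-point toy sets: grid over Euler angles, centred
  a <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 1), 4, 3, byrow = TRUE)
  b <- matrix(c(0, 0, 0, 1.1, 0, 0, 1, 1.2, 0, 0, 0.9, 1.1), 4, 3,
              byrow = TRUE)
  grid_rmsd <- function(a, b) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    eval_r <- function(p, q, r) {
      rz1 <- contactfold:::rotation_matrix(c(0, 0, 1), p)
      ry <- contactfold:::rotation_matrix(c(0, 1, 0), q)
      rz2 <- contactfold:::rotation_matrix(c(0, 0, 1), r)
      fit <- bc %*% t(rz1 %*% ry %*% rz2)
      sqrt(mean(rowSums((ac - fit)^2)))
    }
    # coarse Euler-angle grid, then local refinement around the optimum
    best <- c(0, 0, 0); best_v <- Inf; step <- 2 * pi / 24
    for (p in seq(0, 2 * pi, by = step)) {
      for (q in seq(0, pi, by = step)) {
        for (r in seq(0, 2 * pi, by = step)) {
          v <- eval_r(p, q, r)
          if (v < best_v) { best_v <- v; best <- c(p, q, r) }
        }
      }
    }
    for (refine in 1:6) {
      step <- step / 4
      for (p in best[1] + step * (-4:4)) {
        for (q in best[2] + step * (-4:4)) {
          for (r in best[3] + step * (-4:4)) {
            v <- eval_r(p, q, r)
            if (v < best_v) { best_v <- v; best <- c(p, q, r) }
          }
        }
      }
    }
    best_v
  }
  g <- grid_rmsd(a, b)
  expect_equal(pairwise_rmsd(a, b), g, tolerance = 1e-3)
  expect_lte(pairwise_rmsd(a, b), g + 1e-9)  # optimal <= any grid rotation
})

test_that("spicker_cluster handles degenerate and bimodal ensembles", {
  s <- make_toy_structure("helix_bundle", 25, seed = 9)
  same <- replicate(8, s, simplify = FALSE)
  sols <- spicker_cluster(same, cutoff = 3.5)
  expect_length(sols, 1)
  expect_equal(sols[[1]]$M, 8)
  expect_equal(sols[[1]]$mean_rmsd_to_centroid, 0)

  # two tight blobs of 30 and 10 around structurally distinct folds
  # (RMSD is superposition-invariant, so separation must be in shape)
  set.seed(14)
  blob1 <- replicate(30, random_decoy(s, sd = 0.1), simplify = FALSE)
  other <- make_toy_structure("beta_hairpin", 25, seed = 9)
  blob2 <- replicate(10, random_decoy(other, sd = 0.1), simplify = FALSE)
  sols2 <- spicker_cluster(c(blob1, blob2), cutoff = 3.5)
  expect_equal(sols2[[1]]$M, 30)
  expect_equal(sols2[[2]]$M, 10)
  expect_error(spicker_cluster(list()), class = "cf_domain_error")
})

test_that("spicker_cluster at fixed cutoff equals the exhaustive oracle", {
  s <- make_toy_structure("mixed", 24, seed = 3)
  set.seed(8)
  for (rep in 1:10) {
    ens <- replicate(20, random_decoy(s, sd = runif(1, 0.5, 4)),
                     simplify = FALSE)
    dm <- rmsd_matrix(ens)
    cutoff <- runif(1, 2, 8)
    sols <- spicker_cluster(ens, cutoff = cutoff)
    orc <- oracle_cluster(dm, cutoff)
    expect_equal(length(sols), length(orc))
    for (k in seq_along(sols)) {
      expect_equal(sols[[k]]$centroid_index, orc[[k]]$seed)
      expect_equal(sort(sols[[k]]$members), orc[[k]]$members)
    }
  }
})

test_that("cluster memberships are disjoint and bounded", {
  s <- make_toy_structure("helix_bundle", 25, seed = 9)
  set.seed(4)
  ens <- replicate(25, random_decoy(s, sd = 2), simplify = FALSE)
  sols <- spicker_cluster(ens, cutoff = "auto")
  all_members <- unlist(lapply(sols, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)
  expect_lte(length(all_members), 25)
  for (sol in sols) expect_true(sol$centroid_index %in% sol$members)
})

test_that("convergence_density computes Dc with the degenerate guard", {
  sol <- structure(list(members = 1:500, M = 500, centroid_index = 1,
                        mean_rmsd_to_centroid = 4, rmsd_cutoff = 6),
                   class = "ClusterSolution")
  expect_equal(convergence_density(sol, 1000), 0.125)

  sol$mean_rmsd_to_centroid <- 0
  sol$M <- 1000
  expect_equal(convergence_density(sol, 1000), 2)   # <R> floored at 0.5

  # scale consistency: doubling M and M_tot leaves Dc unchanged
  sol$mean_rmsd_to_centroid <- 3; sol$M <- 120
  expect_equal(convergence_density(sol, 400),
               convergence_density(modifyList(sol, list(M = 240)), 800))
  expect_error(convergence_density(sol, 0), class = "cf_domain_error")
})

test_that("select_first_model picks the largest cluster's centroid", {
  s <- make_toy_structure("helix_bundle", 25, seed = 9)
  set.seed(6)
  ens <- replicate(12, random_decoy(s, sd = 1), simplify = FALSE)
  mk <- function(members, centroid) {
    structure(list(members = members, M = length(members),
                   centroid_index = centroid,
                   mean_rmsd_to_centroid = 1, rmsd_cutoff = 4),
              class = "ClusterSolution")
  }
  sols <- list(mk(1:8, 3), mk(9:12, 10))
  expect_equal(select_first_model(sols, ens)$ca, ens[[3]]$ca)
  # order of the solutions list does not matter
  expect_equal(select_first_model(rev(sols), ens)$ca, ens[[3]]$ca)
  expect_error(select_first_model(list(), ens), class = "cf_domain_error")
})

test_that("multi-model PDB round-trips decoy ensembles", {
  s <- make_toy_structure("mixed", 22, seed = 2)
  set.seed(5)
  decoys <- replicate(3, random_decoy(s, sd = 1), simplify = FALSE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(decoys, f)
  back <- read_pdb(f)
  expect_length(back, 3)
  expect_equal(back[[2]]$ca, decoys[[2]]$ca, tolerance = 1e-3)
  expect_equal(back[[1]]$sequence, s$sequence)
})
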