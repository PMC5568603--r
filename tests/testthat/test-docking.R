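# REMC machinery: Metropolis rule, moves, exchanges, placement, and the
# bookkeeping contracts of the trajectory

test_that("the Metropolis rule accepts downhill always and uphill at exp(-dE/T)", {
  set.seed(1)
  expect_true(metropolis_accept(0, 1))
  expect_true(metropolis_accept(-5, 0.3))
  expect_error(metropolis_accept(1, 0), "positive")
  # dE = T ln 2 must be accepted half the time
  T <- 1.7
  acc <- mean(replicate(1e4, metropolis_accept(T * log(2), T)))
  expect_equal(acc, 0.5, tolerance = 0.04)  # ~8 sigma of a fair coin at 1e4
})

test_that("a two-level system equilibrates to the Boltzmann ratio", {
  # single-temperature Metropolis chain on states {0, dE}: occupancy ratio
  # must converge to exp(-dE/T) (detailed-balance check)
  set.seed(42)
  dE <- 1.2; T <- 1.0
  state <- 0L; n1 <- 0L; n_sweep <- 1e5
  for (i in seq_len(n_sweep)) {
    prop_dE <- if (state == 0L) dE else -dE
    if (metropolis_accept(prop_dE, T)) state <- 1L - state
    n1 <- n1 + state
  }
  p1 <- n1 / n_sweep
  want <- exp(-dE / T) / (1 + exp(-dE / T))
  se <- sqrt(want * (1 - want) / n_sweep) * 20  # generous for autocorrelation
  expect_lt(abs(p1 - want), 3 * max(se, 0.01))
})

test_that("placement yields the requested replicas at 20 A, reproducibly", {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  rec <- coarse_grain_chain(toy$receptor)
  cfg <- docking_config(n_replicas = 4L, n_snapshots_per_replica = 1L,
                        seed = 5L)
  states <- place_peptide_replicas(rec, "CILM", cfg)
  expect_length(states, 4L)
  rec_atoms <- slimdock:::all_pseudo_atoms(rec)
  for (st in states) {
    d <- sqrt(slimdock:::min_sq_dist(slimdock:::all_pseudo_atoms(st$peptide),
                                     rec_atoms))
    expect_equal(d, 20, tolerance = 0.1)
    expect_equal(st$energy, total_energy(st, cfg$energy)$total,
                 tolerance = 1e-9)
  }
  again <- place_peptide_replicas(rec, "CILM", cfg)
  expect_identical(lapply(states, `[[`, "peptide"),
                   lapply(again, `[[`, "peptide"))
  # different conformations across replicas
  expect_false(isTRUE(all.equal(states[[1]]$peptide$ca,
                                states[[2]]$peptide$ca)))
})

test_that("zero-amplitude moves propose the identical state", {
  ts <- toy_state()
  cfg <- docking_config(max_trans = 0, max_rot_deg = 0, max_ca = 0,
                        max_crank_deg = 0, max_pivot_deg = 0,
                        max_receptor = 0)
  set.seed(3)
  for (i in 1:20) {
    prop <- mc_move(ts$state, cfg)
    expect_equal(prop$state$peptide$ca, ts$state$peptide$ca, tolerance = 1e-12)
    expect_equal(prop$state$receptor$ca, ts$state$receptor$ca,
                 tolerance = 1e-12)
  }
})

test_that("receptor moves never exceed their amplitude; labels are known", {
  ts <- toy_state()
  cfg <- ts$cfg
  set.seed(9)
  labels <- character(0)
  for (i in 1:300) {
    prop <- mc_move(ts$state, cfg)
    labels <- c(labels, prop$label)
    if (prop$label == "receptor") {
      shift <- prop$state$receptor$ca - ts$state$receptor$ca
      expect_lte(max(sqrt(rowSums(shift^2))), 0.5 + 1e-12)
      expect_length(prop$changed, 1L)
    }
  }
  expect_true(all(labels %in% c("rigid_trans", "rigid_rot", "single_ca",
                                "crankshaft", "pivot", "receptor")))
  expect_gt(length(unique(labels)), 3L)
})

test_that("local moves preserve untouched coordinates and bond lengths where promised", {
  ts <- toy_state()
  set.seed(17)
  for (i in 1:100) {
    prop <- mc_move(ts$state, ts$cfg)
    if (prop$label == "crankshaft") {
      d_old <- sqrt(rowSums(diff(ts$state$peptide$ca)^2))
      d_new <- sqrt(rowSums(diff(prop$state$peptide$ca)^2))
      # a crankshaft rotation about the i..i+2 axis preserves both bonds
      expect_equal(d_new, d_old, tolerance = 1e-9)
    }
    if (prop$label == "single_ca") {
      moved <- which(rowSums(abs(prop$state$peptide$ca -
                                 ts$state$peptide$ca)) > 0)
      expect_lte(length(moved), 1L)
    }
  }
})

test_that("replica exchange swaps configurations correctly", {
  ts <- toy_state(n_replicas = 4L)
  states <- ts$states
  expect_error(replica_exchange_sweep(states[1]), "at least 2")
  # equal temperatures: every proposed swap accepted (dbeta = 0)
  eq <- lapply(states, function(s) { s$temperature <- 1.5; s })
  set.seed(2)
  out <- replica_exchange_sweep(eq, phase = 0L)
  expect_equal(out$accepted, 2L)
  expect_length(out$states, 4L)
  # swapped slots carry the neighbour's configuration
  expect_equal(out$states[[1]]$peptide$ca, eq[[2]]$peptide$ca)
  expect_equal(out$states[[2]]$peptide$ca, eq[[1]]$peptide$ca)
  # cold replica holding the higher energy: dbeta*dE > 0, swap certain;
  # the reverse arrangement is already ordered and must not always swap
  a <- states[[1]]; b <- states[[2]]
  a$temperature <- 1; b$temperature <- 2
  a$energy <- 5; b$energy <- -10
  out2 <- replica_exchange_sweep(list(a, b), phase = 0L)
  expect_equal(out2$accepted, 1L)
  expect_equal(out2$states[[1]]$energy, -10)
  expect_equal(out2$states[[1]]$temperature, 1)  # ladder slot keeps its T
  a$energy <- -10; b$energy <- 5                 # ordered: swap prob e^-7.5
  set.seed(4)
  acc <- replicate(200, replica_exchange_sweep(list(a, b))$accepted)
  expect_lt(mean(acc), 0.05)
})

test_that("a docking run delivers the contracted snapshot grid, reproducibly", {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  cfg <- docking_config(n_replicas = 2L, n_snapshots_per_replica = 5L,
                        seed = 11L)
  traj <- run_docking(toy$receptor, "CILM", cfg)
  expect_length(traj$snapshots, 10L)
  expect_equal(vapply(traj$snapshots, `[[`, 0L, "replica"),
               rep(1:2, times = 5L))
  traj2 <- run_docking(toy$receptor, "CILM", cfg)
  expect_identical(traj$snapshots, traj2$snapshots)
  cfg2 <- docking_config(n_replicas = 2L, n_snapshots_per_replica = 5L,
                         seed = 12L)
  expect_false(identical(run_docking(toy$receptor, "CILM", cfg2)$snapshots,
                         traj$snapshots))
})

test_that("incrementally tracked energies match from-scratch recomputation", {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  # ~1.3e3 attempted moves per replica at default cadence
  cfg <- docking_config(n_replicas = 2L, n_snapshots_per_replica = 65L,
                        seed = 23L)
  traj <- run_docking(toy$receptor, "CILMFW", cfg)
  model <- prepare_energy(cfg$energy, traj$receptor0)
  for (i in seq(1, length(traj$snapshots), by = 13)) {
    st <- snapshot_state(traj, i)
    expect_equal(traj$snapshots[[i]]$energy, total_energy(st, model)$total,
                 tolerance = 1e-6)
  }
})

test_that("a trajectory survives the save/load round trip", {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  cfg <- docking_config(n_replicas = 2L, n_snapshots_per_replica = 4L,
                        seed = 31L)
  traj <- run_docking(toy$receptor, "CILM", cfg)
  dir <- withr::local_tempdir()
  save_trajectory(traj, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "meta.json", "snapshots.tsv", "coords.tsv", "receptor0.json",
    "models.pdb")))))
  back <- load_trajectory(dir)
  expect_equal(length(back$snapshots), length(traj$snapshots))
  expect_equal(back$snapshots[[5]]$pep_ca, traj$snapshots[[5]]$pep_ca,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$snapshots[[5]]$energy, traj$snapshots[[5]]$energy,
               tolerance = 1e-8)
  expect_equal(back$receptor0$ca, traj$receptor0$ca, tolerance = 1e-8)
  expect_equal(back$digest, traj$digest)
})
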