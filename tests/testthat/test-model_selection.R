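# energy filtering, L-RMSD, k-medoids clustering and density ranking

# a hand-made Trajectory with prescribed energies and rigid receptor
fake_trajectory <- function(energies_by_replica, n_res = 4L, seed = 1L) {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  rec0 <- coarse_grain_chain(toy$receptor)
  snapshots <- list()
  set.seed(seed)
  for (r in seq_along(energies_by_replica)) {
    for (e in energies_by_replica[[r]]) {
      pep <- cbind((seq_len(n_res) - 1) * 3.8 + rnorm(n_res, sd = 0.1),
                   rnorm(n_res, sd = 0.1), rnorm(n_res, sd = 0.1))
      snapshots[[length(snapshots) + 1L]] <- list(
        replica = r, sweep = length(snapshots), temperature = 1,
        energy = e, terms = NULL, pep_ca = pep, rec_ca = rec0$ca)
    }
  }
  traj <- list(snapshots = snapshots,
               sequence = paste(rep("A", n_res), collapse = ""),
               receptor0 = rec0, config = NULL, seed = seed, digest = "x")
  class(traj) <- "Trajectory"
  traj
}

test_that("the energy filter keeps the lowest states per replica, ties by index", {
  traj <- fake_trajectory(list(c(5, 1, 3, 1, 9), c(0, 7, 7, 2, 4)))
  ps <- select_lowest_energy(traj, 3L)
  expect_length(ps$poses, 6L)
  got <- vapply(ps$poses, `[[`, 0L, "snapshot")
  # replica 1 energies 5,1,3,1,9 -> snapshots 2,4 (both 1) then 3
  expect_equal(got[1:3], c(2L, 4L, 3L))
  # replica 2 energies 0,7,7,2,4 -> snapshots 6,9,10
  expect_equal(got[4:6], c(6L, 9L, 10L))
  # brute-force oracle: full sort per replica
  e <- vapply(traj$snapshots, `[[`, 0, "energy")
  r <- vapply(traj$snapshots, `[[`, 0L, "replica")
  want <- unlist(lapply(1:2, function(k) {
    idx <- which(r == k)
    idx[order(e[idx], idx)][1:3]
  }))
  expect_equal(got, want)
  # identity selection when per_replica equals everything available
  expect_length(select_lowest_energy(traj, 5L)$poses, 10L)
  expect_error(select_lowest_energy(traj, 6L), "exceeds")
})

test_that("selection aligns each snapshot's receptor onto the start", {
  traj <- fake_trajectory(list(c(1, 2)))
  # rotate snapshot 2's receptor and peptide rigidly: after realignment the
  # peptide must come back to its unrotated position
  rot <- slimdock:::rotation_about_axis(c(0, 0, 1), pi / 2)
  shift <- c(3, -2, 7)
  sn <- traj$snapshots[[2]]
  pep0 <- sn$pep_ca
  traj$snapshots[[2]]$rec_ca <- sn$rec_ca %*% t(rot) +
    rep(shift, each = nrow(sn$rec_ca))
  traj$snapshots[[2]]$pep_ca <- sn$pep_ca %*% t(rot) +
    rep(shift, each = nrow(sn$pep_ca))
  ps <- select_lowest_energy(traj, 2L)
  expect_equal(ps$poses[[2]]$pep_ca, pep0, tolerance = 1e-8)
  # hand-rolled oracle: Kabsch on receptor, then plain CA RMS on peptide
  fit <- kabsch_superpose(traj$snapshots[[2]]$rec_ca, traj$receptor0$ca)
  back <- traj$snapshots[[2]]$pep_ca %*% t(fit$rotation) +
    rep(fit$translation, each = nrow(pep0))
  expect_equal(lrmsd(ps$poses[[1]], ps$poses[[2]]),
               sqrt(mean(rowSums((ps$poses[[1]]$pep_ca - back)^2))))
})

test_that("lrmsd is a pseudo-metric and sees pure translations exactly", {
  a <- matrix(rnorm(24), 8, 3)
  expect_equal(lrmsd(a, a), 0)
  b <- a + rep(c(2, 0, 0), each = 8)
  expect_equal(lrmsd(a, b), 2)
  expect_error(lrmsd(a, b[1:4, ]), "length mismatch")
  set.seed(5)
  for (i in 1:20) {
    x <- matrix(rnorm(24), 8, 3); y <- matrix(rnorm(24), 8, 3)
    z <- matrix(rnorm(24), 8, 3)
    expect_equal(lrmsd(x, y), lrmsd(y, x))
    expect_gte(lrmsd(x, y), 0)
    expect_lte(lrmsd(x, z), lrmsd(x, y) + lrmsd(y, z) + 1e-12)
  }
})

test_that("the pose distance matrix equals pairwise lrmsd", {
  poses <- make_planted_poses(m = 2L, per_basin = 5L, seed = 3L)
  D <- pose_distance_matrix(poses)
  for (i in c(1, 4, 9)) {
    for (j in c(2, 7, 10)) {
      expect_equal(D[i, j], lrmsd(poses$poses[[i]], poses$poses[[j]]))
    }
  }
})

test_that("k-medoids recovers planted basins and matches brute force when exact", {
  poses <- make_planted_poses(m = 3L, per_basin = 12L, seed = 9L)
  cl <- kmedoids_cluster(poses, 3L, seed = 1L)
  # perfect recovery: every cluster is one basin
  got <- integer(length(poses$labels))
  for (c in seq_along(cl)) got[cl[[c]]$members] <- c
  expect_equal(length(unique(paste(got, poses$labels))), 3L)

  # Rand index > 0.95 against the planted labels
  n <- length(got)
  same_got <- outer(got, got, "==")
  same_true <- outer(poses$labels, poses$labels, "==")
  rand <- (sum(same_got == same_true) - n) / (n * (n - 1))
  expect_gt(rand, 0.95)

  # two well-separated bundles of 3: exhaustive medoid-pair search oracle
  small <- make_planted_poses(m = 2L, per_basin = 3L, seed = 4L)
  D <- pose_distance_matrix(small)
  cl2 <- kmedoids_cluster(small, 2L, seed = 2L)
  cost <- slimdock:::clustering_cost(D, cl2)
  best <- Inf
  for (i in 1:5) for (j in (i + 1):6) {
    assign_cost <- sum(pmin(D[, i], D[, j]))
    best <- min(best, assign_cost)
  }
  expect_equal(cost, best)
  expect_setequal(cl2[[1]]$members, which(small$labels ==
                                            small$labels[cl2[[1]]$medoid]))
})

test_that("k-medoids is deterministic, guards k, and allows k = n", {
  poses <- make_planted_poses(m = 2L, per_basin = 4L, seed = 6L)
  a <- kmedoids_cluster(poses, 3L, seed = 7L)
  b <- kmedoids_cluster(poses, 3L, seed = 7L)
  expect_identical(lapply(a, `[[`, "members"), lapply(b, `[[`, "members"))
  expect_error(kmedoids_cluster(poses, 9L, seed = 1L), "exceeds")
  expect_error(kmedoids_cluster(poses, 0L, seed = 1L), ">= 1")
  singletons <- kmedoids_cluster(poses, 8L, seed = 1L)
  expect_equal(slimdock:::clustering_cost(pose_distance_matrix(poses),
                                          singletons), 0)
  expect_true(all(vapply(singletons, `[[`, 0, "size") == 1L))
  # every cluster nonempty and the medoid belongs to its cluster
  for (cl in a) {
    expect_gte(cl$size, 1L)
    expect_true(cl$medoid %in% cl$members)
  }
})

test_that("our k-medoids cost is no worse than PAM's on a small instance", {
  poses <- make_planted_poses(m = 3L, per_basin = 6L, spread = 3,
                              separation = 12, seed = 13L)
  D <- pose_distance_matrix(poses)
  ours <- min(vapply(1:5, function(s)
    slimdock:::clustering_cost(D, kmedoids_cluster(poses, 3L, seed = s)), 0))
  pam_fit <- cluster::pam(stats::as.dist(D), k = 3L, diss = TRUE)
  pam_cost <- sum(vapply(seq_len(nrow(D)), function(i)
    min(D[i, pam_fit$id.med]), 0))
  expect_lte(ours, pam_cost + 1e-8)
})

test_that("density ranking follows members / mean pairwise distance", {
  # two 5-member clusters of collinear poses: spacing s along x makes the
  # mean pairwise L-RMSD = 2s, so 0.5 A spacing gives 1 A and 1.0 gives 2 A
  mkp <- function(x0, s) lapply(0:4, function(k) {
    m <- matrix(0, 4, 3); m[, 1] <- x0 + k * s; m
  })
  all_ca <- c(mkp(0, 0.5), mkp(50, 1.0))
  poses <- list(poses = lapply(seq_along(all_ca), function(i)
    list(snapshot = i, replica = 1L, energy = -i, pep_ca = all_ca[[i]])),
    coords = do.call(rbind, lapply(all_ca, function(m) as.vector(t(m)))),
    n_res = 4L, sequence = "AAAA", receptor0 = NULL)
  class(poses) <- "PoseSet"
  cl <- kmedoids_cluster(poses, 2L, seed = 1L)
  rk <- rank_and_represent(cl, poses, 2L)
  expect_equal(rk$ranking$density, c(5 / 1, 5 / 2), tolerance = 1e-9)
  expect_equal(rk$ranking$size, c(5L, 5L))
  # permutation invariance of the ranking
  rk2 <- rank_and_represent(rev(cl), poses, 2L)
  expect_equal(rk2$ranking$density, rk$ranking$density)
  expect_equal(rk2$ranking$snapshot, rk$ranking$snapshot)
  # one cluster yields one model regardless of k_out
  one <- kmedoids_cluster(poses, 1L, seed = 1L)
  expect_equal(nrow(rank_and_represent(one, poses, 10L)$ranking), 1L)
  # singletons rank above everything with infinite density
  sing <- kmedoids_cluster(poses, 10L, seed = 1L)
  rks <- rank_and_represent(sing, poses, 10L)
  expect_true(all(is.infinite(rks$ranking$density)))
})

test_that("ranked models write out as PDB files plus a ranking table", {
  poses <- make_planted_poses(m = 2L, per_basin = 5L, seed = 21L)
  cl <- kmedoids_cluster(poses, 2L, seed = 1L)
  rk <- rank_and_represent(cl, poses, 2L)
  dir <- withr::local_tempdir()
  write_models(rk, dir)
  expect_true(all(file.exists(file.path(dir, c("model_01.pdb", "model_02.pdb",
                                               "ranking.tsv")))))
  tab <- read.delim(file.path(dir, "ranking.tsv"))
  expect_equal(nrow(tab), 2L)
  m1 <- read_pdb(file.path(dir, "model_01.pdb"))[[1]]
  expect_equal(n_residues(m1), 8L)
})
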