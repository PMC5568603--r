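# Pose filtering, clustering and ranking: keep the lowest-energy snapshots
# of each replica, align every snapshot's receptor onto the starting
# receptor, cluster the peptide poses with k-medoids under L-RMSD, rank
# clusters by density (members / mean pairwise L-RMSD) and emit the top
# medoids as representative models.

#' Select the lowest-energy poses of each replica
#'
#' Takes the `per_replica` lowest-energy snapshots from every replica
#' (default 100 x 10 = 1000 poses), ties broken by snapshot index, and
#' aligns each snapshot's receptor onto the starting receptor by
#' least-squares CA superposition so that peptide poses live in a common
#' receptor frame.
#'
#' @param trajectory a `Trajectory` from [run_docking()].
#' @param per_replica poses to keep per replica.
#' @return object of class `PoseSet`: per-pose snapshot index, replica,
#'   energy and receptor-frame-aligned peptide CA coordinates.
#' @export
select_lowest_energy <- function(trajectory, per_replica = 100L) {
  sn <- trajectory$snapshots
  reps <- vapply(sn, `[[`, 0L, "replica")
  energies <- vapply(sn, `[[`, 0, "energy")
  picked <- integer(0)
  for (r in sort(unique(reps))) {
    idx <- which(reps == r)
    if (per_replica > length(idx)) {
      stop("per_replica = ", per_replica, " exceeds the ", length(idx),
           " snapshots of replica ", r)
    }
    ord <- idx[order(energies[idx], idx)]
    picked <- c(picked, ord[seq_len(per_replica)])
  }
  ref_ca <- trajectory$receptor0$ca
  n_res <- nchar(trajectory$sequence)
  X <- matrix(NA_real_, length(picked), 3L * n_res)
  poses <- vector("list", length(picked))
  for (p in seq_along(picked)) {
    k <- picked[p]
    fit <- kabsch_superpose(sn[[k]]$rec_ca, ref_ca)
    pep <- sn[[k]]$pep_ca %*% t(fit$rotation) +
      rep(fit$translation, each = n_res)
    poses[[p]] <- list(snapshot = k, replica = reps[k],
                       energy = energies[k], pep_ca = pep)
    X[p, ] <- as.vector(t(pep))
  }
  out <- list(poses = poses, coords = X, n_res = n_res,
              sequence = trajectory$sequence,
              receptor0 = trajectory$receptor0)
  class(out) <- "PoseSet"
  out
}

#' @export
print.PoseSet <- function(x, ...) {
  cat(sprintf("<PoseSet: %d poses of a %d-residue peptide>\n",
              length(x$poses), x$n_res))
  invisible(x)
}

#' Ligand RMSD between two receptor-aligned poses
#'
#' Root-mean-square deviation over peptide CA atoms, with no further
#' fitting of the peptide itself: the receptor superposition applied when
#' the poses were extracted is the only alignment. The clustering distance.
#'
#' @param pose_a,pose_b n x 3 peptide CA matrices (or pose entries of a
#'   `PoseSet`).
#' @return distance in Angstrom.
#' @export
lrmsd <- function(pose_a, pose_b) {
  a <- if (is.list(pose_a)) pose_a$pep_ca else pose_a
  b <- if (is.list(pose_b)) pose_b$pep_ca else pose_b
  if (!all(dim(a) == dim(b))) stop("peptide length mismatch")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Pairwise L-RMSD matrix of a pose set
#'
#' Because poses share a receptor frame and no per-pair fitting is done,
#' the L-RMSD is the Euclidean distance between flattened coordinate rows
#' divided by sqrt(n); the full matrix comes from a single [stats::dist()]
#' call.
#'
#' @param poses a `PoseSet`.
#' @return symmetric numeric matrix (Angstrom).
#' @export
pose_distance_matrix <- function(poses) {
  as.matrix(stats::dist(poses$coords)) / sqrt(poses$n_res)
}

#' k-medoids clustering of poses under L-RMSD
#'
#' Partitions the poses into `k` clusters on the precomputed L-RMSD matrix:
#' k-means++-style seeded initialization of the medoids, then alternating
#' assignment (nearest medoid, ties to the lower index) and medoid update
#' (the member minimizing total within-cluster distance) until the medoid
#' set is stable, to a local optimum of the total distance-to-medoid cost.
#' Deterministic given the seed; empty clusters cannot arise because a
#' medoid is always its own nearest medoid.
#'
#' @param poses a `PoseSet`, or a symmetric distance matrix.
#' @param k number of clusters, `1 <= k <=` number of poses.
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap.
#' @param singleton_density density assigned to single-member clusters,
#'   which have no pairwise distances; the default `Inf` ranks them above
#'   every multi-member cluster, a large finite cap demotes them below any
#'   cluster denser than the cap.
#' @return list of clusters, each of class `Cluster`: `members` (pose
#'   indices), `medoid` (pose index), `size`, `mean_lrmsd` (mean pairwise
#'   distance among members, NA for singletons), `density` (`size /
#'   mean_lrmsd`, `singleton_density` for singletons) and `medoid_energy`
#'   (NA when clustering a bare matrix).
#' @export
kmedoids_cluster <- function(poses, k, seed = 1L, max_iter = 100L,
                             singleton_density = Inf) {
  D <- if (inherits(poses, "PoseSet")) pose_distance_matrix(poses) else as.matrix(poses)
  n <- nrow(D)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of poses (", n, ")")
  medoids <- with_seed(seed, kpp_init(D, k))
  assign_to <- function(med) {
    # nearest medoid, ties to the medoid appearing first in `med`
    max.col(-D[, med, drop = FALSE], ties.method = "first")
  }
  cl <- assign_to(medoids)
  for (it in seq_len(max_iter)) {
    new_med <- medoids
    for (c in seq_len(k)) {
      members <- which(cl == c)
      sub <- D[members, members, drop = FALSE]
      new_med[c] <- members[which.min(colSums(sub))]
    }
    new_cl <- assign_to(new_med)
    if (identical(sort(new_med), sort(medoids)) && identical(new_cl, cl)) break
    medoids <- new_med
    cl <- new_cl
  }
  energies <- if (inherits(poses, "PoseSet")) {
    vapply(poses$poses, `[[`, 0, "energy")
  } else rep(NA_real_, n)
  lapply(seq_len(k), function(c) {
    members <- which(cl == c)
    m <- length(members)
    mean_d <- if (m > 1L) {
      sub <- D[members, members, drop = FALSE]
      sum(sub[upper.tri(sub)]) / (m * (m - 1L) / 2L)
    } else NA_real_
    cluster <- list(members = members, medoid = medoids[c], size = m,
                    mean_lrmsd = mean_d,
                    density = if (m > 1L) m / mean_d else singleton_density,
                    medoid_energy = energies[medoids[c]])
    class(cluster) <- "Cluster"
    cluster
  })
}

# k-means++-style seeding on a distance matrix: first medoid uniform, each
# next with probability proportional to squared distance to the closest
# chosen medoid
kpp_init <- function(D, k) {
  n <- nrow(D)
  medoids <- sample.int(n, 1L)
  while (length(medoids) < k) {
    d2 <- apply(D[, medoids, drop = FALSE], 1, min)^2
    d2[medoids] <- 0
    if (sum(d2) <= 0) {
      cand <- setdiff(seq_len(n), medoids)
      medoids <- c(medoids, cand[sample.int(length(cand), 1L)])
    } else {
      medoids <- c(medoids, sample.int(n, 1L, prob = d2))
    }
  }
  medoids
}

# total within-cluster distance-to-medoid cost of a clustering
clustering_cost <- function(D, clusters) {
  sum(vapply(clusters, function(cl) sum(D[cl$members, cl$medoid]), 0))
}

#' Rank clusters by density and return representative models
#'
#' Clusters are ordered by non-increasing density (members divided by mean
#' pairwise L-RMSD; singletons rank highest with infinite density), ties
#' broken by larger membership and then lower medoid energy; the medoids of
#' the first `k_out` clusters are the representative models.
#'
#' @param clusters list of `Cluster` from [kmedoids_cluster()].
#' @param poses the `PoseSet` that was clustered (supplies medoid poses).
#' @param k_out maximum number of representatives (default 10).
#' @return object of class `RankedModels`: data frame `ranking` (rank,
#'   cluster size, density, medoid energy, snapshot id) and list `models`
#'   of medoid poses.
#' @export
rank_and_represent <- function(clusters, poses = NULL, k_out = 10L) {
  if (length(clusters) == 0L) stop("no clusters to rank")
  dens <- vapply(clusters, `[[`, 0, "density")
  size <- vapply(clusters, `[[`, 0, "size")
  energy <- vapply(clusters, `[[`, 0, "medoid_energy")
  ord <- order(-dens, -size, energy)
  take <- ord[seq_len(min(k_out, length(clusters)))]
  models <- NULL
  snapshot <- rep(NA_integer_, length(take))
  if (!is.null(poses)) {
    models <- lapply(take, function(c) poses$poses[[clusters[[c]]$medoid]])
    snapshot <- vapply(models, `[[`, 0L, "snapshot")
  }
  ranking <- data.frame(rank = seq_along(take),
                        cluster = take,
                        size = size[take],
                        density = dens[take],
                        medoid_energy = energy[take],
                        snapshot = snapshot)
  out <- list(ranking = ranking, models = models, clusters = clusters[take],
              sequence = if (!is.null(poses)) poses$sequence else NULL)
  class(out) <- "RankedModels"
  out
}

#' @export
print.RankedModels <- function(x, ...) {
  cat(sprintf("<RankedModels: %d representative models>\n", nrow(x$ranking)))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Peptide CoarseChain of a ranked model
#'
#' @param ranked a `RankedModels` built from a `PoseSet`.
#' @param rank which representative (default 1).
#' @return a `CoarseChain` of the medoid pose (sites re-derived from the
#'   CA trace).
#' @export
ranked_model_chain <- function(ranked, rank = 1L) {
  if (is.null(ranked$models)) stop("RankedModels was built without a PoseSet")
  if (rank < 1L || rank > length(ranked$models)) {
    stop("rank out of range: ", rank)
  }
  pose <- ranked$models[[rank]]
  seq <- strsplit(ranked$sequence, "")[[1]]
  geo <- derive_from_trace(seq, pose$pep_ca)
  new_coarse_chain("P", seq, pose$pep_ca, geo$cb, geo$sc, geo$pb,
                   seq_along(seq), rep("", length(seq)),
                   origin = "peptide", from = "trace")
}

#' Write ranked models and the ranking table to a directory
#'
#' Emits `model_01.pdb`, `model_02.pdb`, ... (coarse backbone PDB of each
#' representative peptide pose) and `ranking.tsv`.
#'
#' @param ranked a `RankedModels` built from a `PoseSet`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_models <- function(ranked, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(nrow(ranked$ranking))) {
    export_backbone(ranked_model_chain(ranked, r),
                    file.path(dir, sprintf("model_%02d.pdb", r)))
  }
  utils::write.table(ranked$ranking, file.path(dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
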