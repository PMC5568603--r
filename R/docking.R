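# Replica Exchange Monte Carlo docking of a fully flexible coarse-grained
# peptide to a distance-restrained receptor. One root seed feeds one
# L'Ecuyer-CMRG stream per replica (plus one for the exchange moves), so a
# replica's trajectory does not depend on how many other replicas run.

#' Docking run configuration
#'
#' Defaults follow the protocol: 10 replicas, 1000 snapshots per replica
#' (10,000 models in total), peptide placement 20 A from the receptor
#' surface. The Monte Carlo schedule itself (sweeps between snapshots,
#' temperature ladder, exchange cadence, move amplitudes) is this package's
#' own configuration.
#'
#' @param n_replicas number of REMC replicas.
#' @param n_snapshots_per_replica snapshots collected per replica.
#' @param sweeps_between_snapshots MC sweeps between consecutive snapshots.
#' @param exchange_interval sweeps between replica-exchange attempts.
#' @param t_min,t_max dimensionless MC temperature ladder bounds (geometric
#'   ladder across replicas).
#' @param placement_distance initial minimum peptide-receptor pseudo-atom
#'   distance (A).
#' @param placement_tolerance placement bisection tolerance (A).
#' @param seed integer root random seed.
#' @param move_weights named weights of the move set (rigid_trans,
#'   rigid_rot, single_ca, crankshaft, pivot, receptor).
#' @param max_trans rigid translation amplitude (A).
#' @param max_rot_deg rigid rotation amplitude (degrees).
#' @param max_ca single-residue CA displacement (A).
#' @param max_crank_deg,max_pivot_deg crankshaft / end-pivot amplitude (degrees).
#' @param max_receptor receptor single-residue CA displacement (A).
#' @param receptor_flexible allow small receptor CA moves.
#' @param energy an [energy_model()].
#' @return object of class `DockingConfig`.
#' @export
docking_config <- function(n_replicas = 10L,
                           n_snapshots_per_replica = 1000L,
                           sweeps_between_snapshots = 2L,
                           exchange_interval = 10L,
                           t_min = 1.0, t_max = 3.0,
                           placement_distance = 20,
                           placement_tolerance = 0.1,
                           seed = 1L,
                           move_weights = c(rigid_trans = 0.15,
                                            rigid_rot = 0.15,
                                            single_ca = 0.35,
                                            crankshaft = 0.15,
                                            pivot = 0.10,
                                            receptor = 0.10),
                           max_trans = 2.0, max_rot_deg = 30,
                           max_ca = 1.0, max_crank_deg = 60,
                           max_pivot_deg = 60, max_receptor = 0.5,
                           receptor_flexible = TRUE,
                           energy = energy_model()) {
  stopifnot(n_replicas >= 1L, n_snapshots_per_replica >= 1L,
            sweeps_between_snapshots >= 1L, exchange_interval >= 1L,
            t_min > 0, t_max >= t_min, placement_distance > 0)
  cfg <- list(n_replicas = as.integer(n_replicas),
              n_snapshots_per_replica = as.integer(n_snapshots_per_replica),
              sweeps_between_snapshots = as.integer(sweeps_between_snapshots),
              exchange_interval = as.integer(exchange_interval),
              t_min = t_min, t_max = t_max,
              placement_distance = placement_distance,
              placement_tolerance = placement_tolerance,
              seed = as.integer(seed),
              move_weights = move_weights,
              max_trans = max_trans, max_rot_deg = max_rot_deg,
              max_ca = max_ca, max_crank_deg = max_crank_deg,
              max_pivot_deg = max_pivot_deg, max_receptor = max_receptor,
              receptor_flexible = receptor_flexible,
              energy = energy)
  cfg$temperatures <- temperature_ladder(cfg)
  class(cfg) <- "DockingConfig"
  cfg
}

temperature_ladder <- function(cfg) {
  n <- cfg$n_replicas
  if (n == 1L) return(cfg$t_min)
  exp(seq(log(cfg$t_min), log(cfg$t_max), length.out = n))
}

#' Metropolis acceptance rule
#'
#' Accept if the energy does not increase, otherwise with probability
#' `exp(-dE / temperature)`.
#'
#' @param dE energy change of the proposed move.
#' @param temperature dimensionless MC temperature, > 0.
#' @return logical.
#' @export
metropolis_accept <- function(dE, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  dE <= 0 || stats::runif(1) < exp(-dE / temperature)
}

# ---- RNG streams --------------------------------------------------------

make_streams <- function(seed, n) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

use_stream <- function(s) {
  assign(".Random.seed", s, envir = globalenv())
}

current_stream <- function() get(".Random.seed", envir = globalenv())

# ---- placement ----------------------------------------------------------

all_pseudo_atoms <- function(cc) {
  m <- rbind(cc$ca, cc$cb, cc$sc, cc$pb)
  m[!is.na(m[, 1]), , drop = FALSE]
}

# rigidly place a peptide so its minimum pseudo-atom distance to the
# receptor equals `dist`, along direction u from the receptor centroid
place_at_distance <- function(pep, rec_atoms, u, dist, tol = 0.1) {
  pep_atoms <- all_pseudo_atoms(pep)
  cen_rec <- colMeans(rec_atoms)
  cen_pep <- colMeans(pep_atoms)
  mind <- function(t) {
    shift <- cen_rec + t * u - cen_pep
    sqrt(min_sq_dist(pep_atoms + rep(shift, each = nrow(pep_atoms)),
                     rec_atoms)) - dist
  }
  t_lo <- 0
  t_hi <- max(sqrt(rowSums((rec_atoms -
                            rep(cen_rec, each = nrow(rec_atoms)))^2))) +
    max(sqrt(rowSums((pep_atoms - rep(cen_pep, each = nrow(pep_atoms)))^2))) +
    dist + 5
  if (mind(t_lo) > 0) t_lo <- -t_hi   # pathological: already far at centroid
  for (it in 1:100) {
    t_mid <- (t_lo + t_hi) / 2
    if (mind(t_mid) > 0) t_hi <- t_mid else t_lo <- t_mid
    if (abs(mind(t_mid)) < tol / 2) break
  }
  shift <- cen_rec + t_mid * u - cen_pep
  for (f in c("ca", "cb", "sc", "pb")) {
    pep[[f]] <- pep[[f]] + rep(shift, each = nrow(pep[[f]]))
  }
  pep
}

rigid_rotate_chain <- function(pep, rot, center) {
  for (f in c("ca", "cb", "sc", "pb")) {
    pep[[f]] <- sweep(pep[[f]], 2, center) %*% t(rot) +
      rep(center, each = nrow(pep[[f]]))
  }
  pep
}

new_replica_state <- function(replica, temperature, peptide, receptor,
                              energy = NA_real_, terms = NULL) {
  x <- list(replica = replica, temperature = temperature, peptide = peptide,
            receptor = receptor, energy = energy, terms = terms)
  class(x) <- "ReplicaState"
  x
}

#' Place peptide replicas around the receptor
#'
#' Builds one fresh random coarse-grained conformation per replica, applies
#' a random orientation, and translates it along a direction drawn
#' uniformly on the sphere until its minimum pseudo-atom distance to the
#' receptor equals the placement distance (default 20 A, within 0.1 A).
#' Fully reproducible from the config seed.
#'
#' @param receptor receptor `ChainStructure` or `CoarseChain`.
#' @param sequence one-letter peptide sequence.
#' @param config a [docking_config()].
#' @return list of `ReplicaState` (length `n_replicas`), energies evaluated
#'   under the config's energy model prepared on this receptor.
#' @export
place_peptide_replicas <- function(receptor, sequence, config = docking_config()) {
  setup <- placement_setup(receptor, sequence, config)
  setup$states
}

placement_setup <- function(receptor, sequence, config) {
  rec <- if (inherits(receptor, "CoarseChain")) receptor
         else coarse_grain_chain(receptor, origin = "receptor")
  model <- prepare_energy(config$energy, rec)
  streams <- make_streams(config$seed, config$n_replicas + 1L)
  rec_atoms <- all_pseudo_atoms(rec)
  temps <- config$temperatures
  states <- vector("list", config$n_replicas)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  for (r in seq_len(config$n_replicas)) {
    use_stream(streams[[r]])
    child_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    pep <- random_peptide_conformation(sequence, child_seed)
    rot <- rotation_about_axis(random_unit_vector(),
                               stats::runif(1, 0, 2 * pi))
    pep <- rigid_rotate_chain(pep, rot, colMeans(pep$ca))
    u <- random_unit_vector()
    pep <- place_at_distance(pep, rec_atoms, u, config$placement_distance,
                             config$placement_tolerance)
    e <- full_energy(chain_view(pep), chain_view(rec), model)
    states[[r]] <- new_replica_state(r, temps[r], pep, rec,
                                     e$total, e$terms)
    streams[[r]] <- current_stream()
  }
  list(states = states, streams = streams, rec = rec, model = model)
}

# ---- move set -----------------------------------------------------------

# engine-internal peptide representation: CA trace + derived sites
pep_engine_state <- function(pep) {
  v <- chain_view(pep)
  v$sc_len <- unname(SC_DISTANCE[ifelse(pep$seq %in% names(SC_DISTANCE),
                                        pep$seq, "X")])
  v$seq <- pep$seq
  v
}

rederive_sites <- function(v, J = NULL) {
  if (is.null(J)) {
    dir <- trace_directions(v$ca)
    site <- v$ca + v$sc_len * dir
    site[!v$has_sc, ] <- v$ca[!v$has_sc, , drop = FALSE]
    v$site <- site
  } else {
    for (i in J) {
      v$site[i, ] <- if (v$has_sc[i]) {
        v$ca[i, ] + v$sc_len[i] * dir_at(v$ca, i)
      } else v$ca[i, ]
    }
  }
  v
}

# side-chain direction of residue i of a CA trace (same rule as
# trace_directions, evaluated at one index)
dir_at <- function(ca, i) {
  n <- nrow(ca)
  if (i == 1L) return(unit(ca[1, ] - ca[2, ]))
  if (i == n) return(unit(ca[n, ] - ca[n - 1, ]))
  d <- unit(ca[i, ] - ca[i - 1, ]) + unit(ca[i, ] - ca[i + 1, ])
  if (sqrt(sum(d^2)) < 1e-6) {
    u <- unit(ca[i + 1, ] - ca[i - 1, ])
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    d <- c(u[2] * ref[3] - u[3] * ref[2],
           u[3] * ref[1] - u[1] * ref[3],
           u[1] * ref[2] - u[2] * ref[1])
  }
  unit(d)
}

# propose one move on (pep, rec) engine views; returns NULL fields for the
# untouched chain. `changed` indexes residues whose energy terms may change.
propose_move <- function(pep, rec, cfg) {
  w <- cfg$move_weights
  if (!cfg$receptor_flexible) w["receptor"] <- 0
  cum <- cumsum(w) / sum(w)
  label <- names(w)[findInterval(stats::runif(1), cum) + 1L]
  n <- pep$n
  out <- list(label = label, chain = "pep", pep = NULL, rec = NULL,
              changed = NULL)
  if (label == "rigid_trans") {
    shift <- random_in_ball(cfg$max_trans)
    pep$ca <- pep$ca + rep(shift, each = n)
    pep$site <- pep$site + rep(shift, each = n)
    out$pep <- pep; out$changed <- seq_len(n)
  } else if (label == "rigid_rot") {
    ang <- stats::runif(1, -1, 1) * cfg$max_rot_deg * pi / 180
    rot <- rotation_about_axis(random_unit_vector(), ang)
    cen <- colMeans(pep$ca)
    pep$ca <- sweep(pep$ca, 2, cen) %*% t(rot) + rep(cen, each = n)
    pep$site <- sweep(pep$site, 2, cen) %*% t(rot) + rep(cen, each = n)
    out$pep <- pep; out$changed <- seq_len(n)
  } else if (label == "single_ca") {
    j <- sample.int(n, 1L)
    pep$ca[j, ] <- pep$ca[j, ] + random_in_ball(cfg$max_ca)
    out$changed <- intersect((j - 1L):(j + 1L), seq_len(n))
    out$pep <- rederive_sites(pep, out$changed)
  } else if (label == "crankshaft") {
    if (n < 3L) return(propose_move(pep, rec, within_weights(cfg, "single_ca")))
    i <- sample.int(n - 2L, 1L)
    axis <- pep$ca[i + 2L, ] - pep$ca[i, ]
    ang <- stats::runif(1, -1, 1) * cfg$max_crank_deg * pi / 180
    rot <- rotation_about_axis(axis, ang)
    pep$ca[i + 1L, ] <- drop((pep$ca[i + 1L, ] - pep$ca[i, ]) %*% t(rot)) +
      pep$ca[i, ]
    out$changed <- intersect(i:(i + 2L), seq_len(n))
    out$pep <- rederive_sites(pep, out$changed)
  } else if (label == "pivot") {
    end <- sample(c(1L, n), 1L)
    nb <- if (end == 1L) 2L else n - 1L
    ang <- stats::runif(1, -1, 1) * cfg$max_pivot_deg * pi / 180
    rot <- rotation_about_axis(random_unit_vector(), ang)
    pep$ca[end, ] <- drop((pep$ca[end, ] - pep$ca[nb, ]) %*% t(rot)) +
      pep$ca[nb, ]
    out$changed <- intersect((end - 1L):(end + 1L), seq_len(n))
    out$pep <- rederive_sites(pep, out$changed)
  } else { # receptor
    j <- sample.int(rec$n, 1L)
    shift <- random_in_ball(cfg$max_receptor)
    rec$ca[j, ] <- rec$ca[j, ] + shift
    rec$site[j, ] <- rec$site[j, ] + shift
    out$chain <- "rec"; out$rec <- rec; out$changed <- j
  }
  out
}

within_weights <- function(cfg, only) {
  w <- cfg$move_weights * 0
  w[only] <- 1
  cfg$move_weights <- w
  cfg
}

random_in_ball <- function(radius) {
  if (radius <= 0) return(c(0, 0, 0))
  repeat {
    v <- stats::runif(3, -1, 1)
    if (sum(v^2) <= 1) return(v * radius)
  }
}

# local energy of peptide residues J (plus box term, which depends on the
# whole peptide centroid) against the full receptor
pep_local_energy <- function(pep, rec, model, J, pep_atoms, atom_res,
                             sep_mask, rec_atoms) {
  e_contact <- contact_energy_part(pep, rec, model, jp = J)
  aJ <- pep_atoms[atom_res %in% J, , drop = FALSE]
  e_ev <- ev_pair_energy(aJ, rec_atoms, model) +
    intra_ev_atoms(pep_atoms, atom_res, sep_mask, model, J)
  bonds <- intersect(unique(c(J - 1L, J)), seq_len(pep$n - 1L))
  e_bond <- bond_energy_part(pep$ca, rep(model$bond_length, pep$n - 1L),
                             model, bonds)
  e_box <- box_energy_part(pep$ca, model)
  c(contact = e_contact, excluded = e_ev, bond = e_bond, restraint = 0,
    box = e_box)
}

rec_local_energy <- function(pep, rec, model, j, restraint_rows, pep_atoms) {
  e_contact <- contact_energy_part(pep, rec, model, jr = j)
  aj <- steric_atoms(rec, j)$coords
  e_ev <- ev_pair_energy(pep_atoms, aj, model)
  bonds <- intersect(unique(c(j - 1L, j)), seq_len(rec$n - 1L))
  e_bond <- bond_energy_part(rec$ca, model$receptor_bond_ref, model, bonds)
  e_res <- restraint_energy_part(rec$ca, model, restraint_rows)
  c(contact = e_contact, excluded = e_ev, bond = e_bond, restraint = e_res,
    box = 0)
}

#' Propose a single Monte Carlo move on a replica state
#'
#' One of: rigid peptide translation/rotation, single-residue CA
#' displacement (side-chain sites re-derived), two-bond crankshaft,
#' end-residue pivot, or a small receptor CA displacement. All proposals
#' are symmetric, so the Metropolis rule alone preserves detailed balance.
#' Uses R's global random number stream.
#'
#' @param state a `ReplicaState`.
#' @param config a [docking_config()] (move weights and amplitudes).
#' @return list with `state` (the proposed `ReplicaState`, energy not
#'   re-evaluated), `label` (move type) and `changed` (residue indices whose
#'   interactions changed).
#' @export
mc_move <- function(state, config = docking_config()) {
  pep <- pep_engine_state(state$peptide)
  rec <- chain_view(state$receptor)
  prop <- propose_move(pep, rec, config)
  new <- state
  if (prop$chain == "pep") {
    new$peptide <- update_coarse_from_view(state$peptide, prop$pep)
  } else {
    new$receptor <- update_coarse_from_view(state$receptor, prop$rec)
  }
  new$energy <- NA_real_
  new$terms <- NULL
  list(state = new, label = prop$label, changed = prop$changed)
}

# push engine-view coordinates back into a CoarseChain, translating the
# untracked CB/PB pseudo-atoms along with their residue's CA
update_coarse_from_view <- function(cc, v) {
  delta <- v$ca - cc$ca
  cc$cb <- cc$cb + delta
  n <- nrow(cc$ca)
  if (n > 1L) {
    cc$pb[-n, ] <- cc$pb[-n, , drop = FALSE] +
      (delta[-n, , drop = FALSE] + delta[-1, , drop = FALSE]) / 2
  }
  cc$ca <- v$ca
  cc$sc[v$has_sc, ] <- v$site[v$has_sc, , drop = FALSE]
  cc
}

#' Attempt replica exchanges between adjacent temperature rungs
#'
#' Adjacent pairs (alternating even/odd phase) swap configurations with the
#' standard probability `min(1, exp((1/Ti - 1/Tj) (Ei - Ej)))`; the
#' temperatures stay attached to the ladder slots. Uses R's global random
#' number stream.
#'
#' @param states list of `ReplicaState` ordered by ladder slot.
#' @param phase 0 attempts pairs (1,2), (3,4), ...; 1 attempts (2,3), (4,5), ...
#' @return list with `states` (same length, possibly with swapped
#'   configurations) and `accepted` (number of accepted swaps).
#' @export
replica_exchange_sweep <- function(states, phase = 0L) {
  n <- length(states)
  if (n < 2L) stop("need at least 2 replicas for exchange")
  accepted <- 0L
  i <- 1L + (phase %% 2L)
  while (i + 1L <= n) {
    a <- states[[i]]; b <- states[[i + 1L]]
    dbeta <- 1 / a$temperature - 1 / b$temperature
    dE <- a$energy - b$energy
    u <- stats::runif(1)  # one draw per attempted pair, for reproducibility
    if (dbeta * dE >= 0 || u < exp(dbeta * dE)) {
      for (f in c("peptide", "receptor", "energy", "terms")) {
        tmp <- a[[f]]; a[[f]] <- b[[f]]; b[[f]] <- tmp
      }
      states[[i]] <- a; states[[i + 1L]] <- b
      accepted <- accepted + 1L
    }
    i <- i + 2L
  }
  list(states = states, accepted = accepted)
}

# ---- the REMC engine ----------------------------------------------------

#' Run the replica exchange Monte Carlo docking simulation
#'
#' Coarse-grains the receptor, derives near-native distance restraints from
#' its starting conformation, places one random peptide conformation per
#' replica at the placement distance, and runs Metropolis sweeps with
#' periodic replica exchanges, collecting snapshots at a fixed cadence
#' until `n_snapshots_per_replica` are stored for every temperature rung
#' (default: 10 x 1000 = 10,000 models). Energies are tracked
#' incrementally and must agree with [total_energy()] to 1e-6 at every
#' snapshot. Bit-reproducible for a given config seed.
#'
#' @param receptor receptor `ChainStructure` (all-atom) or `CoarseChain`.
#' @param slim_sequence one-letter motif sequence to dock.
#' @param config a [docking_config()].
#' @return object of class `Trajectory`: snapshot list (`replica`, `sweep`,
#'   `temperature`, `energy`, `terms`, `pep_ca`, `rec_ca`), the starting
#'   receptor `CoarseChain`, the peptide sequence, the config and its
#'   digest.
#' @export
run_docking <- function(receptor, slim_sequence, config = docking_config()) {
  setup <- placement_setup(receptor, slim_sequence, config)
  model <- setup$model
  streams <- setup$streams
  nrep <- config$n_replicas
  temps <- config$temperatures

  # engine-internal replica records
  reps <- lapply(setup$states, function(st) {
    pep <- pep_engine_state(st$peptide)
    rec <- chain_view(st$receptor)
    list(pep = pep, rec = rec,
         rec_atoms = steric_atoms(rec, seq_len(rec$n))$coords,
         energy = st$energy, terms = st$terms)
  })
  n_pep <- reps[[1]]$pep$n
  n_rec <- reps[[1]]$rec$n
  atom_res <- atom_residue_index(reps[[1]]$pep)
  sep_mask <- intra_sep_mask(reps[[1]]$pep)
  for (r in seq_along(reps)) {
    reps[[r]]$pep_atoms <- build_steric_atoms(reps[[r]]$pep)
  }
  sc_row <- cumsum(reps[[1]]$rec$has_sc)  # receptor steric-atom row map
  restr_map <- lapply(seq_len(n_rec), function(j) {
    which(model$restraints$i == j | model$restraints$j == j)
  })
  moves_per_sweep <- n_pep + 2L
  total_sweeps <- config$n_snapshots_per_replica *
    config$sweeps_between_snapshots

  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old_rs <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had) assign(".Random.seed", old_rs, envir = globalenv())
  })

  snapshots <- vector("list", nrep * config$n_snapshots_per_replica)
  snap_i <- 0L
  exch_phase <- 0L
  for (sweep in seq_len(total_sweeps)) {
    for (r in seq_len(nrep)) {
      use_stream(streams[[r]])
      rep_r <- reps[[r]]
      for (m in seq_len(moves_per_sweep)) {
        prop <- propose_move(rep_r$pep, rep_r$rec, config)
        if (prop$chain == "pep") {
          J <- prop$changed
          new_atoms <- build_steric_atoms(prop$pep)
          e_old <- pep_local_energy(rep_r$pep, rep_r$rec, model, J,
                                    rep_r$pep_atoms, atom_res, sep_mask,
                                    rep_r$rec_atoms)
          e_new <- pep_local_energy(prop$pep, rep_r$rec, model, J,
                                    new_atoms, atom_res, sep_mask,
                                    rep_r$rec_atoms)
        } else {
          j <- prop$changed
          e_old <- rec_local_energy(rep_r$pep, rep_r$rec, model, j,
                                    restr_map[[j]], rep_r$pep_atoms)
          e_new <- rec_local_energy(rep_r$pep, prop$rec, model, j,
                                    restr_map[[j]], rep_r$pep_atoms)
        }
        dE <- sum(e_new) - sum(e_old)
        if (dE <= 0 || stats::runif(1) < exp(-dE / temps[r])) {
          if (prop$chain == "pep") {
            rep_r$pep <- prop$pep
            rep_r$pep_atoms <- new_atoms
          } else {
            rep_r$rec <- prop$rec
            j <- prop$changed
            rep_r$rec_atoms[j, ] <- prop$rec$ca[j, ]
            if (rep_r$rec$has_sc[j]) {
              rep_r$rec_atoms[n_rec + sc_row[j], ] <- prop$rec$site[j, ]
            }
          }
          rep_r$terms <- rep_r$terms + (e_new - e_old)
          rep_r$energy <- rep_r$energy + dE
        }
      }
      reps[[r]] <- rep_r
      streams[[r]] <- current_stream()
    }
    if (nrep > 1L && sweep %% config$exchange_interval == 0L) {
      use_stream(streams[[nrep + 1L]])
      i <- 1L + (exch_phase %% 2L)
      while (i + 1L <= nrep) {
        dbeta <- 1 / temps[i] - 1 / temps[i + 1L]
        dE <- reps[[i]]$energy - reps[[i + 1L]]$energy
        u <- stats::runif(1)
        if (dbeta * dE >= 0 || u < exp(dbeta * dE)) {
          tmp <- reps[[i]]; reps[[i]] <- reps[[i + 1L]]; reps[[i + 1L]] <- tmp
        }
        i <- i + 2L
      }
      exch_phase <- exch_phase + 1L
      streams[[nrep + 1L]] <- current_stream()
    }
    if (sweep %% config$sweeps_between_snapshots == 0L) {
      for (r in seq_len(nrep)) {
        snap_i <- snap_i + 1L
        snapshots[[snap_i]] <- list(
          replica = r, sweep = sweep, temperature = temps[r],
          energy = reps[[r]]$energy, terms = reps[[r]]$terms,
          pep_ca = reps[[r]]$pep$ca, rec_ca = reps[[r]]$rec$ca)
      }
    }
  }

  traj <- list(snapshots = snapshots, sequence = slim_sequence,
               receptor0 = setup$rec, config = config,
               seed = config$seed, digest = config_digest(strip_config(config)))
  class(traj) <- "Trajectory"
  traj
}

# serializable view of a config (drop the 400-entry contact table from the
# digest payload; its own digest is included instead)
strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$energy <- unclass(cfg$energy)
  cfg$energy$contact_table_digest <- config_digest(cfg$energy$contact_table)
  cfg$energy$contact_table <- NULL
  cfg$energy$restraints <- NULL
  cfg
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "<Trajectory: %d snapshots (%d replicas), peptide %s, seed %d>\n",
    length(x$snapshots), x$config$n_replicas, x$sequence, x$seed))
  invisible(x)
}

#' Rebuild a full replica state from a trajectory snapshot
#'
#' The peptide is rebuilt from its CA trace (side-chain sites re-derived by
#' the same rule the engine uses); the receptor's CB/SC/PB pseudo-atoms
#' follow their residue's CA displacement from the starting structure.
#'
#' @param trajectory a `Trajectory`.
#' @param i snapshot index.
#' @return a `ReplicaState`.
#' @export
snapshot_state <- function(trajectory, i) {
  sn <- trajectory$snapshots[[i]]
  seq <- strsplit(trajectory$sequence, "")[[1]]
  geo <- derive_from_trace(seq, sn$pep_ca)
  pep <- new_coarse_chain("P", seq, sn$pep_ca, geo$cb, geo$sc, geo$pb,
                          seq_along(seq), rep("", length(seq)),
                          origin = "peptide", from = "trace")
  rec0 <- trajectory$receptor0
  delta <- sn$rec_ca - rec0$ca
  rec <- rec0
  rec$ca <- sn$rec_ca
  rec$cb <- rec0$cb + delta
  rec$sc <- rec0$sc + delta
  n <- nrow(delta)
  if (n > 1L) {
    rec$pb[-n, ] <- rec0$pb[-n, , drop = FALSE] +
      (delta[-n, , drop = FALSE] + delta[-1, , drop = FALSE]) / 2
  }
  new_replica_state(sn$replica, sn$temperature, pep, rec, sn$energy, sn$terms)
}

#' Persist a trajectory to a directory
#'
#' Writes `meta.json` (seed, config, digest), `snapshots.tsv` (snapshot id,
#' replica, sweep, temperature, total and per-term energies), `coords.tsv`
#' (full-precision CA coordinates of both chains per snapshot),
#' `receptor0.json` (the starting coarse receptor) and `models.pdb` (a
#' concatenated multi-model coarse PDB for visualization).
#'
#' @param trajectory a `Trajectory`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_trajectory <- function(trajectory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sn <- trajectory$snapshots
  meta <- list(seed = trajectory$seed, digest = trajectory$digest,
               sequence = trajectory$sequence,
               config = strip_config(trajectory$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = 10, null = "null")
  terms <- do.call(rbind, lapply(sn, function(s) s$terms))
  tab <- data.frame(snapshot = seq_along(sn),
                    replica = vapply(sn, `[[`, 0L, "replica"),
                    sweep = vapply(sn, `[[`, 0L, "sweep"),
                    temperature = vapply(sn, `[[`, 0, "temperature"),
                    energy = vapply(sn, `[[`, 0, "energy"))
  tab <- cbind(tab, as.data.frame(terms))
  utils::write.table(tab, file.path(dir, "snapshots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rec0 <- trajectory$receptor0
  jsonlite::write_json(
    list(chain_id = rec0$chain_id, seq = rec0$seq, ca = rec0$ca,
         cb = rec0$cb, sc = rec0$sc, pb = rec0$pb, resno = rec0$resno,
         insert = rec0$insert, origin = rec0$origin, from = rec0$from),
    file.path(dir, "receptor0.json"), digits = 10, auto_unbox = TRUE,
    null = "null", na = "null")
  # full-precision coordinates
  n_p <- nrow(sn[[1]]$pep_ca); n_r <- nrow(sn[[1]]$rec_ca)
  co <- file(file.path(dir, "coords.tsv"), open = "wt")
  writeLines("snapshot\tchain\tresidue\tx\ty\tz", co)
  for (k in seq_along(sn)) {
    m <- rbind(sn[[k]]$rec_ca, sn[[k]]$pep_ca)
    writeLines(sprintf("%d\t%s\t%d\t%.10g\t%.10g\t%.10g", k,
                       c(rep("R", n_r), rep("P", n_p)),
                       c(seq_len(n_r), seq_len(n_p)),
                       m[, 1], m[, 2], m[, 3]), co)
  }
  close(co)
  # multi-model coarse PDB for viewers
  pdb_lines <- character(0)
  rec_res3 <- aa_one_to_three(rec0$seq)
  pep_res3 <- aa_one_to_three(strsplit(trajectory$sequence, "")[[1]])
  for (k in seq_along(sn)) {
    pdb_lines <- c(pdb_lines, sprintf("MODEL %8d", k),
                   ca_records(sn[[k]]$rec_ca, rec_res3, rec0$resno, "R", 0L),
                   ca_records(sn[[k]]$pep_ca, pep_res3, seq_len(n_p), "P", n_r),
                   "ENDMDL")
  }
  writeLines(c(pdb_lines, "END"), file.path(dir, "models.pdb"))
  invisible(dir)
}

ca_records <- function(ca, res3, resno, chain, serial0) {
  sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          (serial0 + seq_len(nrow(ca))) %% 100000L, res3, chain, resno,
          ca[, 1], ca[, 2], ca[, 3])
}

#' Load a trajectory saved by [save_trajectory()]
#'
#' @param dir trajectory directory.
#' @return a `Trajectory` (the config is restored as a plain list).
#' @export
load_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  tab <- utils::read.delim(file.path(dir, "snapshots.tsv"))
  co <- utils::read.delim(file.path(dir, "coords.tsv"))
  r0 <- jsonlite::read_json(file.path(dir, "receptor0.json"),
                            simplifyVector = TRUE)
  to_mat <- function(x) {
    m <- as.matrix(x)
    if (is.null(dim(m)) || ncol(m) != 3) m <- matrix(unlist(x), ncol = 3)
    storage.mode(m) <- "double"
    unname(m)
  }
  rec0 <- new_coarse_chain(r0$chain_id, r0$seq, to_mat(r0$ca), to_mat(r0$cb),
                           to_mat(r0$sc), to_mat(r0$pb), r0$resno,
                           r0$insert %||% rep("", length(r0$seq)),
                           r0$origin, r0$from)
  term_cols <- c("contact", "excluded", "bond", "restraint", "box")
  by_snap <- split(co, co$snapshot)
  snapshots <- lapply(seq_len(nrow(tab)), function(k) {
    ck <- by_snap[[as.character(k)]]
    list(replica = tab$replica[k], sweep = tab$sweep[k],
         temperature = tab$temperature[k], energy = tab$energy[k],
         terms = unlist(tab[k, term_cols]),
         pep_ca = as.matrix(ck[ck$chain == "P", c("x", "y", "z")]),
         rec_ca = as.matrix(ck[ck$chain == "R", c("x", "y", "z")]))
  })
  traj <- list(snapshots = snapshots, sequence = meta$sequence,
               receptor0 = rec0, config = meta$config, seed = meta$seed,
               digest = meta$digest)
  class(traj) <- "Trajectory"
  traj
}
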