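# Surrogate knowledge-based energy for the coarse-grained docking engine:
#   E = contact + excluded volume + bond geometry + receptor restraints
#       + confinement
# All constants are configuration, never hard-coded in the sampler.

AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default residue-type contact energy table
#'
#' A symmetric 20x20 table of pairwise contact energies, shipped as a
#' plain-text CSV and user-replaceable. The default values are a
#' hydrophobicity outer product (Kyte-Doolittle scale, `e_ij = -q_i q_j`
#' with `q` scaled to \[0, 1.4\]) -- the rank-one structure that dominates
#' statistical contact potentials: hydrophobic pairs attract (L-L -1.67,
#' I-I -1.96), polar pairs are neutral.
#'
#' @param path CSV with an `aa` column and 20 amino-acid columns; defaults
#'   to the shipped table.
#' @return 20x20 named numeric matrix (energy units).
#' @export
default_contact_table <- function(path = system.file("extdata",
                                                     "contact_energies.csv",
                                                     package = "slimdock")) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$aa
  m <- m[AA_ORDER, AA_ORDER]
  if (max(abs(m - t(m))) > 1e-9) stop("contact table is not symmetric")
  m
}

#' Construct an energy model
#'
#' The tunable surrogate potential used by the docking engine. Terms:
#' a residue-type contact energy for inter-chain side-chain site pairs
#' within `contact_radius`; a quadratic excluded-volume penalty for any
#' CA/SC site pair below `ev_radius`; a harmonic CA-CA virtual-bond term
#' (peptide target 3.8 A, receptor target = its starting bond lengths); a
#' flat-bottom harmonic restraint set on the receptor; and a soft spherical
#' confinement keeping the peptide centroid within `box_margin` of the
#' receptor.
#'
#' @param contact_table 20x20 symmetric matrix; default [default_contact_table()].
#' @param contact_radius SC-SC contact radius (A).
#' @param ev_radius hard-core excluded-volume radius (A).
#' @param w_ev excluded-volume penalty weight (energy/A^2).
#' @param w_bond bond-geometry weight (energy/A^2).
#' @param bond_length peptide CA-CA virtual bond target (A).
#' @param w_contact contact-term weight.
#' @param restraint_delta flat-bottom half-width (A).
#' @param restraint_k restraint force constant (energy/A^2).
#' @param restraint_min_separation minimum sequence separation of restrained
#'   receptor pairs.
#' @param restraint_window CA-CA distance window (A) of restrained pairs.
#' @param w_box confinement weight (energy/A^2).
#' @param box_margin confinement wall distance beyond the receptor radius (A).
#' @return object of class `EnergyModel`.
#' @export
energy_model <- function(contact_table = default_contact_table(),
                         contact_radius = 6.5,
                         ev_radius = 3.5,
                         w_ev = 1.0,
                         w_bond = 5.0,
                         bond_length = 3.8,
                         w_contact = 1.0,
                         restraint_delta = 1.0,
                         restraint_k = 1.0,
                         restraint_min_separation = 5L,
                         restraint_window = c(5, 15),
                         w_box = 1.0,
                         box_margin = 25) {
  stopifnot(all(dim(contact_table) == c(20L, 20L)),
            contact_radius > 0, ev_radius > 0, w_ev >= 0, w_bond >= 0,
            restraint_delta >= 0, restraint_k >= 0)
  if (max(abs(contact_table - t(contact_table))) > 1e-9) {
    stop("contact table must be symmetric")
  }
  m <- list(contact_table = contact_table, contact_radius = contact_radius,
            ev_radius = ev_radius, w_ev = w_ev, w_bond = w_bond,
            bond_length = bond_length, w_contact = w_contact,
            restraint_delta = restraint_delta, restraint_k = restraint_k,
            restraint_min_separation = restraint_min_separation,
            restraint_window = restraint_window,
            w_box = w_box, box_margin = box_margin,
            restraints = NULL, receptor_bond_ref = NULL,
            box_center = NULL, box_radius = NULL)
  class(m) <- "EnergyModel"
  m
}

#' Distance restraints keeping the receptor near its starting conformation
#'
#' For every receptor residue pair with sequence separation at least
#' `min_separation` and starting CA-CA distance inside `window`, a
#' flat-bottom harmonic restraint centred on the starting distance. The
#' restraint energy of the starting conformation is exactly zero.
#'
#' @param receptor a receptor `CoarseChain`.
#' @param model an `EnergyModel` supplying separation, window, delta and k.
#' @return data frame with columns `i`, `j` (residue indices), `d0` (A),
#'   `delta` (A) and `k`.
#' @export
generate_receptor_restraints <- function(receptor, model = energy_model()) {
  ca <- receptor$ca
  n <- nrow(ca)
  sep <- model$restraint_min_separation
  if (n < sep + 1L) {
    return(data.frame(i = integer(0), j = integer(0), d0 = numeric(0),
                      delta = numeric(0), k = numeric(0)))
  }
  pr <- which(outer(seq_len(n), seq_len(n),
                    function(i, j) j - i >= sep), arr.ind = TRUE)
  d <- sqrt(rowSums((ca[pr[, 1], , drop = FALSE] -
                     ca[pr[, 2], , drop = FALSE])^2))
  keep <- d >= model$restraint_window[1] & d <= model$restraint_window[2]
  data.frame(i = pr[keep, 1], j = pr[keep, 2], d0 = d[keep],
             delta = model$restraint_delta, k = model$restraint_k,
             row.names = NULL)
}

#' Bind an energy model to a starting receptor
#'
#' Derives the receptor-dependent pieces of the potential: the restraint
#' set, the reference CA-CA bond lengths, and the confinement sphere
#' (centred on the receptor centroid, wall at receptor radius +
#' `box_margin`).
#'
#' @param model an `EnergyModel`.
#' @param receptor the starting receptor `CoarseChain`.
#' @return the prepared `EnergyModel`.
#' @export
prepare_energy <- function(model, receptor) {
  ca <- receptor$ca
  n <- nrow(ca)
  model$restraints <- generate_receptor_restraints(receptor, model)
  model$receptor_bond_ref <- if (n > 1L) {
    sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  } else numeric(0)
  model$box_center <- colMeans(ca)
  model$box_radius <- sqrt(max(rowSums(
    (ca - rep(model$box_center, each = n))^2))) + model$box_margin
  model
}

# ---- internal chain views used by the sampler ---------------------------

# reduce a CoarseChain to the arrays the energy core needs
chain_view <- function(cc) {
  type <- match(cc$seq, AA_ORDER)         # NA for non-standard: no contacts
  has_sc <- !is.na(cc$sc[, 1])
  site <- cc$sc
  site[!has_sc, ] <- cc$ca[!has_sc, , drop = FALSE]
  list(ca = cc$ca, site = site, has_sc = has_sc, type = type,
       n = length(cc$seq))
}

# steric atoms of residues `idx`: CA always, SC where distinct from CA
steric_atoms <- function(v, idx) {
  sc_idx <- idx[v$has_sc[idx]]
  list(coords = rbind(v$ca[idx, , drop = FALSE],
                      v$site[sc_idx, , drop = FALSE]))
}

sq_dists <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  matrix(rowSums(a * a), na, nb) +
    matrix(rowSums(b * b), na, nb, byrow = TRUE) - 2 * tcrossprod(a, b)
}

# atom-level bookkeeping for the peptide steric set: CA atoms first, then
# the SC sites of residues that have one
atom_residue_index <- function(v) c(seq_len(v$n), which(v$has_sc))

build_steric_atoms <- function(v) rbind(v$ca, v$site[v$has_sc, , drop = FALSE])

# upper-triangular mask of steric atom pairs belonging to residues with
# sequence separation >= 2 (precomputed once per run)
intra_sep_mask <- function(v, min_sep = 2L) {
  res <- atom_residue_index(v)
  m <- abs(outer(res, res, "-")) >= min_sep
  m[lower.tri(m, diag = TRUE)] <- FALSE
  m
}

# intra-chain excluded volume over masked atom pairs; J (residue indices)
# restricts to pairs involving a changed residue
intra_ev_atoms <- function(atoms, res, mask, model, J = NULL) {
  if (!is.null(J)) {
    inv <- res %in% J
    mask[!inv, !inv] <- FALSE
  }
  d2 <- sq_dists(atoms, atoms)
  low <- mask & d2 < model$ev_radius^2
  if (!any(low)) return(0)
  model$w_ev * sum((model$ev_radius - sqrt(pmax(d2[low], 0)))^2)
}

# contact energy of peptide residues `jp` against receptor residues `jr`
contact_energy_part <- function(pep, rec, model, jp = seq_len(pep$n),
                                jr = seq_len(rec$n)) {
  tp <- pep$type[jp]; tr <- rec$type[jr]
  okp <- !is.na(tp); okr <- !is.na(tr)
  jp <- jp[okp]; jr <- jr[okr]
  if (!length(jp) || !length(jr)) return(0)
  d2 <- sq_dists(pep$site[jp, , drop = FALSE], rec$site[jr, , drop = FALSE])
  inside <- which(d2 < model$contact_radius^2, arr.ind = TRUE)
  if (!nrow(inside)) return(0)
  model$w_contact * sum(model$contact_table[
    cbind(pep$type[jp][inside[, 1]], rec$type[jr][inside[, 2]])])
}

ev_pair_energy <- function(a, b, model) {
  if (!nrow(a) || !nrow(b)) return(0)
  d2 <- sq_dists(a, b)
  low <- d2 < model$ev_radius^2
  if (!any(low)) return(0)
  d <- sqrt(pmax(d2[low], 0))
  model$w_ev * sum((model$ev_radius - d)^2)
}

bond_energy_part <- function(ca, ref, model, bonds = seq_len(nrow(ca) - 1L)) {
  if (!length(bonds)) return(0)
  d <- sqrt(rowSums((ca[bonds + 1L, , drop = FALSE] -
                     ca[bonds, , drop = FALSE])^2))
  model$w_bond * sum((d - ref[bonds])^2)
}

restraint_energy_part <- function(rec_ca, model, rows = NULL) {
  rs <- model$restraints
  if (is.null(rs) || nrow(rs) == 0L) return(0)
  if (!is.null(rows)) rs <- rs[rows, , drop = FALSE]
  if (nrow(rs) == 0L) return(0)
  d <- sqrt(rowSums((rec_ca[rs$i, , drop = FALSE] -
                     rec_ca[rs$j, , drop = FALSE])^2))
  sum(rs$k * pmax(0, abs(d - rs$d0) - rs$delta)^2)
}

box_energy_part <- function(pep_ca, model) {
  if (is.null(model$box_center)) return(0)
  r <- sqrt(sum((colMeans(pep_ca) - model$box_center)^2))
  model$w_box * max(0, r - model$box_radius)^2
}

# full energy of a (pep, rec) chain-view pair under a prepared model
full_energy <- function(pep, rec, model, pep_bond_ref = NULL) {
  if (is.null(pep_bond_ref)) pep_bond_ref <- rep(model$bond_length, pep$n - 1L)
  ap <- build_steric_atoms(pep)
  ar <- build_steric_atoms(rec)
  terms <- c(
    contact   = contact_energy_part(pep, rec, model),
    excluded  = ev_pair_energy(ap, ar, model) +
                intra_ev_atoms(ap, atom_residue_index(pep),
                               intra_sep_mask(pep), model),
    bond      = bond_energy_part(pep$ca, pep_bond_ref, model) +
                bond_energy_part(rec$ca, model$receptor_bond_ref %||%
                                   rep(model$bond_length, rec$n - 1L), model),
    restraint = restraint_energy_part(rec$ca, model),
    box       = box_energy_part(pep$ca, model))
  list(total = sum(terms), terms = terms)
}

#' Total energy of a replica state
#'
#' Recomputes the full surrogate potential from scratch: inter-chain contact
#' term, excluded volume, bond geometry, receptor restraints and peptide
#' confinement. The docking engine tracks this quantity incrementally; this
#' function is the from-scratch reference it must agree with.
#'
#' @param state a `ReplicaState` (from [place_peptide_replicas()] or a
#'   trajectory snapshot), or any list with `peptide` and `receptor`
#'   `CoarseChain`s.
#' @param model a prepared `EnergyModel` (see [prepare_energy()]); if not
#'   prepared it is prepared against `state$receptor`, i.e. the state is
#'   taken as the starting conformation.
#' @return list with `total` and named `terms`
#'   (contact/excluded/bond/restraint/box).
#' @export
total_energy <- function(state, model = energy_model()) {
  if (is.null(model$restraints)) model <- prepare_energy(model, state$receptor)
  full_energy(chain_view(state$peptide), chain_view(state$receptor), model)
}
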