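# hand-built miniature structures used across the unit tests

# a chain from a bare list of atoms: each entry list(resno, resid, elety, xyz)
tiny_chain <- function(chain_id, atoms, insert = NULL) {
  df <- do.call(rbind, lapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    data.frame(resno = a$resno, insert = a$insert %||% "",
               resid = a$resid, elety = a$elety,
               element = substr(gsub("[0-9]", "", a$elety), 1, 1),
               x = a$xyz[1], y = a$xyz[2], z = a$xyz[3],
               o = a$o %||% 1, stringsAsFactors = FALSE)
  }))
  chain_structure(chain_id, df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-atom residue record at a point
point_residue <- function(xyz, resno = 1L, resid = "GLY") {
  list(seq_id = resno, insert = "", resname = resid, aa = "G",
       coords = matrix(xyz, 1, 3))
}

# a straight all-atom test chain along +x with CA spacing 3.8
straight_chain <- function(seq = "AAAA", chain_id = "A", resno0 = 1L,
                           y = 0, z = 0) {
  aa <- strsplit(seq, "")[[1]]
  ca <- cbind((seq_along(aa) - 1) * 3.8, y, z)
  dirs <- matrix(rep(c(0, 0, 1), each = length(aa)), ncol = 3)
  slimdock:::build_chain_from_path(chain_id, aa, ca, dirs,
                                   resno = resno0 + seq_along(aa) - 1L)
}

# brute-force minimum heavy-atom distance between two coordinate matrices
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

# a small ReplicaState around a toy receptor, for move/energy tests
toy_state <- function(seed = 1L, sequence = "CILMFWYV", n_replicas = 1L) {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  cfg <- docking_config(n_replicas = n_replicas,
                        n_snapshots_per_replica = 1L, seed = seed)
  states <- place_peptide_replicas(toy$receptor, sequence, cfg)
  list(state = states[[1]], states = states, toy = toy, cfg = cfg)
}
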