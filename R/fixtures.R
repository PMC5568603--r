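# Deterministic synthetic structures: a toy receptor with a designed
# binding channel, a bound reference complex with a known (planted)
# contact list, and an engineered contact table that makes the designed
# site the global minimum of the surrogate potential. Everything is built
# from code and a seed -- no downloads -- and every emitted reference is
# self-verified against the package's own contact-map definition before it
# is handed out. These are synthetic stand-ins for a real SLiM-mediated
# complex, reduced side chains included (CB plus one dummy side-chain atom
# per residue), not physically realistic structures.

#' Specification of a synthetic SLiM complex
#'
#' @param receptor_length total receptor residues (>= 10).
#' @param fold `"ushape"` (two antiparallel strands joined by a turn,
#'   forming a binding channel; the default) or `"helix"` (a plain
#'   alpha-helix, no groove; used where only receptor geometry matters).
#' @param peptide_sequence one-letter motif sequence; the default 8-mer has
#'   all-distinct residue types so that the designed registry is
#'   energetically unambiguous.
#' @param groove_indices receptor residue indices lining the channel;
#'   `NULL` (default) selects the channel segment nearest the turn.
#' @param planted_contacts expected native contact list (`"recKey|pepKey"`
#'   strings) that the emitted reference must realize exactly at 8 A;
#'   `NULL` resolves it from the construction.
#' @param noise_amplitude uniform jitter (A) applied to the receptor CA
#'   path (0 = exact geometry).
#' @param flank glycine flank length added on both sides of the motif to
#'   form the partner chain.
#' @param seed integer seed.
#' @return object of class `ToyComplexSpec`.
#' @export
toy_complex_spec <- function(receptor_length = 36L,
                             fold = c("ushape", "helix"),
                             peptide_sequence = "CILMFWYV",
                             groove_indices = NULL,
                             planted_contacts = NULL,
                             noise_amplitude = 0,
                             flank = 3L,
                             seed = 42L) {
  fold <- match.arg(fold)
  if (receptor_length < 10L) stop("receptor_length must be >= 10")
  if (noise_amplitude < 0 || noise_amplitude > 0.3) {
    stop("noise_amplitude must be in [0, 0.3] A (bond-window guard)")
  }
  spec <- list(receptor_length = as.integer(receptor_length), fold = fold,
               peptide_sequence = peptide_sequence,
               groove_indices = groove_indices,
               planted_contacts = planted_contacts,
               noise_amplitude = noise_amplitude,
               flank = as.integer(flank), seed = as.integer(seed))
  class(spec) <- "ToyComplexSpec"
  spec
}

TURN_RESIDUES <- 3L

# CA path of the toy receptor plus channel bookkeeping
ushape_path <- function(n) {
  k <- TURN_RESIDUES
  m <- (n - k) %/% 2L                      # strand A length
  nb <- n - m - k                          # strand B length
  r <- CA_BOND_LENGTH / (2 * sin(pi / (2 * (k + 1))))
  xm <- (m - 1) * CA_BOND_LENGTH
  ca <- matrix(0, n, 3)
  ca[seq_len(m), 1] <- (seq_len(m) - 1) * CA_BOND_LENGTH
  th <- seq_len(k) * pi / (k + 1)
  ca[m + seq_len(k), 1] <- xm + r * sin(th)
  ca[m + seq_len(k), 2] <- r - r * cos(th)
  ca[m + k + seq_len(nb), 1] <- xm - (seq_len(nb) - 1) * CA_BOND_LENGTH
  ca[m + k + seq_len(nb), 2] <- 2 * r
  list(ca = ca, m = m, k = k, nb = nb, r = r, xm = xm,
       mid_y = r)                           # channel mid-line y
}

helix_path <- function(n) {
  rise <- 1.5; dphi <- 100 * pi / 180
  rad <- sqrt(CA_BOND_LENGTH^2 - rise^2) / (2 * sin(dphi / 2))
  i <- seq_len(n) - 1
  cbind(rad * cos(i * dphi), rad * sin(i * dphi), i * rise)
}

# unit side-chain directions for the ushape path: channel-lining residues
# point into the channel and are tilted up (+z) toward where the peptide
# binds, which breaks the reflection symmetry of the planar fold; all other
# residues point away in-plane
ushape_side_dirs <- function(path, inward) {
  n <- nrow(path$ca)
  dirs <- matrix(0, n, 3)
  m <- path$m; k <- path$k
  dirs[seq_len(m), 2] <- 1                       # strand A: toward channel
  for (j in seq_len(k)) {                        # turn: toward circle center
    p <- path$ca[m + j, 1:2]
    cen <- c(path$xm, path$r)
    d <- cen - p
    dirs[m + j, 1:2] <- d / sqrt(sum(d^2))
  }
  dirs[m + k + seq_len(path$nb), 2] <- -1        # strand B: toward channel
  dirs[!inward, ] <- -dirs[!inward, , drop = FALSE]
  dirs[inward, 3] <- 0.6
  dirs[inward, ] <- dirs[inward, , drop = FALSE] /
    sqrt(rowSums(dirs[inward, , drop = FALSE]^2))
  dirs
}

# build an all-atom-ish chain (N, CA, C, CB, CG dummy) along a CA path with
# side chains along `side_dirs`
build_chain_from_path <- function(chain_id, seq, ca, side_dirs,
                                  resno = seq_along(seq), source = "synthetic") {
  n <- length(seq)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    t_next <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else unit(ca[i, ] - ca[i - 1, ])
    t_prev <- if (i > 1) unit(ca[i - 1, ] - ca[i, ]) else -t_next
    npos <- ca[i, ] + 1.45 * t_prev
    cpos <- ca[i, ] + 1.52 * t_next
    s <- side_dirs[i, ]
    names <- c("N", "CA", "C")
    coords <- rbind(npos, ca[i, ], cpos)
    if (seq[i] != "G") {
      names <- c(names, "CB")
      coords <- rbind(coords, ca[i, ] + 1.53 * s)
      if (seq[i] != "A") {
        names <- c(names, "CG")
        coords <- rbind(coords, ca[i, ] + 2.60 * s)
      }
    }
    recs[[i]] <- data.frame(
      resno = resno[i], insert = "", resid = aa_one_to_three(seq[i]),
      elety = names, element = substr(names, 1, 1),
      x = coords[, 1], y = coords[, 2], z = coords[, 3], o = 1,
      stringsAsFactors = FALSE)
  }
  chain_structure(chain_id, do.call(rbind, recs), source = source)
}

#' Build the synthetic toy receptor
#'
#' The default fold is two antiparallel strands joined by a circular-arc
#' turn, enclosing an open channel about 10 A wide; the channel-lining
#' residues (the designed binding groove) carry side chains pointing into
#' the channel, all others point away. Residue types are assigned by
#' [make_toy_complex()]; built alone, groove residues are phenylalanine
#' and the rest serine. Consecutive CA distances are exactly 3.8 A (up to
#' the optional jitter); geometry is deterministic given the seed.
#'
#' @param spec a [toy_complex_spec()].
#' @return a `ChainStructure` (chain "R").
#' @export
make_toy_receptor <- function(spec = toy_complex_spec()) {
  make_toy_receptor_impl(spec)$chain
}

make_toy_receptor_impl <- function(spec, seq = NULL) {
  n <- spec$receptor_length
  if (spec$fold == "helix") {
    ca <- helix_path(n)
    dirs <- t(apply(ca, 1, function(p) unit(c(p[1], p[2], 0))))
    groove <- integer(0)
  } else {
    path <- ushape_path(n)
    ca <- path$ca
    groove <- spec$groove_indices
    if (is.null(groove)) {
      # channel segment nearest the turn, on both strands plus the turn
      span <- 4L * CA_BOND_LENGTH
      on_strand <- c(seq_len(path$m), path$m + path$k + seq_len(path$nb))
      groove <- sort(c(on_strand[ca[on_strand, 1] >= path$xm - span],
                       path$m + seq_len(path$k)))
    }
    if (any(groove < 1L | groove > n)) {
      stop("infeasible groove indices (outside 1..", n, ")")
    }
    inward <- rep(FALSE, n)
    inward[groove] <- TRUE
    dirs <- ushape_side_dirs(path, inward)
  }
  if (spec$noise_amplitude > 0) {
    ca <- ca + with_seed(spec$seed, matrix(
      stats::runif(3 * n, -spec$noise_amplitude, spec$noise_amplitude), n, 3))
  }
  if (is.null(seq)) {
    seq <- rep("S", n)
    seq[groove] <- "F"
  }
  list(chain = build_chain_from_path("R", seq, ca, dirs,
                                     source = "synthetic toy receptor"),
       ca = ca, groove = groove,
       path = if (spec$fold == "ushape") path else NULL)
}

#' Build the synthetic reference complex
#'
#' Places the motif peptide along the mid-line of the receptor channel,
#' adjacent to the turn, extends it with glycine flanks rising out of the
#' channel to form the partner chain, and assigns each channel-lining
#' receptor residue the type of its nearest peptide residue (making the
#' designed registry recognizable by residue type). The realized contact
#' list between receptor and motif at the 8 A definition is computed with
#' [contact_map()] and becomes the planted contact list; if the spec
#' already carries one, the construction must reproduce it exactly.
#'
#' @param spec a [toy_complex_spec()] with fold `"ushape"`.
#' @return list: `complex` (reference `ComplexModel`), `receptor`,
#'   `partner`, `peptide` (motif-only `ChainStructure`), `slim`
#'   (`SlimDefinition` on the partner), `slim_keys`, `planted` (contact
#'   keys `"recKey|pepKey"`), `ref_pose_ca` (motif CA matrix in the
#'   receptor frame) and `spec` (resolved).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  if (spec$fold != "ushape") stop("a bound complex needs the ushape fold")
  path <- ushape_path(spec$receptor_length)
  pep_seq <- strsplit(spec$peptide_sequence, "")[[1]]
  np <- length(pep_seq)
  z_off <- 0.8
  x0 <- path$xm - 8.0          # designed site sits mid-strand, clear of
  x_end <- x0 - (np - 1) * CA_BOND_LENGTH      # the turn
  if (x_end < 2) stop("peptide too long for the receptor channel")
  # slight z zig-zag: a perfectly straight CA trace would make the
  # assembly superposition degenerate (collinear fit set)
  core_ca <- cbind(x0 - (seq_len(np) - 1) * CA_BOND_LENGTH, path$mid_y,
                   z_off + 0.35 * rep_len(c(1, -1), np))

  # channel lining follows the designed peptide span on both strands
  if (is.null(spec$groove_indices)) {
    on_strand <- c(seq_len(path$m), path$m + path$k + seq_len(path$nb))
    x_rec <- path$ca[on_strand, 1]
    spec$groove_indices <- on_strand[x_rec >= x_end - 2 & x_rec <= x0 + 2]
  }
  base <- make_toy_receptor_impl(spec)
  side_core <- matrix(rep(c(0, 0, 1), each = np), ncol = 3)
  side_core[, 3] <- rep_len(c(1, -1), np)      # alternate +z/-z
  core_chain0 <- build_chain_from_path("B", pep_seq, core_ca, side_core,
                                       resno = 100L + spec$flank + seq_len(np))

  # receptor types: only residues in actual reference contact (8 A) get a
  # type -- that of their nearest motif residue -- so the planted type
  # pairs encode the designed binding registry and nothing rewards poses
  # away from the site; all other residues stay serine
  rec_seq <- rep("S", spec$receptor_length)
  cm0 <- contact_map(base$chain, core_chain0, 8)
  touched <- which(apply(cm0$map, 1, any))
  for (g in touched) {
    d2 <- rowSums((core_ca - rep(base$ca[g, ], each = np))^2)
    rec_seq[g] <- pep_seq[which.min(d2)]
  }
  base <- make_toy_receptor_impl(spec, seq = rec_seq)
  receptor <- base$chain

  # partner chain: rising glycine flanks + motif core
  fl <- spec$flank
  up1 <- c(cos(50 * pi / 180), 0, sin(50 * pi / 180)) * CA_BOND_LENGTH
  pre <- t(sapply(rev(seq_len(fl)), function(k) core_ca[1, ] + k * up1))
  up2 <- c(-up1[1], 0, up1[3])
  post <- t(sapply(seq_len(fl), function(k) core_ca[np, ] + k * up2))
  part_ca <- rbind(pre, core_ca, post)
  part_seq <- c(rep("G", fl), pep_seq, rep("G", fl))
  side <- matrix(rep(c(0, 0, 1), each = fl + np + fl), ncol = 3)
  side[fl + seq_len(np), 3] <- rep_len(c(1, -1), np)   # alternate +z/-z
  partner <- build_chain_from_path("B", part_seq, part_ca, side,
                                   resno = 100L + seq_len(fl + np + fl),
                                   source = "synthetic toy partner")
  slim_start <- 100L + fl + 1L
  slim_end <- 100L + fl + np
  ext <- extract_slim(partner, slim_start, slim_end)

  # self-verification: planted contacts realized exactly; no steric overlap
  cm <- contact_map(receptor, ext$peptide, 8)
  planted <- contact_keys(cm)
  if (!is.null(spec$planted_contacts) &&
      !setequal(spec$planted_contacts, planted)) {
    stop("construction does not realize the requested planted contacts ",
         "(got ", length(planted), ", wanted ",
         length(spec$planted_contacts), ")")
  }
  if (min(residue_min_dist(receptor, partner)) < 2.0) {
    stop("internal error: partner chain overlaps the receptor")
  }
  spec$planted_contacts <- planted
  spec$groove_indices <- base$groove
  ref <- list(receptor = receptor, partner = partner,
              provenance = list(pose_id = "reference", superposition = NULL))
  class(ref) <- "ComplexModel"
  list(complex = ref, receptor = receptor, partner = partner,
       peptide = ext$peptide, slim = ext$slim,
       slim_keys = residue_ids(ext$peptide)$key,
       planted = planted, ref_pose_ca = core_ca, spec = spec)
}

#' Engineered contact table rewarding the planted binding site
#'
#' Builds a 20x20 contact table that is -2.0 for every residue-type pair
#' occurring in the planted contact list and 0 elsewhere, so the designed
#' binding site is the global minimum of the surrogate potential. Used to
#' test that the sampler funnels into a known site.
#'
#' @param toy output of [make_toy_complex()].
#' @param reward energy of a planted-type contact (default -2.0).
#' @return 20x20 symmetric matrix in [energy_model()] order.
#' @export
funnel_energy_table <- function(toy, reward = -2.0) {
  tab <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  rec_ids <- residue_ids(toy$receptor)
  pep_ids <- residue_ids(toy$peptide)
  for (ct in toy$planted) {
    kk <- strsplit(ct, "|", fixed = TRUE)[[1]]
    ta <- rec_ids$aa[match(kk[1], rec_ids$key)]
    tb <- pep_ids$aa[match(kk[2], pep_ids$key)]
    if (ta %in% AA_ORDER && tb %in% AA_ORDER) {
      tab[ta, tb] <- reward
      tab[tb, ta] <- reward
    }
  }
  tab
}

#' Planted conformational basins for clustering tests
#'
#' Generates poses grouped in `m` well-separated rigid basins (each basin a
#' random rigid placement of one straight trace) with small intra-basin
#' jitter, plus the true labels, for exercising cluster recovery.
#'
#' @param m number of basins.
#' @param per_basin poses per basin.
#' @param n_res peptide length.
#' @param separation distance between basin anchor points (A).
#' @param spread intra-basin jitter amplitude (A).
#' @param seed integer seed.
#' @return object of class `PoseSet` with an extra `labels` field.
#' @export
make_planted_poses <- function(m = 3L, per_basin = 20L, n_res = 8L,
                               separation = 30, spread = 0.5, seed = 7L) {
  with_seed(seed, {
    base <- cbind((seq_len(n_res) - 1) * CA_BOND_LENGTH, 0, 0)
    poses <- list(); labels <- integer(0); X <- NULL
    for (b in seq_len(m)) {
      rot <- rotation_about_axis(random_unit_vector(),
                                 stats::runif(1, 0, 2 * pi))
      shift <- random_unit_vector() * separation * b
      center <- base %*% t(rot) + rep(shift, each = n_res)
      for (p in seq_len(per_basin)) {
        pep <- center + matrix(stats::runif(3 * n_res, -spread, spread),
                               n_res, 3)
        poses[[length(poses) + 1L]] <-
          list(snapshot = length(poses) + 1L, replica = b,
               energy = stats::runif(1, -1, 0), pep_ca = pep)
        labels <- c(labels, b)
        X <- rbind(X, as.vector(t(pep)))
      }
    }
    out <- list(poses = poses, coords = X, n_res = n_res,
                sequence = paste(rep("A", n_res), collapse = ""),
                receptor0 = NULL, labels = labels)
    class(out) <- "PoseSet"
    out
  })
}

#' Emit fixture files for a toy complex
#'
#' Writes `receptor.pdb`, `partner.pdb`, `reference.pdb` and
#' `spec-resolved.json` into a directory.
#'
#' @param spec a [toy_complex_spec()].
#' @param dir output directory.
#' @return the resolved spec, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_complex(spec)
  write_pdb(toy$receptor, file.path(dir, "receptor.pdb"))
  write_pdb(toy$partner, file.path(dir, "partner.pdb"))
  write_pdb(list(toy$receptor, toy$partner), file.path(dir, "reference.pdb"))
  jsonlite::write_json(unclass(toy$spec),
                       file.path(dir, "spec-resolved.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(toy$spec)
}
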