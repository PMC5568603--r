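# Four-pseudo-atom coarse-grained representation: alpha carbon (CA), beta
# carbon (CB), united side chain (SC, centroid of side-chain heavy atoms)
# and peptide-bond center (PB, midpoint of C(i) and N(i+1)). The model is
# off-lattice: continuous coordinates with a 3.8 A virtual CA-CA bond.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# typical CA -> side-chain-centroid distances (A), used when a peptide is
# built from sequence alone and no all-atom side chain exists
SC_DISTANCE <- c(
  A = 1.53, C = 2.07, D = 2.48, E = 3.10, F = 3.41, G = 0.00, H = 3.15,
  I = 2.31, K = 3.50, L = 2.60, M = 2.95, N = 2.47, P = 1.87, Q = 3.09,
  R = 4.10, S = 1.90, T = 1.94, V = 1.97, W = 3.87, Y = 3.83, X = 2.50)

CA_BOND_LENGTH <- 3.8
CA_BOND_WINDOW <- c(3.2, 4.3)

new_coarse_chain <- function(chain_id, seq, ca, cb, sc, pb, resno, insert,
                             origin, from) {
  x <- list(chain_id = chain_id, seq = seq, ca = ca, cb = cb, sc = sc,
            pb = pb, resno = resno, insert = insert, origin = origin,
            from = from)
  class(x) <- "CoarseChain"
  x
}

#' @export
print.CoarseChain <- function(x, ...) {
  cat(sprintf("<CoarseChain %s (%s): %d residues>\n",
              x$chain_id, x$origin, length(x$seq)))
  invisible(x)
}

#' Convert an all-atom chain to the coarse-grained representation
#'
#' Each residue is reduced to up to four pseudo-atoms: CA (copied), CB
#' (copied, or rebuilt from N/CA/C by ideal tetrahedral geometry when
#' absent), SC (the centroid of all side-chain heavy atoms, CB included;
#' absent for glycine, equal to CB for alanine) and PB (midpoint of C(i) and
#' N(i+1); absent for the last residue).
#'
#' @param chain a `ChainStructure`; every residue must have a CA atom.
#' @param origin tag, `"receptor"` or `"peptide"`.
#' @param validate check that consecutive CA-CA distances fall in the
#'   virtual-bond window \[3.2, 4.3\] A (chain-break guard).
#' @param allow_missing_side_chains accept residues whose only side-chain
#'   heavy atom is CB even though the residue type has more (e.g. a
#'   backbone-level file); by default this raises, because the SC centroid
#'   would silently degenerate to CB.
#' @return a `CoarseChain`.
#' @export
coarse_grain_chain <- function(chain, origin = "receptor", validate = TRUE,
                               allow_missing_side_chains = FALSE) {
  ids <- residue_ids(chain)
  n <- nrow(ids)
  rows <- residue_rows(chain)
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  name <- chain$atoms$elety
  ca <- cb <- sc <- matrix(NA_real_, n, 3)
  cpos <- npos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    nm <- name[r]
    i_ca <- r[nm == "CA"]
    if (length(i_ca) == 0L) {
      stop("residue ", ids$key[i], " (", ids$resid[i], ") has no CA atom")
    }
    ca[i, ] <- xyz[i_ca[1], ]
    i_n <- r[nm == "N"]; i_c <- r[nm == "C"]
    if (length(i_n)) npos[i, ] <- xyz[i_n[1], ]
    if (length(i_c)) cpos[i, ] <- xyz[i_c[1], ]
    side <- r[!(nm %in% BACKBONE_ATOMS)]
    i_cb <- r[nm == "CB"]
    if (ids$aa[i] != "G") {
      if (length(i_cb)) {
        cb[i, ] <- xyz[i_cb[1], ]
      } else {
        if (!length(i_n) || !length(i_c)) {
          stop("residue ", ids$key[i],
               ": CB reconstruction needs N and C atoms")
        }
        cb[i, ] <- ideal_cb(npos[i, ], ca[i, ], cpos[i, ])
      }
      beyond_cb <- setdiff(side, i_cb)
      if (!length(beyond_cb) && !(ids$aa[i] %in% c("A", "X")) &&
          !allow_missing_side_chains) {
        stop("residue ", ids$key[i], " (", ids$resid[i], ") has no ",
             "side-chain atoms beyond CB; cannot derive the SC centroid ",
             "(backbone-only input?)")
      }
      sc[i, ] <- if (length(side)) colMeans(xyz[side, , drop = FALSE])
                 else cb[i, ]
    }
  }
  if (validate && n > 1L) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    bad <- which(d < CA_BOND_WINDOW[1] | d > CA_BOND_WINDOW[2])
    if (length(bad)) {
      stop("CA-CA virtual bond outside [", CA_BOND_WINDOW[1], ", ",
           CA_BOND_WINDOW[2], "] A at residue pair(s) ",
           paste(ids$key[bad], collapse = ", "),
           " (chain break or non-protein input?)")
    }
  }
  pb <- matrix(NA_real_, n, 3)
  if (n > 1L) {
    ok <- !is.na(cpos[-n, 1]) & !is.na(npos[-1, 1])
    pb[which(ok), ] <- (cpos[-n, , drop = FALSE][ok, , drop = FALSE] +
                        npos[-1, , drop = FALSE][ok, , drop = FALSE]) / 2
  }
  new_coarse_chain(chain$chain_id, ids$aa, ca, cb, sc, pb,
                   ids$resno, ids$insert, origin, from = "allatom")
}

# ideal tetrahedral CB from backbone N, CA, C (standard geometric
# construction with fixed coefficients)
ideal_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(1, 0, 0))
  v / n
}

# outward side-chain direction for each residue of a CA trace: bisector of
# the two virtual bonds (ends: along the terminal bond)
trace_directions <- function(ca) {
  n <- nrow(ca)
  dir <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (i == 1L) dir[i, ] <- unit(ca[1, ] - ca[2, ])
    else if (i == n) dir[i, ] <- unit(ca[n, ] - ca[n - 1, ])
    else {
      d <- unit(ca[i, ] - ca[i - 1, ]) + unit(ca[i, ] - ca[i + 1, ])
      if (sqrt(sum(d^2)) < 1e-6) {
        # collinear: any perpendicular, chosen deterministically
        u <- unit(ca[i + 1, ] - ca[i - 1, ])
        ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        d <- c(u[2] * ref[3] - u[3] * ref[2],
               u[3] * ref[1] - u[1] * ref[3],
               u[1] * ref[2] - u[2] * ref[1])
      }
      dir[i, ] <- unit(d)
    }
  }
  dir
}

# derive CB/SC/PB for a sequence-built peptide from its CA trace
derive_from_trace <- function(seq, ca) {
  n <- length(seq)
  dir <- trace_directions(ca)
  cb <- ca + 1.53 * dir
  sc <- ca + SC_DISTANCE[seq] * dir
  cb[seq == "G", ] <- NA_real_
  sc[seq == "G", ] <- NA_real_
  pb <- matrix(NA_real_, n, 3)
  if (n > 1L) pb[-n, ] <- (ca[-n, , drop = FALSE] + ca[-1, , drop = FALSE]) / 2
  list(cb = cb, sc = sc, pb = pb)
}

#' Random coarse-grained peptide conformation
#'
#' Builds a self-avoiding CA trace with all virtual bonds exactly 3.8 A and
#' no non-consecutive CA pair closer than 4.0 A, then places CB and SC by
#' ideal geometry (side chain along the local bisector, at the residue
#' type's typical CA-centroid distance). PB pseudo-atoms are virtual-bond
#' midpoints. Deterministic for a given seed.
#'
#' @param sequence one-letter peptide sequence, length >= 2.
#' @param seed integer random seed.
#' @param chain_id chain identifier for the result.
#' @param max_restarts how many whole-chain rebuilds to attempt before
#'   giving up.
#' @return a `CoarseChain` with origin `"peptide"`.
#' @export
random_peptide_conformation <- function(sequence, seed, chain_id = "P",
                                        max_restarts = 100L) {
  seq <- strsplit(sequence, "")[[1]]
  if (length(seq) < 2L) stop("sequence must have length >= 2")
  bad <- setdiff(seq, names(SC_DISTANCE))
  if (length(bad)) stop("invalid amino-acid letter(s): ",
                        paste(unique(bad), collapse = ", "))
  ca <- with_seed(seed, self_avoiding_trace(length(seq), max_restarts))
  geo <- derive_from_trace(seq, ca)
  new_coarse_chain(chain_id, seq, ca, geo$cb, geo$sc, geo$pb,
                   seq_along(seq), rep("", length(seq)),
                   origin = "peptide", from = "trace")
}

self_avoiding_trace <- function(n, max_restarts = 100L,
                                bond = CA_BOND_LENGTH, min_sep = 4.0) {
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(0, n, 3)
    ca[2, ] <- c(bond, 0, 0)
    ok <- TRUE
    for (i in seq_len(n)[-(1:2)]) {
      placed <- FALSE
      for (try in 1:200) {
        step <- random_unit_vector() * bond
        cand <- ca[i - 1, ] + step
        prev <- ca[seq_len(i - 2), , drop = FALSE]
        d2 <- rowSums((prev - rep(cand, each = i - 2))^2)
        if (all(d2 >= min_sep^2)) {
          ca[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("failed to build a self-avoiding CA trace of length ", n)
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

#' Interaction sites of a coarse chain
#'
#' The site carrying the contact energy for each residue: the united side
#' chain where present, the CA for glycine.
#'
#' @param cc a `CoarseChain`.
#' @return n x 3 coordinate matrix.
#' @export
interaction_sites <- function(cc) {
  s <- cc$sc
  g <- is.na(s[, 1])
  s[g, ] <- cc$ca[g, , drop = FALSE]
  s
}

#' Convert a coarse chain to a backbone-level ChainStructure
#'
#' @param cc a `CoarseChain`.
#' @param with_cb include CB pseudo-atoms where present.
#' @return a `ChainStructure` with CA (and CB) atoms.
#' @export
coarse_to_chain <- function(cc, with_cb = TRUE) {
  n <- length(cc$seq)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    has_cb <- with_cb && !is.na(cc$cb[i, 1])
    m <- if (has_cb) 2L else 1L
    recs[[i]] <- data.frame(
      resno = rep(cc$resno[i], m), insert = rep(cc$insert[i], m),
      resid = rep(aa_one_to_three(cc$seq[i]), m),
      elety = c("CA", "CB")[seq_len(m)], element = rep("C", m),
      x = c(cc$ca[i, 1], cc$cb[i, 1])[seq_len(m)],
      y = c(cc$ca[i, 2], cc$cb[i, 2])[seq_len(m)],
      z = c(cc$ca[i, 3], cc$cb[i, 3])[seq_len(m)],
      o = rep(1, m), stringsAsFactors = FALSE)
  }
  chain_structure(cc$chain_id, do.call(rbind, recs),
                  source = "coarse-grained model")
}

#' Export a coarse model (or complex) as a backbone-level PDB
#'
#' Writes CA and CB records only, flagged as coarse output in a REMARK.
#' All-atom reconstruction and side-chain repacking are out of scope; the
#' file is meant for visual inspection and downstream refinement tools.
#'
#' @param model a `CoarseChain` or `ComplexModel`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
export_backbone <- function(model, path) {
  rem <- "COARSE-GRAINED MODEL: CA/CB PSEUDO-ATOM RECORDS ONLY"
  if (inherits(model, "CoarseChain")) {
    write_pdb(coarse_to_chain(model), path, remarks = rem)
  } else if (inherits(model, "ComplexModel")) {
    keep_bb <- function(ch) {
      at <- ch$atoms[ch$atoms$elety %in% c("CA", "CB"), , drop = FALSE]
      chain_structure(ch$chain_id, at, ch$source)
    }
    write_pdb(list(keep_bb(model$receptor), keep_bb(model$partner)), path,
              remarks = rem)
  } else {
    stop("model must be a CoarseChain or ComplexModel")
  }
  invisible(path)
}
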