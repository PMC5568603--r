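# Structure I/O: all-atom chains read from / written to standard PDB, chain
# and motif selection, and heavy-atom geometry primitives. Author (PDB)
# numbering with insertion codes is the public residue coordinate system
# throughout the package; ranges are inclusive.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a ChainStructure
#'
#' A `ChainStructure` holds the heavy atoms of one polypeptide chain as a
#' flat atom table in author numbering. It is the common currency of the
#' package: structure I/O, coarse-graining, complex assembly and interface
#' metrics all consume and produce it.
#'
#' @param chain_id single character chain identifier.
#' @param atoms data frame with columns `resno` (integer author residue
#'   number), `insert` (insertion code, `""` if none), `resid` (3-letter
#'   residue name), `elety` (PDB atom name), `element` (element symbol),
#'   `x`, `y`, `z` (coordinates, Angstrom) and `o` (occupancy). Rows must be
#'   grouped by residue in chain order.
#' @param source free-text provenance label.
#' @return object of class `ChainStructure`.
#' @export
chain_structure <- function(chain_id, atoms, source = "") {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  need <- c("resno", "insert", "resid", "elety", "element", "x", "y", "z", "o")
  if (!all(need %in% names(atoms))) {
    stop("atoms table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("chain '", chain_id, "' has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in chain '", chain_id, "'")
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste0(atoms$resno, atoms$insert)
  runs <- rle(key)
  if (anyDuplicated(runs$values)) {
    stop("duplicated residue key(s) in chain '", chain_id, "': ",
         paste(unique(runs$values[duplicated(runs$values)]), collapse = ", "))
  }
  x <- list(chain_id = chain_id, atoms = atoms, source = source)
  class(x) <- "ChainStructure"
  x
}

#' @export
print.ChainStructure <- function(x, ...) {
  cat(sprintf("<ChainStructure %s: %d residues, %d atoms>\n",
              x$chain_id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

# row indices of each residue, in chain order, named by residue key
residue_rows <- function(chain) {
  key <- paste0(chain$atoms$resno, chain$atoms$insert)
  split(seq_along(key), factor(key, levels = unique(key)))
}

#' Number of residues in a chain
#' @param chain a `ChainStructure`.
#' @return integer count.
#' @export
n_residues <- function(chain) length(residue_rows(chain))

#' Residue identity table of a chain
#'
#' @param chain a `ChainStructure`.
#' @return data frame with one row per residue: `resno`, `insert`, `resid`,
#'   `key` (paste of number and insertion code) and `aa` (one-letter code,
#'   `"X"` for non-standard residues).
#' @export
residue_ids <- function(chain) {
  rows <- residue_rows(chain)
  first <- vapply(rows, `[`, integer(1), 1L)
  at <- chain$atoms[first, , drop = FALSE]
  data.frame(resno = at$resno, insert = at$insert, resid = at$resid,
             key = paste0(at$resno, at$insert),
             aa = aa_three_to_one(at$resid),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-letter sequence of a chain
#' @param chain a `ChainStructure`.
#' @return character scalar; non-standard residues appear as `"X"`.
#' @export
chain_sequence <- function(chain) paste(residue_ids(chain)$aa, collapse = "")

aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

aa_one_to_three <- function(aa) {
  out <- suppressWarnings(bio3d::aa123(aa))
  out[is.na(out)] <- "UNK"
  out
}

#' Extract one residue as a ResidueRecord
#'
#' @param chain a `ChainStructure`.
#' @param i residue position in chain order (1-based).
#' @return list with `seq_id`, `insert`, `resname`, `aa`, `atoms` (the atom
#'   table rows) and `coords` (heavy-atom coordinate matrix).
#' @export
chain_residue <- function(chain, i) {
  rows <- residue_rows(chain)
  if (i < 1L || i > length(rows)) stop("residue index out of range: ", i)
  at <- chain$atoms[rows[[i]], , drop = FALSE]
  list(seq_id = at$resno[1], insert = at$insert[1], resname = at$resid[1],
       aa = aa_three_to_one(at$resid[1]), atoms = at,
       coords = as.matrix(at[, c("x", "y", "z")]))
}

# list of per-residue coordinate matrices (fast path for metrics)
residue_coords <- function(chain) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  lapply(residue_rows(chain), function(r) xyz[r, , drop = FALSE])
}

#' Read chains from a PDB file
#'
#' Parses standard ATOM/HETATM records (via bio3d), drops hydrogens,
#' deuteriums and waters, resolves alternate locations by keeping the
#' highest-occupancy copy of each atom (ties broken by altloc letter), and
#' splits the result into one [chain_structure()] per chain. Only one model
#' of a multi-model file is read.
#'
#' @param path PDB file path.
#' @param model_index which MODEL to read (default 1, the first).
#' @return named list of `ChainStructure`, in order of appearance.
#' @export
read_pdb <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in ", path)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  }
  if (is.matrix(pdb$xyz) && n_models > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- infer_element(at$elety[bad])
  at$element <- toupper(elem)

  keep <- !(at$element %in% c("H", "D")) & !(at$resid %in% WATER_RESIDUES)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy protein atoms in ", path)

  # altloc resolution: one copy per (chain, residue, atom name)
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(akey, unique(akey)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  cols <- c("resno", "insert", "resid", "elety", "element", "x", "y", "z", "o")
  chains <- lapply(split(seq_len(nrow(at)),
                         factor(at$chain, levels = unique(at$chain))),
                   function(r) at[r, cols, drop = FALSE])
  out <- Map(function(id, tab) chain_structure(id, tab, source = basename(path)),
             names(chains), chains)
  out
}

infer_element <- function(elety) {
  e <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "SE", "NA", "CL", "BR"),
         two, one)
}

#' Write chains to a PDB file
#'
#' Emits standard fixed-width ATOM records with 1-based serial numbers and a
#' TER record after each chain. A round trip through [read_pdb()] preserves
#' residue order, author numbering and coordinates to 3 decimals (the PDB
#' coordinate precision).
#'
#' @param chains a `ChainStructure` or list of them.
#' @param path output file.
#' @param remarks optional character vector written as REMARK records.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chains, path, remarks = NULL) {
  if (inherits(chains, "ChainStructure")) chains <- list(chains)
  if (length(chains) == 0L) stop("no chains to write")
  lines <- character(0)
  if (!is.null(remarks)) lines <- sprintf("REMARK   3 %s", remarks)
  serial <- 0L
  for (ch in chains) {
    at <- ch$atoms
    if (any(at$resno > 9999L | at$resno < -999L)) {
      stop("residue numbers outside the PDB range in chain '", ch$chain_id, "'")
    }
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, pdb_atom_name(at$elety[i]), at$resid[i],
        ch$chain_id, at$resno[i], ins_chr(at$insert[i]),
        at$x[i], at$y[i], at$z[i], at$o[i], 0,
        substr(at$element[i], 1, 2)))
    }
    serial <- serial + 1L
    last <- at[nrow(at), ]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d%1s",
                              serial %% 100000L, last$resid, ch$chain_id,
                              last$resno, ins_chr(last$insert)))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

pdb_atom_name <- function(name) {
  # columns 13-16: names shorter than 4 characters start in column 14
  if (nchar(name) >= 4L) substr(name, 1, 4)
  else formatC(paste0(" ", name), width = 4, flag = "-")
}

ins_chr <- function(x) if (is.na(x) || x == "") " " else substr(x, 1, 1)

#' Extract a SLiM peptide from a chain by author residue range
#'
#' Selects the inclusive author-numbered range `start_seq_id:end_seq_id`
#' (e.g. the 13-mer 116-128 of an ephrin chain) and returns both the motif
#' definition and the peptide as a standalone chain. The range must be
#' gapless: every integer in the range must be present in the chain.
#'
#' @param chain a `ChainStructure`.
#' @param start_seq_id,end_seq_id inclusive author residue numbers.
#' @return list with `slim` (a `SlimDefinition`: chain_id, start_seq_id,
#'   end_seq_id, sequence) and `peptide` (a `ChainStructure` of the motif
#'   residues).
#' @export
extract_slim <- function(chain, start_seq_id, end_seq_id) {
  if (end_seq_id < start_seq_id) {
    stop("reversed range: ", start_seq_id, "-", end_seq_id)
  }
  ids <- residue_ids(chain)
  missing <- setdiff(start_seq_id:end_seq_id, ids$resno)
  if (length(missing) > 0L) {
    stop("residues missing from chain '", chain$chain_id, "' in range ",
         start_seq_id, "-", end_seq_id, ": ", paste(missing, collapse = ", "))
  }
  sel <- ids$resno >= start_seq_id & ids$resno <= end_seq_id
  rows <- unlist(residue_rows(chain)[sel], use.names = FALSE)
  pep <- chain_structure(chain$chain_id,
                         chain$atoms[rows, , drop = FALSE],
                         source = paste0(chain$source, " slim ",
                                         start_seq_id, "-", end_seq_id))
  slim <- list(chain_id = chain$chain_id, start_seq_id = start_seq_id,
               end_seq_id = end_seq_id,
               sequence = paste(ids$aa[sel], collapse = ""))
  class(slim) <- "SlimDefinition"
  list(slim = slim, peptide = pep)
}

#' Locate a SLiM in a chain by exact sequence match
#'
#' @param chain a `ChainStructure`.
#' @param sequence one-letter peptide sequence to find as an exact substring
#'   of the chain sequence.
#' @return as [extract_slim()].
#' @export
find_slim <- function(chain, sequence) {
  seq_full <- chain_sequence(chain)
  hit <- gregexpr(sequence, seq_full, fixed = TRUE)[[1]]
  if (hit[1] == -1L) stop("sequence '", sequence, "' not found in chain '",
                          chain$chain_id, "'")
  if (length(hit) > 1L) stop("sequence '", sequence, "' is ambiguous in chain '",
                             chain$chain_id, "' (", length(hit), " matches)")
  ids <- residue_ids(chain)
  i0 <- as.integer(hit[1])
  extract_slim(chain, ids$resno[i0], ids$resno[i0 + nchar(sequence) - 1L])
}

#' Minimum heavy-atom distance between two residues
#'
#' The elementary geometric primitive behind contact maps and interface
#' definitions: the smallest Euclidean distance over all pairs of heavy
#' atoms of the two residues.
#'
#' @param res_a,res_b residue records from [chain_residue()] (or any list
#'   with a `coords` coordinate matrix).
#' @return distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(res_a, res_b) {
  a <- res_a$coords; b <- res_b$coords
  if (is.null(a) || nrow(a) == 0L || is.null(b) || nrow(b) == 0L) {
    stop("residue with no heavy atoms")
  }
  sqrt(min_sq_dist(a, b))
}

# minimum squared distance between two coordinate matrices
min_sq_dist <- function(a, b) {
  cross <- tcrossprod(a, b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross
  max(min(d2), 0)
}

#' Apply a rigid transform to a chain
#'
#' @param chain a `ChainStructure`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @return transformed `ChainStructure` (topology untouched).
#' @export
transform_chain <- function(chain, rotation, translation) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(rotation) + rep(translation, each = nrow(xyz))
  chain$atoms$x <- new[, 1]; chain$atoms$y <- new[, 2]; chain$atoms$z <- new[, 3]
  chain
}
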