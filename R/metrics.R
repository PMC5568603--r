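# Interface evaluation against a reference complex: residue contact maps
# (8 A minimum heavy-atom distance, strict <), fraction of native contacts,
# the SLiM interface (peptide + receptor residues within 4.5 A) and
# interface RMSD. Residue correspondence between model and reference is by
# author number + insertion code; no sequence alignment fallback.

#' Inter-chain residue contact map
#'
#' A residue pair is in contact when the minimum distance over all
#' heavy-atom pairs is strictly below the cutoff (default 8 A).
#'
#' @param chain_a,chain_b `ChainStructure`s (receptor and partner/peptide).
#' @param cutoff contact distance cutoff (A).
#' @return object of class `ContactMap`: logical matrix (rows = `chain_a`
#'   residue keys, columns = `chain_b` residue keys) plus the cutoff.
#' @export
contact_map <- function(chain_a, chain_b, cutoff = 8) {
  dm <- residue_min_dist(chain_a, chain_b)
  out <- list(map = dm < cutoff, min_dist = dm, cutoff = cutoff)
  class(out) <- "ContactMap"
  out
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("<ContactMap %dx%d: %d contacts at %.1f A>\n",
              nrow(x$map), ncol(x$map), sum(x$map), x$cutoff))
  invisible(x)
}

# contact key pairs of a ContactMap as "rowkey|colkey" strings
contact_keys <- function(cm) {
  hit <- which(cm$map, arr.ind = TRUE)
  paste(rownames(cm$map)[hit[, 1]], colnames(cm$map)[hit[, 2]], sep = "|")
}

# restrict a chain to residues with the given keys (in chain order)
restrict_chain <- function(chain, keys) {
  rows <- residue_rows(chain)
  sel <- names(rows) %in% keys
  if (!any(sel)) stop("no residues left after restriction")
  chain_structure(chain$chain_id,
                  chain$atoms[unlist(rows[sel], use.names = FALSE), ,
                              drop = FALSE],
                  chain$source)
}

#' Fraction of native contacts
#'
#' The number of native (reference) inter-chain residue contacts that are
#' also present in the model, divided by the total number of native
#' contacts. Contacts use [contact_map()] at `cutoff` (default 8 A); model
#' and reference residues are matched by author numbering, and the native
#' set is restricted to residues present in the model, so a docked peptide
#' can be scored against the motif region of a full reference complex.
#'
#' @param model a `ComplexModel` (or list with `receptor` and `partner`
#'   `ChainStructure`s).
#' @param reference the reference `ComplexModel`.
#' @param cutoff contact cutoff (A).
#' @return list: `fnc`, `native` (native contact count), `model` (model
#'   contact count), `correct` (reproduced native contacts).
#' @export
fraction_native_contacts <- function(model, reference, cutoff = 8) {
  ref_rec <- restrict_chain(reference$receptor,
                            residue_ids(model$receptor)$key)
  ref_par <- restrict_chain(reference$partner,
                            residue_ids(model$partner)$key)
  native <- contact_keys(contact_map(ref_rec, ref_par, cutoff))
  if (length(native) == 0L) {
    stop("reference has no native contacts at cutoff ", cutoff, " A")
  }
  pred <- contact_keys(contact_map(model$receptor, model$partner, cutoff))
  correct <- length(intersect(native, pred))
  list(fnc = correct / length(native), native = length(native),
       model = length(pred), correct = correct)
}

#' The SLiM interface of a reference complex
#'
#' All motif residues of the partner chain, plus every receptor residue
#' whose minimum heavy-atom distance to any motif residue is below the
#' cutoff (default 4.5 A).
#'
#' @param reference a `ComplexModel`.
#' @param slim_keys residue keys (author number + insertion code) of the
#'   motif residues on the partner chain.
#' @param cutoff interface distance cutoff (A).
#' @return object of class `InterfaceDefinition`: `peptide_keys`,
#'   `receptor_keys`, `cutoff`.
#' @export
interface_residues <- function(reference, slim_keys, cutoff = 4.5) {
  if (length(slim_keys) == 0L) stop("empty SLiM residue set")
  par_keys <- residue_ids(reference$partner)$key
  if (!all(slim_keys %in% par_keys)) {
    stop("SLiM keys absent from the partner chain: ",
         paste(setdiff(slim_keys, par_keys), collapse = ", "))
  }
  slim_chain <- restrict_chain(reference$partner, slim_keys)
  dm <- residue_min_dist(reference$receptor, slim_chain)
  rec_keys <- rownames(dm)[apply(dm, 1, min) < cutoff]
  out <- list(peptide_keys = slim_keys, receptor_keys = rec_keys,
              cutoff = cutoff)
  class(out) <- "InterfaceDefinition"
  out
}

# CA coordinates of the given residue keys of a chain, in key order
ca_by_keys <- function(chain, keys) {
  ids <- residue_ids(chain)
  pos <- match(keys, ids$key)
  if (anyNA(pos)) {
    stop("residue keys missing from chain '", chain$chain_id, "': ",
         paste(keys[is.na(pos)], collapse = ", "))
  }
  ca_matrix(chain)[pos, , drop = FALSE]
}

#' Interface RMSD of a model against a reference
#'
#' CA RMSD over the SLiM interface residue set (defined on the reference:
#' the motif plus receptor residues within the interface cutoff), after
#' least-squares superposition of the model's interface CA atoms onto the
#' reference's. Invariant under rigid motion of either structure.
#'
#' @param model,reference `ComplexModel`s sharing residue numbering.
#' @param interface an `InterfaceDefinition` from [interface_residues()].
#' @param fit `"interface"` (default) fits on the interface CA set itself;
#'   `"receptor"` fits on all shared receptor CA atoms instead.
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interface, fit = c("interface", "receptor")) {
  fit <- match.arg(fit)
  n_if <- length(interface$receptor_keys) + length(interface$peptide_keys)
  if (n_if < 3L) stop("degenerate interface: fewer than 3 residues")
  mod_if <- rbind(ca_by_keys(model$receptor, interface$receptor_keys),
                  ca_by_keys(model$partner, interface$peptide_keys))
  ref_if <- rbind(ca_by_keys(reference$receptor, interface$receptor_keys),
                  ca_by_keys(reference$partner, interface$peptide_keys))
  if (fit == "interface") {
    kabsch_superpose(mod_if, ref_if)$rmsd
  } else {
    keys <- intersect(residue_ids(model$receptor)$key,
                      residue_ids(reference$receptor)$key)
    tr <- kabsch_superpose(ca_by_keys(model$receptor, keys),
                           ca_by_keys(reference$receptor, keys))
    fitted <- mod_if %*% t(tr$rotation) +
      rep(tr$translation, each = nrow(mod_if))
    sqrt(mean(rowSums((fitted - ref_if)^2)))
  }
}

#' Evaluate a model complex against a reference
#'
#' Aggregates the interface metrics at their standard cutoffs: fraction of
#' native contacts (8 A), interface RMSD over the 4.5 A SLiM interface,
#' and the ligand RMSD of the motif after receptor superposition.
#'
#' @param model a `ComplexModel`.
#' @param reference the reference `ComplexModel`.
#' @param slim_keys motif residue keys on the partner chain.
#' @param contact_cutoff contact-map cutoff (A).
#' @param interface_cutoff interface-definition cutoff (A).
#' @return object of class `EvaluationReport`: `fnc`, `irmsd`, `lrmsd`,
#'   `native_contacts`, `model_contacts`, `correct_contacts`, cutoffs.
#' @export
evaluate_model <- function(model, reference, slim_keys,
                           contact_cutoff = 8, interface_cutoff = 4.5) {
  nc <- fraction_native_contacts(model, reference, contact_cutoff)
  iface <- interface_residues(reference, slim_keys, interface_cutoff)
  i_rmsd <- irmsd(model, reference, iface)
  rec_keys <- intersect(residue_ids(model$receptor)$key,
                        residue_ids(reference$receptor)$key)
  tr <- kabsch_superpose(ca_by_keys(model$receptor, rec_keys),
                         ca_by_keys(reference$receptor, rec_keys))
  mod_slim <- ca_by_keys(model$partner,
                         intersect(slim_keys,
                                   residue_ids(model$partner)$key))
  ref_slim <- ca_by_keys(reference$partner,
                         intersect(slim_keys,
                                   residue_ids(model$partner)$key))
  fitted <- mod_slim %*% t(tr$rotation) +
    rep(tr$translation, each = nrow(mod_slim))
  l_rmsd <- sqrt(mean(rowSums((fitted - ref_slim)^2)))
  out <- list(fnc = nc$fnc, irmsd = i_rmsd, lrmsd = l_rmsd,
              native_contacts = nc$native, model_contacts = nc$model,
              correct_contacts = nc$correct,
              contact_cutoff = contact_cutoff,
              interface_cutoff = interface_cutoff)
  class(out) <- "EvaluationReport"
  out
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(
    "<Evaluation: fNC %.2f (%d/%d native), iRMSD %.2f A, L-RMSD %.2f A>\n",
    x$fnc, x$correct_contacts, x$native_contacts, x$irmsd, x$lrmsd))
  invisible(x)
}

#' Write an evaluation report as TSV and JSON
#'
#' @param report an `EvaluationReport`.
#' @param path_tsv output TSV path; a JSON twin is written next to it.
#' @return `path_tsv`, invisibly.
#' @export
write_report <- function(report, path_tsv) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(report), sub("\\.tsv$", ".json", path_tsv),
                       auto_unbox = TRUE, digits = 10)
  invisible(path_tsv)
}

#' Read back an evaluation report written by [write_report()]
#'
#' @param path_tsv the TSV path.
#' @return an `EvaluationReport`.
#' @export
read_report <- function(path_tsv) {
  df <- utils::read.delim(path_tsv)
  out <- as.list(df$value)
  names(out) <- df$metric
  class(out) <- "EvaluationReport"
  out
}

#' Export a contact map as a TSV matrix
#'
#' @param cm a `ContactMap`.
#' @param path output TSV path (0/1 matrix, row/column residue keys).
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  utils::write.table(cm$map * 1L, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
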