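# End-to-end protocol: dock the motif sequence to the receptor, select and
# rank poses, rebuild the partner complex on the chosen pose, and (when a
# reference is available) evaluate the interface. Each stage writes its
# artifacts into the run directory and can be re-run from the persisted
# intermediates of the previous one.

#' Pipeline configuration
#'
#' @param receptor receptor input: a PDB path or a `ChainStructure`.
#' @param receptor_chain chain id to take from the receptor file (default:
#'   first chain).
#' @param partner optional partner-protein input (PDB path or
#'   `ChainStructure`); required for complex assembly.
#' @param partner_chain chain id in the partner file.
#' @param slim motif specification: `"CHAIN:START-END"` (author numbering on
#'   the partner chain, e.g. `"B:116-128"`), a raw one-letter sequence, or a
#'   `SlimDefinition`.
#' @param reference optional reference complex (PDB path with receptor and
#'   partner chains, or a `ComplexModel`) for evaluation.
#' @param outdir run directory.
#' @param seed root seed; overrides the docking config's seed.
#' @param docking a [docking_config()].
#' @param per_replica lowest-energy snapshots kept per replica.
#' @param k number of k-medoids clusters.
#' @param k_out representative models to keep.
#' @param pose_rank which representative to assemble on (default 1).
#' @param contact_cutoff,interface_cutoff evaluation cutoffs (A).
#' @param clash_distance clash-report cutoff (A).
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(receptor, receptor_chain = NULL,
                            partner = NULL, partner_chain = NULL,
                            slim, reference = NULL,
                            outdir = tempfile("slimdock_run_"),
                            seed = 1L,
                            docking = docking_config(),
                            per_replica = 100L, k = 10L, k_out = 10L,
                            pose_rank = 1L,
                            contact_cutoff = 8, interface_cutoff = 4.5,
                            clash_distance = 2.5) {
  cfg <- list(receptor = receptor, receptor_chain = receptor_chain,
              partner = partner, partner_chain = partner_chain,
              slim = slim, reference = reference, outdir = outdir,
              seed = as.integer(seed), docking = docking,
              per_replica = as.integer(per_replica), k = as.integer(k),
              k_out = as.integer(k_out), pose_rank = as.integer(pose_rank),
              contact_cutoff = contact_cutoff,
              interface_cutoff = interface_cutoff,
              clash_distance = clash_distance)
  class(cfg) <- "PipelineConfig"
  cfg
}

load_chain <- function(input, chain_id = NULL) {
  if (inherits(input, "ChainStructure")) return(input)
  chains <- read_pdb(input)
  if (is.null(chain_id)) chains[[1]]
  else if (chain_id %in% names(chains)) chains[[chain_id]]
  else stop("chain '", chain_id, "' not found in ", input)
}

resolve_slim <- function(slim, partner) {
  if (inherits(slim, "SlimDefinition")) {
    if (is.null(partner)) return(list(slim = slim, peptide = NULL))
    return(extract_slim(partner, slim$start_seq_id, slim$end_seq_id))
  }
  if (grepl("^[A-Za-z0-9]+:[0-9]+-[0-9]+$", slim)) {
    if (is.null(partner)) stop("a CHAIN:START-END motif needs a partner chain")
    parts <- strsplit(slim, "[:-]")[[1]]
    return(extract_slim(partner, as.integer(parts[2]), as.integer(parts[3])))
  }
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", slim)) {
    stop("motif must be CHAIN:START-END or a one-letter sequence: ", slim)
  }
  if (is.null(partner)) {
    sl <- list(chain_id = "P", start_seq_id = 1L,
               end_seq_id = nchar(slim), sequence = slim)
    class(sl) <- "SlimDefinition"
    return(list(slim = sl, peptide = NULL))
  }
  find_slim(partner, slim)
}

#' Run the full docking-selection-assembly(-evaluation) protocol
#'
#' Executes the three protocol stages in order -- (1) coarse-grained REMC
#' docking of the motif sequence to the receptor, (2) pose selection
#' (energy filter, k-medoids clustering under L-RMSD, density ranking) and
#' reconstruction of the complex by superposing the partner protein onto
#' the chosen pose, (3) a steric clash report on the rebuilt interface in
#' place of external refinement -- and evaluates against a reference
#' complex when one is given. Every artifact lands in the run directory,
#' stamped with the seed and config digest; a rerun with the same seed is
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `trajectory`, `poses`, `ranked`, `complex` (when a
#'   partner was supplied), `clashes`, `report` (when a reference was
#'   supplied) and `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  receptor <- load_chain(config$receptor, config$receptor_chain)
  partner <- if (!is.null(config$partner)) {
    load_chain(config$partner, config$partner_chain)
  }
  sl <- resolve_slim(config$slim, partner)
  say("[dock] motif %s (%d residues) onto chain %s (%d residues)",
      sl$slim$sequence, nchar(sl$slim$sequence), receptor$chain_id,
      n_residues(receptor))

  dock_cfg <- config$docking
  dock_cfg$seed <- config$seed
  traj <- run_docking(receptor, sl$slim$sequence, dock_cfg)
  save_trajectory(traj, file.path(config$outdir, "trajectory"))
  say("[dock] %d snapshots in %.1f s", length(traj$snapshots),
      as.numeric(Sys.time() - t0, units = "secs"))

  t1 <- Sys.time()
  poses <- select_lowest_energy(traj, config$per_replica)
  clusters <- kmedoids_cluster(poses, config$k, seed = config$seed)
  ranked <- rank_and_represent(clusters, poses, config$k_out)
  write_models(ranked, file.path(config$outdir, "models"))
  say("[select] %d poses -> %d clusters -> %d models in %.1f s",
      length(poses$poses), length(clusters), nrow(ranked$ranking),
      as.numeric(Sys.time() - t1, units = "secs"))

  out <- list(trajectory = traj, poses = poses, ranked = ranked,
              outdir = config$outdir)

  if (!is.null(partner)) {
    pose_chain <- ranked_model_chain(ranked, config$pose_rank)
    cplx <- assemble_complex(receptor, partner, sl$slim, pose_chain,
                             pose_id = sprintf("rank_%02d", config$pose_rank))
    clashes <- clash_report(cplx, config$clash_distance)
    write_complex(cplx, file.path(config$outdir, "complex.pdb"),
                  config$clash_distance)
    say("[assemble] pose rank %d, fit rmsd %.2f A, %d clash pair(s)",
        config$pose_rank, cplx$provenance$superposition$rmsd, clashes$count)
    out$complex <- cplx
    out$clashes <- clashes

    if (!is.null(config$reference)) {
      ref <- if (inherits(config$reference, "ComplexModel")) config$reference
      else {
        chains <- read_pdb(config$reference)
        rr <- list(receptor = chains[[receptor$chain_id]],
                   partner = chains[[partner$chain_id]],
                   provenance = list(pose_id = "reference"))
        class(rr) <- "ComplexModel"
        rr
      }
      slim_keys <- paste0(sl$slim$start_seq_id:sl$slim$end_seq_id, "")
      report <- evaluate_model(cplx, ref, slim_keys,
                               config$contact_cutoff,
                               config$interface_cutoff)
      write_report(report, file.path(config$outdir, "evaluation.tsv"))
      say("[evaluate] fNC %.2f, iRMSD %.2f A, L-RMSD %.2f A",
          report$fnc, report$irmsd, report$lrmsd)
      out$report <- report
    }
  }

  resolved <- list(seed = config$seed,
                   digest = traj$digest,
                   slim = unclass(sl$slim),
                   per_replica = config$per_replica, k = config$k,
                   k_out = config$k_out, pose_rank = config$pose_rank,
                   contact_cutoff = config$contact_cutoff,
                   interface_cutoff = config$interface_cutoff,
                   clash_distance = config$clash_distance,
                   docking = strip_config(dock_cfg),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(resolved, file.path(config$outdir, "run.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  out
}
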