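# contact maps, fraction of native contacts, interface definition, iRMSD

two_chain_model <- function(receptor, partner) {
  structure(list(receptor = receptor, partner = partner,
                 provenance = list()), class = "ComplexModel")
}

test_that("contacts obey the strict 8 A minimum heavy-atom rule", {
  a <- tiny_chain("A", list(list(resno = 1, resid = "GLY", elety = "CA",
                                 xyz = c(0, 0, 0))))
  near <- tiny_chain("B", list(list(resno = 1, resid = "GLY", elety = "CA",
                                    xyz = c(7.9, 0, 0))))
  far <- tiny_chain("B", list(list(resno = 1, resid = "GLY", elety = "CA",
                                   xyz = c(8.1, 0, 0))))
  expect_true(contact_map(a, near, 8)$map[1, 1])
  expect_false(contact_map(a, far, 8)$map[1, 1])
  at <- tiny_chain("B", list(list(resno = 1, resid = "GLY", elety = "CA",
                                  xyz = c(8.0, 0, 0))))
  expect_false(contact_map(a, at, 8)$map[1, 1])  # strict <
})

test_that("the contact map equals an exhaustive atom-pair double loop", {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  cm <- contact_map(toy$receptor, toy$peptide, 8)
  ra <- slimdock:::residue_coords(toy$receptor)
  rb <- slimdock:::residue_coords(toy$peptide)
  for (i in seq_along(ra)) {
    for (j in seq_along(rb)) {
      expect_identical(cm$map[i, j], brute_min_dist(ra[[i]], rb[[j]]) < 8)
    }
  }
})

test_that("fNC is 1 on self, 0 when separated, and exact on a planted overlap", {
  toy <- make_toy_complex(toy_complex_spec())
  ref <- toy$complex
  expect_equal(fraction_native_contacts(ref, ref)$fnc, 1.0)

  apart <- ref
  apart$partner <- transform_chain(ref$partner, diag(3), c(0, 0, 500))
  nc0 <- fraction_native_contacts(apart, ref)
  expect_equal(nc0$fnc, 0.0)
  expect_equal(nc0$native, sum(contact_map(toy$receptor, toy$partner, 8)$map))
  # scoring a motif-only model restricts the native set to the motif region
  motif_model <- two_chain_model(toy$receptor, toy$peptide)
  expect_equal(fraction_native_contacts(motif_model, ref)$native,
               length(toy$planted))

  # planted fixture with a known intersection: residues on a line, model
  # reproduces exactly 6 of 10 native contacts by construction
  mk <- function(xs, chain) tiny_chain(chain, lapply(seq_along(xs), function(i)
    list(resno = i, resid = "GLY", elety = "CA", xyz = c(xs[i] * 10, 0, 0))))
  rec <- mk(1:10, "A")
  par_ref <- tiny_chain("B", lapply(1:10, function(i)
    list(resno = i, resid = "GLY", elety = "CA", xyz = c(i * 10, 5, 0))))
  # model: residues 1-6 at native positions, 7-10 pushed out of range
  par_mod <- tiny_chain("B", lapply(1:10, function(i)
    list(resno = i, resid = "GLY", elety = "CA",
         xyz = c(i * 10, ifelse(i <= 6, 5, 100), 0))))
  ref10 <- two_chain_model(rec, par_ref)
  mod6 <- two_chain_model(rec, par_mod)
  nc <- fraction_native_contacts(mod6, ref10)
  expect_equal(nc$native, 10L)
  expect_equal(nc$correct, 6L)
  expect_equal(nc$fnc, 0.6)
  # an empty native set is an error, not NaN
  empty_ref <- two_chain_model(rec, transform_chain(par_ref, diag(3),
                                                    c(0, 500, 0)))
  expect_error(fraction_native_contacts(mod6, empty_ref), "no native contacts")
})

test_that("the interface is the motif plus receptor residues inside 4.5 A", {
  toy <- make_toy_complex(toy_complex_spec())
  iface <- interface_residues(toy$complex, toy$slim_keys, 4.5)
  expect_setequal(iface$peptide_keys, toy$slim_keys)
  # brute-force scan oracle
  dm <- slimdock:::residue_min_dist(toy$receptor, toy$peptide)
  want <- rownames(dm)[apply(dm, 1, min) < 4.5]
  expect_setequal(iface$receptor_keys, want)
  # cutoff monotonicity
  iface8 <- interface_residues(toy$complex, toy$slim_keys, 8)
  expect_true(all(iface$receptor_keys %in% iface8$receptor_keys))
  # far chains: interface reduces to the motif itself
  apart <- toy$complex
  apart$partner <- transform_chain(toy$partner, diag(3), c(0, 0, 500))
  expect_length(interface_residues(apart, toy$slim_keys, 4.5)$receptor_keys, 0L)
  expect_error(interface_residues(toy$complex, character(0)), "empty SLiM")
  expect_error(interface_residues(toy$complex, "9999"), "absent")
})

test_that("iRMSD is zero under rigid motion and exact for a known displacement", {
  toy <- make_toy_complex(toy_complex_spec())
  ref <- toy$complex
  iface <- interface_residues(ref, toy$slim_keys, 4.5)
  expect_equal(irmsd(ref, ref, iface), 0, tolerance = 1e-10)

  rot <- slimdock:::rotation_about_axis(c(1, 1, 0), 1.1)
  moved <- ref
  moved$receptor <- transform_chain(ref$receptor, rot, c(5, -3, 2))
  moved$partner <- transform_chain(ref$partner, rot, c(5, -3, 2))
  expect_equal(irmsd(moved, ref, iface), 0, tolerance = 1e-8)

  # displace the partner motif CAs by a known field; independent
  # Kabsch + RMS oracle computed by hand
  shifted <- ref
  shifted$partner <- transform_chain(ref$partner, diag(3), c(1.5, 0, 0))
  got <- irmsd(shifted, ref, iface)
  mod_if <- rbind(slimdock:::ca_by_keys(shifted$receptor, iface$receptor_keys),
                  slimdock:::ca_by_keys(shifted$partner, iface$peptide_keys))
  ref_if <- rbind(slimdock:::ca_by_keys(ref$receptor, iface$receptor_keys),
                  slimdock:::ca_by_keys(ref$partner, iface$peptide_keys))
  fit <- kabsch_superpose(mod_if, ref_if)
  expect_equal(got, fit$rmsd)
  expect_gt(got, 0)
  # the receptor-fit variant is exposed and differs for a partner-only shift
  expect_gte(irmsd(shifted, ref, iface, fit = "receptor"), got)
})

test_that("evaluate_model aggregates the metrics and round-trips its report", {
  toy <- make_toy_complex(toy_complex_spec())
  ref <- toy$complex
  rep0 <- evaluate_model(ref, ref, toy$slim_keys)
  expect_equal(rep0$fnc, 1.0)
  expect_equal(rep0$irmsd, 0, tolerance = 1e-10)
  expect_equal(rep0$lrmsd, 0, tolerance = 1e-10)

  shifted <- ref
  shifted$partner <- transform_chain(ref$partner, diag(3), c(2, 0, 0))
  rep1 <- evaluate_model(shifted, ref, toy$slim_keys)
  expect_equal(rep1$fnc,
               fraction_native_contacts(shifted, ref)$fnc)
  expect_equal(rep1$irmsd,
               irmsd(shifted, ref,
                     interface_residues(ref, toy$slim_keys, 4.5)))
  expect_lte(rep1$correct_contacts, min(rep1$native_contacts,
                                        rep1$model_contacts))
  # receptor superposition is identity here, so motif L-RMSD is the shift
  expect_equal(rep1$lrmsd, 2, tolerance = 1e-8)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep1, f)
  back <- read_report(f)
  expect_equal(back$fnc, rep1$fnc)
  expect_equal(back$irmsd, rep1$irmsd, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.tsv$", ".json", f)))
})

test_that("contact maps export as a readable TSV matrix", {
  toy <- make_toy_complex(toy_complex_spec(receptor_length = 30L))
  cm <- contact_map(toy$receptor, toy$peptide, 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, f)
  tab <- as.matrix(read.delim(f, row.names = 1, check.names = FALSE))
  expect_equal(unname(tab), unname(cm$map * 1L))
})
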