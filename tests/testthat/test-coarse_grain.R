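# four-pseudo-atom coarse-graining and random peptide construction

test_that("polyglycine reduces to CA-only pseudo-residues", {
  ch <- straight_chain("GGGGG", "A")
  cc <- coarse_grain_chain(ch)
  expect_length(cc$seq, 5L)
  expect_true(all(is.na(cc$cb[, 1])))
  expect_true(all(is.na(cc$sc[, 1])))
  expect_false(anyNA(cc$ca))
})

test_that("alanine SC equals its CB; multi-atom side chains give the centroid", {
  ch <- straight_chain("A", "A")  # single residue still coarse-grains
  ala <- tiny_chain("A", list(
    list(resno = 1, resid = "ALA", elety = "N",  xyz = c(-1.45, 0, 0)),
    list(resno = 1, resid = "ALA", elety = "CA", xyz = c(0, 0, 0)),
    list(resno = 1, resid = "ALA", elety = "C",  xyz = c(1.52, 0, 0)),
    list(resno = 1, resid = "ALA", elety = "CB", xyz = c(0, 1.53, 0))))
  cc <- coarse_grain_chain(ala)
  expect_equal(cc$sc[1, ], c(0, 1.53, 0))
  expect_equal(cc$cb[1, ], c(0, 1.53, 0))

  # 3-atom side chain: SC is the mean of CB, CG, CD
  side <- rbind(c(0, 1.5, 0), c(0.5, 2.6, 0.3), c(0.2, 3.7, -0.4))
  leu <- tiny_chain("A", list(
    list(resno = 1, resid = "LEU", elety = "N",  xyz = c(-1.45, 0, 0)),
    list(resno = 1, resid = "LEU", elety = "CA", xyz = c(0, 0, 0)),
    list(resno = 1, resid = "LEU", elety = "C",  xyz = c(1.52, 0, 0)),
    list(resno = 1, resid = "LEU", elety = "CB", xyz = side[1, ]),
    list(resno = 1, resid = "LEU", elety = "CG", xyz = side[2, ]),
    list(resno = 1, resid = "LEU", elety = "CD", xyz = side[3, ])))
  cc <- coarse_grain_chain(leu)
  expect_equal(cc$sc[1, ], colMeans(side))
})

test_that("a missing CB is rebuilt at the ideal tetrahedral position", {
  full <- tiny_chain("A", list(
    list(resno = 1, resid = "ALA", elety = "N",  xyz = c(-0.52, 1.36, 0)),
    list(resno = 1, resid = "ALA", elety = "CA", xyz = c(0, 0, 0)),
    list(resno = 1, resid = "ALA", elety = "C",  xyz = c(1.52, 0, 0))))
  cc <- coarse_grain_chain(full)
  # ideal geometry: |CA-CB| close to 1.53 and roughly tetrahedral to N and C
  cb <- cc$cb[1, ]
  expect_equal(sqrt(sum(cb^2)), 1.53, tolerance = 0.02)
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_gt(ang(cb, c(-0.52, 1.36, 0)), 100)
  expect_gt(ang(cb, c(1.52, 0, 0)), 100)

  noN <- tiny_chain("A", list(
    list(resno = 1, resid = "ALA", elety = "CA", xyz = c(0, 0, 0)),
    list(resno = 1, resid = "ALA", elety = "C",  xyz = c(1.52, 0, 0))))
  expect_error(coarse_grain_chain(noN), "needs N and C")
})

test_that("PB pseudo-atoms sit at the C(i)/N(i+1) midpoint and end absent", {
  ch <- straight_chain("AAA", "A")
  cc <- coarse_grain_chain(ch)
  at <- ch$atoms
  c1 <- unlist(at[at$resno == 1 & at$elety == "C", c("x", "y", "z")])
  n2 <- unlist(at[at$resno == 2 & at$elety == "N", c("x", "y", "z")])
  expect_equal(cc$pb[1, ], unname((c1 + n2) / 2))
  expect_true(all(is.na(cc$pb[3, ])))
})

test_that("coarse-graining rejects chain breaks and missing CA", {
  a <- straight_chain("AA", "A")
  b <- straight_chain("AA", "A", resno0 = 3L, y = 30)  # 30 A jump
  broken <- chain_structure("A", rbind(a$atoms, b$atoms))
  expect_error(coarse_grain_chain(broken), "virtual bond")
  noca <- tiny_chain("A", list(
    list(resno = 1, resid = "GLY", elety = "N", xyz = c(0, 0, 0))))
  expect_error(coarse_grain_chain(noca), "no CA")
})

test_that("SC centroid lies within the residue's atom cloud radius", {
  toy <- make_toy_complex(toy_complex_spec())
  cc <- coarse_grain_chain(toy$receptor)
  rows <- slimdock:::residue_rows(toy$receptor)
  xyz <- as.matrix(toy$receptor$atoms[, c("x", "y", "z")])
  for (i in seq_along(rows)) {
    if (is.na(cc$sc[i, 1])) next
    max_r <- max(sqrt(rowSums((xyz[rows[[i]], , drop = FALSE] -
                               rep(cc$ca[i, ], each = length(rows[[i]])))^2)))
    expect_lte(sqrt(sum((cc$sc[i, ] - cc$ca[i, ])^2)), max_r + 1e-9)
  }
})

test_that("random peptide conformations have exact bonds and excluded volume", {
  for (seed in 1:20) {
    cc <- random_peptide_conformation("ACDEFGHIKLMNP", seed)
    d <- sqrt(rowSums(diff(cc$ca)^2))
    expect_equal(d, rep(3.8, 12), tolerance = 1e-6)
    dm <- as.matrix(dist(cc$ca))
    sep <- abs(outer(1:13, 1:13, "-"))
    expect_gte(min(dm[sep >= 2]), 4.0)
  }
})

test_that("random peptide conformations are seed-reproducible and validated", {
  a <- random_peptide_conformation("AAAA", 7)
  b <- random_peptide_conformation("AAAA", 7)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ca,
                                random_peptide_conformation("AAAA", 8)$ca)))
  expect_error(random_peptide_conformation("A", 1), "length >= 2")
  expect_error(random_peptide_conformation("AZJ", 1), "invalid amino-acid")
  # glycine gets no side-chain site; others sit at the type's distance
  g <- random_peptide_conformation("GAG", 3)
  expect_true(is.na(g$sc[1, 1]) && is.na(g$sc[3, 1]))
  expect_equal(sqrt(sum((g$sc[2, ] - g$ca[2, ])^2)),
               unname(slimdock:::SC_DISTANCE["A"]))
})

test_that("backbone export round-trips CA coordinates and skips glycine CB", {
  cc <- random_peptide_conformation("AGADA", 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  export_backbone(cc, f)
  lines <- readLines(f)
  expect_true(any(grepl("^REMARK.*COARSE", lines)))
  back <- read_pdb(f)[[1]]
  expect_equal(n_residues(back), 5L)
  gly <- back$atoms[back$atoms$resno == 2, ]
  expect_false("CB" %in% gly$elety)
  expect_equal(slimdock:::ca_matrix(back), cc$ca, tolerance = 1e-3)
  # re-coarse-graining a backbone-only export is refused, not silent
  expect_error(coarse_grain_chain(back), "side-chain atoms")
})
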