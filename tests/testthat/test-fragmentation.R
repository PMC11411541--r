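test_that("molecule validation enforces the applicability domain", {
  expect_error(parse_molecule("notasmiles"), class = "vgc_parse_error")
  expect_error(parse_molecule("C1CCCCC1"), class = "vgc_scope_error")
  expect_error(suppressWarnings(parse_molecule("CCO")),
               class = "vgc_scope_error")          # hydroxyl: associating
  expect_error(suppressWarnings(parse_molecule("CC[NH2]")),
               class = "vgc_scope_error")          # nitrogen outside scope
  expect_error(suppressWarnings(parse_molecule("CC.CC")),
               class = "vgc_scope_error")          # disconnected
  expect_error(suppressWarnings(parse_molecule("ClC=CCl")),
               class = "vgc_stereo_error")         # ambiguous E/Z
  # annotated isomers parse and record their configuration
  mt <- suppressWarnings(parse_molecule("Cl/C=C/Cl"))
  mc <- suppressWarnings(parse_molecule("Cl/C=C\\Cl"))
  expect_identical(mt$stereo$relation, "trans")
  expect_identical(mc$stereo$relation, "cis")
  # non-stereogenic double bonds need no annotation
  expect_s3_class(suppressWarnings(parse_molecule("CC(Cl)=C")),
                  "vgc_molecule")

  mol <- parse_molecule("CCOC")
  expect_identical(mol$carbon_count, 3L)
  expect_equal(mol$molar_mass, 3 * 12.011 + 8 * 1.008 + 15.999)
})

test_that("group matching reproduces the worked fragmentations", {
  counts <- match_groups(parse_molecule("CC(=O)OC"))
  expect_identical(counts[order(names(counts))],
                   c(CH3 = 2L, ester = 1L))
  expect_identical(sort(names(match_groups(parse_molecule("CCC")))),
                   c("CH2", "CH3"))
  expect_identical(match_groups(parse_molecule("CCC"))[["CH2"]], 1L)
  counts_dme <- suppressWarnings(match_groups(parse_molecule("COC")))
  expect_identical(counts_dme[order(names(counts_dme))],
                   c(CH3 = 2L, ether = 1L))
  # formate takes precedence over aldehyde on the shared carbonyl
  cf <- match_groups(parse_molecule("CCOC=O"))
  expect_identical(cf[["formate"]], 1L)
  expect_false("aldehyde" %in% names(cf))
  # second-order halogenation contexts are counted additively
  c22 <- match_groups(parse_molecule("CC(Cl)(Cl)C"))
  expect_identical(c22[[">C<(X2)"]], 1L)
  expect_identical(c22[["Cl"]], 2L)
  c11 <- match_groups(parse_molecule("CCC(F)F"))
  expect_identical(c11[["CH(X2)"]], 1L)
})

test_that("heavy-atom partition holds across generated in-scope molecules", {
  # fixture molecules plus programmatically grown alkyl chains
  set.seed(402)
  grow_alkane <- function(n) paste(rep("C", n), collapse = "")
  smiles <- c(vgc_fixture_molecules("oxygenated")$smiles[1:8],
              vapply(3:8, grow_alkane, ""),
              "CC(C)CC", "CCC(C)(C)C", "CC(C)C(C)C")
  groups <- vgc_group_defs()
  for (s in smiles) {
    frag <- quiet_frag(s)
    ha <- groups$heavy_atoms[match(names(frag$group_counts), groups$id)]
    expect_identical(sum(ha * frag$group_counts),
                     frag$molecule$heavy_count,
                     info = s)
  }
  # unclaimable heavy atoms are a typed fragmentation error: restrict the
  # group set so oxygen has no owner
  carbon_only <- groups[!grepl("ether|ester|formate|aldehyde|ketone",
                               groups$id), ]
  expect_error(match_groups(parse_molecule("CCOC"), carbon_only),
               class = "vgc_fragment_error")
})

test_that("conformers are deterministic, plausible, and stereo-faithful", {
  f1 <- quiet_frag("CCOC", seed = 11L)
  f2 <- quiet_frag("CCOC", seed = 11L)
  expect_identical(f1$conformer$coords, f2$conformer$coords)

  mol <- suppressWarnings(parse_molecule("CC"))
  conf <- suppressWarnings(embed_conformer(mol, seed = 42L))
  cc <- sqrt(sum((conf$coords[1, ] - conf$coords[2, ])^2))
  expect_lt(abs(cc - 1.53), 0.05)

  ct <- suppressWarnings(embed_conformer(
    suppressWarnings(parse_molecule("Cl/C=C/Cl")), seed = 42L))
  tau <- abs(vectorgc:::dihedral(ct$coords[1, ], ct$coords[2, ],
                                 ct$coords[3, ], ct$coords[4, ]))
  expect_lt(abs(tau - 180), 5)

  # bonded distances within the chemically plausible window
  gt <- suppressWarnings(parse_molecule("Cl/C=C/Cl"))$graph
  d <- sqrt(rowSums((ct$coords[gt$bonds$a, , drop = FALSE] -
                       ct$coords[gt$bonds$b, , drop = FALSE])^2))
  expect_true(all(d > 0.7 & d < 2.5))
})

test_that("cis and trans isomers share counts but differ in geometry", {
  fc <- quiet_frag("ClC/C=C\\Cl")
  ft <- quiet_frag("ClC/C=C/Cl")
  expect_identical(fc$group_counts[order(names(fc$group_counts))],
                   ft$group_counts[order(names(ft$group_counts))])
  tab <- vgc_table_synthetic()
  expect_gt(abs(predict_mu(fc, tab) - predict_mu(ft, tab)), 0.2)
})

test_that("oriented bonds: normalization, composition, rotation covariance", {
  frag <- quiet_frag("CC(=O)OC")
  ob <- frag$oriented_bonds
  norms <- sqrt(ob$ex^2 + ob$ey^2 + ob$ez^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_identical(sum(ob$bond_id == "O-C"), 2L)
  expect_identical(sum(ob$bond_id == "O=C"), 1L)

  # rigid rotation of the conformer rotates every unit vector accordingly
  mol <- frag$molecule
  conf <- frag$conformer
  set.seed(7)
  R <- random_rotation()
  conf_rot <- conf
  conf_rot$coords <- conf$coords %*% t(R)
  ob_rot <- detect_oriented_bonds(mol, conf_rot)
  rotated <- as.matrix(ob[, c("ex", "ey", "ez")]) %*% t(R)
  expect_equal(as.matrix(ob_rot[, c("ex", "ey", "ez")]), rotated,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("halogenated alkenes are in scope and batch interface collects errors", {
  frag <- quiet_frag("FC(F)(F)C=C")
  expect_identical(frag$group_counts[["C(X3)"]], 1L)
  expect_identical(frag$group_counts[["F"]], 3L)

  res <- suppressWarnings(fragment_molecules(
    tibble::tibble(smiles = c("CCCC", "C1CCC1"))))
  expect_true(is.na(res$error[1]))
  expect_match(res$error[2], "cyclic")
  expect_identical(res$carbon_count[1], 4L)
  expect_identical(res$n_polar_bonds[1], 0L)
})
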