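table1_row <- function(id) {
  g <- vgc_table_carbon()$groups
  g[g$id == id, ]
}

test_that("additive sum rules reproduce hand-computed homologue values", {
  tab <- vgc_table_carbon()
  frag <- quiet_frag("CCCC")
  got <- predict_msigmaeps(frag, tab)

  # independent oracle: direct arithmetic on the two carbon rows
  ch3 <- table1_row("CH3"); ch2 <- table1_row("CH2")
  m <- 2 * ch3$m + 2 * ch2$m
  msig3 <- 2 * ch3$m * ch3$sigma^3 + 2 * ch2$m * ch2$sigma^3
  meps <- 2 * ch3$m * ch3$epsilon_k + 2 * ch2$m * ch2$epsilon_k
  expect_identical(got[["m"]], m)               # 2.13608 exactly
  expect_equal(got[["sigma"]], (msig3 / m)^(1 / 3), tolerance = 1e-14)
  expect_equal(got[["epsilon_k"]], meps / m, tolerance = 1e-14)
  expect_equal(got[["epsilon_k"]], 233.79, tolerance = 1e-4)

  # single-group identity: one CH3 occurrence returns its own row exactly
  ident <- predict_msigmaeps(fake_frag(c(CH3 = 1L)), tab)
  expect_identical(ident[["m"]], ch3$m)
  expect_equal(ident[["sigma"]], ch3$sigma, tolerance = 1e-12)
  expect_equal(ident[["epsilon_k"]], ch3$epsilon_k, tolerance = 1e-12)
})

test_that("m, m*sigma^3 and m*eps grow linearly along a homologous series", {
  tab <- vgc_table_carbon()
  res <- lapply(c("CCC", "CCCC", "CCCCC", "CCCCCC"),
                function(s) predict_msigmaeps(quiet_frag(s), tab))
  m <- vapply(res, `[[`, 0, "m")
  msig3 <- vapply(res, function(r) r[["m"]] * r[["sigma"]]^3, 0)
  meps <- vapply(res, function(r) r[["m"]] * r[["epsilon_k"]], 0)
  for (v in list(m, msig3, meps)) {
    expect_equal(diff(v, differences = 2), rep(0, 2), tolerance = 1e-9)
  }
})

test_that("coverage and physicality errors are typed", {
  tab <- vgc_table_carbon()
  expect_error(predict_msigmaeps(fake_frag(c(ether = 1L)), tab),
               class = "vgc_coverage_error")
  # a combination summing to nonpositive m is rejected
  expect_error(predict_msigmaeps(fake_frag(c(`>C<` = 2L, CH3 = 1L)), tab),
               class = "vgc_parameter_error")
  expect_error(
    predict_mu(fake_frag(c(CH3 = 2L), oriented("X-C", c(1, 0, 0))), tab),
    class = "vgc_coverage_error")
})

test_that("vector dipole sum rule: cancellation, orthogonality, closed form", {
  tab <- vgc_table_synthetic()
  anti <- dplyr::bind_rows(oriented("Cl-C", c(1, 0, 0)),
                           oriented("Cl-C", c(-1, 0, 0)))
  expect_identical(predict_mu(fake_frag(c(CH3 = 1L), anti), tab), 0)

  ortho <- dplyr::bind_rows(oriented("O-C", c(1, 0, 0)),
                            oriented("O-C", c(0, 1, 0)))
  mu_oc <- tab$bonds$mu[tab$bonds$id == "O-C"]
  expect_equal(predict_mu(fake_frag(c(CH3 = 1L), ortho), tab),
               sqrt(2) * mu_oc, tolerance = 1e-12)

  # dimethyl ether: mu = 2 mu_OC cos(theta/2) with theta the C-O-C angle
  frag <- quiet_frag("COC")
  co <- frag$conformer$coords
  g <- frag$molecule$graph
  o <- which(g$elements == "O")
  cs <- g$adj[[o]][g$elements[g$adj[[o]]] == "C"]
  v1 <- co[cs[1], ] - co[o, ]; v2 <- co[cs[2], ] - co[o, ]
  theta <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  expect_equal(predict_mu(frag, tab), 2 * mu_oc * cos(theta / 2),
               tolerance = 1e-10)
})

test_that("dipole invariances: hydrocarbons, triangle bound, scaling, order", {
  tab <- vgc_table_synthetic()
  expect_identical(predict_mu(quiet_frag("CCCC"), tab), 0)
  expect_identical(predict_mu(quiet_frag("C/C=C/C"), tab), 0)  # alkene too

  frag <- quiet_frag("CC(=O)OC")
  mu <- predict_mu(frag, tab)
  live <- frag$oriented_bonds[!frag$oriented_bonds$fixed_zero, ]
  mu_sum <- sum(tab$bonds$mu[match(live$bond_id, tab$bonds$id)])
  expect_lte(mu, mu_sum + 1e-12)

  # scaling all bond contributions by c scales mu by exactly c
  tab2 <- tab; tab2$bonds$mu <- 0.37 * tab$bonds$mu
  expect_equal(predict_mu(frag, tab2), 0.37 * mu, tolerance = 1e-12)

  # permutation of the bond listing order leaves mu unchanged
  frag_perm <- frag
  frag_perm$oriented_bonds <- frag$oriented_bonds[rev(seq_len(
    nrow(frag$oriented_bonds))), ]
  expect_identical(predict_mu(frag_perm, tab), mu)
})

test_that("fluoroethene isomer pair: trans cancels, cis does not", {
  tab <- vgc_table_synthetic()
  mu_trans <- predict_mu(quiet_frag("F/C=C/F"), tab)
  mu_cis <- predict_mu(quiet_frag("F/C=C\\F"), tab)
  expect_lt(mu_trans, 0.15)
  expect_gt(mu_cis, 1)
})

test_that("parameter tables round-trip through JSON and CSV", {
  tab <- vgc_table_synthetic()
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(tab, jf)
  write_parameter_table(tab, cf)
  back_j <- read_parameter_table(jf)
  back_c <- read_parameter_table(cf)
  for (back in list(back_j, back_c)) {
    expect_equal(back$groups, tab$groups, tolerance = 1e-9)
    expect_equal(back$bonds, tab$bonds, tolerance = 1e-9)
  }
  # the adopted-carbon file carries exactly the seven carbon groups
  expect_identical(nrow(vgc_table_carbon()$groups), 7L)
  expect_error(read_parameter_table("nope.xlsx"), class = "vgc_config_error")
})

test_that("full prediction pipeline returns tidy parameter tables", {
  out <- suppressWarnings(
    predict_parameters(c("CCCC", "F/C=C/F", "F/C=C\\F", "C1CC1")))
  expect_s3_class(out, "tbl_df")
  expect_equal(out$m[1], 2.13608, tolerance = 1e-12)
  expect_identical(out$mu[1], 0)          # alkanes carry no dipole
  expect_lt(out$mu[2], 0.15)              # trans difluoroethene cancels
  expect_gt(out$mu[3], 1)                 # cis does not
  expect_match(out$error[4], "cyclic")
  expect_true(all(out$eps_ab_k == 0 & out$kappa_ab == 0 & out$q == 0))
})
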