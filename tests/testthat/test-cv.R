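test_that("mapd matches hand-evaluated cases and is scale invariant", {
  expect_identical(mapd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mapd(1.1 * c(5, 9), c(5, 9)), 10, tolerance = 1e-12)
  expect_equal(mapd(c(2, 1), c(1, 2)), 75)
  expect_equal(mapd(c(2, 1) * 13, c(1, 2) * 13), 75)
  expect_error(mapd(numeric(0), numeric(0)), class = "vgc_config_error")
  expect_error(mapd(c(1, 2), c(1, -2)), class = "vgc_config_error")
})

test_that("dipole comparison statistics follow the standard definitions", {
  p <- c(a = 1.0, b = 2.0, c = 3.0)
  expect_equal(compare_dipoles(p, p),
               list(pearson_r = 1, mad_D = 0, n = 3L), tolerance = 1e-12)
  shifted <- compare_dipoles(p + 0.5, p)
  expect_equal(shifted$pearson_r, 1, tolerance = 1e-12)
  expect_equal(shifted$mad_D, 0.5, tolerance = 1e-12)
  anti <- compare_dipoles(c(a = 3, b = 2, c = 1), p)
  expect_lt(anti$pearson_r, 0)
  # intersection semantics: extra keys on either side are ignored
  expect_identical(compare_dipoles(c(p, d = 9), p)$n, 3L)
  expect_error(compare_dipoles(c(a = 1), c(a = 1)),
               class = "vgc_config_error")
})

test_that("LOO-CV refits once per substance and recovers noise-free data", {
  bench <- small_cv_bench()
  cv <- bench$cv
  expect_identical(nrow(cv$fold_fits), 3L)          # 3 substances, no pairs
  # acetone is unpredictable: its ketone group and O=C bond occur nowhere
  # else, and that is reported rather than dropped
  expect_identical(cv$unpredictable$substance_id, "acetone")
  expect_match(cv$unpredictable$missing, "ketone")
  # the ethers' held-out predictions are essentially exact
  expect_true(all(cv$per_substance$mapd < 0.1))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_identical(glance(cv)$method, "vector_gc")
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("cis/trans partners are held out jointly", {
  # three ethers + one ester (keeps the diester pair predictable) + pair
  fx <- vgc_fixture_molecules("oxygenated")[c(1, 2, 3, 15, 17, 18), ]
  expect_identical(fx$isomer_pair_id[5], fx$isomer_pair_id[6])
  truth <- vgc_table_synthetic()
  ds <- suppressWarnings(generate_dataset(fx, surrogate_evaluator(),
                                          vgc_noise_model(0, 0),
                                          truth = truth, seed = 17,
                                          t_frac = c(0.55, 0.8)))
  init <- truth
  init$groups$m[init$groups$id == "ester"] <- 1
  cfg <- vgc_fit_config(table = init, seed = 17,
                        free_groups = c("ether", "ester"),
                        free_bonds = character(0), n_starts = 4)
  cv <- vgc_loo_cv(ds, surrogate_evaluator(), cfg,
                   designs = attr(ds, "designs"))
  expect_identical(nrow(cv$fold_fits), 5L)          # 6 substances, 1 pair
  # both diester isomers are reported from the same fold
  expect_true(all(c("maleate", "fumarate") %in%
                    cv$per_substance$substance_id))
})

test_that("a substance without data reproduces the full-data fit in its fold", {
  bench <- small_cv_bench()
  ds <- bench$ds
  extra_sub <- dplyr::bind_rows(
    ds$substances,
    tibble::tibble(substance_id = "ghost", smiles = "CCCOC",
                   isomer_pair_id = "ghost"))
  ds2 <- as_property_dataset(ds$points, extra_sub)
  designs2 <- c(attr(ds, "designs"),
                list(ghost = precompute_designs(
                  structure(list(substances = extra_sub[4, ]),
                            class = "vgc_dataset"), seed = 13)[[1]]))
  cv2 <- vgc_loo_cv(ds2, surrogate_evaluator(), bench$cfg,
                    designs = designs2)
  full <- vgc_fit(ds2, surrogate_evaluator(), bench$cfg,
                  designs = designs2)
  ghost_obj <- cv2$fold_fits$objective[cv2$fold_fits$fold == "ghost"]
  expect_equal(ghost_obj, full$objective_value, tolerance = 1e-10)
})

test_that("shared-cutoff comparison keeps only points solvable by both", {
  pts_a <- tibble::tibble(
    substance_id = "s1", property = "rho_liq_sat", T_K = c(300, 320, 340),
    p_Pa = NA_real_, exp = c(500, 480, 460),
    pred = c(505, 478, 450), status = c("ok", "ok", "ok"),
    mu_pred = 1, tc_pred = 400)
  pts_b <- pts_a
  pts_b$pred <- c(510, 470, NA)
  pts_b$status <- c("ok", "ok", "no_solution")   # lower predicted Tc
  a <- structure(list(points = pts_a, method = "vector_gc"),
                 class = "vgc_cv")
  b <- structure(list(points = pts_b, method = "mu_zero"), class = "vgc_cv")
  cmp <- compare_cv_reports(a, b)
  expect_identical(unique(cmp$n_shared_points), 2L)
  # medians recomputed over the shared subcritical window only
  expect_equal(cmp$median_mapd[cmp$method == "vector_gc"],
               mapd(c(505, 478), c(500, 480)), tolerance = 1e-12)
  expect_equal(cmp$median_mapd[cmp$method == "mu_zero"],
               mapd(c(510, 470), c(500, 480)), tolerance = 1e-12)
})
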