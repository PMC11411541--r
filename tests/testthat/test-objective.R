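# A one-substance dataset built directly from evaluator output, optionally
# with a fixed log-offset r applied to the vapor-pressure values.
tiny_dataset <- function(properties = "psat", T_K = 300, ln_offset = 0,
                         params = butane_exact()) {
  ev <- surrogate_evaluator()
  q <- tibble::tibble(property = properties, T_K = T_K,
                      p_Pa = ifelse(properties == "rho_liq", 2e5, NA_real_))
  vals <- evaluate_properties(ev, params, q)$value
  as_property_dataset(tibble::tibble(
    substance_id = "butane", smiles = "CCCC", property = properties,
    T_K = T_K, p_Pa = q$p_Pa, value = vals * exp(ln_offset),
    source = "unit-test"))
}

test_that("objective is zero for a perfect fit and pins the stated form", {
  ds <- tiny_dataset(rep("psat", 5), seq(260, 300, 10))
  tab <- vgc_table_carbon()
  cfg <- vgc_fit_config(table = tab, free_groups = character(0),
                        free_bonds = character(0))
  expect_equal(as.numeric(vgc_objective(tab, ds, surrogate_evaluator(), cfg)),
               0, tolerance = 1e-20)

  # one substance, one psat point with log-ratio r: L = 3 r^2 exactly
  r <- 0.37
  ds1 <- tiny_dataset("psat", 300, ln_offset = r)
  L <- vgc_objective(tab, ds1, surrogate_evaluator(), cfg)
  expect_equal(as.numeric(L), 3 * r^2, tolerance = 1e-12)
})

test_that("duplicating every point scales a block's weight by sqrt(2)", {
  tab <- vgc_table_carbon()
  cfg <- vgc_fit_config(table = tab, free_groups = character(0),
                        free_bonds = character(0))
  ds <- tiny_dataset(rep("psat", 4), seq(270, 300, 10), ln_offset = 0.2)
  dup_points <- dplyr::bind_rows(ds$points, ds$points)
  ds_dup <- as_property_dataset(dup_points, ds$substances)
  L1 <- as.numeric(vgc_objective(tab, ds, surrogate_evaluator(), cfg))
  L2 <- as.numeric(vgc_objective(tab, ds_dup, surrogate_evaluator(), cfg))
  # total block weight goes from w sqrt(N) to w sqrt(2N): L halves per
  # point but doubles in count -> L2 = L1 / sqrt(2)
  expect_equal(L2, L1 / sqrt(2), tolerance = 1e-12)
})

test_that("objective is invariant to point order and substance labels", {
  ds <- suppressWarnings(generate_dataset(
    vgc_fixture_molecules("oxygenated")[1:3, ], surrogate_evaluator(),
    vgc_noise_model(0.05, 0.01), seed = 3, t_frac = c(0.55, 0.8)))
  tab <- attr(ds, "truth"); designs <- attr(ds, "designs")
  cfg <- vgc_fit_config(table = tab, free_groups = character(0),
                        free_bonds = character(0))
  L0 <- as.numeric(vgc_objective(tab, ds, surrogate_evaluator(), cfg,
                                 designs))
  set.seed(1)
  shuffled <- as_property_dataset(
    ds$points[sample(nrow(ds$points)), ], ds$substances)
  expect_equal(as.numeric(vgc_objective(tab, shuffled, surrogate_evaluator(),
                                        cfg, designs)), L0,
               tolerance = 1e-14)

  relabel <- function(x) paste0("s_", x)
  ds2 <- as_property_dataset(
    dplyr::mutate(ds$points, substance_id = relabel(substance_id)),
    dplyr::mutate(ds$substances, substance_id = relabel(substance_id)))
  designs2 <- stats::setNames(designs, relabel(names(designs)))
  expect_equal(as.numeric(vgc_objective(tab, ds2, surrogate_evaluator(),
                                        cfg, designs2)), L0,
               tolerance = 1e-14)
})

test_that("unsolvable saturation points are skipped and logged", {
  # grid reaching beyond the pseudo-critical temperature
  ev <- surrogate_evaluator()
  params <- butane_exact()
  tc <- vectorgc:::evaluator_tc(ev, params)
  ds <- tiny_dataset(rep("psat", 3), c(0.8, 0.85, 0.9) * tc)
  hot <- ds$points
  hot$T_K[3] <- 1.1 * tc
  ds_hot <- as_property_dataset(hot, ds$substances)
  tab <- vgc_table_carbon()
  cfg <- vgc_fit_config(table = tab, free_groups = character(0),
                        free_bonds = character(0))
  L <- vgc_objective(tab, ds_hot, ev, cfg)
  expect_identical(attr(L, "n_evaluable"), 2L)
  expect_identical(nrow(attr(L, "skipped")), 1L)
  expect_identical(attr(L, "skipped")$T_K, 1.1 * tc)

  # a dataset with nothing evaluable is a typed objective error
  all_hot <- hot; all_hot$T_K <- rep(1.2 * tc, 3)
  expect_error(vgc_objective(tab, as_property_dataset(all_hot,
                                                      ds$substances),
                             ev, cfg),
               class = "vgc_objective_error")
})
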