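# A compact ether-only bench: four ethers, one free group and one free
# bond; fast enough for repeated fitting in unit tests.
ether_fixtures <- function() {
  vgc_fixture_molecules("oxygenated")[1:4, ]
}

ether_config <- function(table = vgc_default_initial_table(), ...) {
  vgc_fit_config(table = table, free_groups = "ether",
                 free_bonds = "O-C", seed = 5, n_starts = 4, ...)
}

ether_dataset <- function(noise = vgc_noise_model(0, 0), seed = 5,
                          n_temps = 8) {
  suppressWarnings(generate_dataset(ether_fixtures(), surrogate_evaluator(),
                                    noise, seed = seed, n_temps = n_temps,
                                    t_frac = c(0.55, 0.8)))
}

test_that("noise-free fitting recovers the generating contributions", {
  ds <- cached("ether_clean", ether_dataset)
  truth <- attr(ds, "truth")
  fit <- vgc_fit(ds, surrogate_evaluator(), ether_config(),
                 designs = attr(ds, "designs"))
  expect_true(fit$converged)
  expect_lt(fit$objective_value, 1e-12)
  got <- fit$table$groups[fit$table$groups$id == "ether", ]
  want <- truth$groups[truth$groups$id == "ether", ]
  expect_equal(got$m, want$m, tolerance = 1e-4)
  expect_equal(got$sigma, want$sigma, tolerance = 1e-4)
  expect_equal(got$epsilon_k, want$epsilon_k, tolerance = 1e-4)
  expect_equal(fit$table$bonds$mu[fit$table$bonds$id == "O-C"],
               truth$bonds$mu[truth$bonds$id == "O-C"], tolerance = 1e-4)
  # frozen entries never move
  expect_identical(fit$table$groups$m[fit$table$groups$id == "CH3"],
                   vgc_table_carbon()$groups$m[1])
})

test_that("recovery error shrinks as the dataset grows (2 % noise)", {
  err_at <- function(n_temps) {
    ds <- ether_dataset(vgc_noise_model(0.02, 0.005), seed = 5,
                        n_temps = n_temps)
    truth <- attr(ds, "truth")
    fit <- vgc_fit(ds, surrogate_evaluator(), ether_config(),
                   designs = attr(ds, "designs"))
    got <- fit$table$groups[fit$table$groups$id == "ether", ]
    want <- truth$groups[truth$groups$id == "ether", ]
    max(abs(c(got$m / want$m, got$sigma / want$sigma,
              got$epsilon_k / want$epsilon_k) - 1))
  }
  expect_lt(err_at(24), err_at(3))
})

test_that("hydrocarbon data leave bond contributions unidentified but bounded", {
  alkanes <- tibble::tibble(
    substance_id = c("propane", "butane", "pentane"),
    name = substance_id, smiles = c("CCC", "CCCC", "CCCCC"),
    isomer_pair_id = substance_id, class = "hydrocarbon")
  ds <- suppressWarnings(generate_dataset(alkanes, surrogate_evaluator(),
                                          vgc_noise_model(0, 0), seed = 9,
                                          t_frac = c(0.55, 0.8)))
  designs <- attr(ds, "designs")
  tab <- vgc_table_synthetic()
  cfg <- vgc_fit_config(table = tab, free_groups = character(0),
                        free_bonds = "Cl-C")
  # objective does not depend on a bond that never occurs
  t1 <- tab; t1$bonds$mu[t1$bonds$id == "Cl-C"] <- 0
  t2 <- tab; t2$bonds$mu[t2$bonds$id == "Cl-C"] <- 3
  cfg0 <- vgc_fit_config(table = tab, free_groups = character(0),
                         free_bonds = character(0))
  L1 <- as.numeric(vgc_objective(t1, ds, surrogate_evaluator(), cfg0, designs))
  L2 <- as.numeric(vgc_objective(t2, ds, surrogate_evaluator(), cfg0, designs))
  expect_identical(L1, L2)
})

test_that("lower bounds hold when the truth sits on the boundary", {
  # truth O-C dipole of zero plus noise: the fitted value stays >= 0
  truth0 <- vgc_table_synthetic()
  truth0$bonds$mu[truth0$bonds$id == "O-C"] <- 0
  ds <- suppressWarnings(generate_dataset(
    ether_fixtures(), surrogate_evaluator(),
    vgc_noise_model(0.02, 0.005), truth = truth0, seed = 8,
    t_frac = c(0.55, 0.8)))
  fit <- vgc_fit(ds, surrogate_evaluator(), ether_config(),
                 designs = attr(ds, "designs"))
  mu_fit <- fit$table$bonds$mu[fit$table$bonds$id == "O-C"]
  expect_gte(mu_fit, 0)
})

test_that("the mu = 0 benchmark variant freezes every bond at zero", {
  cfg <- ether_config()
  v <- mu_zero_variant(cfg)
  expect_identical(mu_zero_variant(v), v)          # idempotent
  expect_true(v$mu_zero)
  expect_length(v$free_bonds, 0)
  ds <- cached("ether_clean", ether_dataset)
  fit <- vgc_fit(ds, surrogate_evaluator(), v, designs = attr(ds, "designs"))
  expect_true(all(fit$table$bonds$mu == 0))
})

test_that("fit accessors: tidy, glance, convergence history", {
  ds <- cached("ether_clean", ether_dataset)
  fit <- vgc_fit(ds, surrogate_evaluator(), ether_config(),
                 designs = attr(ds, "designs"))
  td <- tidy(fit)
  expect_true(all(c("kind", "id", "free", "m", "mu") %in% names(td)))
  expect_identical(sum(td$free & td$kind == "group"), 1L)
  gl <- glance(fit)
  expect_identical(gl$converged, TRUE)
  expect_gt(gl$n_evaluations, 0L)
  # best-so-far objective trace is monotone non-increasing
  expect_true(all(diff(cummin(fit$history)) <= 0))
  expect_s3_class(autoplot(fit), "ggplot")
})
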