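#' Shipped fixture molecules
#'
#' A set of 45 in-scope molecules (3-8 carbons; ethers, esters, formates,
#' ketones, aldehydes, chloro-/fluoro-/bromo-/iodo-alkanes and -alkenes)
#' spanning every shipped group and polar bond, including three cis/trans
#' pairs (1,2- and 1,3-dichloropropene and diethyl but-2-enedioate). Every free group and bond occurs in at least two
#' isomer-pair-disjoint fixtures, so each remains identifiable when a pair
#' is held out in leave-one-out runs. Together with the synthetic truth
#' table ([vgc_table_synthetic()]) and the surrogate evaluator this gives a
#' fully self-contained simulation bench; the real regression datasets of
#' the original calibration are license-bound.
#'
#' @param class `"both"`, `"oxygenated"` or `"halogenated"`.
#' @return Tibble with `substance_id`, `name`, `smiles`, `isomer_pair_id`,
#'   `class`.
#' @export
vgc_fixture_molecules <- function(class = c("both", "oxygenated",
                                            "halogenated")) {
  class <- match.arg(class)
  fx <- tibble::tribble(
    ~substance_id, ~name, ~smiles, ~isomer_pair_id, ~class,
    "mee",        "methyl ethyl ether",     "CCOC",        "mee",        "oxygenated",
    "dee",        "diethyl ether",          "CCOCC",       "dee",        "oxygenated",
    "mpe",        "methyl propyl ether",    "CCCOC",       "mpe",        "oxygenated",
    "dpe",        "dipropyl ether",         "CCCOCCC",     "dpe",        "oxygenated",
    "mtbe",       "methyl tert-butyl ether","CC(C)(C)OC",  "mtbe",       "oxygenated",
    "acetone",    "acetone",                "CC(C)=O",     "acetone",    "oxygenated",
    "butanone",   "2-butanone",             "CCC(C)=O",    "butanone",   "oxygenated",
    "pentan3one", "3-pentanone",            "CCC(=O)CC",   "pentan3one", "oxygenated",
    "propanal",   "propanal",               "CCC=O",       "propanal",   "oxygenated",
    "butanal",    "butanal",                "CCCC=O",      "butanal",    "oxygenated",
    "isobutanal", "2-methylpropanal",       "CC(C)C=O",    "isobutanal", "oxygenated",
    "etformate",  "ethyl formate",          "CCOC=O",      "etformate",  "oxygenated",
    "prformate",  "propyl formate",         "CCCOC=O",     "prformate",  "oxygenated",
    "meacetate",  "methyl acetate",         "CC(=O)OC",    "meacetate",  "oxygenated",
    "etacetate",  "ethyl acetate",          "CCOC(C)=O",   "etacetate",  "oxygenated",
    "meprop",     "methyl propanoate",      "CCC(=O)OC",   "meprop",     "oxygenated",
    "maleate",    "diethyl maleate",        "CCOC(=O)/C=C\\C(=O)OCC", "butenedioate", "oxygenated",
    "fumarate",   "diethyl fumarate",       "CCOC(=O)/C=C/C(=O)OCC", "butenedioate", "oxygenated",
    "clpropane1", "1-chloropropane",        "CCCCl",       "clpropane1", "halogenated",
    "clpropane2", "2-chloropropane",        "CC(Cl)C",     "clpropane2", "halogenated",
    "clbutane1",  "1-chlorobutane",         "CCCCCl",      "clbutane1",  "halogenated",
    "cl2butane11","1,1-dichlorobutane",     "CCCC(Cl)Cl",  "cl2butane11","halogenated",
    "cl2propane22","2,2-dichloropropane",   "CC(Cl)(Cl)C", "cl2propane22","halogenated",
    "cl2butane22","2,2-dichlorobutane",     "CCC(Cl)(Cl)C","cl2butane22","halogenated",
    "cl3propane", "1,1,1-trichloropropane", "CCC(Cl)(Cl)Cl","cl3propane","halogenated",
    "dcp12_cis",  "cis-1,2-dichloropropene","C/C(Cl)=C\\Cl","dcp12",     "halogenated",
    "dcp12_trans","trans-1,2-dichloropropene","C/C(Cl)=C/Cl","dcp12",    "halogenated",
    "dcp13_cis",  "cis-1,3-dichloropropene","ClC/C=C\\Cl", "dcp13",      "halogenated",
    "dcp13_trans","trans-1,3-dichloropropene","ClC/C=C/Cl", "dcp13",     "halogenated",
    "fbutane1",   "1-fluorobutane",         "CCCCF",       "fbutane1",   "halogenated",
    "f2propane11","1,1-difluoropropane",    "CCC(F)F",     "f2propane11","halogenated",
    "fpropane2",  "2-fluoropropane",        "CC(F)C",      "fpropane2",  "halogenated",
    "brpropane1", "1-bromopropane",         "CCCBr",       "brpropane1", "halogenated",
    "brbutane1",  "1-bromobutane",          "CCCCBr",      "brbutane1",  "halogenated",
    "br2propane13","1,3-dibromopropane",    "BrCCCBr",     "br2propane13","halogenated",
    "ipropane1",  "1-iodopropane",          "CCCI",        "ipropane1",  "halogenated",
    "ibutane1",   "1-iodobutane",           "CCCCI",       "ibutane1",   "halogenated",
    "i2propane13","1,3-diiodopropane",      "ICCCI",       "i2propane13","halogenated",
    "tfp",        "3,3,3-trifluoropropene", "FC(F)(F)C=C", "tfp",        "halogenated",
    "tbucl",      "2-chloro-2-methylpropane","CC(C)(C)Cl", "tbucl",      "halogenated",
    "amylcl",     "2-chloro-2-methylbutane","CCC(C)(C)Cl", "amylcl",     "halogenated",
    "clpropene2", "2-chloropropene",        "CC(Cl)=C",    "clpropene2", "halogenated",
    "clbutene2",  "2-chloro-2-butene",      "C/C=C(\\C)Cl","clbutene2",  "halogenated",
    "cl2propene11","1,1-dichloropropene",   "CC=C(Cl)Cl",  "cl2propene11","halogenated",
    "cl2butene11","1,1-dichloro-1-butene",  "CCC=C(Cl)Cl", "cl2butene11","halogenated"
  )
  if (class != "both") fx <- fx[fx$class == class, ]
  fx
}

#' Multiplicative measurement-noise model
#'
#' Log-normal multiplicative noise: each generated value is multiplied by
#' `exp(sigma * z)`, `z ~ N(0, 1)`, with a relative level of 2 percent for
#' vapor pressures and 0.5 percent for liquid densities by default —
#' typical reproducibility of curated experimental data for these
#' properties.
#'
#' @param sigma_psat,sigma_rho Relative log-scale noise levels.
#' @return A list of class `vgc_noise_model`.
#' @export
vgc_noise_model <- function(sigma_psat = 0.02, sigma_rho = 0.005) {
  stopifnot(sigma_psat >= 0, sigma_rho >= 0)
  structure(list(sigma_psat = sigma_psat, sigma_rho = sigma_rho),
            class = "vgc_noise_model")
}

#' Scope filters for dataset substances
#'
#' Applies the dataset admission rules to a vector of SMILES: aliphatic,
#' acyclic, uncharged, nonassociating (no O-H; N/S/P are outside the
#' element scope anyway), elements either {C,H,O} (oxygenated class,
#' hydrocarbons pass trivially) or {C,H,F,Cl,Br,I} (halogenated class), and
#' 3 to 8 carbon atoms. Every rejection carries its reason; the filter is
#' idempotent on its kept set.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Tibble with `smiles`, `kept`, `reason` (`NA` when kept).
#' @examples
#' \dontrun{
#' apply_scope_filters(c("CCO", "CCOC", "c1ccccc1Cl", "CCCCCCCCCC"))
#' }
#' @export
apply_scope_filters <- function(smiles) {
  res <- purrr::map(smiles, function(s) {
    mol <- withCallingHandlers(
      tryCatch(parse_molecule(s), vgc_error = function(e) e),
      vgc_range_warning = function(w) invokeRestart("muffleWarning"))
    if (inherits(mol, "vgc_error")) {
      reason <- switch(class(mol)[1],
                       vgc_parse_error = "invalid SMILES",
                       vgc_stereo_error = "missing E/Z annotation",
                       vgc_scope_error = scope_reason(mol),
                       conditionMessage(mol))
      return(tibble::tibble(kept = FALSE, reason = reason))
    }
    els <- unique(mol$graph$elements)
    has_o <- "O" %in% els
    has_x <- any(c("F", "Cl", "Br", "I") %in% els)
    if (has_o && has_x) {
      return(tibble::tibble(kept = FALSE,
                            reason = "mixed oxygenated/halogenated classes"))
    }
    if (mol$carbon_count < 3L) {
      return(tibble::tibble(kept = FALSE, reason = "fewer than 3 carbon atoms"))
    }
    if (mol$carbon_count > 8L) {
      return(tibble::tibble(kept = FALSE, reason = "more than 8 carbon atoms"))
    }
    tibble::tibble(kept = TRUE, reason = NA_character_)
  })
  dplyr::bind_cols(tibble::tibble(smiles = smiles), dplyr::bind_rows(res))
}

scope_reason <- function(e) {
  msg <- conditionMessage(e)
  if (grepl("hydroxyl", msg)) "associating (O-H)"
  else if (grepl("cyclic", msg)) "cyclic"
  else if (grepl("charged", msg)) "charged"
  else if (grepl("element", msg)) "unsupported element"
  else if (grepl("disconnected", msg)) "disconnected"
  else msg
}

#' Generate a pseudo-experimental property dataset
#'
#' Builds the dataset the regression assumes, with known ground truth: for
#' each fixture molecule, PCP-SAFT parameters are predicted from the truth
#' table, the evaluator supplies vapor pressures, saturated and compressed
#' liquid densities on a temperature grid spanning a reduced subcritical
#' window, and multiplicative log-normal noise is applied. Deterministic
#' for a fixed seed; `sigma = 0` reproduces the evaluator outputs exactly.
#'
#' @param fixtures Tibble as from [vgc_fixture_molecules()].
#' @param evaluator A property evaluator (needs a critical-temperature
#'   estimate for grid placement; the surrogate provides one).
#' @param noise A [vgc_noise_model()].
#' @param truth Ground-truth [vgc_parameter_table()].
#' @param seed Integer seed (conformers and noise).
#' @param n_temps Grid points per substance and property.
#' @param t_frac Grid span as fractions of the predicted critical
#'   temperature.
#' @param designs Optional precomputed designs for the fixtures.
#' @return A [as_property_dataset()] object; the truth table and designs
#'   are attached as attributes `truth` and `designs`.
#' @export
generate_dataset <- function(fixtures = vgc_fixture_molecules(),
                             evaluator = surrogate_evaluator(),
                             noise = vgc_noise_model(),
                             truth = vgc_table_synthetic(),
                             seed = 42L, n_temps = 8L,
                             t_frac = c(0.55, 0.80), designs = NULL) {
  stopifnot(inherits(noise, "vgc_noise_model"), inherits(truth, "vgc_table"))
  substances <- fixtures[, c("substance_id", "smiles", "isomer_pair_id")]
  skeleton <- as_property_dataset(
    tibble::tibble(substance_id = fixtures$substance_id[1],
                   smiles = fixtures$smiles[1], property = "psat",
                   T_K = 300, value = 1), substances)
  if (is.null(designs)) {
    designs <- precompute_designs(
      structure(list(points = NULL, substances = substances),
                class = "vgc_dataset"), seed = seed)
  }

  pts <- list()
  for (k in seq_len(nrow(fixtures))) {
    sid <- fixtures$substance_id[k]
    params <- design_params(designs[[sid]], truth)
    tc <- evaluator_tc(evaluator, params)
    if (is.na(tc)) tc <- 420
    tg <- seq(t_frac[1] * tc, t_frac[2] * tc, length.out = n_temps)
    q <- tibble::tibble(
      property = rep(c("psat", "rho_liq_sat", "rho_liq"), each = n_temps),
      T_K = rep(tg, 3), p_Pa = NA_real_)
    psat_vals <- evaluate_properties(evaluator, params,
                                     q[q$property == "psat", ])$value
    q$p_Pa[q$property == "rho_liq"] <- 2 * psat_vals
    res <- evaluate_properties(evaluator, params, q)
    res <- res[res$status == "ok", ]
    pts[[k]] <- tibble::tibble(substance_id = sid,
                               smiles = fixtures$smiles[k],
                               property = res$property, T_K = res$T_K,
                               p_Pa = res$p_Pa, value = res$value,
                               source = "synthetic")
  }
  points <- dplyr::bind_rows(pts)
  sig <- ifelse(points$property == "psat", noise$sigma_psat,
                noise$sigma_rho)
  z <- with_seed(seed, stats::rnorm(nrow(points)))
  points$value <- points$value * exp(sig * z)

  ds <- as_property_dataset(points, substances)
  attr(ds, "truth") <- truth
  attr(ds, "designs") <- designs
  ds
}
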