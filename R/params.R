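#' Parameter tables of group and bond contributions
#'
#' A parameter table pairs transferable group contributions (`m`, `sigma` in
#' Angstrom, `epsilon_k` in Kelvin) with bond dipole contributions (`mu` in
#' Debye). Two tables ship with the package:
#' `vgc_table_carbon()` holds the seven adopted carbon groups of the
#' homosegmented GC scheme (plus the two zero-dipole hydrocarbon bonds), and
#' `vgc_table_synthetic()` adds synthetic stand-in contributions for the
#' oxygen and halogen groups, the nine second-order corrections and the six
#' polar bonds — a self-contained ground truth for simulation studies, not a
#' regression to experimental data.
#'
#' @param groups Tibble with columns `id`, `m`, `sigma`, `epsilon_k`.
#' @param bonds Tibble with columns `id`, `mu`.
#' @param metadata List with at least `provenance` and `version`.
#' @return An object of class `vgc_table`.
#' @export
vgc_parameter_table <- function(groups, bonds, metadata = list()) {
  groups <- tibble::as_tibble(groups)[, c("id", "m", "sigma", "epsilon_k")]
  bonds <- tibble::as_tibble(bonds)[, c("id", "mu")]
  stopifnot(!anyDuplicated(groups$id), !anyDuplicated(bonds$id))
  if (any(bonds$mu < 0)) {
    vgc_abort("bond dipole contributions must be nonnegative",
              "vgc_parameter_error")
  }
  structure(list(groups = groups, bonds = bonds,
                 metadata = utils::modifyList(
                   list(provenance = "unspecified", version = "0"), metadata)),
            class = "vgc_table")
}

#' @rdname vgc_parameter_table
#' @export
vgc_table_carbon <- function() {
  read_parameter_table(extdata("params_table1_carbon.json"))
}

#' @rdname vgc_parameter_table
#' @export
vgc_table_synthetic <- function() {
  read_parameter_table(extdata("params_synthetic.json"))
}

#' @export
print.vgc_table <- function(x, ...) {
  cat(sprintf("<vgc_table> %d groups, %d bonds (version %s)\n",
              nrow(x$groups), nrow(x$bonds), x$metadata$version))
  cat(" ", substr(x$metadata$provenance, 1, 76), "\n")
  invisible(x)
}

#' Read and write parameter tables (JSON and CSV)
#'
#' Both dialects carry the same schema. JSON:
#' `{metadata, groups: [{id, m, sigma, epsilon_k}], bonds: [{id, mu}]}`.
#' CSV: one flat file with columns `kind` (`group`/`bond`), `id`, `m`,
#' `sigma`, `epsilon_k`, `mu` (empty where not applicable). Round trips are
#' exact to 9 significant digits.
#'
#' @param path File path; format chosen by extension (`.json` or `.csv`).
#' @param table A [vgc_parameter_table()].
#' @return `read_parameter_table()` returns a `vgc_table`;
#'   `write_parameter_table()` returns `path` invisibly.
#' @export
read_parameter_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    vgc_parameter_table(raw$groups, raw$bonds, as.list(raw$metadata))
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE)
    vgc_parameter_table(
      flat[flat$kind == "group", c("id", "m", "sigma", "epsilon_k")],
      flat[flat$kind == "bond", c("id", "mu")],
      list(provenance = attr(flat, "provenance") %||% "read from CSV",
           version = "csv"))
  } else {
    vgc_abort(sprintf("unsupported table format: %s", path),
              "vgc_config_error")
  }
}

#' @rdname read_parameter_table
#' @export
write_parameter_table <- function(table, path) {
  stopifnot(inherits(table, "vgc_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    write_json_stable(list(
      metadata = table$metadata,
      groups = as.data.frame(lapply(table$groups, signif9_keep)),
      bonds = as.data.frame(lapply(table$bonds, signif9_keep))), path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    g <- table$groups; b <- table$bonds
    flat <- rbind(
      data.frame(kind = "group", id = g$id, m = signif9(g$m),
                 sigma = signif9(g$sigma), epsilon_k = signif9(g$epsilon_k),
                 mu = NA_real_),
      data.frame(kind = "bond", id = b$id, m = NA_real_, sigma = NA_real_,
                 epsilon_k = NA_real_, mu = signif9(b$mu)))
    utils::write.csv(flat, path, row.names = FALSE, na = "")
  } else {
    vgc_abort(sprintf("unsupported table format: %s", path),
              "vgc_config_error")
  }
  invisible(path)
}

signif9_keep <- function(x) if (is.numeric(x)) signif9(x) else x

# --- sum rules -------------------------------------------------------------

#' Sum rules for the nonpolar parameters m, sigma, epsilon
#'
#' Applies the homosegmented group-contribution sum rules: the segment
#' number `m`, the packed volume `m * sigma^3` and the energy sum
#' `m * epsilon` are additive over group occurrences, and `sigma`,
#' `epsilon/k` are recovered by division by `m`. Second-order groups enter
#' identically (as additive corrections, possibly negative).
#'
#' @param frag A [fragment()] result.
#' @param table A [vgc_parameter_table()] covering all of `frag`'s groups.
#' @return Named numeric vector with `m`, `sigma` (Angstrom) and
#'   `epsilon_k` (Kelvin).
#' @examples
#' \dontrun{
#' predict_msigmaeps(fragment("CCCC"), vgc_table_carbon())
#' # m = 2.13608, sigma = 3.793, eps/k = 233.8
#' }
#' @export
predict_msigmaeps <- function(frag, table) {
  stopifnot(inherits(frag, "vgc_fragmentation"), inherits(table, "vgc_table"))
  counts <- frag$group_counts
  idx <- match(names(counts), table$groups$id)
  if (anyNA(idx)) {
    vgc_abort(sprintf("parameter table does not cover group(s): %s",
                      paste(names(counts)[is.na(idx)], collapse = ", ")),
              "vgc_coverage_error")
  }
  g <- table$groups[idx, ]
  m <- sum(counts * g$m)
  msig3 <- sum(counts * g$m * g$sigma^3)
  meps <- sum(counts * g$m * g$epsilon_k)
  if (m <= 0 || msig3 <= 0 || meps <= 0) {
    vgc_abort(sprintf(
      "'%s': unphysical parameter combination (m = %.4f, m*sigma^3 = %.4f, m*eps = %.4f)",
      frag$molecule$smiles, m, msig3, meps), "vgc_parameter_error")
  }
  c(m = m, sigma = (msig3 / m)^(1 / 3), epsilon_k = meps / m)
}

#' Dipole sum rule: vector addition of bond contributions
#'
#' The molecular dipole parameter is the Euclidean norm of the vector sum of
#' bond dipole contributions, each oriented along its bond's unit vector
#' (higher to lower electronegativity). Bonds flagged `fixed_zero` (C-H and
#' the sp2/sp3 carbon bond) contribute nothing, so hydrocarbons come out
#' exactly nonpolar; unit vectors of bonds of identical type cancel exactly
#' when antiparallel, which is what resolves molecular symmetry and
#' cis/trans isomerism.
#'
#' @inheritParams predict_msigmaeps
#' @return Dipole parameter in Debye (nonnegative scalar).
#' @export
predict_mu <- function(frag, table) {
  stopifnot(inherits(frag, "vgc_fragmentation"), inherits(table, "vgc_table"))
  ob <- frag$oriented_bonds
  if (nrow(ob) == 0L) return(0)
  idx <- match(ob$bond_id, table$bonds$id)
  if (anyNA(idx)) {
    vgc_abort(sprintf("parameter table does not cover bond(s): %s",
                      paste(unique(ob$bond_id[is.na(idx)]), collapse = ", ")),
              "vgc_coverage_error")
  }
  mu_b <- ifelse(ob$fixed_zero, 0, table$bonds$mu[idx])
  vnorm(c(sum(mu_b * ob$ex), sum(mu_b * ob$ey), sum(mu_b * ob$ez)))
}

#' Predict PCP-SAFT parameters from SMILES
#'
#' Runs the full prediction pipeline for a set of molecules: fragmentation
#' (substructure search plus seeded 3D conformer), the additive sum rules
#' for `m`, `sigma`, `epsilon/k`, and the vector sum rule for the dipole
#' parameter `mu`. Association and quadrupole parameters are fixed at zero:
#' the method targets nonassociating dipolar substances.
#'
#' @param data A data frame with a SMILES column, or a character vector of
#'   SMILES strings.
#' @param table A [vgc_parameter_table()]; defaults to the shipped synthetic
#'   demonstration table.
#' @param smiles Name of the SMILES column when `data` is a data frame.
#' @param seed Conformer embedding seed.
#' @param groups,bonds Definition tibbles.
#' @return A tibble with one row per molecule: `smiles`, `m`, `sigma`,
#'   `epsilon_k`, `mu`, `molar_mass`, `eps_ab_k`, `kappa_ab`, `q` (zeros),
#'   and `error` for molecules that could not be processed.
#' @examples
#' \dontrun{
#' predict_parameters(c("CCCC", "CC(C)=O"))
#' }
#' @export
predict_parameters <- function(data, table = vgc_table_synthetic(),
                               smiles = "smiles", seed = 42L,
                               groups = vgc_group_defs(),
                               bonds = vgc_bond_defs()) {
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  stopifnot(is.data.frame(data), smiles %in% names(data))
  rows <- purrr::map(data[[smiles]], function(s) {
    tryCatch({
      frag <- fragment(s, groups, bonds, seed = seed)
      mse <- predict_msigmaeps(frag, table)
      tibble::tibble(m = mse[["m"]], sigma = mse[["sigma"]],
                     epsilon_k = mse[["epsilon_k"]],
                     mu = predict_mu(frag, table),
                     molar_mass = frag$molecule$molar_mass,
                     eps_ab_k = 0, kappa_ab = 0, q = 0,
                     error = NA_character_)
    }, vgc_error = function(e) {
      tibble::tibble(m = NA_real_, sigma = NA_real_, epsilon_k = NA_real_,
                     mu = NA_real_, molar_mass = NA_real_,
                     eps_ab_k = 0, kappa_ab = 0, q = 0,
                     error = conditionMessage(e))
    })
  })
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(rows))
}
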