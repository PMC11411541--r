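#' Configuration for group/bond contribution regression
#'
#' Collects everything a fit needs besides the data: the initial parameter
#' table (frozen entries keep these values; free entries start from them),
#' which groups and bonds are free, the property weights, and optimizer
#' controls. By default the seven adopted carbon groups are frozen — they
#' are transferable contributions calibrated on hydrocarbons — and the two
#' fixed-zero hydrocarbon bonds stay at zero dipole, while every other
#' group and bond in the table is regressed. Bounds follow the scheme's
#' constraints: first-order group contributions and bond dipoles are
#' bounded below by zero, second-order corrections may go negative.
#'
#' Free initial values default to the table's entries; a common choice for
#' a fresh regression is the methylene row for new first-order groups and
#' 1 Debye for bond dipoles (see [vgc_default_initial_table()]).
#'
#' @param table Initial [vgc_parameter_table()].
#' @param groups,bonds Definition tibbles (supply group order and the
#'   fixed-zero flags).
#' @param free_groups,free_bonds Character ids; `NULL` means the defaults
#'   described above.
#' @param weights Named weights for `psat`, `rho_liq_sat`, `rho_liq`.
#' @param maxit,ftol,ptol Levenberg-Marquardt controls (see
#'   [minpack.lm::nls.lm.control()]).
#' @param seed Seed for conformer embedding in design precomputation and
#'   for the multi-start jitter.
#' @param n_starts Number of optimizer starts: the first from the table's
#'   initial values, the rest from seeded multiplicative jitter of them;
#'   the lowest-objective solution wins.
#' @param mu_zero If `TRUE`, all bond contributions are frozen at zero (the
#'   benchmark variant that neglects the dipole term).
#' @return A list of class `vgc_fit_config`.
#' @export
vgc_fit_config <- function(table = vgc_table_synthetic(),
                           groups = vgc_group_defs(),
                           bonds = vgc_bond_defs(),
                           free_groups = NULL, free_bonds = NULL,
                           weights = c(psat = 3, rho_liq_sat = 2,
                                       rho_liq = 2),
                           maxit = 300L, ftol = 1e-12, ptol = 1e-10,
                           seed = 42L, n_starts = 1L, mu_zero = FALSE) {
  stopifnot(inherits(table, "vgc_table"), all(weights > 0))
  carbon <- c("CH3", "CH2", ">CH", ">C<", "=CH2", "=CH", "=C<")
  if (is.null(free_groups)) {
    free_groups <- setdiff(table$groups$id, carbon)
  }
  if (is.null(free_bonds)) {
    fz <- bonds$id[bonds$fixed_zero]
    free_bonds <- setdiff(table$bonds$id, fz)
  }
  stopifnot(all(free_groups %in% table$groups$id),
            all(free_bonds %in% table$bonds$id))
  structure(list(table = table, groups = groups, bonds = bonds,
                 free_groups = free_groups, free_bonds = free_bonds,
                 weights = weights, maxit = as.integer(maxit), ftol = ftol,
                 ptol = ptol, seed = as.integer(seed),
                 n_starts = max(1L, as.integer(n_starts)),
                 mu_zero = isTRUE(mu_zero)),
            class = "vgc_fit_config")
}

#' @rdname vgc_fit_config
#' @details `mu_zero_variant()` turns a configuration into the benchmark
#'   that constrains every bond dipole contribution to zero (all bonds
#'   frozen, initial dipoles zeroed). It is idempotent.
#' @param config A `vgc_fit_config`.
#' @export
mu_zero_variant <- function(config) {
  stopifnot(inherits(config, "vgc_fit_config"))
  config$mu_zero <- TRUE
  config$free_bonds <- character(0)
  config$table$bonds$mu <- rep(0, nrow(config$table$bonds))
  config
}

#' Initial table for a fresh regression
#'
#' Builds a full parameter table over the given definitions in which the
#' adopted carbon contributions keep their values, every other first-order
#' group starts from the methylene row, second-order corrections start at
#' zero (with unit sigma/epsilon placeholders), and free bond dipoles start
#' at 1 Debye.
#'
#' @param groups,bonds Definition tibbles.
#' @return A [vgc_parameter_table()].
#' @export
vgc_default_initial_table <- function(groups = vgc_group_defs(),
                                      bonds = vgc_bond_defs()) {
  carbon <- vgc_table_carbon()$groups
  ch2 <- carbon[carbon$id == "CH2", ]
  g <- tibble::tibble(id = groups$id) |>
    dplyr::left_join(carbon, by = "id")
  first <- groups$order[match(g$id, groups$id)] == 1L
  miss <- is.na(g$m)
  g$m[miss & first] <- ch2$m
  g$sigma[miss & first] <- ch2$sigma
  g$epsilon_k[miss & first] <- ch2$epsilon_k
  g$m[miss & !first] <- 0
  g$sigma[miss & !first] <- 1
  g$epsilon_k[miss & !first] <- 1
  b <- tibble::tibble(id = bonds$id,
                      mu = ifelse(bonds$fixed_zero, 0, 1))
  vgc_parameter_table(g, b, list(provenance = "default initial values",
                                 version = "init"))
}

#' Fit group and bond contributions to property data
#'
#' Bound-constrained simultaneous regression of all free group and bond
#' contributions against a property dataset, minimizing the weighted
#' logarithmic least-squares objective ([vgc_objective()]) with
#' bound-constrained Levenberg-Marquardt on the weighted log residuals
#' (finite-difference Jacobian).
#' Internally each free group is optimized in its additive coordinates
#' (`m`, `m sigma^3`, `m epsilon`) — the quantities the sum rules add up —
#' which keeps the design linear in the group part and avoids the
#' degeneracy at `m = 0` that the (`m`, `sigma`, `epsilon`) coordinates
#' have for second-order corrections. Frozen entries never change.
#' Optimizer failure yields a non-converged result (flagged, not raised).
#'
#' @param dataset A [as_property_dataset()] object.
#' @param evaluator A property evaluator.
#' @param config A [vgc_fit_config()].
#' @param designs Optional precomputed designs (else computed here).
#' @return An object of class `vgc_fit`: `table` (fitted),fields
#'   `objective_value`, `n_evaluations`, `converged`, `skipped_points`,
#'   `history`, `config`.
#' @export
vgc_fit <- function(dataset, evaluator, config = vgc_fit_config(),
                    designs = NULL) {
  stopifnot(inherits(dataset, "vgc_dataset"),
            inherits(evaluator, "vgc_evaluator"),
            inherits(config, "vgc_fit_config"))
  if (is.null(designs)) {
    designs <- precompute_designs(dataset, config$groups, config$bonds,
                                  seed = config$seed)
  }
  table0 <- config$table
  if (config$mu_zero) table0$bonds$mu <- rep(0, nrow(table0$bonds))
  ctx <- build_objective_context(dataset, designs, table0, config)
  x0 <- pack_x(table0, ctx)

  if (length(x0) == 0L) {
    vgc_abort("no free parameters to fit", "vgc_config_error")
  }

  order2 <- config$groups$id[config$groups$order == 2L]
  lower <- numeric(length(x0))
  fgn <- length(ctx$free_groups)
  if (fgn) {
    is2 <- ctx$free_groups %in% order2
    lower[seq_len(3 * fgn)] <- rep(ifelse(is2, -Inf, 0), each = 3)
  }
  # bond dipoles: lower bound zero (already 0 in `lower`)

  n_eval <- 0L
  history <- numeric(0)
  n_points <- sum(vapply(ctx$per_sub, function(p) length(p$T_K), 0L))
  fn <- function(x) {
    # a trial point where nothing is evaluable is a penalty, not an error
    r <- tryCatch(residuals_x(x, ctx, evaluator),
                  vgc_objective_error = function(e) rep(1e3, n_points))
    n_eval <<- n_eval + 1L
    history[length(history) + 1L] <<- sum(r * r)
    r
  }

  starts <- list(x0)
  if (config$n_starts > 1L) {
    jitters <- with_seed(config$seed, lapply(seq_len(config$n_starts - 1L),
      function(i) x0 * exp(stats::rnorm(length(x0), 0, 0.4)) +
        0.1 * pmax(abs(x0), 0.5) * stats::rnorm(length(x0))))
    starts <- c(starts, lapply(jitters, function(x) pmax(x, lower)))
  }

  opt <- NULL
  for (x_start in starts) {
    o <- tryCatch(
      minpack.lm::nls.lm(par = x_start, lower = lower, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxit, ftol = config$ftol,
                           ptol = config$ptol,
                           maxfev = (config$maxit + 1L) * (length(x0) + 1L))),
      error = function(e) e)
    if (inherits(o, "vgc_error")) stop(o)
    if (inherits(o, "error")) next
    if (is.null(opt) || o$deviance < opt$deviance) opt <- o
  }

  if (is.null(opt)) {
    return(structure(list(table = table0, objective_value = NA_real_,
                          n_evaluations = n_eval, converged = FALSE,
                          message = "all optimizer starts failed",
                          skipped_points = NULL, history = history,
                          config = config), class = "vgc_fit"))
  }

  fitted_table <- unpack_table(opt$par, ctx)
  fitted_table$metadata$provenance <-
    sprintf("fitted by vgc_fit (%s)", evaluator$name)
  final <- objective_x(opt$par, ctx, evaluator)
  structure(list(table = fitted_table,
                 objective_value = as.numeric(final),
                 n_evaluations = n_eval,
                 converged = opt$info %in% 1:3,
                 message = opt$message,
                 skipped_points = attr(final, "skipped"),
                 history = history,
                 config = config),
            class = "vgc_fit")
}

#' @export
print.vgc_fit <- function(x, ...) {
  cat(sprintf("<vgc_fit> objective %.6g after %d evaluations (%s)\n",
              x$objective_value, x$n_evaluations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted contribution table
#'
#' One row per fitted quantity: group rows carry `m`, `sigma`, `epsilon_k`,
#' bond rows carry `mu`, with the corresponding initial values and whether
#' the entry was free in the regression.
#'
#' @param x A `vgc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vgc_fit <- function(x, ...) {
  cfg <- x$config
  g <- x$table$groups |>
    dplyr::mutate(kind = "group", free = .data$id %in% cfg$free_groups)
  g0 <- cfg$table$groups[, c("id", "m", "sigma", "epsilon_k")]
  names(g0)[-1] <- paste0(names(g0)[-1], "_initial")
  g <- dplyr::left_join(g, g0, by = "id")
  b <- x$table$bonds |>
    dplyr::mutate(kind = "bond",
                  free = .data$id %in% cfg$free_bonds & !cfg$mu_zero)
  b0 <- cfg$table$bonds; names(b0)[-1] <- "mu_initial"
  b <- dplyr::left_join(b, b0, by = "id")
  dplyr::bind_rows(g, b) |>
    dplyr::relocate("kind", "id", "free")
}

#' @rdname tidy.vgc_fit
#' @export
glance.vgc_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective_value,
                 n_evaluations = x$n_evaluations,
                 n_free_groups = length(x$config$free_groups),
                 n_free_bonds = if (x$config$mu_zero) 0L else
                   length(x$config$free_bonds),
                 n_skipped = if (is.null(x$skipped_points)) NA_integer_ else
                   nrow(x$skipped_points),
                 converged = x$converged)
}
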