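#' Mean absolute percentage deviation
#'
#' `(100 / N) * sum_j |pred_j - exp_j| / exp_j`, the per-substance,
#' per-property prediction error reported by the cross-validation. Scale
#' invariant; undefined (error) for empty inputs.
#'
#' @param pred,exp Numeric vectors of equal length; `exp` strictly positive.
#' @return Percent deviation (scalar).
#' @examples
#' mapd(c(2, 1), c(1, 2))  # 75
#' @export
mapd <- function(pred, exp) {
  if (length(pred) == 0L || length(pred) != length(exp)) {
    vgc_abort("mapd() needs equally long, nonempty vectors",
              "vgc_config_error")
  }
  if (any(exp <= 0)) {
    vgc_abort("mapd() reference values must be positive", "vgc_config_error")
  }
  100 * mean(abs(pred - exp) / exp)
}

#' Compare predicted and reference dipole moments
#'
#' Pearson correlation and mean absolute deviation (in Debye) over the
#' intersection of substances, the two statistics used to judge whether
#' regressed effective dipole parameters remain physically sound against
#' (vacuum) dipole data.
#'
#' @param predicted,reference Named numeric vectors (substance -> Debye), or
#'   data frames with columns `substance_id` and `mu`.
#' @return List with `pearson_r`, `mad_D` and `n`.
#' @export
compare_dipoles <- function(predicted, reference) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$mu, x$substance_id) else x
  }
  p <- as_named(predicted); r <- as_named(reference)
  common <- intersect(names(p), names(r))
  if (length(common) < 2L) {
    vgc_abort("need at least two common substances to compare dipoles",
              "vgc_config_error")
  }
  list(pearson_r = stats::cor(p[common], r[common], method = "pearson"),
       mad_D = mean(abs(p[common] - r[common])),
       n = length(common))
}

#' Leave-one-out cross-validation at substance level
#'
#' Performs the validation protocol of the regression framework: for every
#' isomer-pair id (cis/trans partners count as one substance and leave
#' jointly), the free contributions are refitted on the remaining
#' substances from the configured initial values, and the held-out
#' substances' properties are predicted with the refitted table. Deviations
#' are reported as MAPD per substance and property, aggregated as medians
#' per property over substances. A held-out substance containing a free
#' group or polar bond that does not occur in the training remainder is
#' recorded as unpredictable (reported, never silently dropped).
#'
#' @param dataset A [as_property_dataset()] object.
#' @param evaluator A property evaluator.
#' @param config A [vgc_fit_config()].
#' @param designs Optional precomputed designs.
#' @return An object of class `vgc_cv` with `per_substance` (MAPD tibble),
#'   `points` (per-point predictions with statuses), `medians`, `dipoles`
#'   (held-out predicted dipole parameters), `unpredictable`, `skipped`,
#'   and `method` (`"vector_gc"` or `"mu_zero"`).
#' @export
vgc_loo_cv <- function(dataset, evaluator, config = vgc_fit_config(),
                       designs = NULL) {
  stopifnot(inherits(dataset, "vgc_dataset"))
  if (is.null(designs)) {
    designs <- precompute_designs(dataset, config$groups, config$bonds,
                                  seed = config$seed)
  }
  subs <- dataset$substances
  folds <- split(subs$substance_id, subs$isomer_pair_id)

  all_points <- list(); unpredictable <- list(); fits <- list()
  for (fold_id in names(folds)) {
    held <- folds[[fold_id]]
    train_ids <- setdiff(subs$substance_id, held)
    train <- subset_dataset(dataset, train_ids)

    fit <- vgc_fit(train, evaluator, config, designs = designs[train_ids])
    fits[[fold_id]] <- glance(fit)

    # identifiability of the held-out substances under the training data
    train_groups <- unique(unlist(lapply(designs[train_ids],
                                         function(d) names(d$counts))))
    train_bonds <- unique(unlist(lapply(designs[train_ids], function(d) {
      bv <- d$bond_vectors; bv$bond_id[!bv$fixed_zero]
    })))
    for (sid in held) {
      d <- designs[[sid]]
      miss_g <- intersect(setdiff(names(d$counts), train_groups),
                          config$free_groups)
      live <- d$bond_vectors$bond_id[!d$bond_vectors$fixed_zero]
      miss_b <- if (config$mu_zero) character(0) else
        intersect(setdiff(live, train_bonds), config$free_bonds)
      if (length(miss_g) || length(miss_b)) {
        unpredictable[[length(unpredictable) + 1L]] <- tibble::tibble(
          substance_id = sid,
          missing = paste(c(miss_g, miss_b), collapse = ", "))
        next
      }
      params <- design_params(d, fit$table)
      pts <- dataset$points[dataset$points$substance_id == sid, ]
      res <- evaluate_properties(evaluator, params,
                                 pts[, c("property", "T_K", "p_Pa")])
      all_points[[length(all_points) + 1L]] <- tibble::tibble(
        substance_id = sid, property = pts$property, T_K = pts$T_K,
        p_Pa = pts$p_Pa, exp = pts$value, pred = res$value,
        status = res$status, mu_pred = unname(params[["mu"]]),
        tc_pred = evaluator_tc(evaluator, params))
    }
  }

  points <- dplyr::bind_rows(all_points)
  per_substance <- points |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$substance_id, .data$property) |>
    dplyr::summarise(n = dplyr::n(), mapd = mapd(.data$pred, .data$exp),
                     .groups = "drop")
  medians <- per_substance |>
    dplyr::group_by(.data$property) |>
    dplyr::summarise(n_substances = dplyr::n(),
                     median_mapd = stats::median(.data$mapd),
                     .groups = "drop")
  dipoles <- dplyr::distinct(points, .data$substance_id, .data$mu_pred) |>
    dplyr::rename(mu = "mu_pred")
  skipped <- points |>
    dplyr::filter(.data$status != "ok") |>
    dplyr::select("substance_id", "property", "T_K", "status")

  structure(list(per_substance = per_substance, points = points,
                 medians = medians, dipoles = dipoles,
                 unpredictable = dplyr::bind_rows(unpredictable),
                 skipped = skipped,
                 fold_fits = dplyr::bind_rows(fits, .id = "fold"),
                 method = if (config$mu_zero) "mu_zero" else "vector_gc"),
            class = "vgc_cv")
}

#' @export
print.vgc_cv <- function(x, ...) {
  cat(sprintf("<vgc_cv> method %s: %d substances\n", x$method,
              dplyr::n_distinct(x$per_substance$substance_id)))
  print(x$medians)
  if (nrow(x$unpredictable)) {
    cat(sprintf("  unpredictable: %s\n",
                paste(x$unpredictable$substance_id, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname vgc_loo_cv
#' @param x A `vgc_cv`.
#' @param ... Unused.
#' @export
tidy.vgc_cv <- function(x, ...) x$per_substance

#' @rdname vgc_loo_cv
#' @export
glance.vgc_cv <- function(x, ...) {
  out <- tidyr::pivot_wider(x$medians[, c("property", "median_mapd")],
                            names_from = "property",
                            values_from = "median_mapd",
                            names_prefix = "median_mapd_")
  out$method <- x$method
  out$n_unpredictable <- nrow(x$unpredictable)
  out$n_skipped <- nrow(x$skipped)
  out
}

#' Compare two cross-validation runs on a shared basis
#'
#' When two method variants predict different critical temperatures, their
#' saturation predictions fail on different subsets of the data. For a fair
#' comparison the variant with the lower predicted critical temperature
#' sets the cutoff: only points evaluable under both methods (the shared
#' subcritical window) enter the comparison medians.
#'
#' @param a,b `vgc_cv` objects over the same dataset.
#' @return A tibble with per-method, per-property median MAPD over the
#'   shared evaluable points, plus the shared point count.
#' @export
compare_cv_reports <- function(a, b) {
  stopifnot(inherits(a, "vgc_cv"), inherits(b, "vgc_cv"))
  key <- c("substance_id", "property", "T_K", "p_Pa")
  joined <- dplyr::inner_join(
    a$points[, c(key, "exp", "pred", "status")],
    b$points[, c(key, "exp", "pred", "status")],
    by = key, suffix = c("_a", "_b")) |>
    dplyr::filter(.data$status_a == "ok", .data$status_b == "ok")
  summarise_side <- function(pred_col, label) {
    joined |>
      dplyr::group_by(.data$substance_id, .data$property) |>
      dplyr::summarise(mapd = mapd(.data[[pred_col]], .data$exp_a),
                       .groups = "drop") |>
      dplyr::group_by(.data$property) |>
      dplyr::summarise(median_mapd = stats::median(.data$mapd),
                       n_substances = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(method = label)
  }
  dplyr::bind_rows(summarise_side("pred_a", a$method),
                   summarise_side("pred_b", b$method)) |>
    dplyr::mutate(n_shared_points = nrow(joined)) |>
    dplyr::relocate("method")
}
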