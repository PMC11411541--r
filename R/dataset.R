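#' Property datasets for regression and cross-validation
#'
#' A property dataset couples per-substance vapor-pressure and
#' liquid-density observations with the substance roster the
#' cross-validation folds over. Points carry: `substance_id`, `smiles`,
#' `property` (`"psat"`, `"rho_liq_sat"` or `"rho_liq"`), `T_K`, `p_Pa`
#' (compressed-liquid points only), `value` (Pa or kg/m3, strictly
#' positive — the objective works in log space) and `source`. Substances
#' carry an `isomer_pair_id`: cis/trans partners share one id and are held
#' out jointly in leave-one-out runs.
#'
#' @param points Data frame of observations (see details).
#' @param substances Optional roster with `substance_id`, `smiles`,
#'   `isomer_pair_id`; derived from `points` when omitted (each substance
#'   its own pair).
#' @return An object of class `vgc_dataset` with elements `points` and
#'   `substances`.
#' @export
as_property_dataset <- function(points, substances = NULL) {
  points <- tibble::as_tibble(points)
  needed <- c("substance_id", "smiles", "property", "T_K", "value")
  missing <- setdiff(needed, names(points))
  if (length(missing)) {
    vgc_abort(sprintf("dataset points lack column(s): %s",
                      paste(missing, collapse = ", ")), "vgc_config_error")
  }
  if (!"p_Pa" %in% names(points)) points$p_Pa <- NA_real_
  if (!"source" %in% names(points)) points$source <- "unspecified"
  bad <- setdiff(unique(points$property),
                 c("psat", "rho_liq_sat", "rho_liq"))
  if (length(bad)) {
    vgc_abort(sprintf("unknown property kind(s): %s",
                      paste(bad, collapse = ", ")), "vgc_config_error")
  }
  if (any(!is.finite(points$value) | points$value <= 0)) {
    vgc_abort("all property values must be positive (log-deviations)",
              "vgc_config_error")
  }
  if (is.null(substances)) {
    substances <- points |>
      dplyr::distinct(.data$substance_id, .data$smiles) |>
      dplyr::mutate(isomer_pair_id = .data$substance_id)
  }
  substances <- tibble::as_tibble(substances)
  if (!"isomer_pair_id" %in% names(substances)) {
    substances$isomer_pair_id <- substances$substance_id
  }
  orphan <- setdiff(points$substance_id, substances$substance_id)
  if (length(orphan)) {
    vgc_abort(sprintf("points reference unknown substance(s): %s",
                      paste(orphan, collapse = ", ")), "vgc_config_error")
  }
  structure(list(points = points,
                 substances = substances[, c("substance_id", "smiles",
                                             "isomer_pair_id")]),
            class = "vgc_dataset")
}

#' @export
print.vgc_dataset <- function(x, ...) {
  cts <- dataset_counts(x)
  cat(sprintf("<vgc_dataset> %d substances, %d points\n",
              cts$n_substances, cts$n_tot))
  print(dplyr::count(x$points, .data$property))
  invisible(x)
}

#' Data-point counts per substance and property
#'
#' @param dataset A [as_property_dataset()] object.
#' @return List with `n_tot` (total points), `n_substances`, and `per`
#'   (tibble `substance_id`, `property`, `n`).
#' @export
dataset_counts <- function(dataset) {
  stopifnot(inherits(dataset, "vgc_dataset"))
  per <- dplyr::count(dataset$points, .data$substance_id, .data$property)
  list(n_tot = nrow(dataset$points),
       n_substances = nrow(dataset$substances),
       per = per)
}

#' @rdname as_property_dataset
#' @param dataset A `vgc_dataset`.
#' @param path CSV path. The flat file has the point columns plus
#'   `isomer_pair_id`.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "vgc_dataset"))
  flat <- dplyr::left_join(dataset$points,
                           dataset$substances[, c("substance_id",
                                                  "isomer_pair_id")],
                           by = "substance_id")
  flat <- flat[, c("substance_id", "smiles", "isomer_pair_id", "property",
                   "T_K", "p_Pa", "value", "source")]
  num <- vapply(flat, is.numeric, TRUE)
  flat[num] <- lapply(flat[num], signif9)
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname as_property_dataset
#' @export
read_dataset_csv <- function(path) {
  flat <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  substances <- dplyr::distinct(flat, .data$substance_id, .data$smiles,
                                .data$isomer_pair_id)
  as_property_dataset(
    flat[, setdiff(names(flat), "isomer_pair_id")], substances)
}

# Keep only the named substances (and their points).
subset_dataset <- function(dataset, keep_ids) {
  as_property_dataset(
    dataset$points[dataset$points$substance_id %in% keep_ids, ],
    dataset$substances[dataset$substances$substance_id %in% keep_ids, ])
}
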