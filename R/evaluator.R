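#' Property evaluators: the contract, the PCP-SAFT adapter, the surrogate
#'
#' The regression machinery only ever sees a *property evaluator*: an object
#' that maps a parameter set and a query (`psat` at `T`, `rho_liq_sat` at
#' `T`, or `rho_liq` at `T`, `p`) to a positive value or a typed
#' `"no_solution"` outcome (saturation does not exist at or above the
#' predicted critical temperature; such points are skipped and logged, never
#' silently NaN).
#'
#' `surrogate_evaluator()` is a self-contained analytic stand-in with the
#' qualitative structure of a real equation of state: a
#' Clausius-Clapeyron-type vapor pressure, a density declining toward a
#' pseudo-critical point, and a dipole parameter that deepens the effective
#' dispersion energy via `eps_eff = eps/k * (1 + c5 * mu^2 / (m * sigma^3))`
#' (the dipolar perturbation scales with mu^2 over the molecular volume).
#' Explicitly:
#' `ln(psat/Pa) = c1 - c2 * m^0.35 * eps_eff / T`,
#' `rho_liq_sat = c3 * M / (m * sigma^3) * (1 + c4 * (1 - 10 T / (c2 eps_eff)))`
#' in kg/m3, and `rho_liq` multiplies a small linear pressure term
#' `(1 + c6 * p)`. Saturation queries at or above the pseudo-critical
#' temperature `Tc* = c2 * eps_eff / 10` return `"no_solution"`. It is
#' smooth, strictly monotone in `T`, and sensitive to all four parameters.
#'
#' `pcp_saft_evaluator()` adapts a full PCP-SAFT implementation to the same
#' contract. The Helmholtz-energy model itself is deliberately not part of
#' this package; supply `backend` as a function
#' `function(params, queries) -> data.frame(value, status)` wrapping your
#' PCP-SAFT library of choice. Without a backend the constructor raises a
#' typed configuration error.
#'
#' @param coefficients Named numeric vector `c1..c6` (see details).
#' @param backend Backend evaluation function (see details).
#' @return An object of class `vgc_evaluator`.
#' @examples
#' ev <- surrogate_evaluator()
#' p <- c(m = 2.136, sigma = 3.79, epsilon_k = 233.8, mu = 0,
#'        molar_mass = 58.12)
#' evaluate_properties(ev, p,
#'   tibble::tibble(property = "psat", T_K = c(300, 320), p_Pa = NA))
#' @export
surrogate_evaluator <- function(coefficients = c(c1 = 30, c2 = 18, c3 = 900,
                                                 c4 = 0.8, c5 = 1.5,
                                                 c6 = 2e-9)) {
  co <- coefficients
  stopifnot(all(c("c1", "c2", "c3", "c4", "c5", "c6") %in% names(co)))

  eps_eff <- function(params) {
    unname(params[["epsilon_k"]] *
             (1 + co[["c5"]] * params[["mu"]]^2 /
                (params[["m"]] * params[["sigma"]]^3)))
  }
  tc <- function(params) co[["c2"]] * eps_eff(params) / 10

  evaluate <- function(params, queries) {
    ee <- eps_eff(params)
    tcrit <- co[["c2"]] * ee / 10
    msig3 <- params[["m"]] * params[["sigma"]]^3
    kind <- queries$property
    Tk <- queries$T_K
    bad_kind <- setdiff(unique(kind), c("psat", "rho_liq_sat", "rho_liq"))
    if (length(bad_kind)) {
      vgc_abort(sprintf("unknown property kind '%s'", bad_kind[1]),
                "vgc_config_error")
    }
    value <- rep(NA_real_, length(kind))
    i <- kind == "psat"
    value[i] <- exp(co[["c1"]] - co[["c2"]] * params[["m"]]^0.35 * ee / Tk[i])
    rho <- co[["c3"]] * params[["molar_mass"]] / msig3 *
      (1 + co[["c4"]] * (1 - 10 * Tk / (co[["c2"]] * ee)))
    i <- kind == "rho_liq_sat"
    value[i] <- rho[i]
    i <- kind == "rho_liq"
    value[i] <- rho[i] * (1 + co[["c6"]] * queries$p_Pa[i])
    supercrit <- kind != "rho_liq" & Tk >= tcrit
    ok <- !supercrit & is.finite(value) & value > 0
    value[!ok] <- NA_real_
    status <- rep("ok", length(kind)); status[!ok] <- "no_solution"
    list(value = value, status = status)
  }

  structure(list(name = "surrogate", coefficients = co, evaluate = evaluate,
                 critical_temperature = tc),
            class = "vgc_evaluator")
}

#' @rdname surrogate_evaluator
#' @export
pcp_saft_evaluator <- function(backend = NULL) {
  if (is.null(backend) || !is.function(backend)) {
    vgc_abort(paste(
      "no PCP-SAFT backend configured: supply `backend` as a function",
      "(params, queries) -> data.frame(value, status) wrapping a PCP-SAFT",
      "implementation"), "vgc_config_error")
  }
  evaluate <- function(params, queries) {
    out <- as.data.frame(backend(params, queries))
    if (!all(c("value", "status") %in% names(out)) ||
        nrow(out) != nrow(queries)) {
      vgc_abort("backend returned a malformed result", "vgc_config_error")
    }
    bad <- out$status == "ok" & (!is.finite(out$value) | out$value <= 0)
    out$status[bad] <- "no_solution"   # non-convergence is typed, never NaN
    out$value[out$status != "ok"] <- NA_real_
    tibble::as_tibble(out)
  }
  structure(list(name = "pcp_saft", evaluate = evaluate,
                 critical_temperature = attr(backend, "critical_temperature")),
            class = "vgc_evaluator")
}

#' @export
print.vgc_evaluator <- function(x, ...) {
  cat(sprintf("<vgc_evaluator> %s\n", x$name))
  invisible(x)
}

#' Evaluate property queries for one parameter set
#'
#' @param evaluator A `vgc_evaluator`.
#' @param params Named vector or one-row data frame with `m`, `sigma`,
#'   `epsilon_k`, `mu`, `molar_mass`.
#' @param queries Tibble with columns `property` (one of `"psat"`,
#'   `"rho_liq_sat"`, `"rho_liq"`), `T_K`, and `p_Pa` (used for `rho_liq`).
#' @return `queries` with columns `value` (Pa or kg/m3; `NA` where no
#'   solution exists) and `status` (`"ok"` or `"no_solution"`) appended.
#' @export
evaluate_properties <- function(evaluator, params, queries) {
  stopifnot(inherits(evaluator, "vgc_evaluator"))
  if (is.data.frame(params)) params <- unlist(params[1, , drop = TRUE])
  if (!"mu" %in% names(params)) params[["mu"]] <- 0   # nonpolar default
  if (any(queries$T_K <= 0, na.rm = TRUE)) {
    vgc_abort("temperatures must be positive", "vgc_config_error")
  }
  if (any(queries$property == "rho_liq" &
          (is.na(queries$p_Pa) | queries$p_Pa <= 0))) {
    vgc_abort("rho_liq queries require a positive pressure", "vgc_config_error")
  }
  res <- evaluator$evaluate(params, queries)
  dplyr::bind_cols(tibble::as_tibble(queries), tibble::as_tibble(res))
}

# Pseudo-critical temperature if the evaluator exposes one, else NA.
evaluator_tc <- function(evaluator, params) {
  if (is.data.frame(params)) params <- unlist(params[1, , drop = TRUE])
  f <- evaluator$critical_temperature
  if (is.null(f)) NA_real_ else f(params)
}
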