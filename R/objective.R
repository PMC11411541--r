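# Regression internals: per-substance designs (cached fragmentations turned
# into linear-algebra-ready structures) and the weighted log-least-squares
# objective.

#' Precompute per-substance designs for regression
#'
#' Fragments every substance once and stores what the sum rules need in a
#' regression-friendly form: group occurrence counts, the per-bond-type sums
#' of oriented unit vectors (the dipole parameter is
#' `|| sum_b mu_b * v_b ||` with `v_b` that precomputed sum), and the molar
#' mass. Fitting and cross-validation reuse these designs; geometry is never
#' re-embedded inside the optimizer loop.
#'
#' @param dataset A [as_property_dataset()] object.
#' @param groups,bonds Definition tibbles.
#' @param seed Conformer embedding seed.
#' @return Named list (by `substance_id`) of design records.
#' @export
precompute_designs <- function(dataset, groups = vgc_group_defs(),
                               bonds = vgc_bond_defs(), seed = 42L) {
  stopifnot(inherits(dataset, "vgc_dataset"))
  subs <- dataset$substances
  designs <- vector("list", nrow(subs))
  names(designs) <- subs$substance_id
  for (k in seq_len(nrow(subs))) {
    frag <- fragment(subs$smiles[k], groups, bonds, seed = seed)
    ob <- frag$oriented_bonds
    vsum <- if (nrow(ob)) {
      stats::aggregate(cbind(ex, ey, ez) ~ bond_id + fixed_zero, data = ob,
                       FUN = sum)
    } else {
      data.frame(bond_id = character(), fixed_zero = logical(),
                 ex = double(), ey = double(), ez = double())
    }
    designs[[k]] <- list(substance_id = subs$substance_id[k],
                         smiles = subs$smiles[k],
                         counts = frag$group_counts,
                         bond_vectors = vsum,
                         molar_mass = frag$molecule$molar_mass)
  }
  designs
}

# PCP-SAFT parameters for one design under a parameter table.
design_params <- function(design, table) {
  counts <- design$counts
  idx <- match(names(counts), table$groups$id)
  if (anyNA(idx)) {
    vgc_abort(sprintf("table does not cover group(s): %s",
                      paste(names(counts)[is.na(idx)], collapse = ", ")),
              "vgc_coverage_error")
  }
  g <- table$groups[idx, ]
  m <- sum(counts * g$m)
  msig3 <- sum(counts * g$m * g$sigma^3)
  meps <- sum(counts * g$m * g$epsilon_k)
  if (m <= 0 || msig3 <= 0 || meps <= 0) {
    vgc_abort(sprintf("'%s': unphysical parameter combination",
                      design$smiles), "vgc_parameter_error")
  }
  bv <- design$bond_vectors
  mu <- 0
  if (nrow(bv)) {
    bidx <- match(bv$bond_id, table$bonds$id)
    if (anyNA(bidx)) {
      vgc_abort(sprintf("table does not cover bond(s): %s",
                        paste(bv$bond_id[is.na(bidx)], collapse = ", ")),
                "vgc_coverage_error")
    }
    mu_b <- ifelse(bv$fixed_zero, 0, table$bonds$mu[bidx])
    mu <- vnorm(c(sum(mu_b * bv$ex), sum(mu_b * bv$ey), sum(mu_b * bv$ez)))
  }
  c(m = m, sigma = (msig3 / m)^(1 / 3), epsilon_k = meps / m, mu = mu,
    molar_mass = design$molar_mass)
}

# Context shared by objective evaluations during one fit: free-parameter
# bookkeeping in additive coordinates (a = m, b = m sigma^3, c = m eps per
# group; mu per bond) plus per-substance query blocks.
build_objective_context <- function(dataset, designs, table, config) {
  subs_ids <- dataset$substances$substance_id
  fg <- config$free_groups
  fb <- if (config$mu_zero) character(0) else config$free_bonds

  gtab <- table$groups
  btab <- table$bonds

  frozen_g <- setdiff(gtab$id, fg)
  per_sub <- vector("list", length(subs_ids))
  names(per_sub) <- subs_ids
  for (sid in subs_ids) {
    d <- designs[[sid]]
    if (is.null(d)) {
      vgc_abort(sprintf("no design for substance '%s'", sid),
                "vgc_config_error")
    }
    counts <- d$counts
    unknown <- setdiff(names(counts), gtab$id)
    if (length(unknown)) {
      vgc_abort(sprintf("table does not cover group(s): %s",
                        paste(unknown, collapse = ", ")),
                "vgc_coverage_error")
    }
    frozen_names <- intersect(names(counts), frozen_g)
    gi <- gtab[match(frozen_names, gtab$id), ]
    cf <- counts[frozen_names]
    base <- c(a = sum(cf * gi$m),
              b = sum(cf * gi$m * gi$sigma^3),
              c = sum(cf * gi$m * gi$epsilon_k))
    nf <- counts[match(fg, names(counts))]
    nf[is.na(nf)] <- 0L

    bv <- d$bond_vectors
    live <- bv[!bv$fixed_zero, , drop = FALSE]
    unknown_b <- setdiff(live$bond_id, btab$id)
    if (length(unknown_b)) {
      vgc_abort(sprintf("table does not cover bond(s): %s",
                        paste(unknown_b, collapse = ", ")),
                "vgc_coverage_error")
    }
    S <- matrix(0, 3, length(fb), dimnames = list(NULL, fb))
    Dbase <- c(0, 0, 0)
    if (nrow(live)) {
      for (r in seq_len(nrow(live))) {
        v <- c(live$ex[r], live$ey[r], live$ez[r])
        id <- live$bond_id[r]
        if (!config$mu_zero && id %in% fb) S[, id] <- S[, id] + v
        else if (!config$mu_zero) {
          Dbase <- Dbase + btab$mu[match(id, btab$id)] * v
        }
        # mu_zero: every bond contribution pinned at zero
      }
    }

    pts <- dataset$points[dataset$points$substance_id == sid, ]
    per_sub[[sid]] <- list(
      base = base, nf = as.numeric(nf), S = S, Dbase = Dbase,
      molar_mass = d$molar_mass,
      property = pts$property, T_K = pts$T_K, p_Pa = pts$p_Pa,
      queries = tibble::new_tibble(list(property = pts$property,
                                        T_K = pts$T_K, p_Pa = pts$p_Pa),
                                   nrow = nrow(pts)),
      logexp = log(pts$value))
  }

  list(per_sub = per_sub, free_groups = fg, free_bonds = fb,
       weights = config$weights, table = table)
}

# x layout: (a, b, c) per free group, then mu per free bond.
pack_x <- function(table, ctx) {
  fg <- ctx$free_groups; fb <- ctx$free_bonds
  x <- numeric(0)
  if (length(fg)) {
    g <- table$groups[match(fg, table$groups$id), ]
    x <- c(rbind(g$m, g$m * g$sigma^3, g$m * g$epsilon_k))
    names(x) <- as.vector(rbind(paste0(fg, ".a"), paste0(fg, ".b"),
                                paste0(fg, ".c")))
  }
  mu <- numeric(0)
  if (length(fb)) {
    mu <- table$bonds$mu[match(fb, table$bonds$id)]
    names(mu) <- paste0(fb, ".mu")
  }
  c(x, mu)
}

unpack_table <- function(x, ctx) {
  fg <- ctx$free_groups; fb <- ctx$free_bonds
  table <- ctx$table
  if (length(fg)) {
    a <- x[seq(1, by = 3, length.out = length(fg))]
    b <- x[seq(2, by = 3, length.out = length(fg))]
    cc <- x[seq(3, by = 3, length.out = length(fg))]
    sig <- ifelse(abs(a) > 1e-12, sign(b / a) * abs(b / a)^(1 / 3), 0)
    eps <- ifelse(abs(a) > 1e-12, cc / a, 0)
    idx <- match(fg, table$groups$id)
    table$groups$m[idx] <- a
    table$groups$sigma[idx] <- sig
    table$groups$epsilon_k[idx] <- eps
  }
  if (length(fb)) {
    mu <- x[3 * length(fg) + seq_along(fb)]
    table$bonds$mu[match(fb, table$bonds$id)] <- mu
  }
  table
}

# Weighted residual vector in free coordinates: r_ij = sqrt(w_xi /
# (sqrt(N_i_xi) * N_tot)) * (ln pred - ln exp), so that sum(r^2) equals the
# objective. Fixed length (one entry per data point); points the evaluator
# cannot solve contribute zero (they are skipped, and the normalization
# counts only evaluable points). An unphysical parameter combination for
# any substance yields a large uniform residual so the optimizer backs off.
residuals_x <- function(x, ctx, evaluator) {
  fgn <- length(ctx$free_groups)
  xa <- x[seq(1, by = 3, length.out = fgn)]
  xb <- x[seq(2, by = 3, length.out = fgn)]
  xc <- x[seq(3, by = 3, length.out = fgn)]
  xmu <- x[3 * fgn + seq_along(ctx$free_bonds)]
  w <- ctx$weights

  blocks <- vector("list", length(ctx$per_sub))
  n_tot <- 0L
  for (si in seq_along(ctx$per_sub)) {
    ps <- ctx$per_sub[[si]]
    npts <- length(ps$T_K)
    a <- ps$base[["a"]] + sum(ps$nf * xa)
    b <- ps$base[["b"]] + sum(ps$nf * xb)
    cc <- ps$base[["c"]] + sum(ps$nf * xc)
    if (a <= 0 || b <= 0 || cc <= 0) {
      pen <- 1e3 * (1 + abs(min(a, b, cc)))
      return(rep(pen, sum(vapply(ctx$per_sub,
                                 function(p) length(p$T_K), 0L))))
    }
    dv <- ps$Dbase + if (length(xmu)) as.vector(ps$S %*% xmu) else 0
    params <- c(m = a, sigma = (b / a)^(1 / 3), epsilon_k = cc / a,
                mu = vnorm(dv), molar_mass = ps$molar_mass)
    res <- evaluator$evaluate(params, ps$queries)
    ok <- res$status == "ok"
    r <- numeric(npts)
    if (any(ok)) {
      dev <- log(res$value[ok]) - ps$logexp[ok]
      prop_ok <- ps$property[ok]
      wk <- numeric(sum(ok))
      for (kind in unique(prop_ok)) {
        sel <- prop_ok == kind
        wk[sel] <- w[[kind]] / sqrt(sum(sel))
        n_tot <- n_tot + sum(sel)
      }
      r[ok] <- sqrt(wk) * dev
    }
    blocks[[si]] <- r
  }
  if (n_tot == 0L) {
    vgc_abort("no evaluable data points: objective undefined",
              "vgc_objective_error")
  }
  unlist(blocks) / sqrt(n_tot)
}

# Core objective in free coordinates. Returns the scalar L with attributes:
# "skipped" (points with no-solution outcomes), "n_evaluable".
objective_x <- function(x, ctx, evaluator) {
  fgn <- length(ctx$free_groups)
  xa <- x[seq(1, by = 3, length.out = fgn)]
  xb <- x[seq(2, by = 3, length.out = fgn)]
  xc <- x[seq(3, by = 3, length.out = fgn)]
  xmu <- x[3 * fgn + seq_along(ctx$free_bonds)]
  w <- ctx$weights

  total <- 0; n_tot <- 0L
  skipped <- list()
  for (sid in names(ctx$per_sub)) {
    ps <- ctx$per_sub[[sid]]
    a <- ps$base[["a"]] + sum(ps$nf * xa)
    b <- ps$base[["b"]] + sum(ps$nf * xb)
    cc <- ps$base[["c"]] + sum(ps$nf * xc)
    if (a <= 0 || b <= 0 || cc <= 0) return(1e8 + (abs(min(a, b, cc)) * 1e6))
    dv <- ps$Dbase + if (length(xmu)) as.vector(ps$S %*% xmu) else 0
    params <- c(m = a, sigma = (b / a)^(1 / 3), epsilon_k = cc / a,
                mu = vnorm(dv), molar_mass = ps$molar_mass)
    res <- evaluator$evaluate(params, ps$queries)
    ok <- res$status == "ok"
    if (any(!ok)) {
      skipped[[length(skipped) + 1L]] <- tibble::new_tibble(list(
        substance_id = rep(sid, sum(!ok)),
        property = ps$property[!ok], T_K = ps$T_K[!ok]), nrow = sum(!ok))
    }
    if (!any(ok)) next
    r2 <- (log(res$value[ok]) - ps$logexp[ok])^2
    prop_ok <- ps$property[ok]
    for (kind in unique(prop_ok)) {
      sel <- prop_ok == kind
      nk <- sum(sel)
      total <- total + w[[kind]] / sqrt(nk) * sum(r2[sel])
      n_tot <- n_tot + nk
    }
  }
  if (n_tot == 0L) {
    vgc_abort("no evaluable data points: objective undefined",
              "vgc_objective_error")
  }
  out <- total / n_tot
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(substance_id = character(), property = character(),
                   T_K = double())
  attr(out, "n_evaluable") <- n_tot
  out
}

#' The weighted logarithmic least-squares objective
#'
#' Computes the regression objective over a property dataset:
#' `L = (1/N_tot) * sum_i sum_xi  w_xi / sqrt(N_i_xi) * sum_j
#' (ln x_pred - ln x_exp)^2`, so that the total weight of each
#' substance/property block grows with the square root of its number of
#' data points (weights default to 3 for vapor pressure and 2 for the two
#' densities). Points where the evaluator reports no solution (saturation
#' above the predicted critical temperature) are skipped and logged, and
#' all counts refer to evaluable points.
#'
#' @param table A [vgc_parameter_table()] covering the dataset.
#' @param dataset A [as_property_dataset()] object.
#' @param evaluator A property evaluator, e.g. [surrogate_evaluator()].
#' @param config A [vgc_fit_config()]; only weights (and the frozen/free
#'   partition, for coverage checking) are used here.
#' @param designs Optional precomputed designs ([precompute_designs()]).
#' @return The scalar objective, with attributes `skipped` (tibble of
#'   skipped points) and `n_evaluable`.
#' @export
vgc_objective <- function(table, dataset, evaluator,
                          config = vgc_fit_config(table),
                          designs = NULL) {
  stopifnot(inherits(table, "vgc_table"), inherits(dataset, "vgc_dataset"))
  if (is.null(designs)) designs <- precompute_designs(dataset, seed = config$seed)
  cfg <- config
  cfg$free_groups <- character(0)
  cfg$free_bonds <- character(0)
  if (cfg$mu_zero) {
    table$bonds$mu <- rep(0, nrow(table$bonds))
  }
  ctx <- build_objective_context(dataset, designs, table, cfg)
  val <- objective_x(numeric(0), ctx, evaluator)
  out <- as.numeric(val)
  attributes(out) <- attributes(val)[c("skipped", "n_evaluable")]
  out
}
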