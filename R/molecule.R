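#' Parse and validate an isomeric SMILES string
#'
#' Converts a SMILES string into a validated molecule object: the
#' hydrogen-explicit molecular graph (elements, bonds with orders), derived
#' counts, and the cis/trans configuration of every stereogenic double bond.
#' The applicability domain of the method is enforced here: molecules must
#' be single, connected, acyclic, uncharged, built from C/H/O/F/Cl/Br/I, and
#' nonassociating (no O-H). Double bonds whose two ends each carry two
#' distinct substituents are geometrically ambiguous and must be annotated
#' E/Z in the SMILES; unannotated ones are rejected rather than silently
#' embedded, because isomer discrimination is the point of the dipole sum
#' rule.
#'
#' Molecules outside the 3-8 carbon range that the regression datasets use
#' are accepted with a warning: the range is a dataset filter, not a hard
#' prediction limit.
#'
#' @param smiles An isomeric SMILES string.
#' @param name Optional label carried through to results.
#' @return An object of class `vgc_molecule`: a list with `smiles`, `name`,
#'   `graph` (elements, adjacency, bond orders, H counts), `carbon_count`,
#'   `molar_mass`, and `stereo` (one row per stereogenic double bond with
#'   its reference substituents and cis/trans relation).
#' @examples
#' \dontrun{
#' parse_molecule("CCOC")        # methyl ethyl ether
#' try(parse_molecule("C1CCCCC1"))  # rings are out of scope
#' }
#' @export
parse_molecule <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))

  sdf <- smiles_to_sdf(smiles, gen3d = FALSE)
  graph <- sdf_to_graph(sdf)

  if (any(grepl("^M  CHG", sdf))) {
    vgc_abort(sprintf("'%s': charged species are out of scope", smiles),
              "vgc_scope_error")
  }
  bad <- setdiff(unique(graph$elements), ALLOWED_ELEMENTS)
  if (length(bad)) {
    vgc_abort(sprintf("'%s': element(s) %s outside the supported set {%s}",
                      smiles, paste(bad, collapse = ", "),
                      paste(ALLOWED_ELEMENTS, collapse = ", ")),
              "vgc_scope_error")
  }
  comp <- graph_components(graph)
  if (comp > 1L) {
    vgc_abort(sprintf("'%s': %d disconnected fragments (single molecules only)",
                      smiles, comp), "vgc_scope_error")
  }
  if (nrow(graph$bonds) != length(graph$elements) - 1L) {
    vgc_abort(sprintf("'%s': cyclic structures are unsupported", smiles),
              "vgc_scope_error")
  }
  oh <- which(graph$elements == "O" & graph$hcount > 0L)
  if (length(oh)) {
    vgc_abort(sprintf(
      "'%s': hydroxyl group found; self-associating molecules are out of scope",
      smiles), "vgc_scope_error")
  }

  canon <- canon_subtrees(graph)
  stereo <- stereogenic_bonds(graph, canon)
  if (nrow(stereo) > 0L) {
    n_spec <- inchi_defined_db(smiles)
    if (n_spec < nrow(stereo)) {
      vgc_abort(sprintf(
        "'%s': %d stereogenic double bond(s) but only %d annotated; add E/Z ('/','\\') markers",
        smiles, nrow(stereo), n_spec), "vgc_stereo_error")
    }
    stereo$relation <- stereo_relations(smiles, graph, stereo)
  }

  carbon_count <- sum(graph$elements == "C")
  if (carbon_count < 3L || carbon_count > 8L) {
    rlang::warn(sprintf(
      "'%s' has %d carbon atoms, outside the 3-8 range the group table was calibrated for; prediction is extrapolation",
      smiles, carbon_count), class = "vgc_range_warning")
  }

  structure(list(
    smiles = smiles,
    name = name,
    graph = graph,
    canon = canon,
    carbon_count = carbon_count,
    heavy_count = sum(graph$elements != "H"),
    molar_mass = sum(ATOMIC_MASS[graph$elements]),
    stereo = stereo
  ), class = "vgc_molecule")
}

#' @export
print.vgc_molecule <- function(x, ...) {
  cat(sprintf("<vgc_molecule> %s%s\n", x$smiles,
              if (!is.null(x$name)) paste0(" (", x$name, ")") else ""))
  cat(sprintf("  atoms: %d heavy + %d H; C count: %d; M = %.3f g/mol\n",
              x$heavy_count, sum(x$graph$elements == "H"),
              x$carbon_count, x$molar_mass))
  if (nrow(x$stereo)) {
    cat(sprintf("  stereogenic double bonds: %s\n",
                paste(x$stereo$relation, collapse = ", ")))
  }
  invisible(x)
}

# --- SMILES -> SDF -> graph ------------------------------------------------

smiles_to_sdf <- function(smiles, gen3d = FALSE) {
  args <- c(shQuote(paste0("-:", smiles)), "-osdf",
            if (gen3d) c("--gen3d", "2") else "-h")
  res <- run_obabel(args)
  if (any(grepl("0 molecules converted", res$stderr)) ||
      !any(grepl("V2000", res$stdout))) {
    vgc_abort(sprintf("'%s' is not a valid SMILES string (%s)", smiles,
                      paste(grep("Error|error", res$stderr, value = TRUE),
                            collapse = "; ")),
              "vgc_parse_error")
  }
  res$stdout
}

# Parse a single-molecule V2000 SDF into the internal graph structure.
sdf_to_graph <- function(sdf_lines) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  writeLines(sdf_lines, f)
  set <- suppressWarnings(ChemmineR::read.SDFset(f))
  sdf <- set[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  build_graph(elements, bonds, coords)
}

build_graph <- function(elements, bonds, coords = NULL) {
  n <- length(elements)
  adj <- vector("list", n)
  edge_order <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]; o <- bonds$order[k]
    adj[[a]] <- c(adj[[a]], b); edge_order[[a]] <- c(edge_order[[a]], o)
    adj[[b]] <- c(adj[[b]], a); edge_order[[b]] <- c(edge_order[[b]], o)
  }
  degree <- lengths(adj)
  hcount <- vapply(seq_len(n), function(i) {
    sum(elements[adj[[i]]] == "H")
  }, integer(1))
  list(elements = elements, bonds = bonds, adj = adj,
       edge_order = edge_order, degree = degree, hcount = hcount,
       coords = coords)
}

graph_components <- function(graph) {
  n <- length(graph$elements)
  seen <- logical(n); comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- graph$adj[[u]][!seen[graph$adj[[u]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

# --- canonical subtrees and double-bond stereochemistry --------------------

# canon_subtrees(graph)[[u]][[v]] is a canonical string of the subtree seen
# from atom u through neighbor v (trees only). Used to decide substituent
# distinctness and to pick deterministic stereo reference atoms.
canon_subtrees <- function(graph) {
  memo <- new.env(parent = emptyenv())
  rec <- function(v, parent) {
    key <- paste0(v, "|", parent)
    if (!is.null(memo[[key]])) return(memo[[key]])
    kids <- setdiff(graph$adj[[v]], parent)
    label <- graph$elements[v]
    if (length(kids)) {
      parts <- vapply(kids, function(w) {
        o <- graph$edge_order[[v]][match(w, graph$adj[[v]])]
        paste0(o, rec(w, v))
      }, "")
      label <- paste0(label, "(", paste(sort(parts), collapse = ""), ")")
    }
    memo[[key]] <- label
    label
  }
  n <- length(graph$elements)
  out <- vector("list", n)
  for (u in seq_len(n)) {
    out[[u]] <- lapply(graph$adj[[u]], function(v) rec(v, u))
    names(out[[u]]) <- as.character(graph$adj[[u]])
  }
  out
}

# Carbon-carbon double bonds whose ends each carry two distinct
# substituents: these are the E/Z-relevant ones. Reference substituents are
# the heavy atom with the lexicographically largest subtree string on each
# end (heavy preferred so indices survive conformer round-trips).
stereogenic_bonds <- function(graph, canon) {
  res <- list()
  for (k in seq_len(nrow(graph$bonds))) {
    if (graph$bonds$order[k] != 2L) next
    u <- graph$bonds$a[k]; v <- graph$bonds$b[k]
    if (graph$elements[u] != "C" || graph$elements[v] != "C") next
    # cumulated double bonds (allenes) are not handled as stereogenic here
    if (sum(graph$edge_order[[u]] == 2L) > 1L ||
        sum(graph$edge_order[[v]] == 2L) > 1L) next
    su <- setdiff(graph$adj[[u]], v); sv <- setdiff(graph$adj[[v]], u)
    if (length(su) != 2L || length(sv) != 2L) next
    cu <- unlist(canon[[u]][as.character(su)])
    cv <- unlist(canon[[v]][as.character(sv)])
    if (cu[1] == cu[2] || cv[1] == cv[2]) next
    res[[length(res) + 1L]] <- tibble::tibble(
      u = u, v = v,
      ref_u = pick_ref(graph, su, cu),
      ref_v = pick_ref(graph, sv, cv)
    )
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(u = integer(), v = integer(),
                   ref_u = integer(), ref_v = integer())
  out$relation <- rep(NA_character_, nrow(out))
  out
}

pick_ref <- function(graph, subs, canon_strings) {
  heavy <- graph$elements[subs] != "H"
  if (any(heavy)) {
    subs <- subs[heavy]; canon_strings <- canon_strings[heavy]
  }
  subs[order(canon_strings, subs, decreasing = TRUE)][1]
}

# Count double bonds with defined stereo parity via the InChI /b layer.
inchi_defined_db <- function(smiles) {
  res <- run_obabel(c(shQuote(paste0("-:", smiles)), "-oinchi"))
  line <- grep("^InChI=", res$stdout, value = TRUE)
  if (length(line) == 0L) return(0L)
  layers <- strsplit(line[[1]], "/", fixed = TRUE)[[1]]
  b <- grep("^b", layers, value = TRUE)
  if (length(b) == 0L) return(0L)
  entries <- strsplit(sub("^b", "", b[[1]]), ",", fixed = TRUE)[[1]]
  sum(!grepl("\\?", entries))
}

# Extract the discrete cis/trans label of each stereogenic bond from one
# OpenBabel 3D realization of the annotated SMILES. The embedding is
# stochastic but honors the markers, so the labels are deterministic.
stereo_relations <- function(smiles, graph, stereo) {
  sdf <- smiles_to_sdf(smiles, gen3d = TRUE)
  g3 <- sdf_to_graph(sdf)
  if (!identical(g3$elements, graph$elements)) {
    vgc_abort(sprintf("'%s': inconsistent atom ordering between parses",
                      smiles), "vgc_embed_error")
  }
  vapply(seq_len(nrow(stereo)), function(k) {
    tau <- dihedral(g3$coords[stereo$ref_u[k], ], g3$coords[stereo$u[k], ],
                    g3$coords[stereo$v[k], ], g3$coords[stereo$ref_v[k], ])
    if (abs(tau) < 90) "cis" else "trans"
  }, "")
}

# Signed dihedral angle (degrees) of the chain p1-p2-p3-p4.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
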