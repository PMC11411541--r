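#' Count group occurrences in a molecule
#'
#' Runs the substructure search for every defined group. First-order groups
#' are matched in descending priority and claim their heavy atoms exclusively,
#' so that the first-order groups partition the molecule's heavy atoms;
#' second-order groups (halogenated-carbon corrections) are counted
#' additively without claiming atoms. A molecule with heavy atoms left
#' unclaimed is outside the coverage of the group set and raises a
#' fragmentation error.
#'
#' @param mol A molecule from [parse_molecule()].
#' @param groups Group definition tibble, see [vgc_group_defs()].
#' @return Named integer vector of occurrence counts (zero counts omitted).
#' @examples
#' \dontrun{
#' match_groups(parse_molecule("CC(=O)OC"))  # methyl acetate: 2 CH3 + ester
#' }
#' @export
match_groups <- function(mol, groups = vgc_group_defs()) {
  stopifnot(inherits(mol, "vgc_molecule"))
  graph <- mol$graph
  n <- length(graph$elements)
  claimed <- logical(n)
  counts <- stats::setNames(integer(nrow(groups)), groups$id)

  first <- groups[groups$order == 1L, ]
  first <- first[order(-first$priority, -first$heavy_atoms, first$id), ]
  for (k in seq_len(nrow(first))) {
    pat <- compile_smarts(first$smarts[k])
    for (m in smarts_matches_graph(graph, pat)) {
      heavy_atoms <- m[graph$elements[m] != "H"]
      if (any(claimed[heavy_atoms])) next
      claimed[heavy_atoms] <- TRUE
      counts[first$id[k]] <- counts[first$id[k]] + 1L
    }
  }

  unclaimed <- which(!claimed & graph$elements != "H")
  if (length(unclaimed)) {
    vgc_abort(sprintf(
      "'%s': heavy atom(s) %s (%s) not covered by any first-order group",
      mol$smiles, paste(unclaimed, collapse = ","),
      paste(graph$elements[unclaimed], collapse = ",")),
      "vgc_fragment_error")
  }

  second <- groups[groups$order == 2L, ]
  for (k in seq_len(nrow(second))) {
    pat <- compile_smarts(second$smarts[k])
    counts[second$id[k]] <- length(smarts_matches_graph(graph, pat))
  }

  counts[counts > 0L]
}

#' Detect polar bonds and their unit vectors
#'
#' Locates every occurrence of each defined bond type and computes its unit
#' vector from the conformer coordinates. The vector points from the atom
#' with the higher Pauling electronegativity to the atom with the lower one
#' (for the sp2-/sp3-carbon bond: from the sp2 end, a pure convention since
#' that bond's dipole contribution is fixed at zero). Bonds flagged
#' `fixed_zero` are still reported; their contribution is zeroed downstream.
#'
#' @param mol A molecule from [parse_molecule()].
#' @param conformer A conformer of the same molecule, from
#'   [embed_conformer()].
#' @param bonds Bond definition tibble, see [vgc_bond_defs()].
#' @return Tibble with one row per bond occurrence: `bond_id`, atom indices
#'   `from` (higher EN) and `to`, unit-vector components `ex`, `ey`, `ez`,
#'   and `fixed_zero`.
#' @export
detect_oriented_bonds <- function(mol, conformer, bonds = vgc_bond_defs()) {
  stopifnot(inherits(mol, "vgc_molecule"), inherits(conformer, "vgc_conformer"))
  if (!identical(conformer$elements, mol$graph$elements)) {
    vgc_abort("conformer does not belong to this molecule", "vgc_config_error")
  }
  coords <- conformer$coords
  out <- list()
  for (k in seq_len(nrow(bonds))) {
    pat <- compile_smarts(bonds$smarts[k])
    for (m in smarts_matches_graph(mol$graph, pat)) {
      e <- coords[m[2], ] - coords[m[1], ]
      e <- e / vnorm(e)
      out[[length(out) + 1L]] <- tibble::tibble(
        bond_id = bonds$id[k], from = m[1], to = m[2],
        ex = e[1], ey = e[2], ez = e[3],
        fixed_zero = bonds$fixed_zero[k])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(bond_id = character(), from = integer(),
                          to = integer(), ex = double(), ey = double(),
                          ez = double(), fixed_zero = logical()))
  }
  dplyr::bind_rows(out)
}

#' Fragment a molecule into groups and oriented bonds
#'
#' The full fragmentation pipeline: parse and validate the SMILES, embed a
#' seeded 3D conformer refined with MMFF94, count group occurrences, and
#' compute the oriented unit vectors of all defined polar bonds. The result
#' carries everything the sum rules need.
#'
#' @param smiles Isomeric SMILES string.
#' @param groups,bonds Definition tibbles ([vgc_group_defs()],
#'   [vgc_bond_defs()]).
#' @param seed Integer seed for the conformer embedding.
#' @param name Optional label.
#' @return Object of class `vgc_fragmentation`: `molecule`, `conformer`,
#'   `group_counts` (named integer vector) and `oriented_bonds` (tibble).
#' @examples
#' \dontrun{
#' frag <- fragment("CCCC")
#' frag$group_counts   # CH3: 2, CH2: 2
#' }
#' @export
fragment <- function(smiles, groups = vgc_group_defs(),
                     bonds = vgc_bond_defs(), seed = 42L, name = NULL) {
  use_cache <- missing(groups) && missing(bonds)
  key <- paste(smiles, seed, sep = "\r")
  if (use_cache && !is.null(.vgc_fragment_cache[[key]])) {
    return(.vgc_fragment_cache[[key]])
  }
  mol <- parse_molecule(smiles, name = name)
  conf <- embed_conformer(mol, seed = seed)
  counts <- match_groups(mol, groups)
  ob <- detect_oriented_bonds(mol, conf, bonds)

  # heavy-atom partition invariant, checked on every fragmentation
  ha <- groups$heavy_atoms[match(names(counts), groups$id)]
  covered <- sum(ha * counts)
  if (covered != mol$heavy_count) {
    vgc_abort(sprintf("'%s': heavy-atom partition broken (%d claimed, %d present)",
                      smiles, covered, mol$heavy_count), "vgc_fragment_error")
  }

  out <- structure(list(molecule = mol, conformer = conf,
                        group_counts = counts, oriented_bonds = ob,
                        seed = conf$seed),
                   class = "vgc_fragmentation")
  if (use_cache) .vgc_fragment_cache[[key]] <- out
  out
}

#' @export
print.vgc_fragmentation <- function(x, ...) {
  cat(sprintf("<vgc_fragmentation> %s (seed %d)\n", x$molecule$smiles, x$seed))
  cat("  groups: ", paste(sprintf("%s:%d", names(x$group_counts),
                                  x$group_counts), collapse = ", "), "\n")
  nb <- table(x$oriented_bonds$bond_id)
  cat("  bonds:  ", paste(sprintf("%s:%d", names(nb), nb), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fragment a set of molecules
#'
#' Data-frame-first wrapper around [fragment()]: takes a tibble with a
#' SMILES column, returns one row per molecule with the fragmentation stored
#' in a list column next to basic descriptors. Errors are collected per
#' molecule rather than aborting the whole batch.
#'
#' @param data A data frame with at least the column named in `smiles`.
#' @param smiles Name of the SMILES column (default `"smiles"`).
#' @param groups,bonds,seed Passed to [fragment()].
#' @return The input tibble with added columns `fragmentation` (list),
#'   `carbon_count`, `molar_mass`, `n_polar_bonds` and `error`
#'   (`NA` when fragmentation succeeded).
#' @export
fragment_molecules <- function(data, smiles = "smiles",
                               groups = vgc_group_defs(),
                               bonds = vgc_bond_defs(), seed = 42L) {
  stopifnot(is.data.frame(data), smiles %in% names(data))
  res <- purrr::map(data[[smiles]], function(s) {
    tryCatch(list(frag = fragment(s, groups, bonds, seed), error = NA_character_),
             vgc_error = function(e) list(frag = NULL,
                                          error = conditionMessage(e)))
  })
  tibble::as_tibble(data) |>
    dplyr::mutate(
      fragmentation = purrr::map(res, "frag"),
      error = purrr::map_chr(res, "error"),
      carbon_count = purrr::map_int(fragmentation, function(f)
        if (is.null(f)) NA_integer_ else f$molecule$carbon_count),
      molar_mass = purrr::map_dbl(fragmentation, function(f)
        if (is.null(f)) NA_real_ else f$molecule$molar_mass),
      n_polar_bonds = purrr::map_int(fragmentation, function(f)
        if (is.null(f)) NA_integer_
        else sum(!f$oriented_bonds$fixed_zero))
    )
}
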