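#' Group and bond definitions
#'
#' The fragmentation step is driven by definition tables shipped as JSON, not
#' by code: 16 first-order groups (seven carbon, five oxygen, four halogen)
#' that partition the heavy atoms of a molecule, nine second-order groups
#' describing halogenated-carbon contexts that enter additively as
#' corrections, and eight polar bond types whose unit vectors feed the dipole
#' sum rule. Patterns are SMARTS (a subset sufficient for acyclic aliphatic
#' chemistry; see [smarts_matches()]).
#'
#' First-order overlap is resolved by descending `priority`: multi-atom
#' oxygen groups (formate, ester) claim their atoms before aldehyde/ketone,
#' which claim before ether, then halogen atoms, then the plain carbon
#' groups. Bond definitions are written as ordered atom pairs from the
#' higher-electronegativity atom to the lower (Pauling scale); for the
#' sp2-carbon/sp3-carbon bond the sp2 end is treated as the head, which is
#' inconsequential because its dipole contribution is pinned at zero.
#'
#' @param path Path to a definitions JSON file. Defaults to the shipped set.
#' @return `vgc_group_defs()`: a tibble with columns `id`, `order`, `smarts`,
#'   `heavy_atoms`, `priority`. `vgc_bond_defs()`: a tibble with columns
#'   `id`, `smarts`, `fixed_zero`.
#' @examples
#' vgc_group_defs()
#' vgc_bond_defs()
#' @export
vgc_group_defs <- function(path = NULL) {
  load_defs(path)$groups
}

#' @rdname vgc_group_defs
#' @export
vgc_bond_defs <- function(path = NULL) {
  load_defs(path)$bonds
}

load_defs <- function(path = NULL) {
  path <- path %||% extdata("group_defs.json")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  groups <- tibble::as_tibble(raw$groups)
  bonds <- tibble::as_tibble(raw$bonds)
  stopifnot(!anyDuplicated(groups$id), !anyDuplicated(bonds$id))
  validate_bond_directions(bonds)
  list(groups = groups, bonds = bonds)
}

# The head atom of every bond pattern must not be less electronegative than
# the tail (checked for the single-element patterns; the mixed sp2/sp3
# carbon bond is orientation-fixed by convention).
validate_bond_directions <- function(bonds) {
  for (k in seq_len(nrow(bonds))) {
    pat <- compile_smarts(bonds$smarts[k])
    if (length(pat$atoms) != 2L) {
      vgc_abort(sprintf("bond pattern '%s' must have exactly two atoms",
                        bonds$id[k]), "vgc_config_error")
    }
    e1 <- pat$atoms[[1]]$elems; e2 <- pat$atoms[[2]]$elems
    if (length(e1) == 1L && length(e2) == 1L && e1 != e2) {
      if (PAULING_EN[[e1]] < PAULING_EN[[e2]]) {
        vgc_abort(sprintf(
          "bond '%s' is written tail-first: %s is less electronegative than %s",
          bonds$id[k], e1, e2), "vgc_config_error")
      }
    }
  }
  invisible(bonds)
}
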