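# A small SMARTS-subset matcher over hydrogen-explicit acyclic molecular
# graphs. Supported syntax (sufficient for the shipped group/bond set and
# aliphatic C/H/O/halogen chemistry generally):
#   * bracket atoms [..] with primitives: element symbol (C, O, F, Cl, Br,
#     I, H), X<n> (total connection count, H included), H<n> (attached
#     hydrogen count); ';' for AND, ',' for OR between element symbols.
#   * bare atoms C, O, F, Cl, Br, I (any such element, no further
#     constraint).
#   * bond symbols '-', '=', '#', '~' (default: single).
#   * branches in parentheses. No rings, aromatics, charges, recursion.
# No installed R package exposes atom-mapped substructure search (counts
# only), and atom maps are what both the heavy-atom partition and the
# oriented bond vectors need, hence this matcher.

compile_smarts <- function(smarts) {
  chars <- strsplit(smarts, "")[[1]]
  i <- 1L; n <- length(chars)
  atoms <- list()
  bonds <- list()          # list of c(a, b, order); order NA = any
  stack <- integer()       # open-branch attachment atoms
  prev <- 0L               # atom index the next atom bonds to
  pending_order <- 1L

  peek <- function() if (i <= n) chars[i] else ""
  two <- function() if (i + 1L <= n) paste0(chars[i], chars[i + 1L]) else ""

  add_atom <- function(constraint) {
    atoms[[length(atoms) + 1L]] <<- constraint
    idx <- length(atoms)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- list(a = prev, b = idx,
                                           order = pending_order)
    }
    prev <<- idx
    pending_order <<- 1L
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") { pending_order <- 1L; i <- i + 1L
    } else if (ch == "=") { pending_order <- 2L; i <- i + 1L
    } else if (ch == "#") { pending_order <- 3L; i <- i + 1L
    } else if (ch == "~") { pending_order <- NA_integer_; i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) vgc_abort(sprintf("unclosed bracket in SMARTS '%s'", smarts),
                           "vgc_config_error")
      add_atom(parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                             smarts))
      i <- j + 1L
    } else if (two() %in% c("Cl", "Br")) {
      add_atom(list(elems = two(), X = NA_integer_, H = NA_integer_))
      i <- i + 2L
    } else if (ch %in% c("C", "O", "F", "I", "H")) {
      add_atom(list(elems = ch, X = NA_integer_, H = NA_integer_))
      i <- i + 1L
    } else {
      vgc_abort(sprintf("unsupported SMARTS syntax at '%s' in '%s'",
                        ch, smarts), "vgc_config_error")
    }
  }
  list(atoms = atoms, bonds = bonds)
}

parse_bracket <- function(body, smarts) {
  elems <- character(); X <- NA_integer_; H <- NA_integer_
  for (part in strsplit(body, ";", fixed = TRUE)[[1]]) {
    rest <- part
    while (nzchar(rest)) {
      m <- regmatches(rest, regexpr("^(Cl|Br|X[0-9]|H[0-9]|C|O|F|I|H|,)",
                                    rest))
      if (length(m) == 0L) {
        vgc_abort(sprintf("unsupported SMARTS primitive '%s' in '%s'",
                          rest, smarts), "vgc_config_error")
      }
      tok <- m[[1]]
      if (tok == ",") {
        # separator between OR'd element symbols; nothing to record
      } else if (grepl("^X[0-9]$", tok)) {
        X <- as.integer(substr(tok, 2L, 2L))
      } else if (grepl("^H[0-9]$", tok)) {
        H <- as.integer(substr(tok, 2L, 2L))
      } else {
        elems <- c(elems, tok)
      }
      rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
    }
  }
  list(elems = if (length(elems)) elems else NULL, X = X, H = H)
}

atom_ok <- function(graph, ai, constraint) {
  if (!is.null(constraint$elems) &&
      !(graph$elements[ai] %in% constraint$elems)) return(FALSE)
  if (!is.na(constraint$X) && graph$degree[ai] != constraint$X) return(FALSE)
  if (!is.na(constraint$H) && graph$hcount[ai] != constraint$H) return(FALSE)
  TRUE
}

# All embeddings of a compiled pattern in the molecular graph, deduplicated
# by the set of matched atoms. Returns a list of integer vectors (molecule
# atom index per pattern atom).
smarts_matches_graph <- function(graph, pattern) {
  natoms <- length(pattern$atoms)
  if (natoms == 0L) return(list())

  # bonds of pattern atom k to earlier atoms (tree patterns: exactly one
  # for k > 1)
  attach <- vector("list", natoms)
  for (b in pattern$bonds) {
    hi <- max(b$a, b$b); lo <- min(b$a, b$b)
    attach[[hi]] <- c(attach[[hi]], list(list(prev = lo, order = b$order)))
  }

  results <- list()
  assign_next <- function(map, used, k) {
    if (k > natoms) {
      results[[length(results) + 1L]] <<- map
      return(invisible())
    }
    att <- attach[[k]][[1L]]
    base <- map[att$prev]
    for (cand in graph$adj[[base]]) {
      if (used[cand]) next
      if (!is.na(att$order) &&
          graph$edge_order[[base]][match(cand, graph$adj[[base]])] !=
            att$order) next
      if (!atom_ok(graph, cand, pattern$atoms[[k]])) next
      map[k] <- cand; used[cand] <- TRUE
      assign_next(map, used, k + 1L)
      used[cand] <- FALSE
    }
  }

  for (start in seq_along(graph$elements)) {
    if (!atom_ok(graph, start, pattern$atoms[[1L]])) next
    map <- integer(natoms); map[1L] <- start
    used <- logical(length(graph$elements)); used[start] <- TRUE
    if (natoms == 1L) results[[length(results) + 1L]] <- map
    else assign_next(map, used, 2L)
  }

  if (length(results) > 1L) {
    keys <- vapply(results, function(m) paste(sort(m), collapse = ","), "")
    results <- results[!duplicated(keys)]
  }
  results
}

#' Match a SMARTS pattern against a parsed molecule
#'
#' Exposes the package's substructure matcher: returns every embedding of
#' `smarts` (see [vgc_group_defs()] for the supported subset) in the
#' hydrogen-explicit molecular graph of `mol`, as a list of atom-index
#' vectors, deduplicated by matched atom set.
#'
#' @param mol A molecule from [parse_molecule()].
#' @param smarts A SMARTS pattern string.
#' @return List of integer vectors, one per match; each maps pattern atoms
#'   to atom indices of `mol`.
#' @examples
#' \dontrun{
#' mol <- parse_molecule("CCOC")
#' smarts_matches(mol, "[CX4H3]")   # two methyl carbons
#' }
#' @export
smarts_matches <- function(mol, smarts) {
  stopifnot(inherits(mol, "vgc_molecule"))
  smarts_matches_graph(mol$graph, compile_smarts(smarts))
}
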