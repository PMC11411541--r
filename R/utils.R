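# Internal helpers: typed conditions, OpenBabel subprocess wrappers,
# element data, reproducible RNG, stable JSON serialization.

# Condition classes used throughout the package. Every user-facing error is
# one of these so callers (and the CLI) can branch on failure kind:
#   vgc_parse_error   - SMILES does not parse
#   vgc_scope_error   - molecule outside the method's applicability domain
#   vgc_stereo_error  - geometrically ambiguous double bond without E/Z label
#   vgc_embed_error   - 3D embedding / force-field refinement failed
#   vgc_fragment_error- heavy atoms left unclaimed by first-order groups
#   vgc_coverage_error- parameter table missing a referenced id
#   vgc_parameter_error - unphysical parameter combination (m <= 0)
#   vgc_config_error  - missing backend / invalid configuration
vgc_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "vgc_error"), ...)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Pauling electronegativities for the supported element set. Shipped as a
# constant (not config) because the supported elements are fixed by scope.
PAULING_EN <- c(H = 2.20, C = 2.55, O = 3.44, F = 3.98,
                Cl = 3.16, Br = 2.96, I = 2.66)

# Standard atomic weights, g/mol (IUPAC 2021 abridged).
ATOMIC_MASS <- c(H = 1.008, C = 12.011, O = 15.999, F = 18.998,
                 Cl = 35.45, Br = 79.904, I = 126.904)

ALLOWED_ELEMENTS <- c("C", "H", "O", "F", "Cl", "Br", "I")

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    vgc_abort("OpenBabel ('obabel') not found on the PATH.", "vgc_config_error")
  }
  p
}

# Run obabel, returning list(stdout, stderr, status). Never throws on a
# non-zero exit by itself; callers interpret the output.
run_obabel <- function(args, stdin_text = NULL) {
  infile <- NULL
  if (!is.null(stdin_text)) {
    infile <- tempfile(fileext = ".sdf")
    writeLines(stdin_text, infile)
    on.exit(unlink(infile), add = TRUE)
    args <- c(infile, args)
  }
  out <- tempfile(); err <- tempfile()
  on.exit(unlink(c(out, err)), add = TRUE)
  status <- suppressWarnings(
    system2(obabel_path(), args = args, stdout = out, stderr = err)
  )
  list(stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE),
       status = status)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable JSON: fixed key order (as supplied), 9 significant digits, no
# auto-vector boxing surprises -- byte-identical across runs for equal input.
write_json_stable <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(9), pretty = TRUE,
                          null = "null", na = "null")
  writeLines(txt, path)
  invisible(path)
}

signif9 <- function(x) signif(x, 9)

# Vector norm helper used in several modules.
vnorm <- function(v) sqrt(sum(v * v))

# In-session memoization of fragment() under the default definitions:
# conformer embedding shells out to OpenBabel, and regressions revisit the
# same molecules constantly.
.vgc_fragment_cache <- new.env(parent = emptyenv())

extdata <- function(...) {
  system.file("extdata", ..., package = "vectorgc", mustWork = TRUE)
}
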