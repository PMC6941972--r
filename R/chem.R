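# Cheminformatics primitives, delegated to RDKit through a batched Python
# subprocess bridge (inst/python/chem_bridge.py). Validity, canonical
# SMILES, MACCS keys, Morgan fingerprints, Fraggle similarity, the
# Ertl-Schuffenhauer synthetic-accessibility score and Murcko scaffolds are
# standard toolkit operations; every call ships a whole SMILES batch to one
# interpreter launch, so callers should batch.

chem_python <- function() {
  p <- Sys.getenv("GEXMOL_PYTHON", "python")
  if (Sys.which(p) == "" && p == "python") p <- "python3"
  p
}

chem_bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "gexmol")
  if (!nzchar(path)) path <- file.path("inst", "python", "chem_bridge.py")
  if (!file.exists(path)) {
    stop_gexmol("chem_bridge.py not found; is the package installed?",
                class = "gexmol_chem_error")
  }
  path
}

#' Low-level call into the RDKit bridge
#'
#' @param op Bridge operation (`"canonical"`, `"fingerprint"`, `"fraggle"`,
#'   `"sa_score"`, `"murcko"`).
#' @param ... Operation payload fields (see `inst/python/chem_bridge.py`).
#' @return Parsed JSON response as an R list.
#' @keywords internal
#' @export
chem_bridge <- function(op, ...) {
  req <- jsonlite::toJSON(c(list(op = op), list(...)),
                          auto_unbox = TRUE, null = "null", digits = NA)
  out <- suppressWarnings(
    system2(chem_python(), shQuote(chem_bridge_script()),
            input = as.character(req), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop_gexmol("chemistry bridge failed (python + RDKit required): %s",
                paste(utils::tail(out, 3L), collapse = " | "),
                class = "gexmol_chem_error")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

#' Canonicalize SMILES strings with the chemistry toolkit
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` where sanitization
#'   fails.
#' @export
chem_canonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  res <- chem_bridge("canonical", smiles = as.list(as.character(smiles)))
  vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x, "")
}

#' Chemical validity under toolkit sanitization
#'
#' A decoded SMILES counts as valid when the toolkit parses and sanitizes
#' it (valence, aromaticity and ring-closure checks).
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector.
#' @export
chem_is_valid <- function(smiles) {
  if (!length(smiles)) return(logical(0))
  res <- chem_bridge("canonical", smiles = as.list(as.character(smiles)))
  vapply(res$valid, isTRUE, TRUE)
}

#' Structural fingerprints as on-bit index sets
#'
#' @param smiles Character vector of SMILES.
#' @param type `"maccs"` (166 structural keys) or `"morgan"` (circular
#'   substructures; defaults radius 3, 1024 bits).
#' @param radius,nbits Morgan parameters.
#' @return List of 0-based on-bit integer vectors (`NULL` for unparseable
#'   input).
#' @export
chem_fingerprint <- function(smiles, type = c("maccs", "morgan"),
                             radius = 3L, nbits = 1024L) {
  type <- match.arg(type)
  if (!length(smiles)) return(list())
  res <- chem_bridge("fingerprint", smiles = as.list(as.character(smiles)),
                     type = type, radius = radius, nbits = nbits)
  lapply(res$bits, function(b) if (is.null(b)) NULL else as.integer(b))
}

#' Tanimoto similarity of two on-bit index sets
#' @param a,b Integer vectors of on-bit indices.
#' @return Jaccard/Tanimoto coefficient in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Ertl-Schuffenhauer synthetic accessibility scores
#' @param smiles Character vector of SMILES.
#' @return Numeric scores (roughly 1 = easy to 10 = hard); `NA` where the
#'   molecule does not parse.
#' @export
sa_scores <- function(smiles) {
  if (!length(smiles)) return(numeric(0))
  res <- chem_bridge("sa_score", smiles = as.list(as.character(smiles)))
  vapply(res$scores, function(x) if (is.null(x)) NA_real_ else x, 0)
}

#' Murcko scaffolds
#'
#' @param smiles Character vector of SMILES.
#' @param generic Abstract atom and bond types (all atoms carbon, all bonds
#'   single) to obtain the generic framework.
#' @return Character vector of scaffold SMILES (`""` for acyclic molecules,
#'   `NA` for unparseable input).
#' @export
murcko_scaffold <- function(smiles, generic = FALSE) {
  if (!length(smiles)) return(character(0))
  res <- chem_bridge("murcko", smiles = as.list(as.character(smiles)),
                     generic = generic)
  vapply(res$scaffold, function(x) if (is.null(x)) NA_character_ else x, "")
}
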