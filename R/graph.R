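# Lightweight SMILES -> molecular graph reader and structural descriptors.
#
# The synthetic world links molecules to expression signatures through a
# small vector of structural descriptors; those must be computable for any
# grammar-derivable string (including decoder outputs that a strict
# sanitizer would reject), so this reader is deliberately lenient: an
# unmatched ring-closure digit or a dangling bond contributes no edge
# instead of failing.

smiles_graph_tokens <- function(smiles) {
  pat <- "\\[[^][]*\\]|Cl|Br|@@|[BCNOSPFIcnos]|[0-9]|[-=#/\\\\()@]|."
  m <- gregexpr(pat, smiles)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(smiles, gregexpr(pat, smiles))[[1]]
}

#' Parse a SMILES string into a molecular graph
#'
#' Heavy-atom graph only (implicit hydrogens ignored). Bracket atoms are
#' reduced to their element symbol; aromaticity is taken from lowercase
#' notation.
#'
#' @param smiles A SMILES string.
#' @return List with `symbol` (element per atom), `aromatic` (logical per
#'   atom) and `edges` (2-column matrix of atom indices; one row per bond).
#' @export
smiles_graph <- function(smiles) {
  toks <- smiles_graph_tokens(smiles)
  sym <- character(0); arom <- logical(0)
  edges <- matrix(0L, 0L, 2L)
  prev <- NA_integer_
  stack <- integer(0)
  ring <- list()
  for (tk in toks) {
    if (grepl("^\\[", tk)) {
      inner <- regmatches(tk, regexpr("Cl|Br|[BCNOSPFI]|[cnos]", tk))
      if (!length(inner)) next
      a <- inner
    } else if (tk %in% c("B","C","N","O","S","P","F","I","Cl","Br",
                         "c","n","o","s")) {
      a <- tk
    } else if (tk == "(") {
      if (!is.na(prev)) stack <- c(stack, prev)
      next
    } else if (tk == ")") {
      if (length(stack)) {
        prev <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
      }
      next
    } else if (grepl("^[0-9]$", tk)) {
      if (is.na(prev)) next
      open <- ring[[tk]]
      if (is.null(open)) {
        ring[[tk]] <- prev
      } else {
        if (open != prev) edges <- rbind(edges, c(open, prev))
        ring[[tk]] <- NULL
      }
      next
    } else {
      next  # bond orders and stereo marks do not change the heavy-atom graph
    }
    sym <- c(sym, paste0(toupper(substr(a, 1L, 1L)), substr(a, 2L, nchar(a))))
    arom <- c(arom, a %in% c("c", "n", "o", "s"))
    id <- length(sym)
    if (!is.na(prev)) edges <- rbind(edges, c(prev, id))
    prev <- id
  }
  list(symbol = sym, aromatic = arom, edges = edges)
}

graph_components <- function(n, edges) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

#' Structural descriptor vector of a molecule
#'
#' The five descriptors mediating the synthetic molecule-to-signature map:
#' heavy-atom count, aromatic-atom count, ring count (cycle rank of the
#' heavy-atom graph), heteroatom count (non-carbon heavy atoms) and
#' branching count (atoms of graph degree three or more). Deterministic in
#' the input string.
#'
#' @param smiles A SMILES string (or a vector; rows are returned in order).
#' @return A named numeric vector of length 5, or a matrix with one row per
#'   input when `smiles` has length > 1.
#' @examples
#' descriptor_vector("c1ccccc1")
#' @export
descriptor_vector <- function(smiles) {
  one <- function(s) {
    gph <- smiles_graph(s)
    n <- length(gph$symbol)
    if (n == 0L) {
      stop_gexmol("no atoms found in SMILES '%s'", s,
                  class = "gexmol_parse_error")
    }
    deg <- tabulate(gph$edges, nbins = n)
    comps <- graph_components(n, gph$edges)
    out <- c(heavy_atoms = n,
             aromatic_atoms = sum(gph$aromatic),
             rings = nrow(gph$edges) - n + comps,
             heteroatoms = sum(gph$symbol != "C"),
             branch_points = sum(deg >= 3L))
    storage.mode(out) <- "double"
    out
  }
  if (length(smiles) == 1L) return(one(smiles))
  t(vapply(smiles, one, numeric(5)))
}
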