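# Desk-scale synthetic data: a toy molecule corpus plus a known
# molecule -> signature mapping with Gaussian noise, emulating L1000-style
# paired data (z-scored landmark-gene signatures "induced" by molecules)
# and knock-out-like query signatures that carry no paired molecule.
#
# Signatures depend on the molecule only through its structural descriptor
# vector, signature = standardize(A d(mol) + eps), so condition fulfilment
# of generated molecules is measurable post hoc by comparing their
# descriptors with a query's target descriptor profile.

# ---------------------------------------------------------------------------
# Corpus enumeration

VALENCE_CAP <- c(C = 4L, N = 3L, O = 2L)

# random acyclic skeleton over C/N/O respecting valence; optional terminal
# carbonyl; written by depth-first traversal with branch parentheses
random_tree_smiles <- function(n_heavy) {
  syms <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                 prob = c(0.72, 0.14, 0.14))
  deg <- rep.int(0L, n_heavy)
  parent <- rep.int(NA_integer_, n_heavy)
  for (i in seq_len(n_heavy)[-1]) {
    cand <- which(deg[seq_len(i - 1L)] < VALENCE_CAP[syms[seq_len(i - 1L)]])
    if (!length(cand)) return(NULL)
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    parent[i] <- p
    deg[p] <- deg[p] + 1L
    deg[i] <- deg[i] + 1L
  }
  kids <- split(seq_len(n_heavy)[-1], factor(parent[-1], levels = seq_len(n_heavy)))
  carbonyl <- integer(0)
  term_c <- which(syms == "C" & deg <= 2L)
  if (length(term_c) && runif(1) < 0.35) {
    carbonyl <- if (length(term_c) == 1L) term_c else sample(term_c, 1L)
  }
  emit <- function(i) {
    s <- syms[[i]]
    if (i %in% carbonyl) s <- paste0(s, "(=O)")
    ch <- kids[[i]]
    if (length(ch) == 0L) return(s)
    sub <- vapply(ch, emit, "")
    paste0(s, paste0("(", sub[-length(sub)], ")", collapse = ""),
           sub[length(sub)])
  }
  emit(1L)
}

aromatic_templates <- function() {
  subs <- c("C", "CC", "O", "N", "OC", "NC", "C(C)C", "CO", "CN", "Cl", "F")
  cores <- list(
    benzene  = function(p) sprintf("c1c%sc%sc%sc%sc1%s", p[1], p[2], p[3], p[4], p[5]),
    pyridine = function(p) sprintf("c1c%sc%sc%snc1%s", p[1], p[2], p[3], p[4]),
    furan    = function(p) sprintf("c1c%sc%soc1%s", p[1], p[2], p[3]),
    thiophene = function(p) sprintf("c1c%sc%ssc1%s", p[1], p[2], p[3]),
    pyrrole  = function(p) sprintf("c1c%sc%s[nH]c1%s", p[1], p[2], p[3]),
    cyclopentane = function(p) sprintf("C1C%sC%sC%sC1%s", p[1], p[2], p[3], p[4]),
    cyclohexane  = function(p) sprintf("C1C%sC%sC%sCC1%s", p[1], p[2], p[3], p[4]))
  out <- character(0)
  for (core in cores) {
    nslot <- length(formals(core))  # unused; slots given by sprintf arity
    k <- length(gregexpr("%s", deparse1(body(core)))[[1]])
    for (rep_ in 1:120) {
      nsub <- sample(0:2, 1L, prob = c(0.3, 0.45, 0.25))
      p <- rep("", k)
      if (nsub > 0L) {
        at <- sample(k, nsub)
        p[at] <- paste0("(", sample(subs, nsub, replace = TRUE), ")")
      }
      # last slot is an unparenthesised tail substituent position
      if (nzchar(p[k])) p[k] <- substr(p[k], 2L, nchar(p[k]) - 1L)
      out <- c(out, core(p))
    }
  }
  out
}

#' Generate a toy SMILES corpus
#'
#' Seeded enumeration of small alkanes/amines/ethers (random valence-capped
#' trees over C/N/O, occasional carbonyl) and substituted small (hetero)
#' aromatic and alicyclic rings. The returned corpus is canonicalized with
#' the chemistry toolkit, de-duplicated and guaranteed to tokenize under
#' the shipped grammar.
#'
#' @param n Number of distinct molecules.
#' @param complexity `"small"` (2-8 heavy atoms per acyclic skeleton) or
#'   `"medium"` (2-12).
#' @param seed RNG seed; same seed, same corpus.
#' @return Character vector of `n` distinct canonical SMILES.
#' @examples
#' \donttest{make_corpus(10, seed = 1)}
#' @export
make_corpus <- function(n, complexity = c("small", "medium"), seed = 1L) {
  complexity <- match.arg(complexity)
  stopifnot(n >= 1L)
  max_heavy <- if (complexity == "small") 8L else 12L
  pool <- with_seed(derive_seed(seed, "corpus"), {
    trees <- character(0)
    for (k in seq_len(max(12L * n, 1200L))) {
      s <- random_tree_smiles(sample(2:max_heavy, 1L))
      if (!is.null(s)) trees <- c(trees, s)
    }
    c(trees, aromatic_templates())
  })
  canon <- chem_canonical(pool)
  canon <- canon[!is.na(canon)]
  canon <- canon[!duplicated(canon)]
  g <- build_grammar()
  ok <- vapply(canon, function(s) {
    !inherits(tryCatch(smiles_tokenize(s, g), error = identity), "error")
  }, TRUE)
  canon <- canon[ok]
  if (length(canon) < n) {
    stop_gexmol("only %d distinct molecules enumerable at complexity '%s' (requested %d)",
                length(canon), complexity, n, class = "gexmol_config_error")
  }
  with_seed(derive_seed(seed, "corpus_sample"),
            sample(canon, n))
}

# ---------------------------------------------------------------------------
# Synthetic world

#' Create a synthetic molecule/signature world
#'
#' Fixes the corpus, a random projection `A` (genes x descriptors) and the
#' per-gene standardization parameters computed from the corpus' noiseless
#' signatures, so that signatures from [make_signature()] emulate z-scored
#' landmark-gene consensus profiles.
#'
#' @param corpus Character vector of SMILES (see [make_corpus()]).
#' @param n_genes Number of landmark genes `G` (978 at assay scale; the
#'   desk-scale default is 64).
#' @param noise_sd Gaussian noise standard deviation on the raw signature.
#' @param seed Seed fixing `A`.
#' @return An object of class `synthetic_world`.
#' @export
synthetic_world <- function(corpus, n_genes = 64L, noise_sd = 0.1,
                            seed = 1L) {
  stopifnot(length(corpus) >= 2L, n_genes >= 2L, noise_sd >= 0)
  D <- descriptor_vector(corpus)
  d <- ncol(D)
  A <- with_seed(derive_seed(seed, "projection"),
                 matrix(rnorm(n_genes * d), n_genes, d))
  raw <- D %*% t(A)
  gene_mean <- colMeans(raw)
  gene_sd <- apply(raw, 2L, stats::sd)
  gene_sd[gene_sd < 1e-8] <- 1
  structure(list(corpus = corpus, A = A, n_genes = as.integer(n_genes),
                 n_desc = d, noise_sd = noise_sd,
                 descriptors = D, gene_mean = gene_mean, gene_sd = gene_sd,
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d molecules, %d genes, %d descriptors, noise sd %.3g\n",
              length(x$corpus), x$n_genes, x$n_desc, x$noise_sd))
  invisible(x)
}

signature_from_descriptors <- function(target, world, noise) {
  raw <- drop(world$A %*% target) + noise
  (raw - world$gene_mean) / world$gene_sd
}

#' Expression signature induced by a molecule
#'
#' `signature = standardize(A d(mol) + eps)`, `eps ~ N(0, noise_sd^2 I)`,
#' standardized per gene with the world's corpus-wide parameters.
#'
#' @param smiles A SMILES string.
#' @param world A `synthetic_world`.
#' @param seed Seed for the noise draw; `NULL` draws from the current RNG.
#' @return Numeric vector of length `world$n_genes`.
#' @export
make_signature <- function(smiles, world, seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  d <- descriptor_vector(smiles)
  if (length(d) != world$n_desc) {
    stop_gexmol("descriptor dimension %d does not match world (%d)",
                length(d), world$n_desc, class = "gexmol_shape_error")
  }
  noise <- with_seed(seed, rnorm(world$n_genes, sd = world$noise_sd))
  signature_from_descriptors(d, world, noise)
}

#' Build the paired training set and held-out query signatures
#'
#' Pairs every corpus molecule with one noisy induced signature, and builds
#' `n_query` knock-out-like query signatures from synthetic target
#' descriptor profiles that match no corpus molecule: each target is the
#' jittered midpoint of two corpus descriptor vectors, accepted only if its
#' Euclidean distance to every corpus descriptor vector is at least
#' `margin` (checked exhaustively).
#'
#' @param world A `synthetic_world`.
#' @param seed RNG seed (noise draws, query construction).
#' @param n_query Number of query signatures.
#' @param margin Minimum descriptor-space distance between a query target
#'   and any corpus molecule.
#' @return List with `smiles`, `signatures` (n x G), `descriptors` (n x d),
#'   `query_signatures` (n_query x G) and `query_targets` (n_query x d).
#' @export
make_paired_dataset <- function(world, seed = 1L, n_query = 20L,
                                margin = 0.5) {
  stopifnot(inherits(world, "synthetic_world"))
  n <- length(world$corpus)
  G <- world$n_genes
  sigs <- with_seed(derive_seed(seed, "pair_noise"), {
    noise <- matrix(rnorm(n * G, sd = world$noise_sd), n, G)
    t(vapply(seq_len(n), function(i)
      signature_from_descriptors(world$descriptors[i, ], world, noise[i, ]),
      numeric(G)))
  })
  qry <- with_seed(derive_seed(seed, "queries"), {
    targets <- matrix(0, n_query, world$n_desc)
    qsig <- matrix(0, n_query, G)
    for (q in seq_len(n_query)) {
      for (try in seq_len(500L)) {
        ij <- sample(n, 2L)
        tgt <- colMeans(world$descriptors[ij, , drop = FALSE]) +
          rnorm(world$n_desc, sd = 0.3)
        tgt <- pmax(tgt, 0)
        dmin <- min(sqrt(rowSums(sweep(world$descriptors, 2L, tgt)^2)))
        if (dmin >= margin) break
      }
      if (dmin < margin) {
        stop_gexmol("could not place query %d at margin %.2f", q, margin,
                    class = "gexmol_config_error")
      }
      targets[q, ] <- tgt
      qsig[q, ] <- signature_from_descriptors(
        tgt, world, rnorm(G, sd = world$noise_sd))
    }
    list(targets = targets, qsig = qsig)
  })
  colnames(qry$targets) <- colnames(world$descriptors)
  list(smiles = world$corpus, signatures = sigs,
       descriptors = world$descriptors,
       query_signatures = qry$qsig, query_targets = qry$targets)
}

#' Ridge-regression recoverability of descriptors from signatures
#'
#' Sanity check that the conditioning task is learnable: fits a ridge
#' regression from signatures to each descriptor and returns the mean
#' in-sample R^2.
#'
#' @param signatures n x G signature matrix.
#' @param descriptors n x d descriptor matrix.
#' @param lambda Ridge penalty.
#' @return Mean R^2 across descriptor columns.
#' @export
descriptor_recoverability <- function(signatures, descriptors,
                                      lambda = 1e-2) {
  X <- scale(signatures, scale = FALSE)
  Y <- scale(descriptors, scale = FALSE)
  # ridge as augmented least squares on centred data
  Xa <- rbind(X, sqrt(lambda) * diag(ncol(X)))
  r2 <- vapply(seq_len(ncol(Y)), function(j) {
    fit <- stats::lm.fit(Xa, c(Y[, j], rep(0, ncol(X))))
    pred <- X %*% fit$coefficients
    1 - sum((Y[, j] - pred)^2) / sum(Y[, j]^2)
  }, 0)
  mean(r2)
}
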