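# Result-side computations: per-signature generation and decoding,
# validity / uniqueness / synthesizability accounting, fingerprint and
# fragment similarity, scaffold analysis, the signature nearest-neighbour
# baseline and the conditional classification-score comparison.

#' Generate and decode molecules for one expression signature
#'
#' Draws `n` noise vectors, generates latents (stage II refinement of
#' stage I by default), decodes them through the translator, and scores the
#' results: validity by toolkit sanitization, uniqueness by canonical
#' SMILES, synthesizability by SA score below the threshold.
#'
#' @param signature Expression signature vector.
#' @param n Molecules to generate (the publication protocol uses 1000 per
#'   signature).
#' @param gan A `gexmol_gan` fit (or `gan_params`).
#' @param translator A fitted `smiles_translator`.
#' @param stage Generate from stage I or stage II.
#' @param sa_threshold SA-score cutoff counting as synthesizable.
#' @param seed Seed for noise and decoding.
#' @return An object of class `generation_report`: counts (`generated`,
#'   `decoded`, `valid`, `unique_valid`, `synthesizable`) plus the decoded
#'   SMILES and their canonical forms.
#' @export
generate_for_signature <- function(signature, n, gan, translator,
                                   stage = 2L, sa_threshold = 4.5,
                                   seed = 1L) {
  stopifnot(n >= 1L, inherits(translator, "smiles_translator"))
  fit <- if (inherits(gan, "gexmol_gan")) gan else NULL
  if (is.null(fit)) {
    stop_gexmol("expected a fitted gexmol_gan object",
                class = "gexmol_config_error")
  }
  lat <- predict(fit, signature, n = n, stage = stage,
                 seed = derive_seed(seed, "gen_noise"))
  dec <- decode_latent(lat, translator)
  ok <- !is.na(dec)
  canon <- rep(NA_character_, n)
  valid <- logical(n)
  if (any(ok)) {
    canon[ok] <- chem_canonical(dec[ok])
    valid[ok] <- !is.na(canon[ok])
  }
  uniq <- unique(canon[valid])
  synth <- if (length(uniq)) sum(sa_scores(uniq) < sa_threshold) else 0L
  structure(list(generated = as.integer(n),
                 decoded = sum(ok),
                 valid = sum(valid),
                 unique_valid = length(uniq),
                 synthesizable = as.integer(synth),
                 smiles = dec, canonical = canon,
                 sa_threshold = sa_threshold),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("generation report: %d generated, %d decoded, %d valid (%.1f%%), %d unique, %d with SA < %.1f\n",
              x$generated, x$decoded, x$valid, 100 * x$valid / x$generated,
              x$unique_valid, x$synthesizable, x$sa_threshold))
  invisible(x)
}

#' Filter molecules by synthetic accessibility
#'
#' Keeps molecules whose Ertl-Schuffenhauer SA score is below the
#' threshold; unparseable entries are dropped with a message.
#'
#' @param smiles Character vector of SMILES.
#' @param threshold SA-score cutoff (default 4.5).
#' @return The retained SMILES.
#' @export
sa_filter <- function(smiles, threshold = 4.5) {
  if (!length(smiles)) return(character(0))
  sc <- sa_scores(smiles)
  if (anyNA(sc)) {
    message(sprintf("sa_filter: skipping %d unparseable molecule(s)",
                    sum(is.na(sc))))
  }
  smiles[!is.na(sc) & sc < threshold]
}

#' Molecular similarity between two molecules
#'
#' Tanimoto similarity over MACCS keys or Morgan fingerprints (radius 3,
#' 1024 bits), or Fraggle fragment-decomposition similarity.
#'
#' @param query,reference SMILES strings.
#' @param metric `"maccs"`, `"morgan"` or `"fraggle"`.
#' @return A one-row data frame (`query`, `reference`, `metric`, `value`)
#'   with `value` in `[0, 1]`.
#' @export
similarity <- function(query, reference,
                       metric = c("maccs", "morgan", "fraggle")) {
  metric <- match.arg(metric)
  rec <- similarity_to_set(query, reference, metric)
  if (anyNA(rec$value)) {
    stop_gexmol("unparseable SMILES in similarity computation",
                class = "gexmol_chem_error")
  }
  rec
}

# vectorized core: similarity of one query against a reference set
similarity_to_set <- function(query, references, metric) {
  if (metric == "fraggle") {
    res <- chem_bridge("fraggle",
                       queries = as.list(rep(query, length(references))),
                       refs = as.list(as.character(references)))
    val <- vapply(res$sim, function(x) if (is.null(x)) NA_real_ else x, 0)
  } else {
    fps <- chem_fingerprint(c(query, references), type = metric)
    qf <- fps[[1]]
    val <- vapply(seq_along(references), function(i) {
      rf <- fps[[i + 1L]]
      if (is.null(qf) || is.null(rf)) NA_real_ else tanimoto(qf, rf)
    }, 0)
  }
  data.frame(query = query, reference = as.character(references),
             metric = metric, value = val, stringsAsFactors = FALSE)
}

#' Closest known active by molecular similarity
#'
#' @param query SMILES string.
#' @param actives Nonempty character vector of reference SMILES.
#' @param metric `"maccs"`, `"morgan"` or `"fraggle"`.
#' @return One-row data frame for the most similar active (ties broken by
#'   first occurrence).
#' @export
max_similarity_to_set <- function(query, actives,
                                  metric = c("maccs", "morgan", "fraggle")) {
  metric <- match.arg(metric)
  if (!length(actives)) {
    stop_gexmol("empty actives set", class = "gexmol_config_error")
  }
  rec <- similarity_to_set(query, actives, metric)
  best <- which.max(rec$value)
  rec[best, , drop = FALSE]
}

#' Murcko scaffold overlap between generated and active molecules
#'
#' Extracts (optionally generic) Murcko scaffolds for both sets and
#' reports the scaffolds occurring in both; unparseable or acyclic
#' molecules contribute no scaffold.
#'
#' @param generated,actives Character vectors of SMILES.
#' @param generic Use generic frameworks (atoms to carbon, bonds to
#'   single).
#' @return List with `n_generated`, `n_active` (distinct scaffold counts),
#'   `overlap` and `shared` (the shared scaffold SMILES).
#' @export
scaffold_overlap <- function(generated, actives, generic = FALSE) {
  scaf <- function(smiles) {
    s <- murcko_scaffold(smiles, generic = generic)
    bad <- is.na(s)
    if (any(bad)) {
      message(sprintf("scaffold_overlap: skipping %d unparseable molecule(s)",
                      sum(bad)))
    }
    unique(s[!bad & nzchar(s)])
  }
  sg <- scaf(generated)
  sa <- scaf(actives)
  shared <- intersect(sg, sa)
  list(n_generated = length(sg), n_active = length(sa),
       overlap = length(shared), shared = shared)
}

#' Nearest compound-induced signature in a training library
#'
#' The similarity-search baseline: returns the library record whose
#' signature is closest to the query under Euclidean or cosine distance
#' (cosine distance = 1 - cosine similarity); ties break by first
#' occurrence.
#'
#' @param query Query signature vector.
#' @param library_signatures n x G matrix of library signatures.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return List with `index`, `distance`.
#' @export
signature_nn_search <- function(query, library_signatures,
                                metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  M <- as.matrix(library_signatures)
  if (nrow(M) == 0L) {
    stop_gexmol("empty signature library", class = "gexmol_config_error")
  }
  if (length(query) != ncol(M)) {
    stop_gexmol("query dimension %d does not match library (%d)",
                length(query), ncol(M), class = "gexmol_shape_error")
  }
  d <- if (metric == "euclidean") {
    sqrt(rowSums(sweep(M, 2L, query)^2))
  } else {
    qn <- sqrt(sum(query^2))
    1 - (M %*% query) / (sqrt(rowSums(M^2)) * qn)
  }
  i <- unname(which.min(d))
  list(index = i, distance = unname(d[i]))
}

#' Compare conditional classification scores of two molecule sets
#'
#' Scores both sets with the conditional matching network (higher score =
#' condition better fulfilled) and tests whether set A scores higher than
#' set B with a one-sided Mann-Whitney U test (exact for small untied
#' samples, normal approximation with continuity and tie correction
#' otherwise).
#'
#' @param x_a,c_a Latents and signatures of set A.
#' @param x_b,c_b Latents and signatures of set B.
#' @param gan A `gan_params` object (or `gexmol_gan` fit).
#' @param stage Conditional network to use (1, the stage whose score the
#'   conditioned generation optimizes first, or 2).
#' @return List with `scores_a`, `scores_b`, `statistic` (U for set A) and
#'   `p_value` for the alternative A > B.
#' @export
classification_score_compare <- function(x_a, c_a, x_b, c_b, gan,
                                         stage = 1L) {
  if (inherits(gan, "gexmol_gan")) gan <- gan$params
  if (NROW(x_a) == 0L || NROW(x_b) == 0L) {
    stop_gexmol("empty molecule set", class = "gexmol_config_error")
  }
  sa <- conditional_score(x_a, c_a, gan, stage)
  sb <- conditional_score(x_b, c_b, gan, stage)
  # ties fall back to the normal approximation; the warning is expected
  wt <- suppressWarnings(stats::wilcox.test(sa, sb, alternative = "greater",
                                            correct = TRUE, exact = NULL))
  list(scores_a = sa, scores_b = sb,
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Optimize a scaffold toward an expression signature
#'
#' Encodes the scaffold into the latent space, refines the latent with the
#' stage-II generator under the signature condition, and decodes the
#' result (deterministic in argmax mode).
#'
#' @param scaffold Scaffold SMILES (e.g. `"c1ccccc1"`).
#' @param signature Conditioning signature vector.
#' @param gan A `gexmol_gan` fit (or `gan_params`).
#' @param translator A fitted `smiles_translator`.
#' @return Decoded SMILES string (`NA` if decoding truncated), with the
#'   input scaffold as attribute.
#' @export
optimize_scaffold <- function(scaffold, signature, gan, translator) {
  if (inherits(gan, "gexmol_gan")) gan <- gan$params
  if (!chem_is_valid(scaffold)) {
    stop_gexmol("scaffold '%s' is not a valid molecule", scaffold,
                class = "gexmol_parse_error")
  }
  lat <- encode_molecule(scaffold, translator)
  ref <- generate_stage2(lat, signature, gan)
  out <- decode_latent(ref, translator)
  structure(out[[1]], scaffold = scaffold,
            truncated = attr(out, "truncated")[[1]])
}
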