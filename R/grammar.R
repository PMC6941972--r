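# Context-free grammar over SMILES: construction, parsing to leftmost
# derivations, reconstruction, one-hot encoding and stack-masked decoding.
#
# A molecule is represented as the sequence of production-rule indices of
# its leftmost derivation under a fixed CFG. Replaying the sequence with a
# symbol stack (pop the top nonterminal, apply a rule with that left-hand
# side, push the right-hand-side nonterminals right-to-left) reproduces the
# terminal string; masking decoder logits to the rules whose left-hand side
# equals the current stack top guarantees every decoded sequence is a valid
# derivation, whatever the logits.

# ---------------------------------------------------------------------------
# Grammar construction

#' Build a SMILES context-free grammar
#'
#' Loads one of the grammar dialects shipped with the package and validates
#' it. The default `"smiles"` dialect covers the organic subset, bracket
#' atoms, single-digit ring bonds and branches; its last production
#' (`Nothing -> None`) is the padding rule used to right-pad derivations.
#'
#' @param variant Grammar dialect tag. Currently `"smiles"`.
#' @return An object of class `grammar_spec`: a list with `rules` (each a
#'   list with `lhs`, `rhs`, `rhs_is_nt`), `start_symbol`,
#'   `padding_rule_index`, `lhs_index` (nonterminal -> rule indices, 1-based),
#'   `terminals` and `nonterminals`.
#' @examples
#' g <- build_grammar()
#' length(g$rules)
#' @export
build_grammar <- function(variant = "smiles") {
  if (!identical(variant, "smiles")) {
    stop_gexmol("unknown grammar variant '%s'", variant,
                class = "gexmol_config_error")
  }
  path <- system.file("extdata", "smiles_cfg.txt", package = "gexmol")
  if (!nzchar(path)) {
    # during in-source testing before installation
    path <- file.path("inst", "extdata", "smiles_cfg.txt")
  }
  g <- read_grammar(path)
  validate_grammar(g)
  g
}

#' Read a grammar from its plain-text serialization
#'
#' One production per line, `LHS -> RHS` with terminals single-quoted and
#' symbols whitespace-separated; `#` starts a comment. The padding rule is
#' the unique production of the form `Nothing -> None`.
#'
#' @param path File path of the serialized grammar.
#' @return A `grammar_spec` object.
#' @export
read_grammar <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[[k]], "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop_gexmol("malformed production '%s'", lines[[k]],
                  class = "gexmol_config_error")
    }
    lhs <- trimws(parts[[1]])
    toks <- strsplit(trimws(parts[[2]]), "[[:space:]]+")[[1]]
    is_term <- grepl("^'.*'$", toks)
    sym <- ifelse(is_term, substr(toks, 2L, nchar(toks) - 1L), toks)
    if (identical(lhs, "Nothing") && identical(sym, "None")) {
      sym <- character(0)
      is_term <- logical(0)
    }
    rules[[k]] <- list(lhs = lhs, rhs = sym, rhs_is_nt = !is_term)
  }
  lhs_all <- vapply(rules, `[[`, "", "lhs")
  nts <- unique(lhs_all)
  terms <- unique(unlist(lapply(rules, function(r) r$rhs[!r$rhs_is_nt])))
  pad <- which(lhs_all == "Nothing" &
                 vapply(rules, function(r) length(r$rhs) == 0L, TRUE))
  lhs_index <- split(seq_along(rules), factor(lhs_all, levels = nts))
  g <- structure(
    list(rules = rules,
         start_symbol = rules[[1]]$lhs,
         padding_rule_index = if (length(pad)) pad[[1]] else NA_integer_,
         lhs_index = lhs_index,
         terminals = terms,
         nonterminals = nts),
    class = "grammar_spec")
  g
}

#' Serialize a grammar to its plain-text production list
#' @param grammar A `grammar_spec`.
#' @return Character vector, one `LHS -> RHS` production per line.
#' @export
format_grammar <- function(grammar) {
  vapply(grammar$rules, function(r) {
    rhs <- if (length(r$rhs) == 0L) "None" else
      paste(ifelse(r$rhs_is_nt, r$rhs, paste0("'", r$rhs, "'")),
            collapse = " ")
    paste(r$lhs, "->", rhs)
  }, "")
}

validate_grammar <- function(g) {
  lhs_all <- vapply(g$rules, `[[`, "", "lhs")
  pads <- which(lhs_all == "Nothing")
  if (length(pads) != 1L || !identical(pads, g$padding_rule_index) ||
      length(g$rules[[pads]]$rhs) != 0L) {
    stop_gexmol("grammar must contain exactly one padding rule Nothing -> None",
                class = "gexmol_config_error")
  }
  for (r in g$rules) {
    for (i in seq_along(r$rhs)) {
      if (r$rhs_is_nt[[i]] && is.null(g$lhs_index[[r$rhs[[i]]]])) {
        stop_gexmol("nonterminal '%s' on a right-hand side has no production",
                    r$rhs[[i]], class = "gexmol_config_error")
      }
    }
  }
  if (!length(g$lhs_index[[g$start_symbol]])) {
    stop_gexmol("start symbol '%s' has no production", g$start_symbol,
                class = "gexmol_config_error")
  }
  invisible(g)
}

#' @export
print.grammar_spec <- function(x, ...) {
  cat(sprintf("SMILES context-free grammar: %d rules, %d nonterminals, %d terminals\n",
              length(x$rules), length(x$nonterminals), length(x$terminals)))
  cat(sprintf("start symbol '%s', padding rule #%d (%s)\n",
              x$start_symbol, x$padding_rule_index,
              format_grammar(x)[x$padding_rule_index]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tokenization

#' Tokenize a SMILES string against a grammar's terminal set
#'
#' Longest-match scan over the grammar's terminals ("Cl", "Br" and "@@"
#' take precedence over their one-character prefixes).
#'
#' @param smiles A SMILES string.
#' @param grammar A `grammar_spec`.
#' @return Character vector of terminal tokens.
#' @export
smiles_tokenize <- function(smiles, grammar) {
  terms <- grammar$terminals[order(nchar(grammar$terminals),
                                   decreasing = TRUE)]
  out <- character(0)
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    hit <- FALSE
    for (t in terms) {
      w <- nchar(t)
      if (i + w - 1L <= n && substr(smiles, i, i + w - 1L) == t) {
        out <- c(out, t); i <- i + w; hit <- TRUE; break
      }
    }
    if (!hit) {
      stop_gexmol("cannot tokenize SMILES '%s' at position %d ('%s')",
                  smiles, i, substr(smiles, i, i),
                  class = "gexmol_parse_error")
    }
  }
  out
}

#' Strip stereochemistry and isotope annotations from a SMILES string
#'
#' The shipped grammar carries stereo bond and chirality productions, but
#' molecules are canonicalized without stereo before deriving rule
#' sequences: `/`, `\`, `@` marks and bracket isotope labels are removed,
#' and bracket atoms reduced to a bare organic-subset symbol (e.g.
#' `[C@@H]` -> `C`) are unbracketed.
#'
#' @param smiles A SMILES string.
#' @return The stripped SMILES string.
#' @export
strip_stereo <- function(smiles) {
  s <- gsub("[@/\\\\]", "", smiles)
  s <- gsub("\\[([0-9]+)", "[", s)           # isotopes
  gsub("\\[(Cl|Br|[BCNOSPFI]|[cnos])\\]", "\\1", s)
}

# ---------------------------------------------------------------------------
# Earley parser

# Parses a token vector under the grammar and returns chart structures from
# which a leftmost derivation is extracted. Hand-written because the grammar
# is left-recursive (chain -> chain branched_atom), which rules out naive
# recursive descent; the grammar has no nullable symbols other than the
# padding rule, which never participates in parsing, so completion needs no
# nullable handling.
earley_chart <- function(tokens, grammar) {
  rules <- grammar$rules
  n <- length(tokens)
  R <- length(rules)
  rhs_len <- vapply(rules, function(r) length(r$rhs), 0L)
  offset <- c(0L, cumsum(rhs_len + 1L))
  ndot <- offset[R + 1L]

  seen <- vector("list", n + 1L)        # per chart: logical [ndot x (n+1)]
  wait <- vector("list", n + 1L)        # per chart: NT name -> item matrix rows
  comp <- new.env(parent = emptyenv())  # "rule i j" -> TRUE
  ends <- new.env(parent = emptyenv())  # "A i" -> integer ends
  for (j in 0:n) {
    seen[[j + 1L]] <- matrix(FALSE, ndot, n + 1L)
    wait[[j + 1L]] <- new.env(parent = emptyenv())
  }
  queue_r <- integer(0); queue_d <- integer(0); queue_i <- integer(0)
  pend <- vector("list", n + 2L)  # items scanned into later charts

  push <- function(j, r, d, i) {
    dp <- offset[r] + d + 1L
    if (!seen[[j + 1L]][dp, i + 1L]) {
      seen[[j + 1L]][dp, i + 1L] <<- TRUE
      queue_r <<- c(queue_r, r); queue_d <<- c(queue_d, d)
      queue_i <<- c(queue_i, i)
    }
  }

  for (r in grammar$lhs_index[[grammar$start_symbol]]) push(0L, r, 0L, 0L)

  for (j in 0:n) {
    if (!is.null(pend[[j + 1L]])) {
      for (it in pend[[j + 1L]]) push(j, it[1L], it[2L], it[3L])
    }
    while (length(queue_r)) {
      r <- queue_r[[1L]]; d <- queue_d[[1L]]; i <- queue_i[[1L]]
      queue_r <- queue_r[-1L]; queue_d <- queue_d[-1L]; queue_i <- queue_i[-1L]
      rr <- rules[[r]]
      if (d == rhs_len[[r]]) {                      # complete
        key <- paste(r, i, j)
        if (is.null(comp[[key]])) {
          comp[[key]] <- TRUE
          ek <- paste(rr$lhs, i)
          ends[[ek]] <- unique(c(ends[[ek]], j))
          wl <- wait[[i + 1L]][[rr$lhs]]
          if (!is.null(wl)) {
            for (it in wl) push(j, it[1L], it[2L] + 1L, it[3L])
          }
        }
      } else {
        sym <- rr$rhs[[d + 1L]]
        if (rr$rhs_is_nt[[d + 1L]]) {               # predict + register waiter
          wait[[j + 1L]][[sym]] <- c(wait[[j + 1L]][[sym]],
                                     list(c(r, d, i)))
          # if sym already completed from j (cannot happen: no nullables)
          for (r2 in grammar$lhs_index[[sym]]) push(j, r2, 0L, j)
          # late completion: a completed span (sym, j, e) may already exist
          ek <- paste(sym, j)
          if (!is.null(ends[[ek]])) {
            for (e in ends[[ek]]) {
              if (e > j) {
                pend[[e + 1L]] <- c(pend[[e + 1L]], list(c(r, d + 1L, i)))
              }
            }
          }
        } else if (j < n && tokens[[j + 1L]] == sym) {   # scan
          pend[[j + 2L]] <- c(pend[[j + 2L]], list(c(r, d + 1L, i)))
        }
      }
    }
  }
  list(comp = comp, ends = ends, n = n)
}

# Extract the leftmost-derivation rule sequence for span (symbol, i, j).
# Ties (ambiguous parses) are broken deterministically: lowest rule index
# first, then shortest leftmost sub-span.
derivation_from_chart <- function(chart, grammar, symbol, i, j) {
  rules <- grammar$rules
  split_rhs <- function(rhs, rhs_is_nt, k, pos, end) {
    # returns list of per-symbol (start,end) or NULL
    if (k > length(rhs)) {
      if (pos == end) return(list()) else return(NULL)
    }
    sym <- rhs[[k]]
    if (!rhs_is_nt[[k]]) {
      rest <- split_rhs(rhs, rhs_is_nt, k + 1L, pos + 1L, end)
      if (is.null(rest)) return(NULL)
      return(c(list(c(pos, pos + 1L)), rest))
    }
    ee <- chart$ends[[paste(sym, pos)]]
    for (e in sort(ee)) {
      if (e > end) next
      rest <- split_rhs(rhs, rhs_is_nt, k + 1L, e, end)
      if (!is.null(rest)) return(c(list(c(pos, e)), rest))
    }
    NULL
  }
  build <- function(symbol, i, j) {
    for (r in grammar$lhs_index[[symbol]]) {
      if (is.null(chart$comp[[paste(r, i, j)]])) next
      rr <- rules[[r]]
      sp <- split_rhs(rr$rhs, rr$rhs_is_nt, 1L, i, j)
      if (is.null(sp)) next
      out <- r
      for (k in seq_along(rr$rhs)) {
        if (rr$rhs_is_nt[[k]]) {
          out <- c(out, build(rr$rhs[[k]], sp[[k]][1L], sp[[k]][2L]))
        }
      }
      return(out)
    }
    stop_gexmol("internal: no derivation for %s over tokens %d..%d",
                symbol, i + 1L, j, class = "gexmol_parse_error")
  }
  build(symbol, i, j)
}

# ---------------------------------------------------------------------------
# Rule sequences

#' Construct (and validate) a rule sequence
#'
#' @param indices Integer vector of 1-based production-rule indices.
#' @param grammar A `grammar_spec`.
#' @param max_len Maximum length `T`; the sequence is right-padded with the
#'   padding rule up to `T`.
#' @param truncated Logical flag set by [masked_decode()] when the symbol
#'   stack was still nonempty at step `T`.
#' @param validate Check derivation consistency by stack replay.
#' @return An object of class `rule_sequence` with fields `indices`,
#'   `max_len`, `n_active` (steps before padding) and `truncated`.
#' @export
rule_sequence <- function(indices, grammar, max_len = length(indices),
                          truncated = FALSE, validate = TRUE) {
  indices <- as.integer(indices)
  if (length(indices) > max_len) {
    stop_gexmol("derivation length %d exceeds max_len %d", length(indices),
                max_len, class = "gexmol_length_error")
  }
  if (validate && !truncated) {
    rep <- replay_stack(indices, grammar)
    if (!rep$ok) {
      stop_gexmol("derivation-inconsistent sequence at step %d (rule %d: %s)",
                  rep$step, indices[rep$step],
                  format_grammar(grammar)[indices[rep$step]],
                  class = "gexmol_derivation_error")
    }
    n_active <- rep$n_active
  } else {
    n_active <- length(indices)
  }
  pad <- grammar$padding_rule_index
  indices <- c(indices, rep.int(pad, max_len - length(indices)))
  structure(list(indices = indices, max_len = as.integer(max_len),
                 n_active = n_active, truncated = truncated),
            class = "rule_sequence")
}

# Replay a rule-index vector against the symbol stack. Returns ok = FALSE
# with the offending step if some rule's lhs differs from the stack top or
# a non-padding rule follows termination.
replay_stack <- function(indices, grammar) {
  rules <- grammar$rules
  pad <- grammar$padding_rule_index
  stack <- grammar$start_symbol
  n_active <- 0L
  for (t in seq_along(indices)) {
    r <- indices[[t]]
    if (length(stack) == 0L) {
      if (r != pad) return(list(ok = FALSE, step = t, n_active = n_active))
      next
    }
    rr <- rules[[r]]
    if (rr$lhs != stack[[length(stack)]]) {
      return(list(ok = FALSE, step = t, n_active = n_active))
    }
    stack <- stack[-length(stack)]
    nts <- rr$rhs[rr$rhs_is_nt]
    if (length(nts)) stack <- c(stack, rev(nts))
    n_active <- t
  }
  list(ok = length(stack) == 0L, step = NA_integer_, n_active = n_active,
       stack_left = length(stack))
}

#' @export
print.rule_sequence <- function(x, ...) {
  cat(sprintf("rule_sequence: %d active rules (T = %d)%s\n", x$n_active,
              x$max_len, if (isTRUE(x$truncated)) ", truncated" else ""))
  invisible(x)
}

#' Convert a SMILES string to its leftmost-derivation rule sequence
#'
#' Tokenizes and parses `smiles` under `grammar` and returns the leftmost
#' derivation, right-padded with the padding rule to length `max_len`.
#' Stereochemistry and isotopes are stripped first (the rule representation
#' is stereo-free; see [strip_stereo()]).
#'
#' @param smiles A SMILES string.
#' @param grammar A `grammar_spec` from [build_grammar()].
#' @param max_len Maximum derivation length `T`.
#' @param strip Strip stereo/isotope annotations before parsing.
#' @return A `rule_sequence`.
#' @examples
#' g <- build_grammar()
#' rs <- smiles_to_rules("c1ccccc1", g, max_len = 40)
#' rules_to_smiles(rs, g)
#' @export
smiles_to_rules <- function(smiles, grammar, max_len = 80L, strip = TRUE) {
  if (strip) smiles <- strip_stereo(smiles)
  tokens <- smiles_tokenize(smiles, grammar)
  chart <- earley_chart(tokens, grammar)
  n <- length(tokens)
  ok <- !is.null(chart$ends[[paste(grammar$start_symbol, 0)]]) &&
    n %in% chart$ends[[paste(grammar$start_symbol, 0)]]
  if (n == 0L || !ok) {
    # locate the furthest token position any completed span reaches
    reach <- 0L
    for (k in ls(chart$ends)) reach <- max(reach, chart$ends[[k]])
    stop_gexmol("SMILES '%s' does not parse under the grammar (failure near token %d)",
                smiles, min(reach + 1L, n), class = "gexmol_parse_error")
  }
  idx <- derivation_from_chart(chart, grammar, grammar$start_symbol, 0L, n)
  if (length(idx) > max_len) {
    stop_gexmol("derivation of '%s' has %d rules, exceeding max_len %d",
                smiles, length(idx), max_len, class = "gexmol_length_error")
  }
  rule_sequence(idx, grammar, max_len = max_len, validate = FALSE)
}

#' Reconstruct the SMILES string from a rule sequence
#'
#' Replays the leftmost derivation: terminals are emitted in order, each
#' rule rewrites the leftmost nonterminal. Exact inverse of
#' [smiles_to_rules()] on the stripped string.
#'
#' @param ruleseq A `rule_sequence` (or bare integer index vector).
#' @param grammar The `grammar_spec` the indices refer to.
#' @return A SMILES string.
#' @export
rules_to_smiles <- function(ruleseq, grammar) {
  idx <- if (inherits(ruleseq, "rule_sequence")) ruleseq$indices else
    as.integer(ruleseq)
  rules <- grammar$rules
  pad <- grammar$padding_rule_index
  active <- idx[idx != pad]
  if (length(active) == 0L) {
    stop_gexmol("empty derivation: sequence contains only padding rules",
                class = "gexmol_derivation_error")
  }
  out <- character(0)
  stack <- list(list(sym = grammar$start_symbol, nt = TRUE))
  for (t in seq_along(active)) {
    while (length(stack) && !stack[[length(stack)]]$nt) {
      out <- c(out, stack[[length(stack)]]$sym)
      stack[[length(stack)]] <- NULL
    }
    if (!length(stack)) {
      stop_gexmol("derivation already terminated at step %d", t,
                  class = "gexmol_derivation_error")
    }
    top <- stack[[length(stack)]]
    rr <- rules[[active[[t]]]]
    if (rr$lhs != top$sym) {
      stop_gexmol("step %d applies rule with lhs '%s' but stack top is '%s'",
                  t, rr$lhs, top$sym, class = "gexmol_derivation_error")
    }
    stack[[length(stack)]] <- NULL
    if (length(rr$rhs)) {
      for (k in rev(seq_along(rr$rhs))) {
        stack[[length(stack) + 1L]] <- list(sym = rr$rhs[[k]],
                                            nt = rr$rhs_is_nt[[k]])
      }
    }
  }
  while (length(stack) && !stack[[length(stack)]]$nt) {
    out <- c(out, stack[[length(stack)]]$sym)
    stack[[length(stack)]] <- NULL
  }
  if (length(stack)) {
    stop_gexmol("incomplete derivation: %d symbols left on the stack",
                length(stack), class = "gexmol_derivation_error")
  }
  paste(out, collapse = "")
}

# ---------------------------------------------------------------------------
# One-hot encoding

#' One-hot encode a rule sequence
#' @param ruleseq A `rule_sequence`.
#' @param grammar The corresponding `grammar_spec`.
#' @return A `T x R` binary matrix whose row `t` is the one-hot encoding of
#'   rule index `t`.
#' @export
one_hot_encode <- function(ruleseq, grammar) {
  R <- length(grammar$rules)
  T_ <- ruleseq$max_len
  m <- matrix(0, T_, R)
  m[cbind(seq_len(T_), ruleseq$indices)] <- 1
  m
}

#' Recover rule indices from a one-hot (or logit) matrix by row-wise argmax
#' @param mat A `T x R` matrix.
#' @param grammar The corresponding `grammar_spec`.
#' @return A `rule_sequence`.
#' @export
one_hot_decode <- function(mat, grammar) {
  idx <- apply(mat, 1L, which.max)
  rule_sequence(idx, grammar, max_len = nrow(mat), validate = FALSE)
}

# ---------------------------------------------------------------------------
# Stack-masked decoding

# Shared single-step chooser: given a logit row and the current nonterminal
# stack (integer-free character vector, top last), pick a rule among those
# whose lhs equals the stack top and return the updated stack.
masked_step <- function(logit_row, stack, grammar, mode) {
  top <- stack[[length(stack)]]
  allowed <- grammar$lhs_index[[top]]
  r <- if (length(allowed) == 1L) {
    allowed
  } else if (mode == "argmax") {
    allowed[which.max(logit_row[allowed])]
  } else {
    p <- softmax(logit_row[allowed])
    allowed[sample.int(length(allowed), 1L, prob = p)]
  }
  rr <- grammar$rules[[r]]
  stack <- stack[-length(stack)]
  nts <- rr$rhs[rr$rhs_is_nt]
  if (length(nts)) stack <- c(stack, rev(nts))
  list(rule = r, stack = stack)
}

#' Decode a logit matrix into a grammar-consistent rule sequence
#'
#' At each time step the rules whose left-hand side differs from the top of
#' the derivation stack are masked out before taking the argmax (or
#' sampling), so the output is a valid derivation for any finite logits.
#' If the stack is still nonempty after `T` steps the result is flagged
#' `truncated` rather than raising an error.
#'
#' @param logits A `T x R` real matrix of unnormalized per-step rule scores.
#' @param grammar The `grammar_spec` defining the rule inventory.
#' @param mode `"argmax"` (deterministic, default) or `"sample"`.
#' @param seed RNG seed for `mode = "sample"`; ignored for argmax.
#' @return A `rule_sequence`, possibly with `truncated = TRUE`.
#' @examples
#' g <- build_grammar()
#' set.seed(1)
#' rs <- masked_decode(matrix(rnorm(40 * length(g$rules)), 40), g)
#' rs$truncated
#' @export
masked_decode <- function(logits, grammar, mode = c("argmax", "sample"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(logits), ncol(logits) == length(grammar$rules),
            all(is.finite(logits)))
  run <- function() {
    T_ <- nrow(logits)
    pad <- grammar$padding_rule_index
    stack <- grammar$start_symbol
    idx <- rep.int(pad, T_)
    for (t in seq_len(T_)) {
      if (!length(stack)) break
      st <- masked_step(logits[t, ], stack, grammar, mode)
      idx[[t]] <- st$rule
      stack <- st$stack
    }
    rule_sequence(idx, grammar, max_len = T_,
                  truncated = length(stack) > 0L, validate = FALSE)
  }
  if (mode == "sample") with_seed(seed, run()) else run()
}
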