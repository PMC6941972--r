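# SMILES <-> grammar sequence model: a single-GRU encoder reads the
# character one-hots of a canonical SMILES into a bounded latent vector
# (tanh of the final cell state), and a single-GRU decoder, initialized
# with that latent, emits per-step probability distributions over grammar
# production rules (dropout + dense softmax head). Decoding runs through
# the stack-masked chooser so the output is always derivation-consistent.
# Training is teacher-forced cross-entropy with RMSprop.

# Gate weights are stored fused - W: in x 3H for the reset/update/candidate
# input maps, U: H x 2H for the reset/update recurrent maps, Un separate
# (the candidate path multiplies the reset-gated state) - so each step
# costs two large matrix products instead of six small ones. Column-block
# fusion computes the identical dot products, so results are unchanged.
gru_init <- function(in_dim, hidden) {
  sdw <- sqrt(2 / (in_dim + hidden))
  # orthogonal recurrent weights stabilize backprop through time
  o <- function() qr.Q(qr(matrix(stats::rnorm(hidden * hidden), hidden)))
  list(W = matrix(stats::rnorm(in_dim * 3L * hidden, sd = sdw), in_dim),
       U = cbind(o(), o()), Un = o(),
       b = rep(0, 3L * hidden))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_step <- function(p, X, H) {
  hd <- ncol(H)
  i1 <- seq_len(hd); i2 <- hd + i1; i3 <- 2L * hd + i1
  XW <- add_bias(X %*% p$W, p$b)
  HU <- H %*% p$U
  r <- sigmoid(XW[, i1, drop = FALSE] + HU[, i1, drop = FALSE])
  z <- sigmoid(XW[, i2, drop = FALSE] + HU[, i2, drop = FALSE])
  rh <- r * H
  n <- tanh(XW[, i3, drop = FALSE] + rh %*% p$Un)
  list(H = (1 - z) * n + z * H, r = r, z = z, n = n, rh = rh,
       X = X, Hprev = H)
}

gru_grads_zero <- function(p) lapply(p, function(x) x * 0)

# One-step backward; accumulates parameter grads in `acc` (by reference
# semantics via return), returns dH for the previous step and dX.
gru_step_backward <- function(p, st, dH, acc, need_dx = FALSE) {
  dn <- dH * (1 - st$z)
  dz <- dH * (st$Hprev - st$n)
  dHp <- dH * st$z
  dpn <- dn * (1 - st$n^2)
  drh <- tcrossprod(dpn, p$Un)
  dr <- drh * st$Hprev
  dHp <- dHp + drh * st$r
  dpz <- dz * st$z * (1 - st$z)
  dpr <- dr * st$r * (1 - st$r)
  drz <- cbind(dpr, dpz)
  drzn <- cbind(drz, dpn)
  acc$W <- acc$W + crossprod(st$X, drzn)
  acc$U <- acc$U + crossprod(st$Hprev, drz)
  acc$Un <- acc$Un + crossprod(st$rh, dpn)
  acc$b <- acc$b + colSums(drzn)
  dHp <- dHp + tcrossprod(drz, p$U)
  dX <- if (need_dx) tcrossprod(drzn, p$W)
  list(dH = dHp, dX = dX, acc = acc)
}

one_hot_rows <- function(idx, ncol_) {
  m <- matrix(0, length(idx), ncol_)
  keep <- !is.na(idx) & idx > 0L
  m[cbind(seq_along(idx)[keep], idx[keep])] <- 1
  m
}

# ---------------------------------------------------------------------------
# Configuration and fitting

#' Translator hyperparameters
#'
#' @param latent_dim Dimension `L` of the molecular latent space (also the
#'   GRU hidden size; 256 at publication scale, 32 by default for desk
#'   scale).
#' @param epochs,batch_size,learning_rate RMSprop training schedule.
#' @param lr_decay Multiplicative per-epoch learning-rate decay (1 = none).
#' @param dropout Decoder output dropout rate.
#' @param latent_noise Standard deviation of Gaussian noise added to the
#'   latent during training (denoising regularization: the decoder must
#'   also handle latents slightly off the encoder manifold, which is
#'   exactly how GAN-generated latents reach it).
#' @param dec_hidden Decoder GRU width; defaults to `latent_dim`. A wider
#'   decoder (the latent enters through a trained linear map) buys
#'   reconstruction fidelity without changing the latent space.
#' @param max_len Maximum rule-sequence length `T`; `NULL` sets the 99th
#'   percentile of corpus derivation lengths (longer molecules are dropped
#'   with a message).
#' @return A list of class `translator_config`.
#' @export
translator_config <- function(latent_dim = 48L, epochs = 50L,
                              batch_size = 16L, learning_rate = 2e-3,
                              lr_decay = 1, dropout = 0.2,
                              latent_noise = 0.05, dec_hidden = NULL,
                              max_len = NULL) {
  structure(list(latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 dropout = dropout, latent_noise = latent_noise,
                 dec_hidden = as.integer(dec_hidden %||% latent_dim),
                 max_len = max_len),
            class = "translator_config")
}

translator_vocab <- function(smiles) {
  chars <- sort(unique(unlist(strsplit(smiles, ""))))
  c(".pad", chars)   # index 1 is the padding token
}

chars_to_idx <- function(smiles, vocab, max_chars) {
  ch <- strsplit(smiles, "")[[1]]
  idx <- match(ch, vocab)
  if (anyNA(idx)) {
    stop_gexmol("character '%s' of '%s' is not in the translator vocabulary",
                ch[which(is.na(idx))[1]], smiles,
                class = "gexmol_encoding_error")
  }
  c(idx, rep.int(1L, max_chars - length(idx)))
}

#' Fit the SMILES-to-grammar translator
#'
#' Trains the GRU encoder/decoder by teacher forcing: the decoder receives
#' the ground-truth previous production rule at every step and is scored by
#' cross-entropy against the leftmost-derivation rule sequence.
#' Unparseable corpus molecules, and molecules whose derivation exceeds
#' `max_len`, are skipped with a message.
#'
#' @param corpus Character vector of (canonical) SMILES.
#' @param grammar A `grammar_spec`; defaults to the shipped SMILES grammar.
#' @param config A [translator_config()].
#' @param seed Master seed: weight initialization, shuffling and dropout
#'   all derive from it, so the loss history is bitwise reproducible.
#' @return An object of class `smiles_translator` with elements `params`,
#'   `vocab`, `grammar`, `config`, `loss_history` (per-epoch mean
#'   cross-entropy) and `token_accuracy` (teacher-forced, non-padding
#'   positions).
#' @seealso [encode_molecule()], [decode_latent()], [predict.smiles_translator()]
#' @export
train_translator <- function(corpus, grammar = build_grammar(),
                             config = translator_config(), seed = 1L) {
  if (!length(corpus)) {
    stop_gexmol("empty training corpus", class = "gexmol_config_error")
  }
  stripped <- vapply(corpus, strip_stereo, "")
  parsed <- lapply(stripped, function(s) {
    tryCatch(smiles_to_rules(s, grammar, max_len = 10000L, strip = FALSE),
             gexmol_parse_error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, TRUE)
  if (any(bad)) {
    message(sprintf("train_translator: skipping %d unparseable molecule(s)",
                    sum(bad)))
  }
  stripped <- stripped[!bad]; parsed <- parsed[!bad]
  lens <- vapply(parsed, function(p) p$n_active, 0L)
  T_ <- config$max_len %||% as.integer(ceiling(stats::quantile(lens, 0.99)))
  drop_long <- lens > T_
  if (any(drop_long)) {
    message(sprintf("train_translator: dropping %d molecule(s) with derivation > %d",
                    sum(drop_long), T_))
  }
  stripped <- stripped[!drop_long]; parsed <- parsed[!drop_long]
  n <- length(stripped)
  if (n == 0L) {
    stop_gexmol("no usable molecules in corpus", class = "gexmol_config_error")
  }
  vocab <- translator_vocab(stripped)
  V <- length(vocab)
  R <- length(grammar$rules)
  L <- config$latent_dim
  Tc <- max(nchar(stripped))
  Xc <- t(vapply(stripped, chars_to_idx, integer(Tc), vocab = vocab,
                 max_chars = Tc))
  Y <- t(vapply(parsed, function(p) {
    act <- p$indices[seq_len(p$n_active)]
    c(act, rep.int(grammar$padding_rule_index, T_ - length(act)))
  }, integer(T_)))

  H_dec <- config$dec_hidden
  with_seed(derive_seed(seed, "translator"), {
    params <- list(enc = gru_init(V, L), dec = gru_init(R + L, H_dec),
                   W0 = matrix(stats::rnorm(L * H_dec, sd = sqrt(1 / L)),
                               L, H_dec),
                   Wo = matrix(stats::rnorm(H_dec * R,
                                            sd = sqrt(2 / (H_dec + R))),
                               H_dec, R),
                   bo = rep(0, R))
    state <- rapply(params, function(x) x * 0, how = "replace")
    loss_history <- numeric(config$epochs)
    nb <- ceiling(n / config$batch_size)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      lr_ep <- config$learning_rate * config$lr_decay^(ep - 1)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
        fb <- translator_batch(params, Xc[idx, , drop = FALSE],
                               Y[idx, , drop = FALSE], grammar, config,
                               training = TRUE)
        ep_loss <- ep_loss + fb$loss * length(idx)
        upd <- rs_update(params, fb$grads, state, lr_ep)
        params <- upd$params; state <- upd$state
      }
      loss_history[ep] <- ep_loss / n
    }
    acc <- translator_batch(params, Xc, Y, grammar, config,
                            training = FALSE)$accuracy
    structure(list(params = params, vocab = vocab, grammar = grammar,
                   config = config, max_len = T_, max_chars = Tc,
                   n_train = n, loss_history = loss_history,
                   token_accuracy = acc, seed = seed),
              class = "smiles_translator")
  })
}

# recursive RMSprop over a nested list-of-numerics parameter structure
rs_update <- function(params, grads, state, lr, rho = 0.9, eps = 1e-7) {
  if (is.list(params)) {
    for (nm in names(params)) {
      u <- rs_update(params[[nm]], grads[[nm]], state[[nm]], lr, rho, eps)
      params[[nm]] <- u$params; state[[nm]] <- u$state
    }
    return(list(params = params, state = state))
  }
  v <- rho * state + (1 - rho) * grads^2
  list(params = params - lr * grads / (sqrt(v) + eps), state = v)
}

# forward (+ optional backward) over one teacher-forced batch
translator_batch <- function(params, Xc, Y, grammar, config, training) {
  B <- nrow(Xc); Tc <- ncol(Xc); T_ <- ncol(Y)
  V <- nrow(params$enc$W); R <- length(grammar$rules)
  L <- nrow(params$W0); Hd_dim <- ncol(params$W0)
  # encoder
  H <- matrix(0, B, L)
  enc_states <- vector("list", Tc)
  for (t in seq_len(Tc)) {
    st <- gru_step(params$enc, one_hot_rows(Xc[, t], V), H)
    enc_states[[t]] <- st; H <- st$H
  }
  # the GRU state is a convex combination of tanh candidates, so it is
  # already confined to (-1, 1): the latent is the state itself, sharing
  # its support with the generators' tanh outputs without compressing the
  # usable range
  latent <- H
  if (training && config$latent_noise > 0) {
    # denoising regularization; the additive noise is transparent to the
    # gradient, so backprop into the encoder is unchanged
    latent <- latent + matrix(stats::rnorm(B * L, sd = config$latent_noise),
                              B)
  }
  # decoder (teacher forced): the latent initializes the GRU state
  # (through a trained linear map when the decoder is wider) and is
  # re-presented alongside the previous rule one-hot at every step, which
  # keeps free-running decoding anchored to the molecule being decoded
  Hd <- latent %*% params$W0
  dec_states <- vector("list", T_)
  drop_masks <- vector("list", T_)
  P <- vector("list", T_)
  loss <- 0; ncorrect <- 0L; nactive <- 0L
  pad <- grammar$padding_rule_index
  # cross-entropy is averaged over non-padding positions only: once the
  # derivation stack empties, decoder output is never consulted
  A <- max(sum(Y != pad), 1L)
  dWo <- params$Wo * 0; dbo <- params$bo * 0
  dec_acc <- gru_grads_zero(params$dec)
  dH_steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    prev <- if (t == 1L) matrix(0, B, R) else one_hot_rows(Y[, t - 1L], R)
    Xin <- cbind(prev, latent)
    st <- gru_step(params$dec, Xin, Hd)
    dec_states[[t]] <- st; Hd <- st$H
    Hdrop <- Hd
    if (training && config$dropout > 0) {
      mask <- (matrix(stats::runif(B * Hd_dim), B) >= config$dropout) /
        (1 - config$dropout)
      drop_masks[[t]] <- mask
      Hdrop <- Hd * mask
    }
    logits <- add_bias(Hdrop %*% params$Wo, params$bo)
    mx <- apply(logits, 1L, max)
    Z <- exp(logits - mx)
    Psm <- Z / rowSums(Z)
    tgt <- Y[, t]
    act <- tgt != pad
    loss <- loss + sum(-log(pmax(Psm[cbind(seq_len(B), tgt)], 1e-12))[act])
    nactive <- nactive + sum(act)
    ncorrect <- ncorrect + sum(act & (max.col(logits, "first") == tgt))
    if (training) {
      dlog <- Psm
      dlog[cbind(seq_len(B), tgt)] <- dlog[cbind(seq_len(B), tgt)] - 1
      dlog[!act, ] <- 0
      dlog <- dlog / A
      dWo <- dWo + crossprod(Hdrop, dlog)
      dbo <- dbo + colSums(dlog)
      dHd <- tcrossprod(dlog, params$Wo)
      if (!is.null(drop_masks[[t]])) dHd <- dHd * drop_masks[[t]]
      dH_steps[[t]] <- dHd
    }
  }
  loss <- loss / A
  if (!training) {
    return(list(loss = loss, accuracy = ncorrect / max(nactive, 1L)))
  }
  # decoder BPTT; the latent collects gradient through the initial-state
  # map and through its per-step input copies
  dH <- matrix(0, B, Hd_dim)
  dlat <- matrix(0, B, L)
  for (t in rev(seq_len(T_))) {
    dH <- dH + dH_steps[[t]]
    sb <- gru_step_backward(params$dec, dec_states[[t]], dH, dec_acc,
                            need_dx = TRUE)
    dH <- sb$dH; dec_acc <- sb$acc
    dlat <- dlat + sb$dX[, (R + 1L):(R + L), drop = FALSE]
  }
  dW0 <- crossprod(latent, dH)
  dlat <- dlat + tcrossprod(dH, params$W0)
  # into the encoder (latent = final encoder state; additive noise is
  # transparent to the gradient)
  dHenc <- dlat
  enc_acc <- gru_grads_zero(params$enc)
  for (t in rev(seq_len(Tc))) {
    sb <- gru_step_backward(params$enc, enc_states[[t]], dHenc, enc_acc)
    dHenc <- sb$dH; enc_acc <- sb$acc
  }
  list(loss = loss,
       grads = list(enc = enc_acc, dec = dec_acc, W0 = dW0, Wo = dWo,
                    bo = dbo))
}

# ---------------------------------------------------------------------------
# Encoding / decoding

#' Encode molecules into the continuous latent space
#'
#' Pure function of the SMILES and the trained parameters. The latent is
#' the final encoder GRU state, whose components are confined to
#' `(-1, 1)` by the GRU update rule — the same support as the GAN
#' generators' tanh outputs.
#'
#' @param smiles SMILES string (or character vector).
#' @param translator A fitted `smiles_translator`.
#' @return A numeric vector of length `latent_dim` (or a matrix with one
#'   row per molecule).
#' @export
encode_molecule <- function(smiles, translator) {
  stopifnot(inherits(translator, "smiles_translator"))
  stripped <- vapply(smiles, strip_stereo, "")
  V <- length(translator$vocab)
  Tc <- max(translator$max_chars, max(nchar(stripped)))
  Xc <- t(vapply(stripped, chars_to_idx, integer(Tc),
                 vocab = translator$vocab, max_chars = Tc))
  H <- matrix(0, nrow(Xc), nrow(translator$params$W0))
  for (t in seq_len(ncol(Xc))) {
    H <- gru_step(translator$params$enc, one_hot_rows(Xc[, t], V), H)$H
  }
  lat <- H
  rownames(lat) <- NULL
  if (length(smiles) == 1L) drop(lat) else lat
}

#' Decode latent vectors into SMILES strings
#'
#' Runs the decoder GRU from the latent state and applies stack-masked
#' rule selection at every step, so the decoded string is always
#' grammatically derivable (chemical validity is not guaranteed). The
#' decoding horizon is twice the training sequence length; if the
#' derivation stack is still nonempty by then the molecule is truncated
#' and `NA` is returned for it.
#'
#' @param latent A latent vector, or a matrix with one latent per row.
#' @param translator A fitted `smiles_translator`.
#' @param mode `"argmax"` (deterministic) or `"sample"`.
#' @param seed Seed for `mode = "sample"`.
#' @return Character vector of SMILES (`NA` where truncated), with the
#'   logical attribute `truncated`.
#' @export
decode_latent <- function(latent, translator, mode = c("argmax", "sample"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(translator, "smiles_translator"))
  if (!is.matrix(latent)) latent <- matrix(latent, 1L)
  stopifnot(all(is.finite(latent)),
            ncol(latent) == nrow(translator$params$W0))
  run <- function() decode_latent_batch(latent, translator, mode)
  res <- if (mode == "sample") with_seed(seed, run()) else run()
  out <- vapply(res, `[[`, "", "smiles")
  attr(out, "truncated") <- vapply(res, `[[`, TRUE, "truncated")
  out
}

# batched free-running decoder: one GRU matrix step per time step for all
# rows, per-row derivation stacks. The horizon is twice the training
# length: free-running derivations may legitimately run longer than any
# training molecule before closing the stack.
decode_latent_batch <- function(latents, translator, mode) {
  g <- translator$grammar
  p <- translator$params
  R <- length(g$rules)
  B <- nrow(latents)
  T_ <- 2L * translator$max_len
  pad <- g$padding_rule_index
  H <- latents %*% p$W0
  prev <- matrix(0, B, R)
  stacks <- rep(list(g$start_symbol), B)
  seqs <- matrix(pad, B, T_)
  alive <- rep(TRUE, B)
  for (t in seq_len(T_)) {
    if (!any(alive)) break
    H <- gru_step(p$dec, cbind(prev, latents), H)$H
    logits <- add_bias(H %*% p$Wo, p$bo)
    prev <- matrix(0, B, R)
    for (b in which(alive)) {
      st <- masked_step(logits[b, ], stacks[[b]], g, mode)
      seqs[b, t] <- st$rule
      stacks[[b]] <- st$stack
      prev[b, st$rule] <- 1
      if (!length(st$stack)) alive[b] <- FALSE
    }
  }
  lapply(seq_len(B), function(b) {
    if (alive[b]) return(list(smiles = NA_character_, truncated = TRUE))
    list(smiles = rules_to_smiles(seqs[b, ], g), truncated = FALSE)
  })
}

# ---------------------------------------------------------------------------
# S3 methods

#' @export
print.smiles_translator <- function(x, ...) {
  cat(sprintf("SMILES grammar translator (GRU, latent dim %d)\n",
              x$config$latent_dim))
  cat(sprintf("  trained on %d molecules, %d epochs; final CE loss %.4f\n",
              x$n_train, length(x$loss_history),
              utils::tail(x$loss_history, 1L)))
  cat(sprintf("  teacher-forced token accuracy %.3f (T = %d rules)\n",
              x$token_accuracy, x$max_len))
  invisible(x)
}

#' @export
summary.smiles_translator <- function(object, ...) {
  print(object)
  cat(sprintf("  vocabulary: %d characters; grammar: %d rules\n",
              length(object$vocab), length(object$grammar$rules)))
  invisible(object)
}

#' Encode new molecules with a fitted translator
#' @param object A `smiles_translator`.
#' @param newdata Character vector of SMILES.
#' @param ... Unused.
#' @return Latent matrix, one row per molecule.
#' @export
predict.smiles_translator <- function(object, newdata, ...) {
  lat <- encode_molecule(newdata, object)
  if (!is.matrix(lat)) lat <- matrix(lat, 1L)
  lat
}

#' @export
plot.smiles_translator <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "cross-entropy",
                 main = "translator training loss", ...)
  invisible(x)
}
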