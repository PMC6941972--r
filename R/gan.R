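# The two-stage conditional WGAN-GP: generator stage I (noise + signature),
# generator stage II (residual refinement of the stage-I latent), the two
# Wasserstein critics, and the two conditional matching networks whose
# log-score steers generation toward the signature condition.
#
# Loss conventions (lambda = gradient-penalty weight, alpha = conditional
# weight, both 10 by default):
#   L_D = E[-D(x_real)] + E[D(G(.))] + lambda E[(||grad D(xhat)|| - 1)^2]
#   L_G = E[-D(G(.)) - alpha log f(G(.), c)]
# with xhat drawn uniformly on segments between paired real and generated
# latents. f is trained by binary cross-entropy on matched (latent,
# signature) pairs against within-batch shuffled mismatches.

#' GAN hyperparameters and architecture widths
#'
#' Defaults are the publication-scale architecture: 978 landmark genes,
#' 1000-d noise, 256-d molecular latents, [512, 256] condition/noise
#' branches with batch normalization, [256, 256, 256, 1] critics with 0.4
#' dropout, two residual blocks in stage II, and SubMult+NN conditional
#' networks. `gan_config_desk()` gives a reduced configuration for CPU-scale
#' experiments.
#'
#' @param n_genes Signature dimension `G`.
#' @param latent_dim Molecular latent dimension `L` (must match the
#'   translator).
#' @param noise_dim Noise dimension `Z`.
#' @param cond_widths,noise_widths Two-layer branch widths of the stage-I
#'   generator (LeakyReLU + batch norm each).
#' @param merge_hidden Hidden width of the stage-I merge MLP.
#' @param critic_widths Hidden widths of the critics.
#' @param fm_widths,fg_widths Molecule/signature branch widths of the
#'   conditional networks.
#' @param compare_width Width of the SubMult+NN comparison layer.
#' @param lambda_gp Gradient-penalty weight (lambda).
#' @param alpha_cond Conditional log-score weight (alpha).
#' @param leaky_slope Negative slope of every LeakyReLU.
#' @param n_residual_blocks Residual blocks in the stage-II generator.
#' @param dropout_critic,dropout_cond Dropout rates in critics and
#'   conditional-network branches.
#' @param bn_momentum Batch-norm running-average momentum.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(n_genes = 978L, latent_dim = 256L, noise_dim = 1000L,
                       cond_widths = c(512L, 256L),
                       noise_widths = c(512L, 256L),
                       merge_hidden = 256L,
                       critic_widths = c(256L, 256L, 256L),
                       fm_widths = c(256L, 256L),
                       fg_widths = c(512L, 256L),
                       compare_width = 256L,
                       lambda_gp = 10, alpha_cond = 10,
                       leaky_slope = 0.2, n_residual_blocks = 2L,
                       dropout_critic = 0.4, dropout_cond = 0.4,
                       bn_momentum = 0.9) {
  stopifnot(lambda_gp >= 0, alpha_cond >= 0, n_residual_blocks >= 1L,
            all(c(cond_widths, noise_widths, critic_widths) > 0L))
  structure(as.list(environment()), class = "gan_config")
}

#' @rdname gan_config
#' @export
gan_config_desk <- function(n_genes = 64L, latent_dim = 48L,
                            noise_dim = 32L, ...) {
  gan_config(n_genes = n_genes, latent_dim = latent_dim,
             noise_dim = noise_dim,
             cond_widths = c(128L, 64L), noise_widths = c(128L, 64L),
             merge_hidden = 64L, critic_widths = c(64L, 64L, 64L),
             fm_widths = c(64L, 64L), fg_widths = c(128L, 64L),
             compare_width = 64L, ...)
}

mlp_branch <- function(in_dim, widths, slope, bn = TRUE, bn_momentum = 0.9,
                       drop_last = 0) {
  ops <- list()
  d <- in_dim
  for (w in widths) {
    ops <- c(ops, list(op_dense(d, w), op_act("lrelu", slope)))
    if (bn) ops <- c(ops, list(op_bn(w, momentum = bn_momentum)))
    d <- w
  }
  if (drop_last > 0) ops <- c(ops, list(op_drop(drop_last)))
  ops
}

critic_net <- function(latent_dim, widths, slope, dropout) {
  # dropout between hidden layers 2-3 and 3-4 only
  list(op_dense(latent_dim, widths[1]), op_act("lrelu", slope),
       op_dense(widths[1], widths[2]), op_act("lrelu", slope),
       op_drop(dropout),
       op_dense(widths[2], widths[3]), op_act("lrelu", slope),
       op_drop(dropout),
       op_dense(widths[3], 1L))
}

#' Initialize the parameters of the stacked conditional WGAN-GP
#'
#' @param config A [gan_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `gan_params` holding all sub-networks
#'   (generators, critics, conditional networks) and the configuration.
#' @export
gan_init <- function(config = gan_config(), seed = 1L) {
  stopifnot(inherits(config, "gan_config"))
  with_seed(derive_seed(seed, "gan_init"), {
    sl <- config$leaky_slope
    mo <- config$bn_momentum
    res_dim <- config$latent_dim + utils::tail(config$cond_widths, 1L)
    g1_res <- list()
    for (k in seq_len(config$n_residual_blocks)) {
      g1_res <- c(g1_res, list(op_res(res_dim, sl)))
    }
    g1_res <- c(g1_res, list(op_dense(res_dim, config$latent_dim),
                             op_act("tanh")))
    fnet <- function() list(
      m = mlp_branch(config$latent_dim, config$fm_widths, sl, bn = FALSE,
                     drop_last = config$dropout_cond),
      g = mlp_branch(config$n_genes, config$fg_widths, sl, bn = FALSE,
                     drop_last = config$dropout_cond),
      head = list(op_dense(2L * utils::tail(config$fm_widths, 1L),
                           config$compare_width),
                  op_act("lrelu", sl),
                  op_dense(config$compare_width, 1L)))
    nets <- list(
      g0_cond = mlp_branch(config$n_genes, config$cond_widths, sl,
                           bn = TRUE, bn_momentum = mo),
      g0_noise = mlp_branch(config$noise_dim, config$noise_widths, sl,
                            bn = TRUE, bn_momentum = mo),
      g0_merge = list(
        op_dense(utils::tail(config$noise_widths, 1L) +
                   utils::tail(config$cond_widths, 1L),
                 config$merge_hidden),
        op_act("lrelu", sl),
        op_dense(config$merge_hidden, config$latent_dim),
        op_act("tanh")),
      g1_cond = mlp_branch(config$n_genes, config$cond_widths, sl,
                           bn = TRUE, bn_momentum = mo),
      g1_res = g1_res,
      d0 = critic_net(config$latent_dim, config$critic_widths, sl,
                      config$dropout_critic),
      d1 = critic_net(config$latent_dim, config$critic_widths, sl,
                      config$dropout_critic),
      f0 = fnet(), f1 = fnet())
    structure(list(nets = nets, config = config), class = "gan_params")
  })
}

#' @export
print.gan_params <- function(x, ...) {
  cf <- x$config
  cat(sprintf("stacked conditional WGAN-GP parameters\n"))
  cat(sprintf("  G = %d genes, Z = %d noise, L = %d latent; lambda = %g, alpha = %g\n",
              cf$n_genes, cf$noise_dim, cf$latent_dim, cf$lambda_gp,
              cf$alpha_cond))
  cat(sprintf("  stage II: %d residual blocks; critics [%s, 1]\n",
              cf$n_residual_blocks, paste(cf$critic_widths, collapse = ", ")))
  invisible(x)
}

as_batch <- function(x, dim, what) {
  if (!is.matrix(x)) x <- matrix(x, 1L)
  if (ncol(x) != dim) {
    stop_gexmol("%s has dimension %d, expected %d", what, ncol(x), dim,
                class = "gexmol_shape_error")
  }
  x
}

# ---------------------------------------------------------------------------
# Forward passes (with caches for training; exported wrappers drop them)

g0_forward <- function(gan, Z, C, training = FALSE) {
  co <- net_forward(gan$nets$g0_cond, C, training)
  no <- net_forward(gan$nets$g0_noise, Z, training)
  mg <- net_forward(gan$nets$g0_merge, cbind(no$out, co$out), training)
  list(out = mg$out, co = co, no = no, mg = mg)
}

g0_backward <- function(gan, fw, dOut) {
  bm <- net_backward(gan$nets$g0_merge, fw$mg$cache, dOut)
  zc <- ncol(fw$no$out)
  bn <- net_backward(gan$nets$g0_noise, fw$no$cache,
                     bm$dX[, seq_len(zc), drop = FALSE])
  bc <- net_backward(gan$nets$g0_cond, fw$co$cache,
                     bm$dX[, -seq_len(zc), drop = FALSE])
  list(g0_merge = bm$grads, g0_noise = bn$grads, g0_cond = bc$grads)
}

g1_forward <- function(gan, S0, C, training = FALSE) {
  co <- net_forward(gan$nets$g1_cond, C, training)
  rs <- net_forward(gan$nets$g1_res, cbind(S0, co$out), training)
  list(out = rs$out, co = co, rs = rs)
}

g1_backward <- function(gan, fw, dOut) {
  br <- net_backward(gan$nets$g1_res, fw$rs$cache, dOut)
  L <- ncol(fw$rs$cache[[1]]$X) - ncol(fw$co$out)
  bc <- net_backward(gan$nets$g1_cond, fw$co$cache,
                     br$dX[, -seq_len(L), drop = FALSE])
  list(g1_res = br$grads, g1_cond = bc$grads,
       dS0 = br$dX[, seq_len(L), drop = FALSE])
}

f_forward <- function(gan, stage, X, C, training = FALSE) {
  f <- gan$nets[[paste0("f", stage - 1L)]]
  m <- net_forward(f$m, X, training)
  g <- net_forward(f$g, C, training)
  sub <- (m$out - g$out)^2
  mult <- m$out * g$out
  hd <- net_forward(f$head, cbind(sub, mult), training)
  p <- 1 / (1 + exp(-hd$out))
  list(p = p, logit = hd$out, m = m, g = g, sub = sub, mult = mult, hd = hd)
}

f_backward <- function(gan, stage, fw, dLogit) {
  f <- gan$nets[[paste0("f", stage - 1L)]]
  bh <- net_backward(f$head, fw$hd$cache, dLogit)
  k <- ncol(fw$sub)
  dsub <- bh$dX[, seq_len(k), drop = FALSE]
  dmult <- bh$dX[, -seq_len(k), drop = FALSE]
  diff <- fw$m$out - fw$g$out
  dm <- 2 * diff * dsub + fw$g$out * dmult
  dg <- -2 * diff * dsub + fw$m$out * dmult
  bm <- net_backward(f$m, fw$m$cache, dm)
  bg <- net_backward(f$g, fw$g$cache, dg)
  list(m = bm$grads, g = bg$grads, head = bh$grads,
       dX = bm$dX, dC = bg$dX)
}

# ---------------------------------------------------------------------------
# Exported operations

#' Stage-I generation: latent molecules from noise and a signature
#'
#' @param z Noise matrix (rows = samples) or single vector of dimension
#'   `noise_dim`.
#' @param c Expression signature matrix/vector of dimension `n_genes`.
#' @param gan A `gan_params` object.
#' @param training Use batch statistics (training mode) for batch norm.
#' @return Latent matrix in `[-1, 1]^L`, one row per sample.
#' @export
generate_stage1 <- function(z, c, gan, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"))
  Z <- as_batch(z, gan$config$noise_dim, "noise")
  C <- as_batch(c, gan$config$n_genes, "signature")
  if (nrow(C) == 1L && nrow(Z) > 1L) C <- C[rep(1L, nrow(Z)), , drop = FALSE]
  stopifnot(nrow(Z) == nrow(C))
  g0_forward(gan, Z, C, training)$out
}

#' Stage-II generation: residual refinement of a stage-I latent
#'
#' @param s0 Stage-I latent matrix/vector (`latent_dim` columns).
#' @param c Expression signature matrix/vector.
#' @param gan A `gan_params` object.
#' @param training Batch-norm mode.
#' @return Refined latent matrix in `[-1, 1]^L`.
#' @export
generate_stage2 <- function(s0, c, gan, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"))
  S0 <- as_batch(s0, gan$config$latent_dim, "stage-I latent")
  C <- as_batch(c, gan$config$n_genes, "signature")
  if (nrow(C) == 1L && nrow(S0) > 1L) C <- C[rep(1L, nrow(S0)), , drop = FALSE]
  stopifnot(nrow(S0) == nrow(C))
  g1_forward(gan, S0, C, training)$out
}

#' Wasserstein critic score
#'
#' Unbounded scalar score (no sigmoid); dropout is active only in training
#' mode, so inference scores are deterministic.
#'
#' @param x Latent matrix/vector.
#' @param gan A `gan_params` object.
#' @param stage Critic stage (1 or 2).
#' @param training Apply dropout.
#' @return Numeric vector of critic scores.
#' @export
critic_score <- function(x, gan, stage = 1L, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"), stage %in% c(1L, 2L))
  X <- as_batch(x, gan$config$latent_dim, "latent")
  drop(net_forward(gan$nets[[paste0("d", stage - 1L)]], X, training)$out)
}

#' Conditional matching probability
#'
#' Probability that a molecular latent would induce the given signature,
#' from the SubMult+NN conditional network: branch MLPs produce embeddings
#' m and g, which are compared through elementwise `(m - g) o (m - g)`
#' (subtraction) and `m o g` (multiplication), a LeakyReLU comparison
#' layer and a sigmoid output head.
#'
#' @param x Latent matrix/vector.
#' @param c Signature matrix/vector.
#' @param gan A `gan_params` object.
#' @param stage Conditional network stage (1 or 2).
#' @param training Apply branch dropout.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
conditional_score <- function(x, c, gan, stage = 1L, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"), stage %in% c(1L, 2L))
  X <- as_batch(x, gan$config$latent_dim, "latent")
  C <- as_batch(c, gan$config$n_genes, "signature")
  if (nrow(C) == 1L && nrow(X) > 1L) C <- C[rep(1L, nrow(X)), , drop = FALSE]
  stopifnot(nrow(X) == nrow(C))
  drop(f_forward(gan, stage, X, C, training)$p)
}

#' Gradient penalty of a critic
#'
#' `lambda * E[(||grad_xhat D(xhat)||_2 - 1)^2]` with `xhat` drawn
#' uniformly on the segments joining paired real and generated latents.
#'
#' @param real,fake Latent batches of equal size.
#' @param gan A `gan_params` object.
#' @param stage Critic stage (1 or 2).
#' @param seed Seed for the interpolation draw.
#' @param training Critic dropout mode.
#' @return Nonnegative scalar penalty.
#' @export
gradient_penalty <- function(real, fake, gan, stage = 1L, seed = NULL,
                             training = FALSE) {
  stopifnot(inherits(gan, "gan_params"))
  R_ <- as_batch(real, gan$config$latent_dim, "real latents")
  F_ <- as_batch(fake, gan$config$latent_dim, "generated latents")
  if (nrow(R_) == 0L || nrow(F_) == 0L) {
    stop_gexmol("empty batch in gradient penalty", class = "gexmol_shape_error")
  }
  stopifnot(nrow(R_) == nrow(F_))
  Xhat <- with_seed(seed, {
    eps <- stats::runif(nrow(R_))
    eps * R_ + (1 - eps) * F_
  })
  gp_value_grads(gan$nets[[paste0("d", stage - 1L)]], Xhat,
                 gan$config$lambda_gp, training = training)$value
}

#' Critic (discriminator) loss
#'
#' `E[-D(x_real)] + E[D(x_gen)] + gradient penalty`, the WGAN-GP critic
#' objective of either stage.
#'
#' @param real,generated Latent batches of equal size (generated by the
#'   corresponding stage's generator).
#' @param gan A `gan_params` object.
#' @param stage 1 or 2.
#' @param seed Seed for the penalty interpolation.
#' @param training Critic dropout mode.
#' @return Scalar loss.
#' @export
loss_discriminator <- function(real, generated, gan, stage = 1L,
                               seed = NULL, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"))
  R_ <- as_batch(real, gan$config$latent_dim, "real latents")
  F_ <- as_batch(generated, gan$config$latent_dim, "generated latents")
  if (nrow(R_) == 0L) {
    stop_gexmol("empty batch", class = "gexmol_shape_error")
  }
  mean(-critic_score(R_, gan, stage, training)) +
    mean(critic_score(F_, gan, stage, training)) +
    gradient_penalty(R_, F_, gan, stage, seed, training)
}

#' Generator loss
#'
#' `E[-D(G(.)) - alpha log f(G(.), c)]`: the Wasserstein generator term
#' plus the conditional matching log-score. The matching probability is
#' clamped away from 0/1 before the log for numerical safety.
#'
#' @param input Noise batch (stage 1) or stage-I latent batch (stage 2).
#' @param c Signature batch.
#' @param gan A `gan_params` object.
#' @param stage 1 or 2.
#' @param training Batch-norm/dropout mode for the forward passes.
#' @return Scalar loss.
#' @export
loss_generator <- function(input, c, gan, stage = 1L, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"))
  X <- if (stage == 1L) generate_stage1(input, c, gan, training)
       else generate_stage2(input, c, gan, training)
  p <- pmin(pmax(conditional_score(X, c, gan, stage, training), 1e-7),
            1 - 1e-7)
  mean(-critic_score(X, gan, stage, training) -
         gan$config$alpha_cond * log(p))
}

#' Conditional-network training loss
#'
#' Binary cross-entropy of the matching network: observed (latent,
#' signature) pairs are labelled 1, mismatched pairings 0.
#'
#' @param x_pos,c_pos Matched latent/signature batches.
#' @param x_neg,c_neg Mismatched latent/signature batches (typically the
#'   same latents against within-batch shuffled signatures).
#' @param gan A `gan_params` object.
#' @param stage 1 or 2.
#' @param training Dropout mode.
#' @return Scalar BCE loss (>= 0).
#' @export
conditional_net_loss <- function(x_pos, c_pos, x_neg, c_neg, gan,
                                 stage = 1L, training = FALSE) {
  stopifnot(inherits(gan, "gan_params"))
  if (NROW(x_pos) == 0L || NROW(x_neg) == 0L) {
    stop_gexmol("empty batch in conditional_net_loss",
                class = "gexmol_shape_error")
  }
  pp <- pmin(pmax(conditional_score(x_pos, c_pos, gan, stage, training),
                  1e-7), 1 - 1e-7)
  pn <- pmin(pmax(conditional_score(x_neg, c_neg, gan, stage, training),
                  1e-7), 1 - 1e-7)
  -(sum(log(pp)) + sum(log(1 - pn))) / (length(pp) + length(pn))
}
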