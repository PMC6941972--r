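# Training loop of the stacked conditional WGAN-GP, with per-epoch
# Fréchet-distance monitoring between the real and generated latent
# distributions. Both stages are stepped in the same loop; critics and
# conditional networks update every step, generators every
# `g_update_every` steps; every network uses RMSprop at one learning rate.

#' Training schedule
#'
#' Publication-scale defaults: 1000 epochs of 125 steps, batch 256,
#' critics updated every step and generators every ten, RMSprop at 5e-5.
#'
#' @param epochs Number of epochs.
#' @param steps_per_epoch Optimization steps per epoch.
#' @param batch_size Minibatch size.
#' @param d_update_every,g_update_every Update cadence (in steps) of
#'   critics/conditional nets and of generators.
#' @param learning_rate RMSprop learning rate for all networks.
#' @param rho RMSprop decay.
#' @param monitor_n Signatures sampled per epoch for Fréchet monitoring
#'   (`Inf` = all; the publication protocol generates one latent per
#'   training signature each epoch).
#' @return A list of class `gan_schedule`.
#' @export
gan_schedule <- function(epochs = 1000L, steps_per_epoch = 125L,
                         batch_size = 256L, d_update_every = 1L,
                         g_update_every = 10L, learning_rate = 5e-5,
                         rho = 0.9, monitor_n = 500L) {
  stopifnot(epochs >= 1L, steps_per_epoch >= 1L, batch_size >= 1L,
            g_update_every >= d_update_every, d_update_every >= 1L)
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size),
                 d_update_every = as.integer(d_update_every),
                 g_update_every = as.integer(g_update_every),
                 learning_rate = learning_rate, rho = rho,
                 monitor_n = monitor_n),
            class = "gan_schedule")
}

#' Mean and covariance of a latent batch
#'
#' @param x Latent matrix (rows = samples, >= 2).
#' @return List of class `distribution_moments` with `mean` and
#'   (symmetrized) `covariance`.
#' @export
compute_moments <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop_gexmol("need at least 2 samples to compute moments",
                class = "gexmol_shape_error")
  }
  cv <- stats::cov(x)
  structure(list(mean = colMeans(x), covariance = (cv + t(cv)) / 2),
            class = "distribution_moments")
}

psd_sqrt <- function(M, tol = 1e-6) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1)) {
    stop_gexmol("covariance is not positive semidefinite (min eigenvalue %.3g)",
                min(e$values), class = "gexmol_numeric_error")
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between two Gaussians summarized by their moments
#'
#' `d^2 = ||mu_g - mu_r||^2 + Tr(C_g + C_r - 2 (C_g C_r)^{1/2})`, the
#' standard similarity measure between real and generated latent
#' distributions. The matrix square root is taken by eigendecomposition of
#' the symmetrized similarity transform with negative eigenvalues clipped
#' at zero.
#'
#' @param a,b `distribution_moments` objects (order is irrelevant).
#' @return Nonnegative squared Fréchet distance.
#' @export
frechet_distance <- function(a, b) {
  stopifnot(inherits(a, "distribution_moments"),
            inherits(b, "distribution_moments"))
  s <- psd_sqrt(a$covariance)
  M <- s %*% b$covariance %*% s
  ev <- pmax(eigen((M + t(M)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values, 0)
  d2 <- sum((a$mean - b$mean)^2) +
    sum(diag(a$covariance)) + sum(diag(b$covariance)) - 2 * sum(sqrt(ev))
  max(d2, 0)
}

# ---------------------------------------------------------------------------
# Fitting

#' Fit the stacked conditional WGAN-GP
#'
#' Trains stage I (noise + signature -> latent) and, optionally, stage II
#' (stage-I latent + signature -> refined latent) simultaneously on paired
#' (latent molecule, signature) records. Critics and conditional networks
#' are updated every step; generators every `g_update_every` steps. The
#' conditional networks are trained by binary cross-entropy on matched
#' versus within-batch shuffled pairs on the critic schedule. At the end of
#' each epoch latents are generated for (a subsample of) the training
#' signatures and compared with the real latents by Fréchet distance.
#'
#' @param latents n x L matrix of translator-encoded molecules.
#' @param signatures n x G matrix of paired expression signatures.
#' @param config A [gan_config()]; its `latent_dim`/`n_genes` must match.
#' @param schedule A [gan_schedule()].
#' @param stages Train stage I only (`1`) or both stages (`2`).
#' @param latent_jitter Standard deviation of fresh Gaussian noise added
#'   to each real latent batch (instance noise). Thickening the real
#'   distribution gives the critic overlapping supports to compare and
#'   lets the generator match a full-dimensional target; pairing it with
#'   the translator's `latent_noise` keeps the decoder competent exactly
#'   on that thickened manifold.
#' @param seed Master seed; the full loss history is reproducible.
#' @param verbose Print one line per `verbose` epochs (0 = silent).
#' @return An object of class `gexmol_gan`: the fitted `gan_params` plus a
#'   `history` data frame (per-epoch mean losses and Fréchet distances).
#' @export
train_gan <- function(latents, signatures, config = gan_config_desk(),
                      schedule = gan_schedule(), stages = 2L,
                      latent_jitter = 0, seed = 1L, verbose = 0L) {
  latents <- as.matrix(latents); signatures <- as.matrix(signatures)
  n <- nrow(latents)
  if (n == 0L) stop_gexmol("empty dataset", class = "gexmol_config_error")
  if (nrow(signatures) != n) {
    stop_gexmol("latents (%d) and signatures (%d) differ in rows", n,
                nrow(signatures), class = "gexmol_shape_error")
  }
  if (ncol(latents) != config$latent_dim ||
      ncol(signatures) != config$n_genes) {
    stop_gexmol("data dimensions (%d, %d) do not match config (L = %d, G = %d)",
                ncol(latents), ncol(signatures), config$latent_dim,
                config$n_genes, class = "gexmol_shape_error")
  }
  if (schedule$batch_size > n) {
    stop_gexmol("batch_size %d exceeds dataset size %d",
                schedule$batch_size, n, class = "gexmol_config_error")
  }
  stopifnot(stages %in% c(1L, 2L))

  gan <- gan_init(config, seed = seed)
  with_seed(derive_seed(seed, "gan_train"), {
    opt <- new.env(parent = emptyenv())
    for (nm in c("g0_cond", "g0_noise", "g0_merge", "g1_cond", "g1_res",
                 "d0", "d1")) {
      opt[[nm]] <- rmsprop_state(gan$nets[[nm]])
    }
    for (nm in c("f0", "f1")) {
      opt[[nm]] <- lapply(gan$nets[[nm]], rmsprop_state)
    }
    step_net <- function(name, grads) {
      u <- rmsprop_step(gan$nets[[name]], grads, opt[[name]],
                        schedule$learning_rate, schedule$rho)
      gan$nets[[name]] <<- u$net
      opt[[name]] <<- u$state
    }
    step_fnet <- function(name, grads) {
      for (part in c("m", "g", "head")) {
        u <- rmsprop_step(gan$nets[[name]][[part]], grads[[part]],
                          opt[[name]][[part]], schedule$learning_rate,
                          schedule$rho)
        gan$nets[[name]][[part]] <<- u$net
        opt[[name]][[part]] <<- u$state
      }
    }
    B <- schedule$batch_size
    lam <- config$lambda_gp
    alp <- config$alpha_cond
    real_mom <- compute_moments(latents)
    hist_cols <- c("d0", "g0", "f0", "d1", "g1", "f1", "fd1", "fd2")
    history <- matrix(NA_real_, schedule$epochs, length(hist_cols),
                      dimnames = list(NULL, hist_cols))
    gstep <- 0L

    critic_update <- function(dname, Xr, Xf) {
      fwr <- net_forward(gan$nets[[dname]], Xr, training = TRUE)
      gan$nets[[dname]] <<- fwr$net
      br <- net_backward(fwr$net, fwr$cache, matrix(-1 / B, B, 1L))
      fwf <- net_forward(gan$nets[[dname]], Xf, training = TRUE)
      bf <- net_backward(fwf$net, fwf$cache, matrix(1 / B, B, 1L))
      eps <- stats::runif(B)
      gp <- gp_value_grads(gan$nets[[dname]], eps * Xr + (1 - eps) * Xf,
                           lam, training = TRUE)
      g <- grads_add(grads_add(br$grads, bf$grads), gp$grads)
      step_net(dname, g)
      mean(-fwr$out) + mean(fwf$out) + gp$value
    }
    f_update <- function(stage, Xp, Cp) {
      perm <- sample.int(nrow(Cp))
      fp <- f_forward(gan, stage, Xp, Cp, training = TRUE)
      fn <- f_forward(gan, stage, Xp, Cp[perm, , drop = FALSE],
                      training = TRUE)
      N <- 2L * nrow(Xp)
      bp <- f_backward(gan, stage, fp, (fp$p - 1) / N)
      bn <- f_backward(gan, stage, fn, fn$p / N)
      nm <- paste0("f", stage - 1L)
      step_fnet(nm, list(m = grads_add(bp$m, bn$m),
                         g = grads_add(bp$g, bn$g),
                         head = grads_add(bp$head, bn$head)))
      pc <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
      -(sum(log(pc(fp$p))) + sum(log(1 - pc(fn$p)))) / N
    }
    gen_loss_grad_x <- function(stage, X, C) {
      # d/dX of mean(-D(X) - alpha log f(X, C)) plus the loss value
      dname <- paste0("d", stage - 1L)
      fwd <- net_forward(gan$nets[[dname]], X, training = TRUE)
      bd <- net_backward(fwd$net, fwd$cache, matrix(-1 / B, B, 1L))
      ff <- f_forward(gan, stage, X, C, training = TRUE)
      bf <- f_backward(gan, stage, ff, -alp / B * (1 - ff$p))
      val <- mean(-fwd$out - alp * log(pmin(pmax(ff$p, 1e-7), 1 - 1e-7)))
      list(dX = bd$dX + bf$dX, value = val)
    }

    for (ep in seq_len(schedule$epochs)) {
      acc <- stats::setNames(numeric(length(hist_cols)), hist_cols)
      cnt <- stats::setNames(numeric(length(hist_cols)), hist_cols)
      for (st in seq_len(schedule$steps_per_epoch)) {
        gstep <- gstep + 1L
        idx <- sample.int(n, B)
        Xr <- latents[idx, , drop = FALSE]
        if (latent_jitter > 0) {
          Xr <- Xr + matrix(stats::rnorm(length(Xr), sd = latent_jitter),
                            nrow(Xr))
        }
        Cb <- signatures[idx, , drop = FALSE]
        Zb <- matrix(stats::rnorm(B * config$noise_dim), B)
        if (gstep %% schedule$d_update_every == 0L) {
          fw0 <- g0_forward(gan, Zb, Cb, training = TRUE)
          acc["d0"] <- acc["d0"] + critic_update("d0", Xr, fw0$out)
          acc["f0"] <- acc["f0"] + f_update(1L, Xr, Cb)
          cnt["d0"] <- cnt["d0"] + 1; cnt["f0"] <- cnt["f0"] + 1
          if (stages >= 2L) {
            fw1 <- g1_forward(gan, fw0$out, Cb, training = TRUE)
            acc["d1"] <- acc["d1"] + critic_update("d1", Xr, fw1$out)
            acc["f1"] <- acc["f1"] + f_update(2L, Xr, Cb)
            cnt["d1"] <- cnt["d1"] + 1; cnt["f1"] <- cnt["f1"] + 1
          }
        }
        if (gstep %% schedule$g_update_every == 0L) {
          fw0 <- g0_forward(gan, Zb, Cb, training = TRUE)
          gan$nets$g0_cond <- fw0$co$net
          gan$nets$g0_noise <- fw0$no$net
          gan$nets$g0_merge <- fw0$mg$net
          gl <- gen_loss_grad_x(1L, fw0$out, Cb)
          bg <- g0_backward(gan, fw0, gl$dX)
          step_net("g0_cond", bg$g0_cond)
          step_net("g0_noise", bg$g0_noise)
          step_net("g0_merge", bg$g0_merge)
          acc["g0"] <- acc["g0"] + gl$value; cnt["g0"] <- cnt["g0"] + 1
          if (stages >= 2L) {
            S0 <- g0_forward(gan, Zb, Cb, training = TRUE)$out  # detached
            fw1 <- g1_forward(gan, S0, Cb, training = TRUE)
            gan$nets$g1_cond <- fw1$co$net
            gan$nets$g1_res <- fw1$rs$net
            gl1 <- gen_loss_grad_x(2L, fw1$out, Cb)
            bg1 <- g1_backward(gan, fw1, gl1$dX)
            step_net("g1_cond", bg1$g1_cond)
            step_net("g1_res", bg1$g1_res)
            acc["g1"] <- acc["g1"] + gl1$value; cnt["g1"] <- cnt["g1"] + 1
          }
        }
      }
      # epoch-end monitoring: one generated latent per (subsampled)
      # training signature, compared with the real latents
      midx <- if (is.finite(schedule$monitor_n) && schedule$monitor_n < n)
        sample.int(n, schedule$monitor_n) else seq_len(n)
      Cm <- signatures[midx, , drop = FALSE]
      Zm <- matrix(stats::rnorm(length(midx) * config$noise_dim),
                   length(midx))
      S0m <- generate_stage1(Zm, Cm, gan)
      history[ep, "fd1"] <- frechet_distance(real_mom, compute_moments(S0m))
      if (stages >= 2L) {
        history[ep, "fd2"] <- frechet_distance(
          real_mom, compute_moments(generate_stage2(S0m, Cm, gan)))
      }
      history[ep, names(acc)[cnt > 0]] <-
        acc[cnt > 0] / cnt[cnt > 0]
      if (verbose > 0L && ep %% verbose == 0L) {
        message(sprintf(
          "epoch %4d | D0 %8.3f G0 %8.3f f0 %6.3f | FD1 %8.4f%s", ep,
          history[ep, "d0"], history[ep, "g0"], history[ep, "f0"],
          history[ep, "fd1"],
          if (stages >= 2L) sprintf(" FD2 %8.4f", history[ep, "fd2"]) else ""))
      }
    }
    structure(list(params = gan, config = config, schedule = schedule,
                   stages = stages, seed = seed,
                   history = as.data.frame(cbind(epoch = seq_len(schedule$epochs),
                                                 history))),
              class = "gexmol_gan")
  })
}

# ---------------------------------------------------------------------------
# S3 methods

#' @export
print.gexmol_gan <- function(x, ...) {
  h <- x$history
  cat(sprintf("conditional WGAN-GP fit (%s)\n",
              if (x$stages >= 2L) "stages I + II" else "stage I only"))
  cat(sprintf("  %d epochs x %d steps, batch %d, RMSprop lr %g\n",
              x$schedule$epochs, x$schedule$steps_per_epoch,
              x$schedule$batch_size, x$schedule$learning_rate))
  cat(sprintf("  Frechet distance (stage I): %.4f (epoch 1) -> %.4f (final)\n",
              h$fd1[1], utils::tail(h$fd1, 1L)))
  if (x$stages >= 2L) {
    cat(sprintf("  Frechet distance (stage II): %.4f -> %.4f\n",
                h$fd2[1], utils::tail(h$fd2, 1L)))
  }
  invisible(x)
}

#' @export
summary.gexmol_gan <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 3L))
  invisible(object)
}

#' @export
plot.gexmol_gan <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$fd1, type = "l", xlab = "epoch",
                 ylab = "Frechet distance", main = "training monitoring", ...)
  if (x$stages >= 2L && any(is.finite(h$fd2))) {
    graphics::lines(h$epoch, h$fd2, lty = 2)
    graphics::legend("topright", c("stage I", "stage II"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Generate latent molecules from a fitted GAN
#'
#' @param object A `gexmol_gan` fit.
#' @param signature A single signature vector (or matrix of signatures,
#'   one per generated sample).
#' @param n Number of latents to generate (per signature vector input).
#' @param stage Use the stage-I output or the stage-II refinement.
#' @param seed Noise seed.
#' @param ... Unused.
#' @return Latent matrix with `n` rows.
#' @export
predict.gexmol_gan <- function(object, signature, n = 1L,
                               stage = object$stages, seed = NULL, ...) {
  gan <- object$params
  C <- as_batch(signature, gan$config$n_genes, "signature")
  if (nrow(C) == 1L) C <- C[rep(1L, n), , drop = FALSE]
  Z <- with_seed(seed,
                 matrix(stats::rnorm(nrow(C) * gan$config$noise_dim),
                        nrow(C)))
  S0 <- generate_stage1(Z, C, gan)
  if (stage >= 2L) generate_stage2(S0, C, gan) else S0
}

#' Simulate decoded molecules from a fitted GAN
#'
#' Convenience wrapper: generates latents with [predict.gexmol_gan()] and
#' decodes them with the paired translator.
#'
#' @param object A `gexmol_gan` fit.
#' @param nsim Number of molecules.
#' @param seed Noise/decode seed.
#' @param signature Conditioning signature vector.
#' @param translator A fitted `smiles_translator`.
#' @param ... Passed to [predict.gexmol_gan()].
#' @return Character vector of SMILES (`NA` where decoding truncated).
#' @export
simulate.gexmol_gan <- function(object, nsim = 1L, seed = NULL,
                                signature, translator, ...) {
  lat <- predict(object, signature, n = nsim, seed = seed, ...)
  decode_latent(lat, translator)
}
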