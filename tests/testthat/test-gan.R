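# GAN core: architectures, the four losses, the gradient penalty and the
# SubMult+NN conditional network, all checked against closed forms,
# hand-built arithmetic oracles and finite differences.

test_that("default configuration is the published architecture", {
  cf <- gan_config()
  expect_identical(cf$cond_widths, c(512L, 256L))
  expect_identical(cf$noise_widths, c(512L, 256L))
  expect_identical(cf$critic_widths, c(256L, 256L, 256L))
  expect_identical(cf$n_genes, 978L)
  expect_identical(cf$noise_dim, 1000L)
  expect_identical(cf$latent_dim, 256L)
  expect_identical(cf$n_residual_blocks, 2L)
  expect_identical(cf$dropout_critic, 0.4)
  expect_identical(cf$dropout_cond, 0.4)
  expect_identical(cf$lambda_gp, 10)
  expect_identical(cf$alpha_cond, 10)
  expect_error(gan_config(lambda_gp = -1))
})

test_that("generator outputs live in [-1, 1] and respect shapes", {
  gan <- gan_init(toy_gan_config(), seed = 3)
  set.seed(1)
  Z <- matrix(rnorm(8 * 8), 8)
  C <- matrix(rnorm(8 * 6), 8)
  s0 <- generate_stage1(Z, C, gan)
  expect_identical(dim(s0), c(8L, 16L))
  expect_true(all(abs(s0) <= 1))
  s1 <- generate_stage2(s0, C, gan)
  expect_identical(dim(s1), c(8L, 16L))
  expect_true(all(abs(s1) <= 1))
  expect_error(generate_stage1(Z[, 1:3], C, gan), class = "gexmol_shape_error")
  # zero weights: tanh(0) = 0
  gan0 <- gan
  gan0$nets <- zero_params(gan$nets)
  expect_true(all(generate_stage1(Z, C, gan0) == 0))
})

test_that("a zeroed residual block is the identity and matches its formula", {
  # f = 0 => x + f(x) = x
  blk <- gexmol:::op_res(4L)
  blk$W1[] <- 0; blk$W2[] <- 0; blk$b1[] <- 0; blk$b2[] <- 0
  X <- matrix(rnorm(12), 3L)
  expect_identical(gexmol:::net_forward(list(blk), X)$out, X)
  # f(x) = W2 act(W1 x + b1) + b2 against direct arithmetic on a 2-d toy
  blk2 <- gexmol:::op_res(2L, slope = 0.2)
  x <- matrix(c(0.3, -0.7), 1L)
  a <- drop(x %*% blk2$W1) + blk2$b1
  f <- drop(ifelse(a > 0, a, 0.2 * a) %*% blk2$W2) + blk2$b2
  expect_equal(drop(gexmol:::net_forward(list(blk2), x)$out), drop(x) + f,
               tolerance = 1e-12)
})

test_that("critic scores are deterministic in inference and zero for zero weights", {
  gan <- gan_init(toy_gan_config(), seed = 5)
  x <- matrix(runif(4 * 16, -1, 1), 4)
  expect_identical(critic_score(x, gan), critic_score(x, gan))
  gan0 <- gan
  gan0$nets$d0 <- zero_params(gan$nets$d0)
  expect_identical(unname(critic_score(x, gan0)), rep(0, 4))
})

test_that("the conditional network computes sigmoid(W[sub, mult] + b)", {
  cfg <- gan_config(n_genes = 2L, latent_dim = 2L, noise_dim = 2L,
                    cond_widths = c(3L, 2L), noise_widths = c(3L, 2L),
                    merge_hidden = 3L, critic_widths = c(3L, 3L, 3L),
                    fm_widths = c(2L, 2L), fg_widths = c(2L, 2L),
                    compare_width = 3L, dropout_cond = 0)
  gan <- gan_init(cfg, seed = 7)
  x <- c(0.4, -0.2); cc <- c(1.1, -0.6)
  p <- conditional_score(x, cc, gan)
  expect_true(p > 0 && p < 1)
  # independent arithmetic oracle over the same weights
  fwd_branch <- function(net, v) {
    for (op in net) {
      if (op$kind == "dense") v <- drop(v %*% op$W) + op$b
      if (op$kind == "act" && op$fun == "lrelu")
        v <- ifelse(v > 0, v, op$slope * v)
    }
    v
  }
  f <- gan$nets$f0
  m <- fwd_branch(f$m, x)
  g <- fwd_branch(f$g, cc)
  sub <- (m - g)^2           # m == g makes this exactly zero
  mult <- m * g
  h <- fwd_branch(f$head, c(sub, mult))
  expect_equal(unname(p), 1 / (1 + exp(-h)), tolerance = 1e-12)
  expect_identical(sub - (m - g) * (m - g), rep(0, length(m)))
})

test_that("gradient penalty closed forms hold for linear critics", {
  w <- c(0.6, 0.8, 0, 0)                       # unit L2 norm
  gan1 <- linear_critic_gan(w, latent_dim = 16L)
  gan1$nets$d0 <- list(list(kind = "dense", W = matrix(c(w, rep(0, 12)),
                                                       16L, 1L), b = 0))
  set.seed(2)
  real <- matrix(runif(10 * 16, -1, 1), 10)
  fake <- matrix(runif(10 * 16, -1, 1), 10)
  expect_equal(gradient_penalty(real, fake, gan1, seed = 1), 0,
               tolerance = 1e-6)
  gan2 <- gan1
  gan2$nets$d0[[1]]$W <- 2 * gan1$nets$d0[[1]]$W
  expect_equal(gradient_penalty(real, fake, gan2, seed = 1), 10,
               tolerance = 1e-6)
  # lambda = 0 kills the penalty; label swap leaves linear critics unchanged
  gan0 <- gan2; gan0$config$lambda_gp <- 0
  expect_identical(gradient_penalty(real, fake, gan0, seed = 1), 0)
  expect_equal(gradient_penalty(fake, real, gan2, seed = 1),
               gradient_penalty(real, fake, gan2, seed = 1),
               tolerance = 1e-12)
  expect_error(gradient_penalty(real[0, ], fake[0, ], gan2),
               class = "gexmol_shape_error")
})

test_that("discriminator loss matches its closed forms", {
  set.seed(3)
  X <- matrix(runif(6 * 16, -1, 1), 6)
  # zero-weight critic: scores 0, gradient 0 => loss = lambda * (0-1)^2
  gan <- gan_init(toy_gan_config(), seed = 1)
  gan$nets$d0 <- zero_params(gan$nets$d0)
  expect_equal(loss_discriminator(X, X, gan, stage = 1, seed = 4), 10,
               tolerance = 1e-9)
  # constant critic k with lambda = 0: -k + k + 0 = 0
  gank <- gan
  gank$config$lambda_gp <- 0
  gank$nets$d0[[length(gank$nets$d0)]]$b <- 3.7
  expect_equal(loss_discriminator(X, X * 0.5, gank, stage = 1, seed = 4), 0,
               tolerance = 1e-9)
})

test_that("generator loss reduces correctly when alpha = 0 or f = 1", {
  gan <- gan_init(toy_gan_config(), seed = 9)
  set.seed(5)
  Z <- matrix(rnorm(6 * 8), 6)
  C <- matrix(rnorm(6 * 6), 6)
  g0 <- generate_stage1(Z, C, gan)
  # alpha = 0: pure Wasserstein generator term
  gan_a0 <- gan; gan_a0$config$alpha_cond <- 0
  expect_equal(loss_generator(Z, C, gan_a0, stage = 1),
               mean(-critic_score(g0, gan)), tolerance = 1e-9)
  # f == 1 (huge positive head bias): conditional term is -alpha log 1 = 0
  gan_f1 <- gan
  gan_f1$nets$f0$head[[3]]$W[] <- 0
  gan_f1$nets$f0$head[[3]]$b <- 40
  expect_equal(loss_generator(Z, C, gan_f1, stage = 1),
               mean(-critic_score(g0, gan)), tolerance = 1e-5)
})

test_that("conditional-network loss has its closed forms and pairing bound", {
  gan <- gan_init(toy_gan_config(), seed = 2)
  X <- matrix(runif(5 * 16, -1, 1), 5)
  C <- matrix(rnorm(5 * 6), 5)
  # f == 0.5 via zero head
  gan05 <- gan
  gan05$nets$f0$head <- zero_params(gan$nets$f0$head)
  expect_equal(conditional_net_loss(X, C, X, C, gan05), log(2),
               tolerance = 1e-12)
  # positives == negatives: no classifier beats the constant 1/2
  expect_gte(conditional_net_loss(X, C, X, C, gan), log(2) - 1e-9)
  expect_error(conditional_net_loss(X[0, ], C[0, ], X, C, gan),
               class = "gexmol_shape_error")
})

test_that("all network backward passes agree with finite differences", {
  set.seed(10)
  net <- list(gexmol:::op_dense(3L, 4L), gexmol:::op_act("lrelu"),
              gexmol:::op_bn(4L), gexmol:::op_res(4L),
              gexmol:::op_dense(4L, 2L), gexmol:::op_act("tanh"))
  X <- matrix(rnorm(15), 5L)
  Tgt <- matrix(rnorm(10), 5L)
  fw <- gexmol:::net_forward(net, X, training = TRUE)
  bw <- gexmol:::net_backward(fw$net, fw$cache, 2 * (fw$out - Tgt))
  ga <- gexmol:::grads_flatten(net, bw$grads)
  th <- gexmol:::net_flatten(net)
  lossf <- function(theta) {
    out <- gexmol:::net_forward(gexmol:::net_unflatten(net, theta), X,
                                training = TRUE)$out
    sum((out - Tgt)^2)
  }
  base <- lossf(th)
  for (k in sample(length(th), 20L)) {
    e <- th; e[k] <- e[k] + 1e-6
    expect_equal(ga[[k]], (lossf(e) - base) / 1e-6, tolerance = 1e-3)
  }
})

test_that("gradient-penalty weight gradients agree with finite differences", {
  set.seed(11)
  critic <- list(gexmol:::op_dense(3L, 5L), gexmol:::op_act("lrelu"),
                 gexmol:::op_drop(0.4), gexmol:::op_dense(5L, 1L))
  Xh <- matrix(rnorm(12), 4L)
  gpfun <- function(theta) {
    set.seed(77)   # fixed dropout draw
    gexmol:::gp_value_grads(gexmol:::net_unflatten(critic, theta), Xh,
                            lambda = 10)$value
  }
  th <- gexmol:::net_flatten(critic)
  set.seed(77)
  rr <- gexmol:::gp_value_grads(critic, Xh, lambda = 10)
  ga <- gexmol:::grads_flatten(critic, rr$grads)
  base <- rr$value
  for (k in sample(length(th), 15L)) {
    e <- th; e[k] <- e[k] + 1e-6
    expect_equal(ga[[k]], (gpfun(e) - base) / 1e-6, tolerance = 1e-3)
  }
})

test_that("with alpha = 0 the system is a plain conditional WGAN-GP that
           matches the real moments on a 2-d Gaussian task", {
  set.seed(21)
  n <- 300
  C <- matrix(rnorm(n * 2), n)
  X <- tanh(0.8 * C + 0.15 * matrix(rnorm(n * 2), n))
  cfg <- gan_config(n_genes = 2L, latent_dim = 2L, noise_dim = 4L,
                    cond_widths = c(16L, 8L), noise_widths = c(16L, 8L),
                    merge_hidden = 16L, critic_widths = c(32L, 32L, 32L),
                    fm_widths = c(8L, 8L), fg_widths = c(8L, 8L),
                    compare_width = 8L, alpha_cond = 0)
  fit <- train_gan(X, C, cfg,
                   gan_schedule(epochs = 60L, steps_per_epoch = 25L,
                                batch_size = 64L, learning_rate = 1e-3,
                                monitor_n = 200L),
                   stages = 1L, seed = 13)
  # generated moments end close to the real ones, and closer than the
  # worst epoch encountered along the way
  expect_lt(utils::tail(fit$history$fd1, 1L), 0.35)
  expect_lt(utils::tail(fit$history$fd1, 1L), max(fit$history$fd1))
})
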