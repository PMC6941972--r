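# Training loop and Fréchet-distance monitoring.

test_that("moments match the textbook two-pass computation", {
  v <- c(0.3, -1.2, 0.5)
  m <- compute_moments(rbind(v, v, v))
  expect_equal(m$mean, v, tolerance = 1e-12)
  expect_true(all(m$covariance == 0))
  m2 <- compute_moments(rbind(c(0, 0), c(2, 2)))
  expect_equal(m2$mean, c(1, 1), tolerance = 1e-12)
  set.seed(5)
  X <- matrix(rnorm(60), 12L)
  mm <- compute_moments(X)
  # independent two-pass oracle
  mu <- apply(X, 2L, mean)
  Cv <- matrix(0, 5L, 5L)
  for (i in seq_len(12L)) Cv <- Cv + tcrossprod(X[i, ] - mu) / 11
  expect_equal(mm$mean, mu, tolerance = 1e-12)
  expect_equal(mm$covariance, Cv, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(compute_moments(X[1, , drop = FALSE]),
               class = "gexmol_shape_error")
})

test_that("Fréchet distance obeys its closed forms and metric properties", {
  mom <- function(mu, C) structure(list(mean = mu, covariance = as.matrix(C)),
                                   class = "distribution_moments")
  expect_equal(frechet_distance(mom(0, 1), mom(1, 1)), 1, tolerance = 1e-8)
  expect_equal(frechet_distance(mom(0, 1), mom(0, 4)), 1, tolerance = 1e-8)
  expect_identical(frechet_distance(mom(c(1, 2), diag(2)),
                                    mom(c(1, 2), diag(2))), 0)
  set.seed(9)
  for (k in 1:25) {
    d <- sample(2:5, 1L)
    A <- crossprod(matrix(rnorm(d * d), d)) + 0.1 * diag(d)
    B <- crossprod(matrix(rnorm(d * d), d)) + 0.1 * diag(d)
    a <- mom(rnorm(d), A); b <- mom(rnorm(d), B)
    f1 <- frechet_distance(a, b); f2 <- frechet_distance(b, a)
    expect_gte(f1, 0)
    expect_lt(abs(f1 - f2), 1e-8)
  }
  bad <- mom(c(0, 0), matrix(c(1, 2, 2, 1), 2))   # eigenvalues 3, -1
  expect_error(frechet_distance(bad, mom(c(0, 0), diag(2))),
               class = "gexmol_numeric_error")
})

test_that("the schedule carries the published training protocol as default", {
  sch <- gan_schedule()
  expect_identical(sch$epochs, 1000L)
  expect_identical(sch$steps_per_epoch, 125L)
  expect_identical(sch$batch_size, 256L)
  expect_identical(sch$learning_rate, 5e-5)
  expect_identical(sch$d_update_every, 1L)
  expect_identical(sch$g_update_every, 10L)
  expect_error(gan_schedule(g_update_every = 1L, d_update_every = 2L))
})

test_that("short training runs are bitwise reproducible and validated", {
  set.seed(2)
  X <- matrix(runif(80 * 4, -1, 1), 80)
  C <- matrix(rnorm(80 * 3), 80)
  cfg <- gan_config(n_genes = 3L, latent_dim = 4L, noise_dim = 4L,
                    cond_widths = c(8L, 8L), noise_widths = c(8L, 8L),
                    merge_hidden = 8L, critic_widths = c(8L, 8L, 8L),
                    fm_widths = c(8L, 8L), fg_widths = c(8L, 8L),
                    compare_width = 8L)
  sch <- gan_schedule(epochs = 2L, steps_per_epoch = 6L, batch_size = 16L,
                      learning_rate = 1e-3, monitor_n = 40L)
  f1 <- train_gan(X, C, cfg, sch, stages = 2L, seed = 3)
  f2 <- train_gan(X, C, cfg, sch, stages = 2L, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_true(all(c("d0", "g0", "f0", "d1", "g1", "f1", "fd1", "fd2") %in%
                    names(f1$history)))
  expect_true(all(f1$history$fd1 >= 0))
  expect_error(train_gan(X[0, ], C[0, ], cfg, sch),
               class = "gexmol_config_error")
  expect_error(train_gan(X, C, cfg, gan_schedule(batch_size = 200L)),
               class = "gexmol_config_error")
  expect_error(train_gan(X, C[, 1:2], cfg, sch),
               class = "gexmol_shape_error")
  # predict/simulate surface
  lat <- predict(f1, C[1, ], n = 5L, seed = 1)
  expect_identical(dim(lat), c(5L, 4L))
  expect_identical(lat, predict(f1, C[1, ], n = 5L, seed = 1))
})
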