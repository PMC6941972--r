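# GRU translator: encoding purity and bounds, decoding guarantees,
# teacher-forced training behaviour, and exactness of the hand-derived
# backpropagation against finite differences.

test_that("encoding is a pure, bounded function of (smiles, params)", {
  tr <- toy_translator()
  l1 <- encode_molecule("CCO", tr)
  l2 <- encode_molecule("CCO", tr)
  expect_identical(l1, l2)
  expect_length(l1, tr$config$latent_dim)
  expect_true(all(abs(l1) <= 1))
  lat <- predict(tr, c("CCO", "CCN", "c1ccccc1"))
  expect_identical(dim(lat), c(3L, tr$config$latent_dim))
  expect_true(all(abs(lat) <= 1))
})

test_that("zero parameters encode every molecule to the origin", {
  tr <- toy_translator()
  tr0 <- tr
  tr0$params <- rapply(tr$params, function(x) x * 0, how = "replace")
  expect_identical(unname(encode_molecule("CC(C)O", tr0)),
                   rep(0, tr$config$latent_dim))
})

test_that("out-of-vocabulary characters raise a named encoding error", {
  tr <- toy_translator()
  err <- tryCatch(encode_molecule("CC%C", tr), error = identity)
  expect_s3_class(err, "gexmol_encoding_error")
  expect_match(conditionMessage(err), "%", fixed = TRUE)
})

test_that("decoded latents always parse under the grammar", {
  tr <- toy_translator()
  set.seed(8)
  lat <- matrix(runif(20 * tr$config$latent_dim, -1, 1), 20)
  dec <- decode_latent(lat, tr)
  for (i in which(!is.na(dec))) {
    expect_no_error(smiles_to_rules(dec[i], tr$grammar, 10000L))
  }
  # argmax decoding is deterministic
  expect_identical(dec, decode_latent(lat, tr))
  # sampling reproducible under seed
  expect_identical(decode_latent(lat, tr, mode = "sample", seed = 3),
                   decode_latent(lat, tr, mode = "sample", seed = 3))
})

test_that("uninformative output weights give cross-entropy log R", {
  g <- test_grammar()
  corpus <- c("CCO", "CCN", "CC(C)O")
  cfg <- translator_config(latent_dim = 8L, dropout = 0, latent_noise = 0)
  vocab <- gexmol:::translator_vocab(corpus)
  Xc <- t(vapply(corpus, gexmol:::chars_to_idx, integer(7L), vocab = vocab,
                 max_chars = 7L))
  Y <- t(vapply(lapply(corpus, smiles_to_rules, grammar = g, max_len = 20L),
                function(p) p$indices, integer(20L)))
  set.seed(1)
  params <- list(enc = gexmol:::gru_init(length(vocab), 8L),
                 dec = gexmol:::gru_init(length(g$rules) + 8L, 8L),
                 W0 = diag(8L),
                 Wo = matrix(0, 8L, length(g$rules)),
                 bo = rep(0, length(g$rules)))
  loss0 <- gexmol:::translator_batch(params, Xc, Y, g, cfg,
                                     training = FALSE)$loss
  expect_equal(loss0, log(length(g$rules)), tolerance = 0.1)
})

test_that("teacher-forced backpropagation matches finite differences", {
  g <- test_grammar()
  corpus <- c("CCO", "c1ccccc1", "CC(N)=O")
  cfg <- translator_config(latent_dim = 5L, dropout = 0, latent_noise = 0)
  vocab <- gexmol:::translator_vocab(corpus)
  Tc <- max(nchar(corpus))
  Xc <- t(vapply(corpus, gexmol:::chars_to_idx, integer(Tc), vocab = vocab,
                 max_chars = Tc))
  Y <- t(vapply(lapply(corpus, smiles_to_rules, grammar = g, max_len = 35L),
                function(p) p$indices, integer(35L)))
  set.seed(4)
  R <- length(g$rules)
  params <- list(enc = gexmol:::gru_init(length(vocab), 5L),
                 dec = gexmol:::gru_init(R + 5L, 6L),
                 W0 = matrix(rnorm(30, sd = 0.4), 5L, 6L),
                 Wo = matrix(rnorm(6 * R, sd = 0.3), 6L, R),
                 bo = rep(0, R))
  fb <- gexmol:::translator_batch(params, Xc, Y, g, cfg, training = TRUE)
  th <- unlist(params)
  ga <- unlist(fb$grads)
  pick <- sample(length(th), 25L)
  for (k in pick) {
    e <- th; e[k] <- e[k] + 1e-6
    num <- (gexmol:::translator_batch(utils::relist(e, params), Xc, Y, g,
                                      cfg, training = TRUE)$loss -
              fb$loss) / 1e-6
    expect_equal(ga[[k]], num, tolerance = 1e-3)
  }
})

test_that("training decreases the loss and is bitwise reproducible", {
  corp <- make_corpus(30, "small", seed = 31)
  cfg <- translator_config(latent_dim = 12L, epochs = 6L, batch_size = 10L,
                           learning_rate = 2e-3)
  t1 <- suppressMessages(train_translator(corp, config = cfg, seed = 7))
  t2 <- suppressMessages(train_translator(corp, config = cfg, seed = 7))
  expect_identical(t1$loss_history, t2$loss_history)
  expect_lt(mean(utils::tail(t1$loss_history, 2L)),
            mean(utils::head(t1$loss_history, 2L)))
  expect_identical(t1$config$dropout, 0.2)
  expect_error(train_translator(character(0)), class = "gexmol_config_error")
})
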