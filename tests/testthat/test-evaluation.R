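# Evaluation suite: similarity metrics, scaffold analysis, the
# nearest-neighbour signature baseline, rank-test comparison and the
# generation report invariants.

test_that("similarity metrics are bounded, symmetric and exact on identity", {
  for (m in c("maccs", "morgan")) {
    rec <- similarity("CCO", "CCO", m)
    expect_identical(rec$value, 1)
    ab <- similarity("CCO", "CCNC", m)$value
    ba <- similarity("CCNC", "CCO", m)$value
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_true(ab >= 0 && ab <= 1)
  }
  fr <- similarity("Cc1ccccc1CC(O)c1ccccc1", "CCc1ccccc1CC(O)c1ccccc1",
                   "fraggle")$value
  expect_true(fr >= 0 && fr <= 1)
  expect_error(similarity("C(", "CCO", "maccs"), class = "gexmol_chem_error")
})

test_that("fingerprint similarity equals set arithmetic over the raw bits", {
  fps <- chem_fingerprint(c("CCO", "c1ccccc1"), type = "maccs")
  direct <- length(intersect(fps[[1]], fps[[2]])) /
    length(union(fps[[1]], fps[[2]]))
  expect_equal(similarity("CCO", "c1ccccc1", "maccs")$value, direct,
               tolerance = 1e-12)
  fpm <- chem_fingerprint(c("CCO", "CCN"), type = "morgan")
  expect_equal(similarity("CCO", "CCN", "morgan")$value,
               length(intersect(fpm[[1]], fpm[[2]])) /
                 length(union(fpm[[1]], fpm[[2]])),
               tolerance = 1e-12)
})

test_that("the closest-active search equals the brute-force maximum", {
  actives <- c("CCO", "CCN", "c1ccccc1", "Cc1ccccc1", "CC(C)O")
  rec <- max_similarity_to_set("CCO", actives, "maccs")
  expect_identical(rec$value, 1)
  expect_identical(rec$reference, "CCO")
  q <- "CCCO"
  rec2 <- max_similarity_to_set(q, actives, "maccs")
  brute <- vapply(actives, function(a) similarity(q, a, "maccs")$value, 0)
  expect_equal(rec2$value, max(brute), tolerance = 1e-12)
  expect_identical(rec2$reference, actives[which.max(brute)])
  one <- max_similarity_to_set(q, actives[2], "maccs")
  expect_equal(one$value, similarity(q, actives[2], "maccs")$value,
               tolerance = 1e-12)
  expect_error(max_similarity_to_set(q, character(0), "maccs"),
               class = "gexmol_config_error")
})

test_that("scaffold overlap counts shared Murcko frameworks", {
  # toluene and ethylbenzene share the benzene scaffold
  ov <- scaffold_overlap("Cc1ccccc1", "CCc1ccccc1")
  expect_identical(ov$overlap, 1L)
  expect_identical(ov$shared, murcko_scaffold("c1ccccc1"))
  # disjoint ring systems
  ov2 <- scaffold_overlap("Cc1ccccc1", "CC1CCCC1")
  expect_identical(ov2$overlap, 0L)
  # identical sets share every distinct scaffold
  setx <- c("Cc1ccccc1", "CCc1ccncc1", "C1CCCCC1")
  ov3 <- scaffold_overlap(setx, setx)
  expect_identical(ov3$overlap, ov3$n_generated)
})

test_that("signature NN search equals an exhaustive scan", {
  set.seed(14)
  lib <- matrix(rnorm(200 * 10), 200)
  q <- lib[37, ]
  hit <- signature_nn_search(q, lib, "euclidean")
  expect_identical(hit$index, 37L)
  expect_equal(hit$distance, 0, tolerance = 1e-12)
  q2 <- rnorm(10)
  for (m in c("euclidean", "cosine")) {
    hit2 <- signature_nn_search(q2, lib, m)
    brute <- if (m == "euclidean") {
      apply(lib, 1L, function(r) sqrt(sum((r - q2)^2)))
    } else {
      apply(lib, 1L, function(r)
        1 - sum(r * q2) / sqrt(sum(r^2) * sum(q2^2)))
    }
    expect_identical(hit2$index, which.min(brute))
    expect_equal(hit2$distance, min(brute), tolerance = 1e-12)
  }
  # cosine is scale-invariant, euclidean is not: q = 2v is collinear with
  # v but euclidean-closer to w
  v <- c(1, 0, 0); w <- c(1.8, 0.3, 0)
  lib3 <- rbind(v, w)
  expect_identical(signature_nn_search(2 * v, lib3, "cosine")$index, 1L)
  expect_identical(signature_nn_search(2 * v, lib3, "euclidean")$index, 2L)
  expect_error(signature_nn_search(q2[1:3], lib),
               class = "gexmol_shape_error")
})

test_that("classification-score comparison reduces to the rank test", {
  gan <- gan_init(toy_gan_config(), seed = 6)
  X <- matrix(runif(6 * 16, -1, 1), 6)
  C <- matrix(rnorm(6 * 6), 6)
  same <- classification_score_compare(X, C, X, C, gan)
  expect_equal(same$p_value, 0.5, tolerance = 0.1)
  # direct U closed form on constant score sets: all 9 pairs won
  wt <- suppressWarnings(stats::wilcox.test(c(.9, .9, .9), c(.1, .1, .1),
                                            alternative = "greater"))
  expect_identical(unname(wt$statistic), 9)
  expect_error(classification_score_compare(X[0, ], C[0, ], X, C, gan),
               class = "gexmol_config_error")
})

test_that("generation reports keep the count chain ordered", {
  tr <- toy_translator()
  L <- tr$config$latent_dim
  cfg <- toy_gan_config(n_genes = 5L, latent_dim = L)
  X <- predict(tr, make_corpus(40, "small", seed = 51))
  set.seed(5)
  C <- matrix(rnorm(40 * 5), 40)
  fit <- train_gan(X, C, cfg,
                   gan_schedule(epochs = 2L, steps_per_epoch = 5L,
                                batch_size = 16L, learning_rate = 1e-3,
                                monitor_n = 30L),
                   stages = 2L, seed = 5)
  rep1 <- suppressMessages(
    generate_for_signature(C[1, ], n = 25L, fit, tr, seed = 8))
  expect_gte(rep1$generated, rep1$decoded)
  expect_gte(rep1$decoded, rep1$valid)
  expect_gte(rep1$valid, rep1$unique_valid)
  expect_gte(rep1$unique_valid, 0L)
  expect_lte(rep1$synthesizable, rep1$valid)
  rep2 <- suppressMessages(
    generate_for_signature(C[1, ], n = 25L, fit, tr, seed = 8))
  expect_identical(rep1$smiles, rep2$smiles)
})

test_that("SA filtering keeps easy molecules and tolerates bad input", {
  expect_identical(sa_filter(character(0)), character(0))
  expect_true("CCO" %in% sa_filter(c("CCO", "CC(C)Cc1ccc(C)cc1")))
  expect_identical(suppressMessages(sa_filter(c("CCO", "C("))), "CCO")
})

test_that("scaffold optimization is deterministic and validates input", {
  tr <- toy_translator()
  cfg <- toy_gan_config(n_genes = 4L, latent_dim = tr$config$latent_dim)
  gan <- gan_init(cfg, seed = 3)
  fit <- structure(list(params = gan, config = cfg, stages = 2L,
                        schedule = NULL, history = NULL),
                   class = "gexmol_gan")
  sig <- rnorm(4)
  o1 <- optimize_scaffold("c1ccccc1", sig, fit, tr)
  o2 <- optimize_scaffold("c1ccccc1", sig, fit, tr)
  expect_identical(as.character(o1), as.character(o2))
  expect_error(optimize_scaffold("C(", sig, fit, tr),
               class = "gexmol_parse_error")
})
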