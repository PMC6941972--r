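# Shared fixtures. Expensive objects (grammar, corpora, trained toy
# models, study runs) are built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

test_grammar <- function() fixture("grammar", build_grammar())

# a tiny fixed molecule set that exercises chains, branches, rings,
# aromatics, bracket atoms and double bonds
tiny_molecules <- function() {
  c("C", "CCO", "CC(C)O", "CC(=O)O", "c1ccccc1", "Cc1ccccc1",
    "c1ccncc1", "C1CCCCC1", "CC(C)Cc1ccc(C)cc1", "O=C(O)c1ccccc1",
    "[NH4+]", "CN1CCC1", "c1cc[nH]c1", "CCOC(=O)C", "N#CCO")
}

# toy translator trained on a 60-molecule corpus (fast, good enough for
# plumbing tests that need a fitted model)
toy_translator <- function() {
  fixture("toy_translator", {
    corp <- make_corpus(60, "small", seed = 41)
    suppressMessages(train_translator(
      corp,
      config = translator_config(latent_dim = 16L, epochs = 8L,
                                 batch_size = 16L, learning_rate = 2e-3),
      seed = 41))
  })
}

toy_gan_config <- function(n_genes = 6L, latent_dim = 16L) {
  gan_config(n_genes = n_genes, latent_dim = latent_dim, noise_dim = 8L,
             cond_widths = c(16L, 8L), noise_widths = c(16L, 8L),
             merge_hidden = 16L, critic_widths = c(16L, 16L, 16L),
             fm_widths = c(16L, 16L), fg_widths = c(16L, 16L),
             compare_width = 16L)
}

# zero every trainable weight of a net / nested net structure (leaves
# structural constants like eps, momentum and slopes untouched)
zero_params <- function(x) {
  fields <- c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2")
  walk <- function(node) {
    if (is.list(node) && !is.null(node$kind)) {
      for (f in intersect(fields, names(node))) node[[f]] <- node[[f]] * 0
      node
    } else if (is.list(node)) {
      lapply(node, walk)
    } else node
  }
  walk(x)
}

# a 2-op critic whose score is the fixed linear map w . x
linear_critic_gan <- function(w, latent_dim = length(w)) {
  cfg <- toy_gan_config(latent_dim = latent_dim)
  gan <- gan_init(cfg, seed = 1)
  gan$nets$d0 <- list(list(kind = "dense",
                           W = matrix(w, latent_dim, 1L), b = 0))
  gan$nets$d1 <- gan$nets$d0
  gan
}

# cached acceptance studies (shared between the criterion blocks that
# measure different properties of the same experiment): one fixed world
# and translator, repeated stochastic GAN trainings
recovery_base <- function() {
  fixture("recovery_base", suppressMessages(recovery_world()))
}

recovery_study <- function(seed) {
  key <- paste0("recovery", seed)
  fixture(key, suppressMessages(
    conditional_recovery_study(seed = seed, base = recovery_base())))
}

reconstruction_study <- function(seed = 1L) {
  key <- paste0("reconstruction", seed)
  fixture(key, suppressMessages(translator_reconstruction_study(seed = seed)))
}
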