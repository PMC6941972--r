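# gexmol

Conditional molecular generation from gene-expression signatures, in R.

## What problem this solves

Phenotypic drug discovery often starts from a transcriptomic readout: a
desired expression change (for instance, the signature induced by CRISPR
knock-out of a target) with no chemical matter attached. `gexmol`
implements a generative pipeline that proposes small molecules expected
to induce a given landmark-gene signature, together with the evaluation
machinery needed to judge the proposals (validity, uniqueness,
synthesizability, fingerprint/fragment similarity to known actives,
scaffold analysis, and a similarity-search baseline). It is aimed at
computational chemists and bioinformaticians who want a fully inspectable
implementation of this model class — every network, loss and training
loop is plain R matrix code with finite-difference-tested gradients —
plus a synthetic benchmark that makes the whole pipeline trainable and
testable on one CPU in minutes.

## The model

Three components are chained:

1. **Grammar SMILES codec.** A context-free grammar over SMILES ships as
   data; a molecule is the rule-index sequence of its leftmost
   derivation. Decoding is stack-masked: at each step, only productions
   whose left-hand side matches the top of the derivation stack are
   eligible, so every decoded sequence is grammatically well formed.
2. **GRU translator.** An encoder GRU reads SMILES characters into a
   latent vector *x* ∈ [−1, 1]^L (tanh of the final cell state); a
   decoder GRU (dropout 0.2, softmax head over rules) maps latents back
   to molecules. Trained by teacher forcing.
3. **Stacked conditional WGAN-GP.** With signature *c*, noise *z*:

   - stage I: x̂ = G₀(z, c); stage II refines via residual blocks,
     x̂′ = G₁(x̂, c);
   - critics D₀, D₁ score latents, trained with the Wasserstein loss
     plus gradient penalty
     L_D = E[−D(x)] + E[D(G(·))] + λ E[(‖∇ₓ̂ D(x̂)‖₂ − 1)²], λ = 10;
   - matching networks f₀, f₁ (SubMult+NN comparison) score
     latent/signature compatibility and steer the generators:
     L_G = E[−D(G(·)) − α log f(G(·), c)], α = 10.

   Training: RMSprop, critics every step, generators every tenth step,
   with per-epoch Fréchet-distance monitoring
   d² = ‖μ_g − μ_r‖² + Tr(C_g + C_r − 2(C_g C_r)^{1/2}).

Because real training corpora (L1000 signatures, million-molecule SMILES
libraries) are far beyond desk scale, the package includes a synthetic
world: molecules map to signatures through five structural descriptors
plus Gaussian noise, and held-out "knock-out" queries are built from
descriptor targets that match no training molecule. Conditioning quality
is then measurable: compare the descriptors of generated molecules with
the query's target profile.

## Worked example

```r
library(gexmol)

# 1. synthetic world: 300 molecules, 64 genes, paired signatures + queries
corpus <- make_corpus(300, "medium", seed = 7)
world  <- synthetic_world(corpus, n_genes = 64, noise_sd = 0.1, seed = 7)
ds     <- make_paired_dataset(world, seed = 7, n_query = 5)

# 2. molecular latent space
tr <- train_translator(corpus,
        config = translator_config(latent_dim = 32, epochs = 60),
        seed = 7)
print(tr)
#> SMILES grammar translator (GRU, latent dim 32)
#>   trained on 298 molecules, 60 epochs; final CE loss 0.2689
#>   teacher-forced token accuracy 0.908 (T = 61 rules)

# 3. conditional WGAN-GP on (latent, signature) pairs
fit <- train_gan(predict(tr, ds$smiles), ds$signatures,
                 config   = gan_config_desk(n_genes = 64, latent_dim = 32),
                 schedule = gan_schedule(epochs = 120, steps_per_epoch = 25,
                                         batch_size = 64,
                                         learning_rate = 1e-3,
                                         monitor_n = 200),
                 stages = 2, seed = 7)
print(fit)
#> conditional WGAN-GP fit (stages I + II)
#>   120 epochs x 25 steps, batch 64, RMSprop lr 0.001
#>   Frechet distance (stage I): 27.6706 (epoch 1) -> 9.0766 (final)
#>   Frechet distance (stage II): 33.3535 -> 19.1231
plot(fit)   # monitoring curves

# 4. generate candidates for a held-out knock-out-like query signature
rep1 <- generate_for_signature(ds$query_signatures[1, ], n = 100,
                               fit, tr, stage = 1, seed = 1)
print(rep1)
#> generation report: 100 generated, 100 decoded, 6 valid (6.0%), 4 unique, 4 with SA < 4.5
head(na.omit(unique(rep1$canonical)), 3)
#> [1] "CC1=C(O)O1"   "CC1=C(CO)OC1" "CC1=CC=C1"

# what the query asked for, and what generation delivered on average
rbind(target = ds$query_targets[1, ],
      generated = colMeans(descriptor_vector(na.omit(rep1$smiles))))
#>           heavy_atoms aromatic_atoms     rings heteroatoms branch_points
#> target       8.052566       5.601961 0.6457552    2.190414      1.056835
#> generated    6.100000       2.960000 0.9800000    2.390000      1.840000

# 5. classical similarity search baseline for the same query
nn <- signature_nn_search(ds$query_signatures[1, ], ds$signatures, "cosine")
ds$smiles[nn$index]
#> [1] "COc1ccncc1"

similarity("CCO", "CCN", "maccs")
#>   query reference metric     value
#> 1   CCO       CCN  maccs 0.3571429
```

The generation report chain (`generated >= decoded >= valid >=
unique_valid`) mirrors the bookkeeping used when this model family is
evaluated at scale: every decoded string is grammatically well formed by
construction, but only a single-digit percentage survives chemical
sanitization at this deliberately small training budget — the same order
as validity rates reported for grammar-constrained generators at full
scale. The mean descriptors of the generated set track the query's
heteroatom target and sit below its size/aromaticity target; the
reference study in `conditional_recovery_study()` (500 molecules, longer
training, the package's calibrated noise scales) quantifies exactly this
conditioning fidelity against the retrieval baseline.

Similarity and scaffold utilities for comparing generated molecules with
known actives:

```r
similarity("CCO", "CCN", "maccs")          # Tanimoto on MACCS keys
max_similarity_to_set("CCO", corpus, "morgan")   # closest known active
scaffold_overlap(rep1$canonical[!is.na(rep1$canonical)], corpus,
                 generic = TRUE)
optimize_scaffold("c1ccccc1", ds$query_signatures[1, ], fit, tr)
```

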