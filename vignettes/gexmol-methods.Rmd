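---
title: "Generating molecules from expression signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating molecules from expression signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gexmol generates candidate small molecules conditioned on a transcriptomic
signature: given the differential expression of landmark genes observed
after perturbing a target (for instance a CRISPR knock-out), it proposes
molecules whose induced signature should resemble it. This vignette
explains the three models involved, the choices made where the design was
genuinely open, what the synthetic benchmark does and does not show, and
the numerical details a user may need to trust or modify the code.

## The molecular latent space

Molecules enter the system as canonical SMILES strings. Two
representations are used:

* **Grammar rule sequences.** A context-free grammar over SMILES is
  shipped as data (`build_grammar()`, serialized one production per line
  under `inst/extdata/`). A molecule is the sequence of production-rule
  indices of its leftmost derivation (`smiles_to_rules()`), padded with
  the dedicated `Nothing -> None` rule. Decoding replays the derivation
  with a symbol stack, and `masked_decode()` restricts every decoding step
  to the rules whose left-hand side matches the stack top, so *any*
  logit matrix decodes to a grammatically well-formed string. Grammatical
  does not mean chemically valid: valence and kekulization are checked
  separately by the RDKit bridge (`chem_is_valid()`).

  The shipped grammar is a compact SMILES CFG (organic subset, bracket
  atoms, single-digit ring bonds, branches). Atom-class annotations are
  omitted; stereochemistry and isotopes are stripped before parsing
  (`strip_stereo()`), since conditioning on transcriptional response does
  not resolve stereochemistry at this level. The parser is a hand-written
  Earley chart parser because the grammar is left-recursive and R has no
  CFG parsing infrastructure; derivation extraction breaks ambiguities
  deterministically (lowest rule index, then shortest leftmost span).

* **Continuous latents.** A single-GRU encoder reads the character
  one-hots of the SMILES; the final cell state is the molecular latent
  (dimension `latent_dim`, 256 at publication scale, 48 in the
  desk-scale studies). A single-GRU decoder emits per-step rule
  probabilities (dropout 0.2, dense softmax head) and is trained by
  teacher forcing with RMSprop (`train_translator()`).

Three decisions here were open and deserve their rationale:

1. **Latent bounding.** The GAN generators end in tanh, so generated
   latents live in $(-1,1)^L$, and real and generated latents must share
   support. The GRU update $h' = (1-z)\odot\tilde h + z\odot h$ with
   $\tilde h = \tanh(\cdot)$ already confines the encoder state to
   $(-1,1)$ by induction from $h_0 = 0$, so the state itself is the
   latent. An additional tanh squashing (the other obvious choice) is
   not merely redundant: it compresses the real latents into
   $[-\tanh 1, \tanh 1] \approx [-0.76, 0.76]$ while generated latents
   can reach $\pm 1$, creating a region of generated-only latent space
   that the decoder has never seen — measurably degrading decoded
   molecules near the boundary.
2. **Decoder conditioning.** The latent initializes the decoder state
   *and* is concatenated to the decoder input at every step. With
   initial-state conditioning alone, free-running decoding (generation
   mode, no teacher forcing) degraded sharply after a few steps because
   nothing re-anchors the state to the molecule; per-step conditioning
   removed that failure mode while leaving teacher-forced training
   unchanged in form.
3. **Denoising regularization.** During training, Gaussian noise
   (`latent_noise`, default sd 0.05) is added to the latent before
   decoding. GAN-generated latents are near, but not on, the encoder
   manifold; a decoder trained only on exact encodings treats such points
   as out-of-distribution and decodes erratically. Training on perturbed
   latents makes decoding a locally smooth function of the latent, which
   is precisely the property generation relies on.

The cross-entropy is averaged over non-padding positions only: once the
derivation stack empties, decoder output is never consulted, so training
it to predict padding would only dilute the gradient. At initialization
the per-token loss is therefore $\log R$ for $R$ rules (a tested sanity
bound). Free-running decoding runs up to twice the training sequence
length before flagging truncation.

## The stacked conditional WGAN-GP

Generation is a two-stage conditional Wasserstein GAN with gradient
penalty, trained on pairs of molecular latents $x$ and signatures $c$.

Stage I draws $z \sim N(0, I_Z)$ and computes $G_0(z, c)$: signature and
noise pass through separate two-layer MLPs ([512, 256] at paper scale,
LeakyReLU + batch norm), are concatenated, and merged by a further MLP
whose output layer is tanh. Stage II refines: $G_1(s_0, c)$ processes the
signature the same way, concatenates it with $s_0 = G_0(z,c)$, applies
$n = 2$ residual blocks $x \mapsto x + W_2\,\mathrm{act}(W_1 x + b_1) +
b_2$, and projects back to the latent dimension through tanh. Critics
$D_0, D_1$ are [256, 256, 256, 1] MLPs (LeakyReLU, dropout 0.4 between
the later layers, no sigmoid). The critic loss is

$$\mathcal{L}_D = \mathbb{E}[-D(x)] + \mathbb{E}[D(G(\cdot))] +
\lambda\, \mathbb{E}\big[(\lVert \nabla_{\hat x} D(\hat x)\rVert_2 -
1)^2\big],$$

with $\hat x$ uniform on segments between paired real and generated
latents and $\lambda = 10$. The generator loss adds a conditional term,

$$\mathcal{L}_G = \mathbb{E}\big[-D(G(\cdot)) - \alpha \log
f(G(\cdot), c)\big], \qquad \alpha = 10,$$

where $f$ is a matching network scoring whether a latent belongs to a
signature: branch MLPs embed molecule and signature, the embeddings are
compared by SubMult+NN (elementwise squared difference and product,
concatenated through a LeakyReLU layer) and a sigmoid head.

Open points resolved here, and how:

* **Training $f$.** $f_0$ and $f_1$ are separate networks of identical
  architecture, trained jointly with the critics (every critic step) by
  binary cross-entropy: observed pairs are positives, within-batch
  shuffled pairings negatives. This mirrors matching-aware conditional
  GAN practice; nothing else in the system supervises $f$.
* **Numerical safety.** $f$'s output is clamped to
  $[10^{-7}, 1 - 10^{-7}]$ before the log.
* **LeakyReLU slope** 0.2 everywhere; batch norm uses batch statistics
  in training and running averages (momentum 0.9) at inference, and
  appears only in the generators.
* **Stage coupling.** Both stages train in the same loop; the stage-II
  generator receives $s_0$ as data (no gradient flows back into $G_0$
  from stage II).

All forward and backward passes are hand-written batched matrix
arithmetic; there is no autodiff framework underneath. The gradient of
the penalty term with respect to critic weights needs second-order
information, which for a piecewise-linear critic (dense, LeakyReLU,
dropout) reduces to a forward-tangent pass through the linearized network
followed by reverse accumulation — the activation pattern has zero
derivative almost everywhere, so no true second derivatives arise. Every
backward path, including this one, is verified against finite differences
in the test suite.

Training (`train_gan()`) follows the published protocol shape: critics
and matching networks update every step, generators every tenth step, all
under RMSprop at one learning rate (5e-5 at paper scale over 1000 epochs
of 125 steps at batch 256). At the end of each epoch, one latent is
generated per (subsampled) training signature, and the squared Fréchet
distance

$$d^2 = \lVert \mu_g - \mu_r \rVert^2 +
\mathrm{Tr}\big(C_g + C_r - 2 (C_g C_r)^{1/2}\big)$$

between generated and real latent moments is recorded. The matrix square
root uses the eigendecomposition of the symmetrized similarity transform
$C_a^{1/2} C_b C_a^{1/2}$ with negative eigenvalues clipped at zero
(tolerance 1e-6); this keeps the computed distance symmetric to better
than 1e-8 and nonnegative.

`train_gan()` accepts a `latent_jitter`: fresh Gaussian noise added to
each real latent batch (instance noise). At desk scale the real latents
are a few hundred points in a 30-50-dimensional space — a measure-zero
target that a Wasserstein critic can separate from any generated cloud,
leaving the generator stranded off-manifold where the decoder mistreats
its output. Jittering thickens the real distribution into a
full-dimensional one the generator can actually match; setting the
translator's `latent_noise` to the same scale makes the decoder
competent exactly on that thickened manifold. The two knobs are two
halves of one decision and are both set to 0.15 in the desk-scale
study (larger values blur conditioning toward the corpus prior of small
molecules; smaller ones strand the generator off-manifold again).

A single user seed fans out to per-component seeds (initialization,
shuffling, noise, dropout) through a fixed mixing function, so a fit is
bitwise reproducible on one machine while components stay decoupled.

## The synthetic benchmark

Real training data for this model class are L1000 consensus signatures
paired with treatment compounds — far beyond desk scale. The package
therefore ships a simulator whose structure, not its biology, matches
that setting:

* a corpus of small molecules (`make_corpus()`: seeded enumeration of
  valence-correct C/N/O trees with occasional carbonyls, plus substituted
  five- and six-membered (hetero)aromatic and alicyclic rings,
  canonicalized and de-duplicated);
* a descriptor map $d(\text{mol})$: heavy atoms, aromatic atoms, rings,
  heteroatoms, branch points — computed by a lenient built-in SMILES
  graph reader so that even chemically invalid decoder output has
  descriptors;
* signatures $= \mathrm{standardize}(A\, d(\text{mol}) + \varepsilon)$
  with a fixed random gene-by-descriptor loading matrix $A$ and
  $\varepsilon \sim N(0, \sigma^2 I)$, standardized per gene against the
  corpus (mimicking z-scored consensus signatures);
* query signatures built from *target descriptor profiles with no paired
  molecule* (jittered midpoints of corpus descriptor pairs, kept at
  Euclidean distance at least 0.5 from every corpus molecule), mimicking
  knock-out conditions.

Because signatures depend on the molecule only through descriptors,
condition fulfilment is falsifiable: decode what the GAN generates for a
query and compare descriptors with the query's target. A ridge regression
from signatures to descriptors achieves $R^2 \ge 0.9$ at the default
noise (sd 0.1), so the conditioning task is learnable by construction.

Desk-scale defaults are 64 genes, 5 descriptors and 200–500 molecules;
paper-scale dimensions (978 genes) are a configuration change. What
passing desk-scale tests shows is that the machinery — grammar codec,
latent space, conditional WGAN-GP, evaluation stack — is implemented
correctly and that conditioning information measurably flows from
signature to generated structure. What it does not show is chemical or
biological realism: the simulator has no transcriptomic covariance
structure, no cell-line or dose effects, and a five-dimensional,
noiseless-by-construction structure-response link far simpler than
biology.

## The reference experiments

`translator_reconstruction_study()` (200 molecules, 50 epochs) reports
teacher-forced token accuracy (expected ≥ 0.9) and the exact free-running
round-trip rate. The conditional recovery experiment fixes one world —
`recovery_world()` builds the corpus (500 molecules), the signature map
(64 genes, noise 0.1), 20 queries and the translator (latent 48, decoder
width 96, 120 epochs) under one world seed — and
`conditional_recovery_study()` then trains the stage-I conditional
WGAN-GP (300 epochs of 50 steps, batch 64, instance noise 0.15) under a
separate training seed and generates 100 molecules per query. It
reports:

* **Spearman recovery** — for each descriptor, the Spearman correlation
  across queries between the target value and the mean descriptor of the
  generated molecules, averaged over descriptors. Correlating across
  queries (20 points per descriptor) rather than within a query (5
  points) is the statistically meaningful direction; a per-query rank
  correlation over five descriptor values would be dominated by ties and
  scale differences.
* **Baseline comparison** — per query, the root-mean-square descriptor
  error (descriptors standardized by corpus spread) of the generated mean
  against the error of the nearest-neighbour answer: the corpus molecule
  whose *signature* is closest (cosine distance) to the query. This
  baseline is strong: with a near-noiseless linear signature map it
  essentially retrieves the best single corpus molecule. The generative
  model can beat it because queries are deliberately placed between
  molecules — a mean over a generated *mixture* reaches fractional
  descriptor targets no single molecule can.
* **Monitoring sanity** — the stage-I Fréchet distance at the final epoch
  against epoch 1.

Both studies are deliberately sized for a single CPU (about a minute for
the reconstruction study; a few minutes per component of the recovery
experiment); the same functions scale up by argument. GAN training is
stochastic, so the package's reference check repeats the stage-I
training under three seeds on the one fixed world and requires a
majority to pass rather than every seed. On that world the generative
route beats the retrieval baseline on a little over half to two-thirds
of queries depending on the training seed — the baseline is genuinely
strong on the subset of queries that land near a corpus molecule (the
disjointness margin is expressed in raw descriptor counts, which leaves
some queries within a fraction of a standard deviation of a stored
answer), and the generative margin comes from the remaining queries,
where mixtures reach fractional descriptor targets no single molecule
can.

## Evaluation utilities

Validity is RDKit sanitization of the decoded SMILES; uniqueness is
de-duplication of canonical SMILES among the valid; synthesizability is
an Ertl–Schuffenhauer SA score below 4.5. Similarity offers Tanimoto over
MACCS keys or Morgan fingerprints (radius 3, 1024 bits) and Fraggle
similarity; scaffold analysis uses Murcko frameworks, optionally generic
(all atoms carbon, all bonds single). These are standard toolkit
operations and are delegated to RDKit through a batched subprocess bridge
(`inst/python/chem_bridge.py`, JSON over stdin/stdout) — R has no
implementation of MACCS, Fraggle, SA scores or Murcko scaffolds, and
re-deriving them would add nothing. The conditional classification-score
comparison uses the stage-I matching network by default (it is the score
conditioned generation optimizes first) and a one-sided Mann–Whitney U
test via `stats::wilcox.test` (exact for small untied samples, normal
approximation with continuity and tie corrections otherwise); the test
suite checks it against exhaustive pair-counting enumeration.

## Known limitations

* Chemical validity of decoded molecules is not guaranteed (only
  grammatical consistency is); validity rates at desk scale are reported,
  not optimized.
* The decoder's robustness to off-manifold latents is obtained by
  denoising regularization, not by any guarantee; strongly conditioned
  queries far outside the corpus descriptor range will decode poorly.
* The simulator's structure-response link is linear in five descriptors;
  none of the results here certify behaviour on real transcriptomic
  data.
* Training is single-threaded R; paper-scale dimensions are expressible
  but not practical in this implementation.
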