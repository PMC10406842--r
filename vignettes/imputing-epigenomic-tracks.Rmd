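---
title: "Imputing epigenomic tracks with factorized self-attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing epigenomic tracks with factorized self-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Consortium epigenome maps are incomplete: of all (cell type, assay)
combinations one could measure — histone-mark ChIP-seq, DNase-seq — only a
fraction has been assayed. Representing the data as a third-order tensor
$\mathcal{Y}_{ijk}$ (cell type $i$, assay $j$, 25 bp genomic bin $k$) of
arcsinh-transformed average $-\log_{10}$ p-value signal, imputation means
completing the missing tracks $\mathcal{Y}_{ij\cdot}$ from the observed
ones. `edice` implements a local, attention-based completion model plus the
surrounding machinery: baselines, peak-based evaluation metrics, replicate
simulation, a transfer protocol for individual-specific prediction, and a
synthetic generator that makes all of it testable at desk scale.

## Model

The key observation is that for a missing track the most informative signal
is the *other tracks at the same genomic position*. Let $Y^k$ be the
$n_c \times n_a$ slice of signal at bin $k$, with unobserved (or masked)
entries set to zero. The model predicts

$$\hat{Y}^k_{ij} = g_\theta\!\left(c_i(\tilde{Y}^k),\; a_j(\tilde{Y}^k)\right),$$

a factorized regression: a *cell encoder* and an *assay encoder* each embed
their entities' local signal vectors and contextualize them with one
transformer-style self-attention block, and a shared MLP decoder maps each
(cell, assay) embedding pair to a scalar.

Per encoder, entity $i$'s visible-zeroed signal vector $y_i$ passes through
a shared affine map with ReLU, is scaled by $1/n_{obs,i}$ (its number of
visible entries, analogous to dropout's activation scaling, so cells with
sparse coverage are comparable to well-mapped ones), and a learned global
embedding $u_i$ is added — the analogue of a position embedding:

$$h_i = \tfrac{1}{n_{obs,i}}\,\mathrm{ReLU}(W y_i + b) + u_i.$$

The self-attention block is a standard transformer layer (multi-head scaled
dot-product attention, residual, position-wise feed-forward, residual) with
layer normalisation removed — it adds nothing in a single-block network.
Training minimises the mean squared reconstruction error of randomly masked
observed tracks, one fresh mask per bin per epoch, with Adam.

Conventions this implementation had to fix where the architecture
description is silent:

* **$n_{obs}$ counts visible entries** (observed *and* unmasked): masked
  entries are zeroed exactly like missing ones, and the dropout analogy
  implies rescaling by the surviving count.
* **$n_{obs} = 0$**: the scaled signal term is defined as zero, so a fully
  masked entity falls back to its global embedding $u$.
* **Scaling order**: the $1/n_{obs}$ factor multiplies the ReLU activations
  of the signal embedding, before $u$ is added.
* **Residual wiring**: post-residual placement, no normalisation anywhere.
* **Head widths**: the concatenated heads are linearly projected back to
  the embedding width before the residual; the block's feed-forward output
  width must equal the embedding width (enforced at configuration).
* **Initialisation**: uniform fan-in weights, zero biases, small Gaussian
  global embeddings, all under a caller-supplied seed.
* **Precision**: R computes in double precision; oracle comparisons use a
  1e-6 relative tolerance, chosen so they would also hold in 32-bit floats.

## Default parameters

`model_config()` defaults to the full-scale architecture: 256-dimensional
embeddings, 4 heads, a 128→256 feed-forward inside the attention block, a
decoder with two 2048-unit ReLU layers, dropout 0.3 on decoder hidden
layers. `train_config()` defaults to the full-scale regime: mask 120 tracks
per bin, 50 epochs of Adam at 3e-4; the transfer protocol pretrains 30
epochs and fine-tunes 15 at 3e-5 with tissue-wise masking (all observed
tracks of one random cell type per bin).

The test suite and benchmarks use a *desk-scale* configuration — embedding
width 32, 4 heads, 32-unit attention feed-forward, 2×128 decoder, dropout
0.05, Adam 2e-3 (fine-tuning at one tenth of that, keeping the same
pretrain/fine-tune ratio), 24 masked tracks out of ~60 observed, 5000 (recovery) or 3000
(transfer) training bins — because the full-size model on consortium data
is far outside a test budget. These are model choices, tuned for the small
synthetic world; the package applies the full-scale defaults when you do not
override them.

## What the synthetic generator emulates

`generate_tensor()` produces a world with the structure the model exploits:

* a low-rank background, `softplus(<z_i, w_j>)` from latent cell and assay
  factors, modulated by a smooth positive per-bin process with mean 1;
* peaks planted per assay at shared loci (Poisson-distributed, ~1 per
  10 kb) with Gaussian shapes (~300 bp) and *cell-specific amplitudes*
  driven by the cell latents — so a cell's amplitude profile is predictable
  from its other assays, which is exactly the leverage the encoders have
  over the cross-cell AVG baseline;
* truncated-Gaussian measurement noise (sd 0.2 on the measurement scale);
* a partial observation mask: 5 core assays everywhere, 50% coverage
  elsewhere, mirroring the structure of real consortium compendia.

The noise level was chosen once, before any model benchmarking, from the
generator's own noise ceiling: at sd 0.2 the correlation between a track's
clean and noisy versions — the score of a *perfect* imputation — is ≈0.89,
comparable to replicate-level concordance of real signal tracks. (At sd
0.5 the ceiling is ≈0.65, which would contradict the benchmark this package
must meet; the ceiling is a property of the generator alone.)

What the generator does **not** emulate: assay-specific marginal
distributions (broad vs punctate marks), spatial autocorrelation of noise,
mappability artefacts, and copy-number effects. A green synthetic benchmark
therefore establishes that the implementation learns the factorized
structure it claims to learn — not that it would match performance on real
consortium data.

`generate_individual_pair()` builds the transfer scenario: two individuals
share the latent structure and peak blueprint; 30% of peaks (at
`individual_effect = 0.3`) are toggled, half deleted from the target
individual B (A-only) and half deleted from the training individual A
(B-only). B-only peaks are recorded as ground-truth individual-specific
regions; every planted peak spans ≥150 bp so none falls to the
minimum-length filter.

## Evaluation layer

Enrichment detection is a deliberate simplification of MACS2: each bin's
inverse-arcsinh signal, rounded to an integer, is treated as a count and
tested against a background rate λ with a one-sided upper-tail Poisson
test; Benjamini–Hochberg adjustment across all bins of the track; adjusted
p ≤ 0.01 bins merged into peaks when contiguous (no gap tolerance). λ
defaults to the track's per-chromosome mean for determinism; a MACS2-style
local mode (max of the global mean and 1/5/10 kb window means) is
available. Absolute peak counts will not match MACS2 — fragment-length
modelling, duplicate handling and dynamic λ are out of scope — but the
bin-level foreground/background partition behaves analogously.

Metrics follow standard definitions on the arcsinh scale: MSE and Pearson
genome-wide and stratified by the observed track's enriched bins; AUPRC of
imputed signal against the enriched-bin indicator (average precision with
tied scores grouped); peakset precision/recall at 25 bp bin resolution.
Pearson over a stratum with fewer than two bins or zero variance is
reported missing rather than zero. For individual-specific scoring, target
peaks overlapping (≥1 bp) any training-individual peak are excluded as
conserved, target-only peaks under 150 bp (one nucleosome) are excluded as
spurious, the rest are positives, and AUPRC is computed over the remaining
bins alongside the positive-fraction baseline.

## Replicate simulation

Imputations are mean tracks; differential analyses need replicates.
`estimate_nb()` fits a per-region negative binomial by the method of
moments from observed replicates ($\hat\mu$ = sample mean, size
$r = \mu^2/(\widehat{var}-\hat\mu)$, Poisson when the variance does not
exceed the mean). Because $\hat\mu^2$ overestimates $\mu^2$ by
$var/n$ — a ~25% median inflation of $r$ at 4 replicates — the default
substitutes the unbiased moment $\hat\mu^2 - \widehat{var}/n$;
`correct_bias = FALSE` restores the plain plug-in. `simulate_replicates()`
then draws seeded NB counts around the region-aggregated inverse-arcsinh
imputed mean (the signal→count bridge is
round-to-integer, a documented simplification). `wasserstein_peak_distance()` compares
normalized peak shapes via the 1-D Wasserstein-1 distance (integrated
absolute CDF difference, in bp), and `export_affinity_matrix()` writes the
regions × replicates count matrix that external differential tools consume.

## Numerical and degenerate-input choices

* Masking-by-zero is a hard contract: slice values must be zero wherever
  invisible, enforced by the `signal_slice()` validator; the attention
  softmax is stabilised by row-max subtraction with deterministic
  tie-breaking (no RNG is consumed outside sampling and dropout).
* All randomness — bin sampling, masks, dropout, initialisation,
  simulation — flows from explicit integer seeds; a fixed seed and thread
  count give bit-identical checkpoints, imputations and reports.
* Gradients are hand-derived reverse-mode and verified against central
  finite differences in the test suite; training aborts on a non-finite
  loss.
* An all-zero track yields an empty peak set (not an error); an empty
  predicted peak set has undefined precision and recall 0; the Wasserstein
  distance rejects all-zero shapes (no normalisable mass).
* Imputed tracks may undershoot zero on the arcsinh scale; the CLI clamps
  exports at zero since $-\log_{10}$ p signal is nonnegative, while the
  in-memory API returns raw predictions.
* Track splits guarantee every cell type and assay at least one training
  track (both encoders always have context); when the forced training set
  crowds out the requested validation/test fractions, those counts shrink
  proportionally rather than failing.
* The tensor store is a versioned single-file serialisation with the same
  layout keys an HDF5 store would use (`values`, `observed`, `binning`,
  `tracks`) and a bit-exact round-trip contract; no R HDF5 bindings are
  assumed on the host.

## Known limitations

* Pure-R training: practical for desk-scale tensors (minutes for 10⁵
  bin-updates), not for genome-wide consortium runs.
* The factorization baseline is single-resolution and exists for synthetic
  benchmarking, not as a faithful reimplementation of multi-scale models.
* The peak caller is a simplification (above); peak *counts* are not
  comparable with MACS2 output.
* Whether fine-tuning should update all parameters or freeze the encoders
  is a genuinely open choice; the default updates everything, which worked
  better in the synthetic transfer benchmark.
* Variance estimation details for the replicate model live in supplementary
  material not available here; the method-of-moments estimator is a
  documented, replaceable stand-in.
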