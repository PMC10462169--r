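---
title: "Methods: stochastic latent-space generation and screening in sgnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic latent-space generation and screening in sgnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgnc)
```

## The generative model

`sgnc` generates candidate molecules by integrating a Langevin equation in
the latent space of a molecular encoder,

$$\frac{dX}{dt} = \alpha \sum_k a_k (X_k - X) + \xi(t),
\qquad \sum_k a_k = 1,\ a_k > 0,$$

with $X_k$ the latent vectors of chosen reference inhibitors and $\xi$ a
small noise process. Because the weights are normalized, the deterministic
part is a linear pull toward the weighted centroid $m = \sum_k a_k X_k$,
and the process is an Ornstein--Uhlenbeck (OU) relaxation: without noise
$X(t) = m + (X(0) - m)e^{-\alpha t}$, and with Gaussian white noise of
amplitude $\sigma$ the stationary distribution has mean $m$ and
per-coordinate variance $\sigma^2 / (2\alpha)$. Both closed forms are used
as oracles in the test suite: zero-noise trajectories must track the
exponential relaxation with an error that shrinks roughly linearly in the
step size, and long Gaussian-noise runs must recover the stationary mean
and variance (`test-acceptance.R` runs $\alpha = 1$, $\sigma = 0.2$,
$\Delta t = 0.01$, $2\times10^5$ steps after $10^4$ burn-in in $d = 4$).

### Discretization

Integration is explicit Euler--Maruyama:
$x' = x + \Delta t\,\alpha\sum_k a_k(X_k - x) + \eta$. No particular
scheme is canonical for this model; Euler--Maruyama is the simplest
consistent choice and its bias is measured directly by the
closed-form comparison. The linear drift makes the scheme's stability
condition exact: the contraction factor per step is $|1-\alpha\Delta t|$,
so `generator_config()` rejects $\alpha\Delta t \ge 1$ outright rather
than letting trajectories oscillate or diverge.

### Noise law

The model's noise is nominally Gaussian white noise, but what keeps the
decoder functional in practice is a *bounded* perturbation: large latent
edits leave the region the decoder has learned to invert. The package
therefore exposes three laws via `generator_config(noise_law = ...)`:

- `uniform` (default): each coordinate increment is uniform on
  $[-A, A]$ with $A = 0.1$ by default — the controlled, range-bounded
  noise that keeps edited vectors decodable;
- `gaussian`: $A\sqrt{\Delta t}\,\mathcal N(0,1)$ per coordinate, the
  diffusion scaling under which the OU stationary formulas hold exactly —
  this law is what the stationary-moment tests use;
- `clipped_gaussian`: the Gaussian increment clamped to $[-A, A]$.

An optional `step_cap` rescales any step whose total displacement exceeds
a Euclidean threshold; it is off by default.

### Candidate emission

Snapshots are taken at steps `burn_in`, `burn_in + snapshot_every`, ...,
decoded, and deduplicated by SMILES keeping the first occurrence. How many
latent points to decode is not a property of the model, only a compute
budget; the defaults in `run_config()` (2000 steps, burn-in 100, stride
10) keep a desk-scale run around a second.

Reference weights $a_k$ default to uniform $1/K$. Non-uniform weights (to
bias generation toward one target's chemotype) are supported but no
specific tuning ships with the package.

## Unit conversions

Affinities are carried as Gibbs free energies of binding in kcal/mol and
converted from inhibition constants by
$\Delta G \approx 1.3633 \times \log_{10} K_i$ ($K_i$ molar). The
composite factor 1.3633 is used verbatim rather than recomputed from
$RT\ln 10$ with $R = 1.987$ cal/(mol K), $T = 298.15$ K (which gives
$\approx 1.3641$): the composite factor is the one that reproduces the
conventional thresholds $-9.54$ kcal/mol ($K_i = 0.1$ uM) and $-8.18$
kcal/mol ($K_i = 1$ uM) at two-decimal precision, and those two numbers
anchor every downstream filter. $IC_{50}$ values are halved to $K_i$,
the flat competitive/uncompetitive approximation, with no
substrate-concentration correction.

## Affinity regressors

The per-target regressors are fully connected networks with three hidden
layers (512/1024/512 rectified units by default) trained with minibatch
Adam on mean squared error, batch 16, 1000 epochs with learning rate
1e-4 dropping to 1e-5 after epoch 500. The loss and nonlinearity are
standard regression choices (MSE is what the RMSE report measures;
rectifiers are the default in this architecture family and `tanh` is
available). Features and labels are standardized internally and
predictions returned in kcal/mol. There is no early stopping, weight
decay or dropout.

For desk-scale data, `desk_predictor_config()` scales the same family
down: 32/64/32 units, 150 epochs, learning rate 1e-2 dropping to 1e-3 at
epoch 76. These sizes were chosen once for datasets of a few hundred
molecules in $d = 16$; the tests run cross-validation at $n = 500$,
$d = 16$ and require pooled $R \ge 0.95$ on noiseless planted-linear
labels, $\ge 0.9$ at label noise 0.5 kcal/mol, and $|R| \le 0.25$ on
pure-noise labels.

Cross-validation shuffles with the configuration seed into $k$ folds
whose sizes differ by at most one; per-fold and pooled Pearson $R$ and
RMSE are both reported (pooled metrics are computed on the concatenated
out-of-fold predictions — when fold sizes differ the two summaries
differ, so neither is dropped).

## Reference selection and similarity

Similarity between molecules is cosine similarity between their latent
vectors; fingerprint similarity is deliberately out of scope since the
latent representation is the working coordinate system throughout. A
reference compound for a target must satisfy three strict inequalities:
$\Delta G < -9.54$ kcal/mol on its target, Lipinski's rule of five
(MW $\le 500$ Da, $\log P \le 5$, donors $\le 5$, acceptors $\le 10$ —
non-strict, as the rule is stated), and average cosine similarity
$> 0.40$ to its dataset. The average excludes the candidate's own vector:
including self-similarity would inflate every average by roughly $1/n$
and make the criterion easier for small datasets. Ranking is by average
similarity, ties by more negative affinity, then id, so selection is a
total deterministic order.

## Screening cascade

The post-generation filters are, in any order (the tests verify
order-independence): deduplication; predicted $\Delta G < -9.54$ on each
transporter and $> -8.18$ on hERG (strict); novelty, i.e. cosine
similarity $< 0.5$ to every reference; Lipinski; and the ten-property
range classification. Each property is classed `excellent`, `medium` or
`fail`; the overall verdict requires at least `medium` everywhere, and
candidates are ranked by the percentage of properties in the excellent
range.

Interval conventions: excellent intervals are closed at finite printed
endpoints; where an excellent range `0–0.3` meets a medium range
`0.3–0.7` the shared endpoint 0.3 belongs to the excellent class and the
medium interval is $(0.3, 0.7]$; one-sided ranges (`> -5.15`, `< 6`) are
strict as printed; properties with no medium range fail outright outside
the excellent one. These choices are exercised explicitly at the
boundaries in `test-screening.R`.

Property values are *inputs*, read from a CSV (or planted by the
synthetic module): the package screens ADMET profiles, it does not
predict them, mirroring a workflow where an external predictor service
produces the profile table.

## Synthetic data

`synthetic_spec()` plants everything downstream tests need to assert:

- per-target latent clusters — isotropic Gaussians of spread 0.3 around
  standard-normal centers, giving within-cluster cosine similarity around
  0.9, the regime in which the 0.40 average-similarity criterion is
  meaningful;
- affinity labels — an affine map per target,
  $\Delta G = b_t + w_t\cdot(x - c_t) + \varepsilon$, with transporter
  intercepts $-11$ kcal/mol (inside the active region), hERG intercept
  $-6$ (weak binding, as hERG liabilities should be), weight norms 5
  (label SD about 1.5 kcal/mol at the default spread) and 0.5 for hERG,
  and label noise 0.5 kcal/mol — ranges comparable to curated inhibitor
  sets spanning roughly $-15$ to $-3$ kcal/mol;
- property profiles — each value drawn strictly inside the region of its
  planted class (60% excellent / 25% medium / 15% fail by default, medium
  mass folding into excellent for properties without a medium range), so
  boundary arithmetic can never flip a planted class;
- synthetic SMILES — unique linear chains over the C/N/O alphabet
  encoding the molecule index, syntactically valid by construction so an
  optional canonicalizer cannot reject them. Descriptors are sampled
  inside drug-like ranges, not computed from the structures; the strings
  are identifiers with valid syntax, not chemistry.

The fixture latent dimension is 16 (512 remains the pipeline default for
real codecs); fixture sizes are 50 molecules per target, and the
cross-validation tests use 500. All generators are pure functions of
(spec, seed) and the planted truth is returned alongside the data.

What passing tests on this fixture do *not* show: that the method finds
good chemistry in a real autoencoder's latent space. The synthetic
clusters are isotropic and linearly labeled; real latent spaces are
anisotropic, labels are not linear in the coordinates, and decoding can
produce invalid strings. The fixture validates the machinery — the
dynamics, the filters, the bookkeeping — not the chemistry.

### The codebook codec and the empty-cascade regime

The built-in codec decodes a latent vector to the SMILES of the nearest
codebook center (ties to the lowest index). It is exact on its own
codebook (reconstruction rate 1 by construction), which makes it a sharp
test instrument, but it can only ever emit dataset members. Under the
default three-transporter configuration this makes the full cascade
nearly always empty: a candidate similar enough to a transporter cluster
to be predicted potent on all three targets is necessarily similar to a
reference, so the novelty ceiling of 0.5 removes it. That is a property
of nearest-neighbour decoding, not of the cascade; a generative decoder
occupies exactly the gap between clusters that the codebook cannot. The
examples therefore demonstrate non-empty survivor sets with a
single-transporter configuration and a relaxed novelty ceiling, and the
determinism/monotonicity guarantees are tested in both regimes.

## Numerical and engineering choices

- All stochastic stages derive independent child seeds from one root seed
  (stage-name hashing, kept below $2^{31}$), so a stage can be re-run in
  isolation and two runs with the same configuration are byte-identical,
  including output files.
- CSV writers format doubles with 17 significant digits; 15 (the
  `write.csv` default) does not round-trip IEEE doubles exactly and would
  break byte-identical replays through files.
- Cosine similarity raises an error on zero-norm vectors rather than
  returning 0 or NaN; a zero vector has no direction and silently mapping
  it anywhere would corrupt averages.
- Nearest-neighbour decoding, reference ranking and lead ranking all have
  deterministic total tie-breaks (lowest index / id order), so no result
  depends on storage order.
- `affinity_net` standardizes features and labels internally; with raw
  kcal/mol labels around $-10$ the first Adam epochs would be spent
  learning the offset.

## Known limitations

- No real encoder/decoder ships with the package; the `Codec` contract
  (`encode`/`decode`/`dimension`) is the integration point for one.
- The screening module consumes property tables; it performs no ADMET
  prediction and no synthetic-accessibility computation.
- $K_i = IC_{50}/2$ is a fixed approximation; no inhibition-mode or
  substrate-concentration correction is available.
- The regressor trains full epochs with no early stopping; on very noisy
  small datasets this can overfit (visible as pooled CV $R$ near zero,
  which the pure-noise test bounds).
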