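---
title: "Statistical potentials from a Gaussian-chain reference state: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical potentials from a Gaussian-chain reference state: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Every knowledge-based potential obtained by Boltzmann inversion stands or
falls with its reference state: the ensemble that defines what "no
interaction" looks like. floryref's reference state comes from polymer
physics. Inside a dense globule, a chain fragment is surrounded by protein
matter at melt-like density; by the Flory theorem, excluded-volume repulsion
is then screened by the surrounding attractions, and the fragment's
end-to-end vector behaves like that of an ideal chain. The end-to-end
distance $R$ of a buried fragment spanning $m$ residues along the sequence
is therefore Maxwell-distributed,

$$M_m(R, b) = 4\pi R^2 \left(\frac{3}{2\pi b^2 m}\right)^{3/2}
  \exp\!\left(-\frac{3R^2}{2 b^2 m}\right),$$

i.e. each Cartesian component of the end-to-end vector is a centred Gaussian
with variance $b^2 m/3$. The single scale parameter $b$ is the Kuhn length.
Its maximum-likelihood estimate given a sample $\{R_i\}$ is available in
closed form — stationarity of the log-likelihood gives
$\hat b = \sqrt{\overline{R^2}/m}$ — and the Fisher information at the
optimum yields $\sigma_b = \hat b/\sqrt{6n}$. The closed form is the
implementation ([fit_kuhn_length]); a direct numerical likelihood maximizer
exists in the test suite as an independent oracle, and the two agree to
better than $10^{-6}$ relative on random samples.

Fragments qualify as *buried* by a purely sequence-geometric criterion:
$m < N^{2/3}$, with $N$ the residue count of the chain. Fragments short
relative to the globule diameter are unlikely to touch the surface, so
interior–exterior partitioning does not bias their statistics. All
overlapping windows are pooled. Two separation ranges play distinct roles:

* **Flory plateau, $70 \le m \le 90$.** Here the fitted $b(m)$ is flat
  (plateau value $b^*$ = unweighted mean over the range), the mean distance
  scales as $\langle R\rangle \sim m^{\nu}$ with $\nu = 1/2$, and rescaled
  distance distributions collapse. Potentials averaged here are the cleanest.
* **Broad Gaussian range, $30 \le m \le 90$.** Below $m \approx 70$ the
  Maxwell form still fits well but $b(m)$ drifts upward, so the reference
  uses a per-$m$ Kuhn length. The broad average buys short-range statistics
  at the price of plateau purity. The lower cut-off at 30 is where the
  tangent–tangent correlation of real chains (computed by
  [tangent_correlation] from central-difference tangents) has decayed, so
  secondary-structure stiffness no longer distorts the statistics.

The empirical counterpart of $M_m$ is a Gaussian kernel density estimate
$E_m(R, w)$ evaluated exactly (no binning), with bandwidth $w$ selected by
5-fold cross-validated held-out likelihood and extended across sample sizes
through the scaling model $w = a\,n^s$. The potential for separation $m$ is
the Boltzmann inversion

$$V_m(R \mid b, w) = -\ln\frac{E_m(R, w)}{M_m(R, b)},$$

in units of $k_BT = 1$. The $R$-independent partition-function ratio of the
underlying free-energy difference is dropped, so every curve carries an
arbitrary additive constant; all comparisons against known potentials are
made after subtracting the mean over the common support ("gauge fixing").
Averaging $V_m$ pointwise over a separation range gives the sequence-
independent potential (with a per-grid-point spread across $m$); restricting
the fragment sets by the unordered residue-type pair at the fragment ends
before rerunning the whole per-$m$ derivation gives sequence-dependent
potentials. A whole structure is scored by
$V_{tot} = \sum_{i<j} V_{|j-i|}(R_{ij})$, a pairwise decomposition that is
exact for the reference ensemble and an approximation otherwise.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| buriedness bound | $m < N^{2/3}$, strict | – | interior selection; $N$ is the post-break-split chain length |
| collection range | 30–90 | residues | Gaussian regime of real chains |
| plateau range | 70–90 | residues | flat $b(m)$, $\nu = 1/2$ |
| globularity threshold | 3 | residual SD | single-pass pruning of non-globular chains |
| distance grid | 0–30 Å, 0.1 Å | Å | shared by all levels and $m$ so curves average pointwise |
| bandwidth grid | 40 log-spaced in 0.01–10 Å | Å | brackets plausible KDE scales for Å-resolution data |
| CV folds / separations | 5 folds at $m \in \{42,48,60,64,66,72,78,84,92\}$ | – | spreads the $w(n)$ anchor points over the collection range |
| support threshold | 5 expected counts per 0.1 Å bin | counts | keeps $-\ln$ of sampling noise out of the curves |
| sequence-dependent minimum | 50 fragments per $m$ | counts | below this the restricted KDE is dominated by noise |
| $k_BT$ | 1 | – | energies are reported in thermal units |

# Numerical choices

* **Globularity residuals in log space.** The fit of $R_g = aN^{1/3}$ is an
  intercept-only regression of $\log R_g - \tfrac13\log N$; the 3σ rule is
  applied to log-residuals. A power law with multiplicative scatter is the
  natural model in log space, and the procedure is then scale-covariant
  (rescaling all $R_g$ changes $a$, not the discard set). The fit-and-discard
  is one pass; $a$ is not re-estimated after discarding.
* **Plateau uncertainty.** $b^*$ is the unweighted mean of $b(m)$; its
  uncertainty is the standard error of that mean across the range, which is
  zero for a perfectly flat profile.
* **Bandwidth CV at full sample size.** Exact held-out likelihood over the
  bandwidth grid costs $O(n^2)$ per separation, so the training-fold KDE is
  evaluated through a finely binned FFT approximation (8192 bins spanning
  the sample range; bins are orders of magnitude narrower than any plausible
  bandwidth, and the approximation agrees with the exact kernel sum to
  ~$10^{-4}$ relative). This keeps the CV on the *full* sample at any $n$ —
  important because the CV-optimal bandwidth does not follow a single
  universal power of $n$ across decades, so extrapolating a subsampled
  selection would bias it. The selected bandwidth is refined by parabolic
  interpolation of the likelihood in $\log w$ around the grid maximum. Fold
  assignment is a seeded permutation; a degenerate sample (all values
  identical) returns the smallest grid bandwidth with a warning. The
  held-out likelihood is intrinsically flat near its maximum, so the
  selection retains some sampling variability; pipelines share bandwidths
  across separations through the $w = an^s$ model, which averages this
  noise down.
* **KDE boundary.** The Gaussian kernel is used on the real line without
  boundary correction at $R = 0$: for end-to-end distances of several Å with
  $w \ll R$, the mass leaking below zero is far below the $10^{-6}$
  normalization tolerance the tests enforce.
* **Support masking.** Grid points where the empirical density implies an
  expected count below 5 per bin are undefined (`NA`), never $\pm\infty$.
  Averages over $m$ are restricted (by default) to points defined in every
  curve, so the averaged potential is never extrapolated.
* **Minima.** Detection runs on a lightly smoothed curve (3-point moving
  average) to suppress single-bin noise; position and depth are then refined
  by parabolic interpolation through the *raw* values around the detected
  point, so an exact parabola yields its vertex exactly. Pipeline reports
  keep only minima whose depth exceeds the local spread across $m$; the
  low-level [find_minima] reports all of them unless asked otherwise, since
  synthetic curves carry no spread.
* **Short-range repulsion.** The power-law fit regresses $\ln V$ on
  $\ln R$; its default window runs from the smallest defined grid point to
  the first distance where $V$ drops below 1 $k_BT$. The fitted exponent is
  sensitive to this window — a caveat inherited by any short-range estimate,
  since small distances are the worst-sampled region.
* **Scoring boundary rule.** Distances outside a curve's defined support
  contribute the nearest defined boundary value and are flagged per pair;
  separations with no curve are skipped and counted.
* **Alt-locs and chain breaks.** Alternate locations resolve to the highest
  occupancy (ties: first listed); multi-model files use model 1; chains are
  split at residue-numbering gaps, because distances across unresolved
  regions are meaningless; waters and ligands are dropped at parse time
  while CA-carrying HETATM residues (modified amino acids) are retained for
  geometry but excluded from the 20-type sequence classification.

# What the synthetic generators emulate — and what they do not

[generate_gaussian_chain] realizes the ideal-chain null exactly: independent
isotropic Gaussian steps with per-component SD $b/\sqrt3$, so
$E[R^2] = b^2m$ for every separation, with no excluded volume (an optional
hard core exists for stress tests). [generate_confined_globule] produces
compact chains by redrawing steps that would leave a sphere of radius
`radius_factor`·$N^{1/3}$; across an ensemble $R_g \propto N^{1/3}$.
[generate_extended_chain] plants rod-like outliers with $R_g \propto N$.
[sample_reweighted_maxwell] draws end-to-end distances from
$M_m(R,b)\,e^{-U(R)}$ by rejection, so the Boltzmann-inversion stage has an
exact known answer to recover.

Two deliberate idealizations matter when reading test results. First, the
confined walk needs a multiple of its correlation time $\sim (R/b)^2$ steps
to fill its sphere, which leaves an $O(N^{-1/3})$ finite-size deficit in
$R_g$; the default `radius_factor = 2` keeps this small enough that the
fitted size exponent stays within 0.05 of $1/3$ over $N \in [100, 1000]$,
at the price of a somewhat denser packing than real proteins. Second, none
of the generators contain secondary structure, side chains, or
interior/exterior composition gradients. Passing tests therefore demonstrate
that the *inference machinery* is correct and calibrated — that fragments
drawn from the null invert to a flat potential ($|\bar V| < 0.05\,k_BT$ over
the central 95% reference mass at $n = 10^5$ per separation), and that an
injected interaction is recovered gauge-fixed to better than 0.1 $k_BT$ RMS
with per-$m$ curves collapsing pairwise — not that real proteins satisfy the
Flory assumptions; that is an empirical property of real structure sets, and
the short-$m$ stiffness and atomic packing effects that motivate the
30/70–90 cut-offs simply do not exist in the synthetic corpus.

# Problem sizes

The test suite and the acceptance script size their simulations as follows,
chosen to make each statistical guarantee sharp at desk scale: thermal
exponent and Kuhn-profile flatness from 2000 chains of 1000 residues
($\nu = 0.50 \pm 0.01$, $b(m)$ flat within 1%); Fisher calibration from 200
replicates of $10^4$ draws (empirical SD of $\hat b$ within 15% of
$b/\sqrt{6n}$); null-potential and injected-well checks at $10^5$ draws per
separation; globularity classification with 500 confined globules and 20
planted extended chains (all 20 discarded, no globule discarded). Unit
tests use smaller corpora with correspondingly looser, pre-computed
statistical bands.

# Known limitations

* The reference state is justified only for buried fragments; the derived
  potentials carry no information about solvent exposure or local
  conformational preferences, and applications would need complementary
  scoring terms for those.
* Bandwidth reproduction is approximate by construction: the cross-validated
  $w$ depends on the bandwidth grid and fold seed, and the $(a, s)$
  decomposition of $w = an^s$ is ill-conditioned when the fragment counts
  span less than about a decade (predictions inside the observed $n$ range
  remain stable; the exponent itself does not).
* The short-range repulsion exponent depends on the fit window; it should be
  quoted together with that window.
* The pairwise total score neglects correlations between residue pairs; it
  is exact only for the reference ensemble.
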