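---
title: "Methods: federated PCA stratification under local differential privacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated PCA stratification under local differential privacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedstrat)
```

## The problem and the model

Population stratification — assigning each sample to an ancestral
population cluster — is a quality-control prerequisite for pooling
genotype datasets across research groups. The de-facto tool is PCA on the
standardized minor-allele dosage matrix: samples from the same population
cluster together in the space of the top principal components. The
obstacle in a collaboration is that a *joint* PCA normally needs the
pooled genotypes.

`fedstrat` sidesteps pooling with a projected-PCA protocol. A server fits
PCA once on a **public** panel: per SNP, dosages are centered and scaled
(mean $\mu_s$, standard deviation $\sigma_s$), and the SVD of the
standardized matrix $Z = P\Delta Q^\top$ yields the projection matrix
$Q$ (top-$d$ right singular vectors). Factor scores of any sample —
training or new — are $F = ZQ$ after standardizing with the *training*
parameters. Because every collaborator projects through the same frozen
$(Q, \mu, \sigma)$, their score clouds live in one coordinate system and
can be concatenated server-side, which an independently fitted local PCA
would not allow.

Key modeling assumptions:

* genotypes are biallelic and encoded as minor-allele dosage 0/1/2; the
  minor allele is decided per SNP from the data at hand (ties count the
  ALT allele as minor, a deterministic tie-break);
* all parties share one QC-filtered, lexicographically ordered SNP list
  (`qc_filter()` then `align_snp_sets()`); training errors out on
  zero-variance SNPs rather than silently dropping them;
* missing dosages are imputed with the training mean (exactly 0 after
  standardization), so clients never leak local statistics through their
  imputation;
* the public panel spans enough structure that its top components
  separate the populations the collaborators actually hold. When it does
  not (too few panel populations, or more populations than $d$ can
  linearly resolve), federated and centralized analyses degrade
  *together* — the protocol approximates centralized PCA, not ground
  truth.

## Local differential privacy

Each researcher perturbs every coordinate before release:
$X_j = x_j + \mathrm{Lap}(\lambda_j)$ with
$\lambda_j = s_j / (\varepsilon / d) = s_j d / \varepsilon$, i.e. the
total budget $\varepsilon$ is split evenly over the $d$ components and
$s_j$ is the server-supplied sensitivity of component $j$. The Laplace
density is $\frac{1}{2\lambda} e^{-|x-\mu|/\lambda}$ with $\mu = 0$;
sampling is by inverse CDF (`rlaplace()`). `epsilon = Inf` is an exact
no-noise sentinel used for benchmarking. Sample identifiers are
pseudonymized with plain SHA-256; an unsalted hash of a guessable ID is
dictionary-attackable, which is why the IDs, not the hash, must already
be opaque (the simulator's are).

**Sensitivity estimation.** "The range (max − min) of each principal
component over the public panel" admits two readings, and the package
implements both (`fit_pca_model(sensitivity = )`):

* `"loadings"` (default): the range of the entries of each eigenvector
  column of $Q$. A principal *component* in the eigenvector sense is the
  loading vector; its range is on the scale of the projection weights
  ($\mathcal{O}(m^{-1/2})$ for $m$ SNPs), is nearly invariant to which
  populations the panel happens to contain, and yields noise comparable
  to the within-population spread at moderate budgets
  ($\varepsilon \in [1, 5]$). Under this reading the protocol's utility
  and attack-power curves behave the way a practical deployment needs
  them to: clusters survive moderate noise, power rises smoothly with
  $\varepsilon$.
* `"scores"`: the range of the public panel's factor scores
  (`compute_sensitivity()`). This is on the scale of the
  between-population separation itself, so
  $\lambda = s d / \varepsilon \approx (d/\varepsilon) \times$ the
  cluster span: at any practical $\varepsilon$ the noise is of the order
  of the structure it is protecting, and clustering utility collapses.
  The reading is kept because it is the more literal parsing of
  "values of each principal component *in the public dataset*", and
  because it is the conservative choice when the released coordinates
  must be protected against reconstruction of their absolute position.

Both estimators are exposed, tested, and serialized; the default is the
one under which the protocol is useful. Note that neither is a formal
worst-case $\ell_1$ sensitivity over all possible genotypes — both are
empirical plug-ins, so the $\varepsilon$ should be read as a calibration
knob rather than a proven DP guarantee (a known limitation of
range-based sensitivities).

## Server-side clustering

The combined noisy coordinates are clustered with k-means: k-means++
seeding, Lloyd iterations (300 cap, via `stats::kmeans`), best
within-cluster sum of squares (WCSS) over 10 restarts, all deterministic
given a seed. Cluster labels are canonicalized by decreasing size.

`k = "auto"` selects the cluster count by the elbow rule: normalize both
axes of the WCSS-vs-$k$ curve to $[0,1]$ and take the $k$ with maximal
perpendicular distance to the chord joining the endpoints, ties broken
toward smaller $k$, flat or collinear curves returning the smallest $k$
with a warning. Two numerical choices matter here:

* **The curve starts at $k = 1$.** The chord rule can never select an
  endpoint, so a curve starting at $k = 2$ makes a two-population
  federation — the most common real case — unselectable. The selected
  $k$ is still clamped to $\ge 2$, the minimum meaningful number of
  population clusters.
* **Monotone WCSS by warm starts.** Restarted k-means does not guarantee
  a non-increasing WCSS curve. At each $k$ the candidate set therefore
  always includes the best $(k-1)$-centers augmented by the point they
  serve worst; the assignment-step WCSS of that candidate is already
  $\le \mathrm{WCSS}(k-1)$, so the reported curve is non-increasing by
  construction (and Lloyd can only improve it further).

Utility is scored against the **centralized benchmark**: PCA + k-means on
the pooled (local + public) genotypes, samples sorted by ID first so the
benchmark is invariant to the order datasets are supplied in. Predicted
and reference partitions are matched one-to-one by maximizing contingency
overlap (Hungarian assignment, `clue::solve_LSAP`, brute-force-verified
in the tests); accuracy is the fraction of matched agreement, and
precision/recall are computed per cluster from the stated definitions and
averaged weighted by reference-cluster size (an aggregation choice —
single reported values require one; unmatched reference clusters
contribute 0).

## Membership-inference evaluation

The Euclidean attack plays the curious server: project a target's raw
genome through the *same* model (no noise — the attacker holds the
genome), take the minimum distance to the released noisy coordinates, and
compare with a threshold $\gamma$ calibrated on known non-members as the
$\lfloor \mathrm{fpr} \cdot |G| \rfloor$-th smallest control distance
(at most a 5% fraction of controls falls strictly below; with fewer than
$1/\mathrm{fpr}$ controls the minimum is used, with a warning). Power is
the fraction of true members strictly below $\gamma$. Two properties are
worth spelling out:

* with a noise-free release of the members themselves, every member's
  distance is exactly 0, so power is exactly 1 at any positive
  $\gamma$ — the no-privacy ceiling;
* the control pool's composition drives $\gamma$. Controls drawn from
  the whole finite cohort (other researchers' samples included, as
  `run_experiment()` does) make $\gamma$ generous when same-population
  non-members are scarce — which is exactly why two researchers holding
  the *same* two populations face markedly lower attack power than two
  researchers holding one population each: the attacker can still place
  a victim's population, but not which dataset it sits in.

The LRT baseline quantifies the customary alternative of releasing $l$
per-SNP MAF statistics $a_s$ against a reference population's $pop_s$.
The genotype enters per allele: dosage $z \in \{0,1,2\}$ contributes
$z \log(a_s/pop_s) + (2-z) \log\left(\frac{1-a_s}{1-pop_s}\right)$
(each allele an independent Bernoulli draw). A `"verbatim"` mode weights
the second term by $(1-z)$ instead — the classic haploid form applied to
dosages as printed in some derivations; it goes negative for
homozygous-minor genotypes, which is why it is not the default.
Frequencies are clamped to $[\frac{1}{2n+1}, 1-\frac{1}{2n+1}]$ before
logs (pseudocount against released MAFs of exactly 0 or 1). The decision
threshold is the $\lfloor \mathrm{fpr} \cdot n \rfloor$-th *largest*
control statistic, mirroring the distance calibration; the released SNPs
default to the first $l$ in canonical order.

## The synthetic-data generator

`simulate_populations()` draws Balding–Nichols cohorts: per SNP an
ancestral frequency $q \sim U(0.05, 0.5)$, per population
$q_k \sim \mathrm{Beta}\!\left(q\frac{1-F_{ST}}{F_{ST}},
(1-q)\frac{1-F_{ST}}{F_{ST}}\right)$, per individual a
$\mathrm{Binomial}(2, q_k)$ dosage. Defaults emulate common-variant
panels after MAF filtering (ancestral MAF $\ge 0.05$) with
continental-scale divergence ($F_{ST} = 0.1$ in the reference studies).
One global RNG stream per call, seeded from the config, makes every
cohort bit-reproducible; the per-population frequencies are kept as
attributes so disjoint members/controls can be drawn from the *same*
generating distribution (`simulate_from_freqs()`).

What the generator deliberately does **not** emulate: linkage
disequilibrium (SNPs are independent), admixed individuals, realistic
site-frequency spectra, genotyping error, and missingness mechanisms
beyond uniform thinning (`missing_rate`). Passing tests therefore
demonstrate the protocol's behavior under clean population structure;
on real data LD reduces the effective number of independent markers and
admixture blurs cluster boundaries, so real-data accuracy at matched
$\varepsilon$ will be somewhat lower and the elbow less crisp.

## Reference study designs and sizes

The four pre-registered designs behind `scripts/acceptance.R` (all sizes
chosen once, as laptop-scale stand-ins for cohort-scale studies):

* *Benchmark agreement*: 5 populations sized 60/60/20/20/20 × 2000 SNPs,
  researchers hold 20 + 18 samples of populations 1–2, no noise. The two
  researcher populations are the cohort's largest, mirroring a public
  panel whose substructure was itself defined by PCA (the dominant
  populations are the ones the top components must resolve at $d = 2$).
* *No-noise power*: 100 released members, 100 fresh controls, 5% FPR.
* *Elbow consistency*: 3 × 50 samples, 2000 SNPs, researchers covering
  the three populations, $\varepsilon \in \{1, 3, 5\}$, WCSS over
  $k = 2..10$, 100 replicates (the three-population curve has an interior
  elbow, so the $k=2$ anchor question does not arise).
* *FPR calibration*: threshold from 1000 non-member distances at
  $\varepsilon = 3$, evaluated on 1000 fresh non-members. The empirical
  quantile makes the held-out FPR distribution-free: its spread is the
  fresh binomial component plus an equal calibration component,
  regardless of the distance distribution's shape.

Experiment sweeps (`run_experiment()`) derive every RNG stream from the
master seed through `substream_seed()` — a SHA-256 hash of
stage-name-plus-indices truncated to 28 bits — so adding a stage never
perturbs existing streams and identical configs reproduce identical
tables.

## Known limitations

* The range-based sensitivities are empirical, not worst-case; the
  formal $\varepsilon$-LDP guarantee is conditional on the range bound
  actually holding for the records perturbed.
* $d = 2$ resolves at most a few populations linearly; more populations
  need larger $d$, and the elbow search caps at $k = 10$.
* k-means assumes convex, similar-scale clusters; strong admixture calls
  for model-based clustering, which is out of scope.
* The Euclidean attack assumes the attacker holds the victim's raw
  genome and the exact trained model — the strongest reasonable
  adversary; weaker adversaries achieve less than the reported power.
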