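---
title: "Detecting compensatory substitutions by phylogenetic substitution mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory substitutions by phylogenetic substitution mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A compensatory substitution restores a biochemical property that an
earlier substitution at another site perturbed. Because the evolutionary
process is observed only through extant sequences, detecting such events
requires a phylogenetic treatment: the shared history of the sequences
induces correlations that must be separated from genuine functional
coupling between sites. `compmap` follows the substitution-mapping
approach: instead of reconstructing one ancestral history, it computes,
for every site i and branch j of a rooted phylogeny, the *expected*
signed change of a biochemical property P,

$$x_{ij} \;=\; \sum_{a,b} \Pr(\mathrm{parent}=a,\,\mathrm{child}=b \mid
\mathrm{data},\,\mathrm{model})\,\bigl(P(b)-P(a)\bigr),$$

where the posterior over the two branch endpoint states is obtained by a
two-pass pruning algorithm under a time-reversible 20-state model (LG by
default, Poisson for tests), integrating over discrete-gamma rate
categories with equal prior weight. Within-branch multiple hits cancel by
telescoping in the *signed* change, so the endpoint-pair expectation is
exact under the model; no sampling of substitution histories is needed.
The *unweighted* and the |ΔP|-weighted expected substitution counts, which
do not telescope, use the exact Markov-reward expectation
$\int_0^t e^{Qs} W e^{Q(t-s)}\,ds$ evaluated through the spectral
decomposition of the rate matrix. The evolutionary rate of a site is the
Euclidean norm over branches of its |ΔP|-weighted expected counts,
standardized within the family to mean 1.

Writing $X_i = (x_{ij})_j$, the compensation index of a group of sites
$G$ is

$$C(G) = 1 - \frac{\lVert\sum_{i\in G} X_i\rVert}{\sum_{i\in G}\lVert X_i\rVert},$$

equal to 1 for perfectly opposing changes and 0 for parallel ones; the
single-branch restriction $C_j(G) = 1 - |\sum_i x_{ij}| / \sum_i |x_{ij}|$
describes individual branches. Norms are Euclidean throughout (the
convention of the site-rate measure; on a single branch it reduces to the
absolute value).

Assumptions worth keeping in mind: sites evolve under a common
time-reversible model with site-specific rates; the tree (topology,
branch lengths, root) is taken as known and is honored as given — signed
changes depend on branch orientation, but all sites share the same tree,
so compensation statistics are orientation-consistent. Branches are
indexed deterministically in preorder from the root, and that indexing is
carried into every output, so branch-level results are reproducible.

## Candidate search and significance

Variable analyzable sites with non-negligible change signal are clustered
by average linkage on the dissimilarity $d(i,k) = 1 - C(\{i,k\})$; every
nested cluster of size 2–10 is a candidate group. The clustering distance
and linkage are this package's choice — the reference implementations of
this method family do not print their algorithm.

$C$ itself cannot be the test statistic: it is scale-invariant, and a
pair of sites with *negligible* property change reaches $C \approx 1$ by
chance easily (we measured null ensembles whose maximal pairwise $C$ had
median above 0.99). The detection score is therefore the total
branch-local cancelled change,

$$T(G) \;=\; \sum_j \Bigl(\sum_i |x_{ij}| - \bigl|\sum_i x_{ij}\bigr|\Bigr)
 \;=\; \sum_j C_j(G) \sum_i |x_{ij}|,$$

the sum over branches of the branch compensation index weighted by the
amount of change on the branch — the same weight that ranks branches in a
compensogram. $T$ measures *how much* property change was mutually
cancelled, which is what distinguishes repeated compensation from a
single coincidental opposition. $C(G)$ is still computed and reported for
every group.

The null ensemble (`simulate_null()`) simulates alignments of
independently evolving sites on the same tree under the same model,
conserving the empirical site-rate distribution (each simulated site
receives the posterior-mean-rate of an empirical site drawn with
replacement; we condition on the family-wide rate distribution, not on
each tested group's exact rates — the alternative is noted as an open
choice). Every simulation passes through the identical mapping and
clustering search and all candidate scores are recorded.

Raw p-values use the pooled rule: the observed score is ranked among
*all* null candidates of the same size, $p = (\#\{\ge T\} + 1)/(n + 1)$,
ties counting as exceeding. Selection across the many nested candidates
of the search is then corrected by a simulation-estimated FDR
(`simulation_fdr()`): each null candidate receives a p-value under the
identical definition, giving the expected number of false candidates per
family at any threshold; dividing by the observed count and monotonizing
yields the adjusted values, thresholded at 1%. A per-simulation-maximum
p-value mode is also available; it corrects for selection inside the raw
p-value, but then the FDR stage double-counts that correction and all
resolution below the per-simulation maximum is lost — with 500
simulations the attainable floor (1/501) is larger than any workable
threshold over ~50 candidates, which also rules out a plain
Benjamini–Hochberg step-up over the candidate list (the exact BH
procedure remains available as `fdr_adjust()` and via
`fdr_method = "BH"`). Overlapping significant groups are resolved by
keeping the smallest raw p, then the smallest size, then the lowest site
index; a site is flagged coevolving iff it belongs to a selected group.

Two post hoc permutation tests characterize a group per branch: the
branch-randomization test permutes each site's changes across branches
independently (conditioning on the site's total amount of change) and
returns per-branch null means with central 95% intervals; the
site-randomization test redraws groups of the same size from the family's
variable sites (branch identity, hence branch length, fixed) and returns
per-branch and pooled means with a one-sided 95% upper bound. Intervals
are empirical percentiles. Branches whose changes are all below 1e-9 of
the maximum have an undefined $C_j$ and are flagged, never imputed, and
excluded from ranking. Compensogram branch ranking uses
$C_j \sum_i |x_{ij}|$ by default (`rank_by = "C"` for the bare index).
Marginal maximum-likelihood ancestral states can be attached for display;
they never feed any statistic.

## Structural tests

The per-site structure table (C-alpha coordinates, RSA, secondary
structure with element ids, optional disorder index) arrives precomputed;
sites with a hotloop index above 0.1204 and no secondary-structure motif
are relabelled disordered. Two proximity statistics are tested: the mean
pairwise C-alpha distance of a group, and $N_{sub} = (c-1)/(|G|-1)$ where
$c$ counts connected components of the 8 Å contact graph (0 = all in
contact, 1 = all apart; 5 and 10 Å are supported for contact-count
annotation, 8 Å is used in all tests). Both are averaged over groups and
compared, lower-tailed with $p = (N+1)/(R+1)$, against replicates in
which every group is replaced by a conditionally matched pseudo-group.

Conditional sampling matches each focus site on evolutionary rate or RSA
within a 10% *relative* similarity window ($|v - v_0|/v_0 \le 0.1$,
measured against the focus site's value); the candidate set is balanced
so it holds as many values below as above the focus value (the larger
side is uniformly downsampled; ties at the focus value are always kept;
a one-sided candidate set is retained — the reference procedure is silent
on that case). A focus site with fewer than 5 similar sites excludes its
group from the test; sites may not repeat within one sampled group
(bounded resampling, then exclusion), though a site may serve several
groups. The secondary-structure co-location test restricts groups and
pool to helix sites (alpha/3-10/pi), strand sites, or sheets (strands
without a sheet id count as singleton sheets), defines contact as sharing
an element, and uses the same $(c-1)/(|G|-1)$ statistic.

## The synthetic-data generator

`sample_tree()` draws coalescent-style topologies with exponential branch
lengths (default mean 0.1). `simulate_independent()` evolves sites by
root draws from the stationary frequencies and exact transition sampling
along branches. `simulate_coevolving_pair()` plants compensation at the
substitution-event level: site A evolves by Gillespie simulation (so
"same branch" is well defined); each property-changing event of A
triggers, with probability `strength`, a substitution of B to the
reachable residue that best restores the *pair's root-state property
sum*. Targeting the conserved sum, rather than mirroring each event
locally, prevents a pure responder from drifting to the property boundary
where no compensating residue exists; for the same reason the root pair
is drawn from the stationary distribution conditioned on a compensable
joint state (pair sum within the central 50% of its stationary
distribution), emulating an established compensatory partnership. On
branches without a triggered response, B evolves independently with
probability `1 - strength` and stays put otherwise: `strength = 0` is
exact independence, `strength = 1` a pure responder. The generator
reports per-branch realized property changes of both sites as ground
truth.

What the generator emulates: site-independent evolution under LG with
arbitrary rate multipliers, and pairs whose property changes co-occur on
branches with tunable coupling. What it does not emulate: selection and
population dynamics (no fitness model, no order-of-fixation effects),
indels and alignment error, model misspecification (data are generated
under the analysis model), larger coevolving groups, and inter-protein
coupling. Passing the recovery experiments therefore shows that the
statistical machinery detects branch-coupled property compensation at
realistic signal strengths — not that real proteins satisfy the
generator's mechanism.

`build_toy_structure()` places planted contact pairs at 5 Å and all other
site pairs beyond 12 Å (clustered geometry), or uses ideal alpha-helical
/ extended-chain coordinates, with uniform RSA (planted buried sites
below 0.2) and contiguous secondary-structure runs.

## Study conditions of the validation experiments

The test suite's statistical experiments (type-I control, recovery,
sampler-bias removal) run at one fixed desk-scale configuration, chosen
once to emulate the kind of data the method is meant for and small enough
for a laptop: 100-leaf trees (the minimum number of sequences per family
the method realistically needs; deep bacterial families carry hundreds),
mean branch length 0.1 (total tree length ≈ 20 substitutions per site, so
a site experiences a handful of property-changing events — compensation
is undetectable in principle from a single event, which a lone
coincidence can mimic), 50-site families, 4 planted pairs at
`strength = 1` (16% of sites, a realistic per-family prevalence), LG
without rate variation for both generation and mapping (a deliberately
matched model; the real-data default is LG with four gamma categories and
`fit_gamma_shape()` for the shape), and a single 500-simulation null
ensemble shared by all replicate families — legitimate because every
replicate is generated on the same tree, model and rate distribution, so
their null is identical by construction. The type-I experiment checks
that the fraction of independent-site families with any significant group
is statistically compatible with the nominal 1% and that falsely flagged
sites stay below 5%; the recovery experiment requires at least 80% of
planted pairs to be flagged; the sampler experiment requires the sampled
groups' mean conditioning value to sit within 2% of the included observed
groups' mean at the 10% window.

## Numerical choices and degenerate inputs

* Pruning uses per-node rescaling, so underflow raises an error rather
  than returning silent `-Inf`.
* The endpoint-pair posterior is computed per site and rate category and
  renormalized per branch, so likelihood scaling cancels exactly; the
  implementation is verified against brute-force enumeration of all
  ancestral states on trees of up to 4 leaves to 1e-8 (it agrees to
  ~1e-13).
* Expected-count integrals use the eigendecomposition form with the
  $t e^{\lambda t}$ limit when eigenvalues coincide within 1e-10.
* Gamma shape estimation is a 1-D golden-section-based optimization
  (`stats::optimize`, tolerance 1e-4).
* A mapped change at an *invariant* site is not exactly zero: it equals
  the difference between the child's and the parent's marginal property
  expectations, which vanishes only as branch lengths shrink. Invariant
  sites are excluded from the candidate search, so this has no downstream
  effect.
* $C$ is clipped to [0, 1] against rounding; groups whose change vectors
  are all zero are an error (no signal), all-zero branches yield `NA`.
* Empirical p-values count ties as exceeding (conservative) and use the
  add-one estimator everywhere: $1/(n+1)$ is the attainable floor.
* If a null simulation's hierarchy has no candidate of some size, the
  per-size maximum falls back to that simulation's overall maximum
  (conservative); in pooled mode the stratum simply contributes no draw
  from that simulation.
* Ties in the generator's compensating-jump choice break toward the
  higher transition rate, then alphabet order.
* TSV outputs embed the seed and a configuration hash; identical inputs
  give byte-identical files.

## Known limitations

* Signed changes depend on the input rooting; re-rooting changes
  per-branch signs (not the compensation statistics' validity, but
  branch-level outputs are only comparable across runs with the same
  root).
* The null conditions on the family-wide rate distribution, not on each
  group's exact rates; groups of extreme-rate sites are therefore tested
  slightly liberally.
* Structural tests consume a precomputed annotation table; mapping
  between alignment columns and structure residues is the user's
  responsibility, as is running any structure-annotation software.
* The detector needs repeated compensated events: at shallow tree depths
  (one property-changing event per site) no method distinguishes a
  compensated pair from a one-branch coincidence, and power collapses.
* Synthetic indices beyond the shipped examples (e.g. centers of AAindex
  property clusters) must be supplied by the user as TSV tables; the
  pipeline logic is identical for any complete 20-residue table.
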