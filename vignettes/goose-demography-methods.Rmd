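---
title: "Methods: population-genomic inference of goose domestication history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic inference of goose domestication history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`goosepop` implements the analysis chain used to study the domestication
history of the European domestic goose from genome-wide SNP data of wild
graylags (*Anser anser*) and domestic geese. This vignette documents the
models, the estimators, the numerical choices, and the package's own
design decisions where the underlying methods leave latitude.

## Data model and filtering

Genotypes are diploid alternate-allele dosages (0/1/2, or missing) at
SNP loci read from VCF; phase is ignored, half-calls count as missing,
and alleles are taken as written. The canonical cleaning pipeline
(`apply_site_filters()`, `apply_individual_filter()`) removes, in a
fixed order, indels, loci with more than two alleles, loci invariant
within the dataset, and loci with observed heterozygosity above 0.75
(likely collapsed paralogs in reduced-representation data), then drops
individuals with more than 20% missing genotypes. Both thresholds are
strict inequalities. The fixed rule order makes per-rule removal counts
deterministic; each locus is attributed to exactly one rule. Loci that
are invariant within the dataset but fixed for a non-reference allele
can be retained (`keep_cross_species_divergent = TRUE`); they are
informative about divergence from the mapping reference (a swan-goose
assembly) and belong in cross-species trees but not in within-species
statistics.

For SFS-based inference the spectrum needs a monomorphic-site
denominator. `site_accounting()` mimics the accounting used with GBS
data: from the base pairs covered by sequencing tags, sites removed as
indels/multi-allelic/heterozygosity-excess are subtracted as absolute
counts, and the remainder is scaled down by the proportion of SNPs lost
to the complete-data requirement. The per-rule removal counts between
the raw and filtered SNP totals are inputs, not constants, because they
depend on the dataset at hand.

## Diversity and differentiation

Expected heterozygosity uses the unbiased gene-diversity estimator
$H_E = \frac{2n}{2n-1}(1 - p^2 - q^2)$ per locus and population
(`unbiased = FALSE` gives naive $2pq$ for oracle comparisons). Loci
monomorphic in a population contribute $H_E = 0$ to its mean — averaging
is across loci, not across polymorphic loci — while cells with no
non-missing genotype are undefined and dropped (their count is
reported). The wild/domestic contrast is a Welch two-sample t-test whose
unit is the population (one mean $H_E$ per population): with half a
dozen populations per group this yields the fractional degrees of
freedom characteristic of that design.

Pairwise differentiation is the Weir–Cockerham (1984) two-population
estimator combined across loci as a ratio of sums
$\sum a / \sum(a+b+c)$, never as a mean of per-locus ratios. Loci
missing entirely in one population of a pair are skipped and counted;
small negative estimates are reported as computed. Note one property of
this estimator worth remembering when testing: on two *duplicated*
samples (identical genotype tables) it is systematically negative
because the between-sample variance is exactly zero; the proper null for
"no differentiation" is two independent samples from one pool.

The hierarchical AMOVA treats each diploid genotype as two 0/1 allele
copies and partitions their variance among groups, among populations
within groups, and within populations, with unequal-sample-size
coefficients computed per locus (over populations with data at that
locus) and components summed across loci. Significance uses three
permutation schemes — whole populations among groups ($F_{CT}$),
individuals among populations within groups ($F_{SC}$), individuals
among all populations ($F_{ST}$) — with the $+1$-corrected p-value; the
full-scale convention is 16,000 permutations.

## The f3 admixture test

`f3_test()` computes $\hat f_3(C;A,B) = \overline{(\hat c-\hat a)(\hat
c-\hat b)} - \overline{\hat c(1-\hat c)/(n_C-1)}$, the outgroup-free
form whose second term removes the bias contributed by sampling variance
in the target's frequencies ($n_C$ is the target's allele count at the
locus). Loci undefined in any of the three populations, or monomorphic
across all three, are dropped before blocking. Standard errors use a
delete-one block jackknife over contiguous blocks of 500 loci in genome
order — no genetic map exists for goose GBS loci, so locus-count blocks
are the reproducible analogue of map-distance blocks — with the weighted
delete-$m_j$ form so an odd-sized final block is handled exactly.
$Z = f_3/\mathrm{SE}$, and $Z < -3$ (roughly $P < 0.01$) is the working
threshold for declaring admixture. A frequency mode
(`f3_from_freq()`, no bias correction) exists for hand-checkable
examples and simulation oracles. The package reports $f_3$ and $Z$
without interpreting non-negative values: strong target-specific drift
can mask genuine admixture.

## Population structure

PCA normalises each locus by centring on its mean dosage and dividing
by $\sqrt{\hat p(1-\hat p)}$, so loci contribute variance on the drift
scale; missing dosages are mean-imputed for the decomposition only (the
imputation count is reported). Axis significance is tested sequentially
against the Tracy–Widom law with the effective-marker correction
re-estimated from the remaining eigenvalues at each step, stopping at
the first non-significant axis. The TW1 distribution function is
evaluated through its shifted-gamma representation (Chiani 2014), which
matches the first three moments and is accurate to about $10^{-3}$
across the support — well inside the precision these tests need. (A
stored quantile table was considered and rejected: the closed form is
smaller, smoother in the tails, and needs no interpolation code.)

Individual distances are allele-sharing distances (mean absolute dosage
difference over co-called loci, scaled to $[0,1]$); the
neighbor-joining tree uses the Saitou–Nei criterion via `ape::nj`, with
negative branch lengths clamped to zero and the deficit transferred to
the sister edge so path lengths through the parent are preserved.

## Demographic models

Three two-population histories are considered, all sharing a split of
an ancestral population (diploid size `ANCSIZE`) into wild and domestic
demes (`N_WILD`, `N_DOM`) `T1` generations ago: (i) no gene flow after
the split; (ii) constant bidirectional gene flow; (iii) gene flow whose
rates switch at `T2 < T1`. Migration rates follow the convention that
`M_XY` is the per-generation fraction of deme Y replaced by migrants
from X, so `N_Y * M_XY` is the expected migrant count into Y — the only
convention under which the fitted parameter table and the narrative
migrant numbers (0.41 graylags and 1.34 domestics per generation before
the switch) agree, and therefore the one fixed package-wide. Sizes are
diploid individuals, times are generations backward from the present,
and the per-pair coalescent rate is $1/(2N)$ per generation.

The coalescent simulator (`simulate_sfs()`, compiled core) runs the
structured coalescent in continuous time: within each epoch lineages
coalesce within demes and switch demes backward at the corresponding
backward migration rate; at `T1` the demes merge. Each lineage carries
the number of sampled chromosomes it subtends in each deme; summing
lifetimes per configuration gives expected branch lengths, and
multiplying by the mutation rate gives the expected unfolded joint SFS
per site under the infinite-sites, small-$\mu$ approximation (at these
parameter scales the per-site polymorphism probability is ~$10^{-3}$,
so the linearisation error is far below Monte-Carlo noise, as is the
discrete-vs-continuous-generation difference). `mode = "sampled"` draws
multinomial site counts around the expectation. Folding merges each
cell with its complement by pooled minor allele; cells exactly on the
half-sample boundary take half the mass from each orientation, so total
sites are conserved to the last site.

The fixed mutation rate is $\mu = 1.38\times10^{-7}$ per site per
generation (a pedigree estimate from the pink-footed goose, the closest
available relative) and the generation time is 3 years. Because the
monomorphic class enters the likelihood (the observed spectrum carries
1,675,087 monomorphic of 1,681,316 sites), $\mu$ fixed makes the sizes
and times identifiable in absolute units.

## Composite likelihood and its maximisation

The fit criterion is the multinomial composite log-likelihood
$\ln CL = \sum O_{cell} \ln p_{cell}$ over all cells including the
monomorphic class, with expected probabilities from the simulated
spectrum; empty expected cells holding observations are floored at
$10^{-10}$ and flagged. Model comparison uses
$AIC = 2k - 2\ln CL$ and Akaike weights
$w_i \propto \exp(-\Delta_i/2)$; confidence intervals come from a
parametric bootstrap (spectra simulated at the MLE in sampled mode,
each refit, percentile intervals; at least 20 replicates enforced, 100
at full scale).

Maximisation is ECM-style block-coordinate ascent over the blocks
{sizes}, {times}, {rates}, each parameter maximised by golden-section
search on a log scale within finite bounds. Three numerical choices do
most of the work:

* **Common random numbers.** Every likelihood evaluation within a cycle
  reuses one coalescent seed. Without this the Monte-Carlo noise
  (orders of magnitude larger than the per-step likelihood gains)
  defeats one-dimensional maximisation outright.
* **Ridge-aligned searches.** Two parameter pairs are nearly
  unidentified pointwise and trap naive coordinate ascent: the split
  time against the ancestral size (deep coalescence depth
  $\approx T1 + 2\,ANCSIZE$), and the switch time against the recent
  migration rates (the "dose" $T2 \times M2$). The 1-D searches for
  `T1` and `T2` therefore move along these ridges — co-adjusting
  `ANCSIZE` and rescaling the recent rates respectively — so each step
  compares history *shapes* rather than sliding along a flat direction.
  An explicit epoch-swap proposal (exchange the two epochs' rates) ends
  each cycle, as the mirrored mode is otherwise locally stable.
* **Staged effort with profile exploration.** Random starts are drawn
  log-uniformly within bounds, a wider pool is screened by single
  evaluations, survivors run full cycles at base precision, the best
  few are refined at higher replicate counts, and the winner is
  finished by a Nelder–Mead simplex on the log scale under one fixed
  seed — coordinate ascent cannot follow the curved multi-parameter
  valley (split time, ancestral size and old-epoch rates trade off
  jointly), a joint simplex can. For the epoch-switch model the starts
  are built hierarchically: a short fit of the nested
  constant-migration model pins the backbone, full-model starts are
  laid on a grid over switch-time fractions and rate ratios around it
  (the nested warm-start practice standard in SFS fitting), and during
  the cheap exploration cycles each cell's epoch parameters stay
  *frozen* while the backbone adapts — a profile-likelihood sweep that
  compares epoch shapes at ranking precision instead of letting noisy
  cycles slide every start down the dose ridge first. Candidates from
  different basins are compared only at the highest replicate counts,
  where genuine inter-mode gaps (tens of log-units) dwarf the noise.

Default search bounds are 100–20,000 for sizes and times (the published
confidence intervals sit well inside) and $10^{-8}$–$10^{-2}$ for
rates; above 1% migration per generation two demes are effectively one.
The desk profile uses 2,000 coalescent replicates per evaluation during
exploration, refinement at 4x, the simplex finish at 25x, and candidate
ranking at 50x; the full-scale profile records the published effort of
100,000 simulations, 40 cycles and 100 independent runs. Desk-profile
problem sizes throughout the test suite — spectra of 1,681,316 sites for
recovery, $10^5$ sites for model-selection calibration, $10^3$–$10^4$
loci elsewhere — were chosen once as the smallest sizes at which the
relevant signals are comfortably above Monte-Carlo noise.

The recovery check in the acceptance suite fits the epoch-switch model
to its own *expected* spectrum at the published MLEs rather than to one
multinomial draw: residual error then reflects the estimator and
optimiser alone, which is what a scaled-down consistency check should
measure. Multinomial resampling adds dataset-level scatter along the
two ridges above that is the business of the full-scale parametric
bootstrap, not of a desk-scale refit.

## The synthetic-data generator

`generate_dataset()` builds study-like datasets with known truth: three
diverged gene pools (wild graylag, European domestic, Chinese domestic),
populations of 5–15 diploids with population-level drift, optional
admixed populations formed as locus-wise frequency mixtures
$\alpha p_{src1} + (1-\alpha) p_{src2}$, genotypes drawn
Binomial(2, p), and i.i.d. missingness, over roughly $10^4$ candidate
loci and $10^6$ callable sites. Cluster frequencies come from a
Balding–Nichols hierarchy by default — drift coefficients F = 0.08
(wild), 0.18 (European domestic; the domestication bottleneck), 0.55
(Chinese; a different source species), with extra breed-formation drift
within European breeds (0.12) — or from the two-deme coalescent for the
wild/European pair when fidelity to a specific demographic scenario
matters. These drift levels were set once to reproduce the magnitudes
seen in geese (wild-vs-domestic $F_{ST}$ near 0.2, domestic diversity
about two-thirds of wild).

What the generator does *not* emulate: linkage (loci are exchangeable,
so block-jackknife robustness to LD is exercised only structurally),
GBS coverage artefacts and allele dropout, individual- or locus-biased
missingness (available behind config flags, i.i.d. by default), and
reference-mapping bias. Tests passing on synthetic data therefore
validate estimator algebra and Monte-Carlo machinery, not robustness to
those real-data pathologies.

`generate_worked_toy()` ships a deterministic 12-individual, 60-locus
miniature with four planted defective loci (indel, triallelic,
invariant, heterozygosity 11/12) and a built-in 50:50 admixed
population, used as the end-to-end pipeline fixture.

## Pipeline and reproducibility

`run_pipeline()` drives the stages from one JSON-able config and one
master seed, from which every stage draws a named substream; the
manifest records the package version, input checksums, per-stage output
checksums and timings, so identical config plus seed reproduces
identical checksums. Stage failure halts the run with completed outputs
and the partial manifest on disk.

## Known limitations

* Only three two-deme histories: no growth or bottleneck epochs, no
  recombination, no linkage-aware likelihood, no more than two demes.
* Composite-likelihood AIC is used as a ranking device, as is
  conventional for SFS fits; it is not a calibrated likelihood-ratio
  test, and with ~370 SNPs (the $10^5$-site calibration scale) nested
  models differ by only a few log-units, so desk-scale selection rates
  are sensitive to optimiser noise.
* The two near-ridges above mean that single-dataset point estimates of
  `ANCSIZE` and of the (T2, M2) pair should be read jointly, not
  marginally; the bootstrap intervals express this.
* AMOVA sums of squares depend on a per-locus scaling convention;
  fixation indices are the comparable quantities across
  implementations.
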