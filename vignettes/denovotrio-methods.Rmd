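---
title: "Models and methods behind denovotrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind denovotrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovotrio)
```

# Overview

`denovotrio` analyses germline de novo mutations found by whole-genome
sequencing of parent–offspring trios. It covers the full chain from
per-site trio observations to population-level conclusions:

1. **Calling** — a seven-criterion filter turns per-site genotype
   likelihoods, read counts and site quality metrics into de novo calls.
2. **Callability and rates** — a probabilistic model of the same filter
   converts depth profiles into effective numbers of callable sites, the
   denominators of per-generation and per-year mutation rates.
3. **Clustering** — multi-nucleotide mutation (MNM) detection against
   simulation and permutation null models, tandem events and read-backed
   phasing.
4. **Spectra** — strand-collapsed mutation types, sequence-context motifs
   (CpG, TCW, DCH) and spectrum comparisons across clustering strata.
5. **Genomic covariates** — replication-timing and recombination
   association tests.
6. **Synthetic cohorts** — a generator that produces trios, truth
   mutations, read-level observations and covariate tracks with realistic
   statistical structure, so that every stage can be validated end to end
   without restricted human data.

# The calling filter

A candidate site in a trio is accepted as a de novo mutation only if all
seven criteria hold, evaluated in a fixed order so a rejection carries the
first violated criterion as its label:

1. proband genotype likelihood ratio $\mathrm{lik}(AR)/\mathrm{lik}(RR) > 10^{10}$;
2. in both parents $\mathrm{lik}(RR)/\mathrm{lik}(AR) > 200$;
3. no other sequenced individual (descendants of the proband excluded)
   carries the allele with likelihood ratio above $10^4$;
4. at least 15 quality reads (base quality ≥ 20) in the proband and at
   least 8 in each parent;
5. alternate reads make up at least 30% of the proband's quality reads;
6. the alternate allele is seen on both strands in the proband;
7. site quality metrics in range: ReadPosRankSum and MQRankSum within
   $[-6, 6]$, Phred-scaled strand bias FS below 20.

Likelihood comparisons are strict; depth and fraction thresholds are
"at least". The MQRankSum band is symmetric with the ReadPosRankSum band
by default: both are Z-score approximations of Wilcoxon rank-sum
statistics, for which a one-sided bound at $+6$ would reject essentially
every site, so the package treats the band as $[-6, 6]$ and exposes both
bounds as configuration. Likelihood ratios are handled in log10 space
throughout to avoid overflow at high depth; thresholds are applied exactly
as stated on the natural scale.

Indel calling uses the same machinery with depth thresholds scaled by a
configurable multiplier (default 4/3), reflecting that indels are harder
to call from short reads.

# Callability and rate estimation

Hard callable/non-callable cutoffs bias rate denominators. Instead, the
*callability* $C_f(x)$ of site $x$ in family $f$ is the probability that a
true de novo mutation there would survive the depth-dependent criteria
(1, 2, 4, 5, 6), conditional on the three members' depths, under a
binomial read model:

- proband alternate reads $\sim \mathrm{Binomial}(d_c, 1/2)$, assigned to
  strands uniformly;
- parental alternate reads $\sim \mathrm{Binomial}(d_p, \varepsilon)$ with
  base error rate $\varepsilon$ (default 0.005);
- genotype likelihoods computed from the same model, so criterion
  thresholds translate into alt-read-count cutoffs.

The package evaluates this in closed form by enumerating the alt-read
distribution (`site_callability()`); a Monte-Carlo simulation of the same
model serves as an independent oracle in the test suite (agreement within
±0.003). Criteria 3 and 7 are depth-independent and enter as constant pass
probabilities (default 1, configurable). Callability is exactly zero below
the hard depth cutoffs and increases with depth; one caveat is that the
parental criterion has a *discrete* alt-read cutoff, so its pass
probability shows sub-0.005 dips at depths where the cutoff fails to
advance — callability is monotone in depth only up to this discreteness.

With $n_f$ mutations called in family $f$ and $\sum_x C_f(x)$ its callable
sum, the estimators are

$$\mathrm{rate}_{PPPG} = \frac{\sum_f n_f}{2 \sum_f \sum_x C_f(x)}, \qquad
  \mathrm{rate}_{PPPY} = \frac{\sum_f n_f}{\sum_f (p_f + m_f) \sum_x C_f(x)},$$

where $p_f$ and $m_f$ are the paternal and maternal ages at conception
(the generation intervals). Confidence intervals are Wilson score
intervals on the mutation count at fixed denominator; the interval is
clamped exactly to 0 (or 1) at the count boundaries so that degenerate
cases are exact. Genome-wide callable sums are computed from binned depth
profiles, taking the expectation over Poisson depth variation within each
bin; the expectation factorises over the three family members, which makes
whole-genome sums cheap. Context-stratified sums (CpG / non-CpG strong /
weak) reuse the per-bin context composition of the reference and add up
exactly to the total SNV callable sum.

The parental-age model is an ordinary least-squares regression of
per-family counts on both ages jointly (ages are strongly correlated, so
only the joint fit separates the effects); a Poisson log-link fit is
available behind the `family` argument for users who prefer a count model.

# MNM clustering

All mutations are projected onto a single axis formed by concatenating
chromosomes in order with no gap (`concat_positions()`), which guarantees
every mutation set of the same size yields distance lists of the same
length. Three forward-scan distance lists (next mutation in any / the same
/ a different individual) feed QQ comparisons against an independence
null that preserves each individual's per-context mutation counts and
draws positions with probability proportional to mean callability.

Two nulls are provided because they answer different questions:

- `simulate_independence_null()` resimulates positions — the fully
  independent expectation;
- `permutation_expected_fraction()` permutes individual labels of the
  *observed* positions — the expectation given the observed positional
  landscape.

Clusters are built by single-linkage chaining of same-individual mutations
with consecutive gaps strictly below 20 kb; a cluster may span more than
20 kb through shorter links. Chaining additionally requires the members to
share a chromosome; `strict_concat = TRUE` switches to pure
concatenated-axis linking for users who want cross-boundary behaviour.
Tandem events are runs of SNVs at consecutive positions in one individual;
a run of $k \ge 2$ counts as one event, and the tandem rate is events over
total SNVs with a Wilson CI. Read-backed phasing counts templates
supporting cis (alt–alt or ref–ref) versus trans configurations and calls
a pair phased when at least 90% of informative reads agree (inclusive at
the boundary).

Distance thresholds are strict everywhere (`< 20000`), including the
spectrum distance bins, whose final clustered stratum is the right-open
interval $(2000, 20000)$.

# Spectra and motifs

SNVs are collapsed so the reference base is A or C (a G/T reference is
reverse-complemented along with its alternate and flanks), giving six
change types; classification is an involution under reverse complement,
which the suite checks property-style. Context classes are CpG (C directly
5' of G, or the paired G), non-CpG strong (other C/G) and weak (A/T).
Motifs for cytosine mutations are TCW (T-C-[A/T], the APOBEC deamination
target), DCH ([A/G/T]-C-[A/C/T], cytosines neither preceded by C nor
followed by G) and CpG context for C→T. Spectrum comparisons use Fisher's
exact test on the 2×6 type table, falling back to a fixed-seed Monte-Carlo
p-value (≥ 10^5 draws) when the exact network evaluation is infeasible;
the method used is reported. The tandem polymerase-ζ signature is the
dinucleotide change GC→AA or GA→TT on either strand.

# Replication timing and recombination

Replication signals from several individuals are averaged positionwise
(bins without data are dropped, policy configurable), joined to
callability bins, and analysed three ways: per-decile per-context PPPY
rates (decile boundaries from the callability-weighted signal
distribution, so each decile holds ~10% of callable mass), a weighted
logistic regression of mutated-vs-callable on the signal with context
covariates (signal rounded to 2 decimals to bound the design), and a
late/early split at the callability-weighted median combined across the
three context strata with the Cochran–Mantel–Haenszel odds ratio
$\sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i$ (Robins–Breslow–Greenland
CI; strata with an empty margin drop out of the sums, no continuity
correction).

The recombination test counts calls inside a crossover bin of their own
family — bins are half-open 0-based intervals, so a 1-based call at $p$
overlaps $[s, e)$ iff $s < p \le e$ — and compares against permutations of
whole per-family bin lists (uniform relabeling, derangements not
enforced). The p-value uses the add-one convention with a ≥ comparison,
the conservative reading when ties occur; the expectation is the median
permuted count. Families without mapped crossovers are excluded.

# The synthetic cohort generator

The generator is first-class, tested code. Its defaults emulate a large
trio study: 283 families; parental ages bivariate normal (means 31.6 and
28.9 years, SDs 5.5 and 5.0, $r^2 = 0.65$, truncated at 15 by resampling —
the study reports only means and $r^2$, so SDs and the truncation are the
package's own realistic choices); SNV counts Poisson around
$\beta_0 + 1.7\,p_f + 0.34\,m_f$ with $\beta_0$ solved so the mean-age
expectation is 62.9 (Poisson dispersion is itself a modelling choice — the
emulated study does not report count dispersion beyond the age
regression); indels analogous with mean 4.53 and slopes 0.1/0.01; a
six-class spectrum proportional to observed study counts; deletions
outnumber insertions 2.6:1 with geometric lengths capped at 35/8 bp.

The MNM process marks a binomial fraction (default 3.1%) of each family's
SNVs as clustered, groups them into events of 2–8 mutations (truncated
geometric), and draws consecutive gaps from a mixture: tandem (distance 1,
weight 0.19), short (log-uniform 2–2000 bp, weight 0.37) and long
(log-uniform 2–20 kb, weight 0.44), chosen to reproduce the reported
tandem share, the ~525 bp median intra-cluster distance and the ~56%
sub-2kb share. Tandem pairs at C/G sites are biased toward C→A changes
(polymerase-ζ-like), strength configurable.

Observations emulate a variant caller's per-site output: Poisson depths
around a log-normal binned profile (35× default), binomial alt reads,
log10 genotype likelihoods from the same error model, Gaussian rank-sum
metrics, exponential FS, and a log-normal population likelihood ratio that
is large only at simulated inherited variants. Covariate tracks are sums
of low-frequency sinusoids (shared plus per-individual components, slope
analytically bounded) for replication timing, and exponential-length
crossover bins (mean 201 kb) per parent.

**Scale.** The default genome is 50 Mb over two chromosomes — a desk-scale
stand-in, with per-family counts governed by the age model rather than
genome length. One consequence matters for interpretation: with ~63
mutations per individual on 50 Mb, the *chance* probability of finding a
same-individual neighbour within 20 kb is already several percent, far
above the ~0.1% of a 2.45 Gb genome. The ~3% MNM excess therefore shows up
at desk scale only as the difference between the observed clustered
fraction and the permutation expectation, and the suite tests exactly
that difference; the raw 3% figure re-emerges when the independence null
is run on a genome-scale axis, which the acceptance script does. Test
problem sizes (2–20 Mb genomes, 30–1200 families depending on what the
check needs) were chosen so each statistical property is tested with
adequate power at desk scale.

What the generator does *not* emulate: alignment artefacts, mapping-quality
structure, GC-dependent coverage bias, mutation-rate variation along the
genome beyond context classes, recurrent mutations across probands, and
X/Y chromosomes (the analyses are autosomal). Passing tests therefore
validate the statistical machinery, not robustness to real-data artefacts.

# Numerical choices

- Likelihoods in log10 space; ratio thresholds applied as stated.
- Wilson intervals clamped exactly at count boundaries (0 successes →
  lower bound exactly 0; all successes → upper bound exactly 1).
- Decile assignment uses the cumulative callability-weighted signal with a
  $10^{-9}$ tolerance at decile edges so equal-weight bins split 10/10.
- Degenerate inputs raise errors rather than returning silent zeros:
  constant replication signal (deciles undefined), zero rate denominators,
  context classes with zero callability but nonzero counts, collinear
  parental ages, missing genotype likelihoods.
- Fixed seeds make every stochastic component byte-reproducible; the
  generator derives one seed per stage from `config$seed` so stages can be
  regenerated independently.

# Known limitations

- The callability model treats criteria 3 and 7 as depth-independent; if
  population evidence or site metrics correlate with depth in real data,
  denominators shift slightly.
- Indel callability reuses the SNV read model with stricter depths; real
  indel detectability also depends on length and local sequence, which is
  out of scope.
- The 2×6 Fisher test's Monte-Carlo fallback gives a simulated p-value;
  its resolution is bounded by the draw count.
- Cluster linking is single-linkage; other linkage rules would split large
  sparse clusters differently.
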