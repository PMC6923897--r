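---
title: "Methods: multi-species STR panel selection and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-species STR panel selection and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpanel)
```

## The problem

A forensic STR panel for a single species is chosen so that the combined
power of discrimination (CPD) across its loci is near 1 and the random-match
probability (RMP) is below the reciprocal of the population size. When
several species must be served by *one* panel — e.g. a laboratory handling
casework on livestock, companion animals and humans — the loci must be
typable and informative in each species simultaneously, and must in
addition perform well on the integrated "pseudo species" obtained by
pooling them. `strpanel` implements that workflow downstream of STR
genotyping: it consumes per-species genotype tables (repeat-count calls per
sample and locus, missing calls allowed) and a locus catalog, and returns a
minimal ordered panel with full diagnostics.

## Model and assumptions

All statistics are computed from **observed** genotype-class frequencies,
estimated by plain maximum-likelihood counting over called samples (no
pseudo-counts, no smoothing). Two assumptions run through every formula:

1. **Locus independence.** Panel-level quantities are products over loci
   (CPM `= Π M`, RMP `= Π F`, CPE `= 1 − Π(1−E)`, CPI `= Π PI`). Linked or
   associated loci would make these optimistic; the package performs no
   linkage testing (a documented non-goal), so users should avoid physically
   clustered candidates.
2. **Hardy–Weinberg equilibrium in simulations.** The generator and all
   simulation experiments draw two alleles independently per individual.
   The estimators themselves do not assume HWE — PM is `Σ f_G²` over
   observed classes rather than its HWE expectation.

Per locus and species we compute: call rate η (fraction of samples with a
call), heterozygosity H (observed by default; an "expected" `1 − Σp²` mode
exists because either convention is common and the estimator consuming it
should be explicit), probability of matching M, power of discrimination
`D = 1 − M`, power of exclusion E, and maximum profile frequency F.

**Power of exclusion.** No closed form is universal in the literature for
multi-allelic loci; we use the standard single-locus average-exclusion
formula `E = h²(1 − 2h(1−h)²)` on observed heterozygosity h. It is exact
under random mating for the average random-man exclusion probability, is
monotone in h (verified on a grid in the tests) and maps [0,1] onto [0,1].

**Pseudo-species quantities.** The per-locus joint PD is
`𝔻 = 1 − Π_s M_s`: the probability that two random individuals — one per
species profile — are separated somewhere. By the same product structure we
define the pseudo-species MPF as `𝔽 = Π_s F_s`; this is a design choice
(the quantity has no canonical definition), flagged here and in reports.
Its consequence is that pseudo-RMP is the all-species product `Π_ℓ Π_s F`.
A species with no data at a locus contributes `M = F = 1`, i.e. it is
uninformative there: absent species neither help nor hurt a locus.

**Paternity index.** The trio PI is the classical likelihood ratio
`P(child | mother, alleged father) / P(child | mother, random man)`,
computed by enumerating which parent transmitted which child allele, the
random man transmitting from population allele frequencies. There is no
mutation model, no silent alleles and no kinship prior; a man carrying no
copy of any obligate paternal allele gets `PI = 0`. Because a single
exclusion zeroes the product, the combined PI floors zero-PI loci at a
configurable ε (default 1e-30) so log-scale reports stay finite, and the
exclusion count is always reported next to the CPI — the floor is a
reporting convenience, never a statistical claim.

## The filter cascade and greedy selection

Candidates pass four screens in order: shared in ≥ 2 species; autosomal
with repeat unit ≥ 2 bp (sex-linked loci fail for individuals of unknown
sex; mononucleotide repeats are too noisy to type); call rate ≥ δ_η per
species, with a below-threshold species treated as *not observing* the
locus rather than failing it; and, in every observing species, the four
forensic constraints `D ≥ δ_d`, `M ≤ δ_m`, `E ≥ δ_e`, `H ≥ δ_h`
(defaults 0.6, 0.4, 0.3, 0.5; all comparisons inclusive — the source
operators are ≥/≤, and with strict comparisons a locus sitting exactly on a
boundary would be discarded arbitrarily). δ_m is deliberately an
independent knob rather than being forced to `1 − δ_d`.

Selection then runs greedily. Per species s we track running products
`v_C(s) = Π M` and `v_R(s) = Π F` over the panel so far (both start at 1).
A species is *satisfied* once **both** `v_C(s) ≤ 1 − δ_c` and
`v_R(s) ≤ δ_r` hold — one criterion alone keeps it active. Each iteration
adds the locus minimizing `Π_{active s} M·F`: since both panel-level
criteria are products, "the locus that decreases the product of combined
matching probability and RMP the most" is exactly the locus with the
smallest product of its own M·F factors over the active species, and
restricting the product to active species implements the skip-once-satisfied
rule. Ties are broken by larger joint PD, then by (chromosome, position) —
an arbitrary but total order chosen purely so the algorithm is
deterministic and invariant to input row order (a tested property).
Termination is `complete` when no species is active, or `exhausted` (a
warning plus a partial panel, exit code 3 in the CLI) when candidates run
out; unreachable thresholds are a legitimate user outcome, not an error.

Greedy selection is a heuristic on what is essentially a covering problem;
it does not promise the minimum panel. The test suite compares it against
an exhaustive subset-search oracle on instances with ≤ 12 candidates and
≤ 3 species: whenever any satisfying subset exists the greedy panel also
satisfies the thresholds, with size ≥ the exhaustive minimum (equality is
*not* asserted). The exhaustive solver exists only as a test oracle, never
in the product path.

## The synthetic population generator

The generator stands in for an upstream read-mapping / STR-calling
workflow, which is out of scope. It emulates the features of such output
that matter to panel selection: a locus catalog with coordinates and repeat
unit lengths; partial cross-species locus sharing (each species observes
each locus with probability `sharing`, every locus forced to be observed at
least once); species-specific allele-frequency spectra over a common allele
support; HWE genotypes; and configurable missingness. Frequencies are
symmetric-Dirichlet draws (concentration 1 by default — a uniform prior
over the simplex, giving realistically uneven spectra). When a minimum
allele frequency t is requested, frequencies are drawn as
`t + (1 − k·t) · Dirichlet`, which meets the floor exactly in one draw
rather than by iterated truncation and renormalization. Defaults of 3–8
alleles per locus and concentration 1 yield locus heterozygosities of
roughly 0.5–0.85, the range typical of forensically useful dinucleotide and
tetranucleotide STRs. Everything is reproducible bit-for-bit from the seed.

What the generator does **not** emulate: population structure and F_ST,
inbreeding, stutter and other genotyping-error modes, stepwise mutation,
and linkage between loci. Tests passing on synthetic data therefore
validate the *machinery* — estimators, filters, the greedy algorithm, the
simulation experiments — not the field performance of any particular panel
on real populations.

## Simulation experiments

**Sample size.** For each sample size n the experiment draws n diploid HWE
individuals per locus (sampling with replacement from the frequency
distribution — an infinite-population model, since no finite cohort is
available; an exhaustive mode covers the n-equals-population identity
case), and reports the mean fraction of population alleles detected plus
the mean absolute deviation (MAD) of sample-estimated PD, HE and MPF from
their population values, averaged over loci and replicates; the maxima are
reported alongside because "difference less than 0.1" could be read either
way, and we implement the mean while still exposing the max. At the
package's study conditions (100 loci, 3–8 alleles all at frequency ≥ 0.05,
50 replicates, n = 25) detection is ≈ 99% and each MAD is ≈ 0.04–0.07 —
comfortably inside the ≥ 90% and < 0.1 expectations for informative
alleles, and consistent with the closed form detection probability
`1 − (1−p)^(2n)` that the tests verify.

**RMP distributions.** Profiles of simulated individuals are scored by the
product over panel loci of the HWE population frequency of their genotype —
the profile-frequency convention — yielding the RMP vector used for log10
box plots; nested panels give elementwise-smaller RMPs under coupled draws.

**Trios.** True families draw both parents from the population and the
child by Mendelian transmission; false families replace the tested man with
an unrelated draw. With 10 polymorphic loci the true-cohort median CPI sits
above 1 and the false-cohort median far below it, with at least one
exclusion in essentially every false family.

## Numerical and design choices

- Frequencies must sum to 1 within 1e-12; D + M = 1 holds exactly by
  construction.
- Empty-panel conventions: CPD = 0, RMP = 1, CPE = 0, CPI = 1 (empty
  products).
- Degenerate thresholds (δ_c = 0, δ_r = 1) are satisfied by the empty
  panel; `complete` with zero loci is the correct answer there.
- Missing genotype calls are all-or-nothing per call (`NA NA`);
  half-missing rows are rejected at parse time.
- Problem sizes in tests and the acceptance script (100-locus populations,
  50 replicates, 20 000 simulated pairs, 500–1000 trios) were chosen as the
  smallest sizes at which the Monte-Carlo error bands in the checks are
  meaningful.

## Known limitations

- No θ-correction / subpopulation (Balding–Nichols) match probabilities;
  estimates are for the sampled population itself.
- No mutation-aware PI, no X-linked or mitochondrial statistics.
- The greedy panel is not guaranteed minimal; for small candidate sets an
  exact search is feasible but intentionally not part of the product path.
- Whether upstream STR calls should be depth-filtered before frequency
  estimation is left to the user; the package applies no such filter.
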