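---
title: "Gene-centric strain typing with scatyper: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric strain typing with scatyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatyper)
```

## The problem

Specialist populations such as the cellulolytic rumen bacterium
*Ruminococcus flavefaciens* are rare in whole-community 16S surveys, yet
their intraspecific (strain-level) structure matters functionally. The
small scaffoldin gene *scaC* — a single-copy cellulosomal adaptor carrying
one cohesin and one dockerin module — is polymorphic enough to act as a
strain-level marker. `scatyper` implements the two workflows such a survey
needs:

1. **T-RFLP community profiling.** Fluorescently end-labeled amplicons
   (16S or *scaC*) are restriction-digested and the labeled terminal
   fragment sized on a capillary sequencer. The package normalizes peak
   tables, bins fragments into a relative-abundance matrix, and tests
   group separation (animal, hour post-feeding, planktonic vs
   fiber-adherent fraction) with Bray-Curtis + NMDS + ANOSIM + SIMPER.
2. **Clone-library typing.** Cloned *scaC* sequences are trimmed to their
   open reading frames, binned by greedy percent-identity clustering over
   a threshold sweep (99% → 40%), summarized by richness/diversity
   estimators, intersected across animals ("universal" types), and their
   translations scanned for the duplicated 22-residue dockerin repeat.

A synthetic-community generator provides ground truth for every stage, so
each statistic can be validated end to end without any external data.

## The statistical core

All five statistics are implemented from first principles and checked
against closed-form or exhaustive oracles in the test suite.

**Bray-Curtis.** For composition vectors $x_i, x_j$:
$d_{ij} = \sum_k |x_{ik} - x_{jk}| \,/\, \sum_k (x_{ik} + x_{jk})$.
A pair of all-zero profiles is defined as $d = 0$ with a warning.

**ANOSIM.** All $M = n(n-1)/2$ dissimilarities are ranked (average ranks
on ties) and
$R = (\bar r_{between} - \bar r_{within}) / (M/2)$.
The p-value is permutational with the +1 correction,
$p = (1 + \#\{R^\ast \ge R\}) / (1 + B)$. When the number of distinct
relabelings $n!/\prod_k n_k!$ is at most $B$, the full permutation
distribution is enumerated and the test is exact — this engages for every
12-sample two-group design (924 labelings), so the per-week fraction tests
are exact. Pairwise mode re-runs each level pair on its submatrix;
pairwise p-values are reported raw, with no multiple-testing correction,
matching how such tables are conventionally presented.

**SIMPER.** For each between-group pair the per-feature term
$c_k(i,j) = |x_{ik} - x_{jk}| / \sum_m (x_{im} + x_{jm})$ is averaged over
pairs; the per-feature averages sum exactly to the average between-group
dissimilarity (asserted to 1e-9), and the top-10 listing is extracted.

**NMDS.** Kruskal stress-1,
$\sqrt{\sum (\hat d_{ij} - d^\ast_{ij})^2 / \sum \hat d_{ij}^2}$, where
$d^\ast$ is the isotonic regression of configuration distances on the
rank order of the input dissimilarities. Each start alternates
pool-adjacent-violators isotonic regression (`stats::isoreg`) with a
step-halving gradient descent; both half-steps are non-increasing in
stress, so the per-iteration trace is monotone (a tested invariant).
Defaults: 2 dimensions, 200 random starts, at most 300 iterations per
start, convergence when the stress decrease falls below 1e-6. Exactly
embeddable 4-point configurations reach stress below 1e-3. The returned
solution is the best over starts, centered at the origin; stress is
invariant under rotation/reflection, so coordinates are unique only up to
isometry.

**Diversity.** Chao1 uses the classic form $S_{obs} + F_1^2/(2F_2)$ with
the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ as an automatic
fallback when $F_2 = 0$ (both are reported side by side in the sweep
table, since which form a given legacy pipeline used is often unknowable).
Shannon-Wiener uses natural logarithms by default. Rarefaction is the
analytic expectation $E[S_n] = \sum_i (1 - \binom{N-n_i}{n}/\binom{N}{n})$
with log-binomials for stability.

## Peak normalization

The normalization is a deliberate single pass, mirroring the standard
capillary T-RFLP procedure: (1) per-sample total fluorescence; (2) the
smallest total is the reference; (3) per-sample ratio = reference/total;
(4) heights scaled by the ratio; (5) scaled peaks below the 25-RFU
detection limit removed; (6) totals recomputed; (7) relative heights =
scaled height / new total. There is no second scaling pass after removal.
Raising the cutoff can only remove peaks (tested property), and the
procedure is idempotent on profiles already at a common total.

Fragments are binned at 1 bp (floor bins $[k, k+1)$), the resolution of
capillary size calls; the bin width is a parameter because cross-sample
alignment rules are the least standardized part of legacy T-RFLP
pipelines. Peak height, not area, is the abundance proxy.

## In-silico digestion and fragment assignment

Primer matching is one-directional IUPAC compatibility: degeneracy in the
primer (R, H, K, ...) is honored, template `N` matches everything, and up
to a configured number of incompatible positions is tolerated. The
amplicon runs from the 5' end of the forward-primer match through the 3'
end of the reverse-primer site; with multiple placements the shortest
amplicon is returned and flagged. TRF lengths are measured from the
labeled 5' base, primer included, matching how capillary size calls work;
uncut ends are reported with a flag rather than dropped. The built-in
enzyme table covers AluI (AG^CT), HhaI (GCG^C), MspI (C^CGG), HaeIII
(GG^CC) and RsaI (GT^AC) — all palindromic, so one-strand scanning finds
every cut.

Assignment uses a ±1.0 bp window by default (the bin width of the
assignment tool this emulates is unpublished, and 1 bp matches the size-
call resolution). Ambiguous fragments keep their whole candidate taxon
set, and a taxon enters a profile's consensus only if matched in every
digested enzyme.

## Greedy clustering and its dialect

Clustering is FastGroup-style: sequences are processed in input order and
each joins the **first** bin (in bin-creation order) whose **founder**
identity meets the threshold, else founds a new bin named by its clone id.
This join-first rule is deterministic and order-sensitive by construction;
`greedy_cluster()` accepts records in file order, and order effects can be
probed by shuffling the input upstream. Identity is computed from a global
affine-gap alignment (match +1, mismatch −1, gap open 5, gap extend 2; a
run of $k$ gaps costs $5 + 2k$) as matching columns over alignment columns
**excluding end-gap runs**, because trimmed clones have ragged ends. The
aligner is compiled (Gotoh dynamic programming with traceback) and its
scores are asserted equal to an independent aligner's on random pairs.
Identity is symmetric by canonical ordering of the two sequences. The
machinery is alphabet-agnostic, so amino-acid clustering is simply
translate-then-cluster.

S_obs is empirically non-increasing along the 99→40% sweep on all tested
libraries; the greedy rule does not guarantee this in general, which is
why it is a tested property rather than an assumption.

## The synthetic generator: what it emulates

`simulate_community()` draws per-sample type abundances over the full
3 animals × 3 weeks × 2 hours × 2 fractions = 36-sample crossing:

* **Base abundances** follow a geometric series with decay 0.7: a few
  types dominate, as real *scaC* libraries show (one type reaching ~30% of
  one animal's clones). The decay is configurable; 1.0 gives uniform.
* **Animal effects** are Dirichlet perturbations (concentration 50 by
  default); rare types can drop to effectively zero in an animal, which is
  what makes "universal type" a non-trivial notion.
* **Fraction effects** are per-type log-fold factors applied in fiber
  samples, drawn N(0, 2) by default — strong enough that the per-week
  fraction ANOSIM rejects with high power, a regression-guarded property.
* **Week effects** are per-type log-slopes over week index, N(0, 0.5).
* Hours post-feeding carry no effect, reflecting the weakest factor in
  such designs. Effects act multiplicatively and the simplex is
  renormalized; rows sum to 1 within 1e-12 at every stage.

`type_sequence_model()` builds a base amplicon flanked by concrete
realizations of the degenerate primer pair, with a conserved span (the
N-terminal cohesin region) mutating at one tenth of the variable span's
between-type substitution rate (the second dockerin repeat region).
Generated base amplicons are **coding**: an ATG right after the forward
primer followed by stop-free sense codons, and all substitutions — both
between types and within clones — re-draw any change that would create an
in-frame stop. This "ORF-preserving" error model (the purifying-selection
view of a functional scaffoldin gene) is what makes ORF trimming
deterministic downstream, so the noise-free round trip can recover type
structure exactly. It is also a known simplification: real PCR/sequencing
errors do create nonsense codons, as well as indels and chimeras, none of
which are simulated. Other features of real data the generator does not
emulate: the internal duplicated 22-residue dockerin repeat (synthetic
proteins will generally score below the motif threshold — motif detection
is validated on constructed positives and shuffle nulls instead),
pseudo-gene fragments, and heteroduplex/partial-digest artifacts in the
electropherograms.

Peak tables place each type's peak at its predicted TRF plus Gaussian
jitter (sd 0.3 bp), with lognormal height noise (sigma 0.3,
mean-corrected so the expected height is abundance × total fluorescence),
Poisson baseline peaks (rate 2/sample), and heights rounded to positive
integers — so noise-free proportionality is exact up to one part in twice
the total fluorescence.

All randomness flows from a single master seed split into named
substreams per operation, so changing the draw order inside one operation
never perturbs another.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately scaled simulations chosen
as the smallest sizes at which the targeted properties are sharp: a
20-type, ~600-clone library for parameter recovery (between-type identity
below 65% after trimming, within-type above 85%, verified in-test before
the recovery assertion); 1000 null replicates at 12 samples for ANOSIM
calibration (the exact 924-labeling enumeration engages); 100 random
amplicons per enzyme for the TRF oracle; 25–50 NMDS starts in tests
against 200 in the analysis defaults. Ties in dissimilarity ranks take
average ranks; ties among equally qualifying bins resolve to the earliest
founder; UPGMA merges resolve deterministically by pre-sorting leaves
lexicographically; degenerate inputs (all-zero profiles, zero-total
samples, empty groups, all-gap alignment columns) are defined outcomes —
zero distance with warning, exclusion with report, errors with typed
condition classes, and `NA` columns respectively.

## Known limitations

* The greedy clustering dialect (join-first, founder-based) is one of
  several in circulation; counts at a given threshold can differ by a few
  bins from best-match or average-linkage dialects on borderline pairs.
* NMDS is a local optimizer; 200 random starts make the best-of-starts
  stress reproducible for a fixed seed but global optimality is not
  guaranteed for pathological inputs.
* The motif scanner scores 22-mer pairs with BLOSUM62 and a threshold set
  at the expected score of 40% identical pairs; it is a reconstruction of
  a visual-inspection criterion, not a calibrated HMM.
* Synthetic power/calibration results transfer to real T-RFLP data only
  to the extent the noise model (Gaussian size jitter, lognormal heights,
  Poisson baseline) matches an instrument's behavior; passing tests
  demonstrate correctness of the statistics, not instrument realism.
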