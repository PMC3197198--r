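# scatyper

Gene-centric strain typing of rumen cellulolytic bacteria from *scaC*
clone libraries and T-RFLP community profiles.

## The problem

*Ruminococcus flavefaciens*, the major cellulosome-producing bacterium of
the bovine rumen, is too rare for whole-community 16S surveys to resolve
at strain level. Its small scaffoldin gene *scaC* (one cohesin + one
dockerin) is polymorphic enough to serve as a strain proxy: clone
libraries binned at a percent-identity threshold define *scaC*-types, and
fluorescently labeled amplicon digests (T-RFLP) track community dynamics
across animals, planktonic vs fiber-adherent fractions, and time after a
dietary switch. `scatyper` is for microbial ecologists running either
workflow — or validating one — with every statistic implemented from first
principles and testable against a built-in synthetic-community generator.

## What it computes

* **T-RFLP profiles:** single-pass total-fluorescence normalization with a
  25-RFU detection cutoff, 1-bp fragment binning into a relative-abundance
  matrix `X` (rows on the simplex).
* **Community statistics** on `sqrt(X)`: Bray-Curtis
  `d_ij = Σ|x_ik − x_jk| / Σ(x_ik + x_jk)`; Kruskal NMDS minimizing
  stress-1 over isotonic disparities (200 random starts); one-way and
  pairwise ANOSIM, `R = (r̄_between − r̄_within)/(M/2)` with exact
  enumeration whenever the relabeling count permits; SIMPER top-10
  decompositions.
* **In-silico digestion:** degenerate-primer amplicon detection, cut-site
  scanning (AluI, HhaI, MspI, HaeIII, RsaI), labeled-end TRF prediction,
  and multi-enzyme consensus assignment of observed fragments to taxa.
* **Clone typing:** ORF trimming, compiled affine-gap global alignment
  identity (end-gap excluded), FastGroup-style greedy binning over a
  99→40% threshold sweep, Chao1 `S_obs + F1²/(2F2)` (bias-corrected
  fallback), Shannon-Wiener `H' = −Σ p_i ln p_i`, analytic rarefaction,
  universal-type summaries across animals, and duplicated-22-residue
  dockerin repeat detection in the translated types.

## Worked example

Simulate a 10-type community over the 36-sample design (3 animals ×
3 weeks × 2 hours × 2 fractions), sample 8 clones per sample, and run the
typing workflow:

```r
library(scatyper)

model  <- type_sequence_model(between_type_substitution_rate = 0.5,
                              within_type_error_rate = 0.02, seed = 11)
seqs   <- simulate_type_sequences(model, 10, seed = 11)
truth  <- simulate_community(10, decay = 0.8, seed = 11)
clones <- simulate_clone_library(truth, seqs, depth = 8, model = model,
                                 seed = 11)
res <- run_clone_pipeline(clones, truth$design,
                          thresholds = c(90, 80, 70, 60, 50),
                          focal_threshold = 70)
res$sweep
#>  threshold n_sequences s_obs chao1 chao1_bc  shannon
#>         90         288    10    10       10 1.516723
#>         80         288    10    10       10 1.516723
#>         70         288    10    10       10 1.516723
#>         60         288     9     9        9 1.216736
#>         50         288     1     1        1 0.000000
res$universal
#> Universal-type summary at 70% identity
#>   10 types, 8 universal (seen in all 3 animals)
#>   universal share per animal:
#>    64    71     8
#> 0.990 0.979 0.958
```

Reading this: all 10 simulated types are recovered as distinct bins at
thresholds of 70% and above (the clustering plateau), the sweep collapses
below the types' mutual identity (~55–65%), and Chao1 equals the observed
richness because deep, even sampling leaves no singletons. Eight of the
ten types were drawn in all three animals; the per-animal Dirichlet
perturbation kept two rare types out of at least one animal, and the
universal types account for 96–99% of each animal's clones.

The companion T-RFLP workflow runs the same way from peak tables:

```r
pr  <- scac_primers()
lib <- predict_trf_library(seqs, pr$fwd, pr$rev,
                           enzymes = c("MspI", "RsaI"))
pks <- list(MspI = simulate_peak_tables(truth, lib, "MspI", seed = 1),
            RsaI = simulate_peak_tables(truth, lib, "RsaI", seed = 2))
out <- run_trflp_pipeline(pks, truth$design, seed = 1)
out$anosim_table   # R and p per enzyme x week x factor
```

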