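# globinquant

Tools for the computational side of a dual-guide CRISPR deletion screen of
the beta-globin locus, built around one hard problem: estimating the
expression of globin transcripts that are up to ~99.5% identical to each
other (HBG1/HBG2, HBA1/HBA2) from 50-nt single-end RNA-seq reads, and
correcting the residual paralog-assignment bias by simulation-based
calibration.

The package is for people running or reanalysing deletion screens of
candidate gamma-globin silencers: it designs the reagents (guide pairs and
"stapler" ssODN donors), genotypes the edited clones from amplicon deep
sequencing, quantifies globin expression, and compares genotype groups.

## What it computes

**Quantification.** Reads are assigned to transcript *equivalence classes*
by a canonical k-mer index (k = 31): a read's class is the intersection of
the transcript sets of its indexed k-mers, skipping k-mers absent from the
index. Abundances θ maximise the class-mixture likelihood

    l(θ) = Σ_c n_c · log Σ_{t∈c} θ_t / eff_t ,   eff_t = max(L_t − ℓ + 1, 1)

over the simplex by EM (uniform start, deterministic), where `n_c` is the
class read count, `L_t` the transcript length and `ℓ` the read length.

**Calibration.** Reads are simulated from a known mixture — transcript
chosen ∝ weight × (L − ℓ + 1), uniform start, fair-coin strand — then
quantified; a transcript's *adjustment factor* is the mean ratio of
observed (EM-estimated) over expected (truth-label) counts across
replicates, pooled over a sweep of gamma-globin levels. Dividing a raw
count by its factor maps it back toward the truth. The shipped study
conditions are the erythrocyte mixture (HBA1 0.7, HBA2 0.7, HBM 0.01, HBB
1.00, HBD 0.04; HBG1 = HBG2 swept over 0.005–0.10), 10 replicates of
1,000,000 50-nt reads per level.

**Design and genotyping.** `scan_guides()` enumerates every NGG site on
both strands (blunt cut 3 bp 5' of the PAM, 0-based between-base offsets),
`design_deletion_pair()` picks the cuts nearest the target region's
breakpoints, and `design_stapler()` builds the 150-nt donor whose 75/75
arms are the exact flanks of the two cuts. `classify_amplicon_reads()`
scores amplicon reads against WT/deletion/inversion allele models by
semi-global alignment, flags junction indels, and `call_genotype()` turns
allele fractions over junction-informative reads into a diploid call
(hom_WT / het_DEL / hom_DEL / INV_carrier / complex / low_coverage).

A synthetic-data module generates paralog families with controlled
identity, truth-labelled mixture reads, and edited-amplicon reads, so the
whole pipeline runs and is tested without any external data. The bundled
12-transcript globin reference (`synthetic_globin_reference()`) is a
labelled synthetic stand-in that mimics the real family's identity
structure.

## Worked example

```r
library(globinquant)

ts <- synthetic_globin_reference()
spec <- calibration_spec(globin_mixture(), gamma_ids = c("HBG1", "HBG2"),
                         gamma_levels = c(0.005, 0.02, 0.10),
                         n_reads = 1e5, n_reps = 3, read_length = 50, seed = 7)
af <- compute_adjustment_factors(ts, spec)
print(af)
#> Adjustment factors (mean observed/expected over 9 replicates):
#>     id    factor          sd n
#> 1 HBA1 1.0028841 0.004729283 9
#> 2 HBA2 0.9971254 0.004738514 9
#> 3  HBM 1.0000000 0.000000000 9
#> 4  HBB 1.0000000 0.000000000 9
#> 5  HBD 1.0000000 0.000000000 9
#> 6 HBG1 0.9530519 0.060147490 9
#> 7 HBG2 1.0457373 0.058647916 9

reads <- simulate_reads(ts, globin_mixture(gamma = 0.04), n_reads = 1e5,
                        read_length = 50, seed = 42)
ab <- quantify_reads(reads, transcripts = ts)
adj <- adjust_counts(coef(ab)[names(coef(af))], af)
globin_fractions(adj$adjusted)
#> Globin expression (% of globin transcripts); gamma = 3.14%
#>   HBA1   HBA2    HBM    HBB    HBD   HBG1   HBG2
#> 26.239 26.712  0.472 41.461  1.979  1.757  1.380
```

The factor table says how each transcript's estimated counts relate to
truth under the known mixture: values of exactly 1 (HBM, HBB, HBD) mean
every simulated read resolved to its true source; the HBG1/HBG2 deviations
(−4.7% / +4.6%) are the paralog-ambiguity bias the calibration exists to
remove. In the sample report, gamma-globin is 3.14% of globin transcripts —
close to the 4%-weight truth once length weighting is accounted for — and
HBB dominates as expected for adult-pattern erythroid cells.

`run_pipeline()` chains the same steps (calibrate → quantify → adjust →
genotype → report, plus a genotype-group t test) over a YAML or list
configuration and writes TSV/JSON outputs with a reproducibility manifest;
see `?run_pipeline` and the vignette in `vignettes/`.

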