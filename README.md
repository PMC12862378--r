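# epiDRS

Epitranscriptomic analysis of nanopore **direct RNA sequencing (DRS)**
data for bacteria under stress, built around basecalling-error-based
modification detection.

Modified nucleotides perturb the nanopore signal and surface as local
basecalling errors. epiDRS quantifies this as **BCError** — the
proportion of aligned reads with a discrepancy (substitution, spanning
deletion, or adjacent insertion) at each reference position — and works
with the differential against an unmodified in vitro transcribed (IVT)
control:

```
ΔBCError = BCError_sample − BCError_control
Normalized ΔBCError = ΔBCError / BCError_control
```

Under the package's molecule-level error model, a site where a fraction
*s* of molecules is modified has expected BCError `e_base + s·δ_mod`, so
ΔBCError against the IVT control estimates `s·δ_mod` and
`ΔBCError / δ_mod` recovers the stoichiometry.

The package covers, module by module:

* **Synthetic data** (`syntheticConfig`, `generateReference`,
  `sampleTruth`, `simulateAlignments`, `simulatePretrnaLengths`,
  `generateTeTable`) — a seeded generator producing FASTA references,
  ground-truth modification tables, error-injected sorted/indexed BAMs,
  pre-tRNA read populations and translational-efficiency tables, so every
  stage is testable without raw sequencing data.
* **Error profiling** (`readAlignments`, `filterReads`, `computeBCError`,
  `poolProfiles`, `readLengthTable`) — read-level quality filtering
  (Q > 9 for mRNA-enriched, Q > 5 for tRNA-seq libraries), per-position
  BCError pileups with a ≥ 5-read depth mask, and count-based replicate
  pooling.
* **Site detection** (`deltaProfile`, `calibrateThreshold`,
  `classifySites`, `consensusSites`, `motifProximityFraction`,
  `knownModTable`) — ΔBCError profiles, precision/recall threshold
  calibration against the shipped table of 36 known E. coli 16S/23S rRNA
  modification positions, putative-site classification, cross-replicate
  (and external-region) consensus, and motif-proximity summaries.
* **Site annotation** (`transcriptAnnotation`, `assignBiotype`,
  `relativePosition`, `metageneDensity`, `functionalRollup`) — region
  labels (5'UTR/CDS/3'UTR/ncRNA/intergenic), length-normalized metagene
  placement, and functional-category rollups.
* **tRNA analysis** (`anticodonDeltaMatrix`, `anticodonTotalDelta`,
  `classifyStressResponsive`, `lengthDistributions`, `maturityMetric`,
  `correlationTest`, `maturityModificationCorrelation`) — anticodon-loop
  differential error, wobble-position summaries, equal-weighted read-
  length distributions, a log2 mean-length maturity proxy, and the
  Shapiro–Wilk-gated Pearson/Spearman correlation between the two.
* **Codon usage** (`codonSetTable`, `countCodons`, `rankSelect`,
  `compareTeGroups`) — modification-dependent codon abundance
  `n_dep / (n_dep + n_ind)` over nine Q/Mnm-pathway codon pairs,
  tie-aware top/bottom selection, and Mann–Whitney U comparison across
  translational-efficiency classes.

## Worked example

Simulate an rRNA with three modified sites, profile the no-stress and IVT
arms, and detect sites from the pooled differential profile:

```r
library(epiDRS)

cfg <- syntheticConfig(seed = 1, nMrna = 4L, nTrna = 6L, nNcrna = 1L,
                       rrnaLengths = c(`16S` = 400), coverage = 200L)
ref   <- generateReference(cfg)
sites <- data.frame(molecule = "16S", position = c(120, 250, 330),
                    mod = c("m5C", "Y", "m7G"))
truth <- sampleTruth(ref, cfg, rrnaSites = sites,
                     rrnaStoichiometries = c(0.3, 0.6, 0.9))

dir  <- tempfile()
sams <- simulateAlignments(ref, truth, cfg, dir,
                           conditions = c("nostress", "IVT"),
                           transcripts = "16S")
profs <- lapply(seq_len(nrow(sams)), function(i)
  computeBCError(filterReads(readAlignments(sams$path[i]), "mRNAe"),
                 referenceSequences(ref)["16S"],
                 sample = paste0(sams$condition[i], "_", sams$replicate[i])))

ns  <- poolProfiles(profs[sams$condition == "nostress"], "nostress")
ivt <- poolProfiles(profs[sams$condition == "IVT"], "IVT")
ns
#> PileupProfile 'nostress' (mRNAe): 1 transcripts, 400 positions (0 masked at depth < 5)

delta <- deltaProfile(ns, ivt)
head(classifySites(delta, tau = 0.02), 3)
#>   transcript pos      delta
#> 1        16S   6 0.03251563
#> 2        16S  13 0.02099566
#> 3        16S  15 0.02672632

calibrateThreshold(delta, sites)
#> ThresholdCalibration over 41 thresholds (restriction: all)
#>   chosen tau = 0.04: precision 1.000, recall 1.000, F1 1.000
```

At the conventional 0.02 threshold the call set includes baseline noise
(at 400× pooled coverage the binomial jitter of ΔBCError crosses 0.02
regularly); the three injected sites stand far above it (Δ ≈ 0.068,
0.173, 0.179 at stoichiometries 0.3/0.6/0.9), and calibration against
the known-site table picks τ = 0.04, which separates them perfectly.

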