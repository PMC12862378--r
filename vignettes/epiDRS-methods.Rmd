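---
title: "Basecalling-error epitranscriptomics: models and design choices"
author: "epiDRS"
output: rmarkdown::html_document
---

# Scope

epiDRS analyses nanopore direct RNA sequencing (DRS) of bacterial RNA to
characterize stress-dependent changes in the epitranscriptome. A modified
nucleotide perturbs the ionic current as the RNA transits the pore, and the
basecaller converts that perturbation into an excess of local basecalling
errors. The package turns this artifact into a measurement: the proportion
of aligned reads showing a discrepancy at a reference position (BCError) is
a proxy for the fraction of molecules modified there. Around this core the
package provides site detection calibrated against known ribosomal RNA
modifications, transcript-region annotation and metagene placement of
putative sites, anticodon-resolved differential analysis of pre-tRNAs with
a read-length maturity proxy, and scoring of coding sequences for
wobble-modification-dependent codon content.

Basecalling, alignment, quantification and signal-space detection are out
of scope: the package consumes BAM/SAM against a transcript-space FASTA,
and can incorporate region calls from an external signal-level detector as
a BED restriction.

# The error model

At a position with modification stoichiometry $s$ (the fraction of
molecules modified), a read's molecule is modified with probability $s$.
An unmodified molecule basecalls erroneously at the position with the
baseline probability $e_{base}$; a modified one with
$e_{base} + \delta_{mod}$. The expected per-position error proportion is
therefore

$$\mathrm{E}[\mathrm{BCError}] = e_{base} + s\,\delta_{mod},$$

and the differential error against an unmodified in vitro transcribed
(IVT) control,

$$\Delta \mathrm{BCError} = \mathrm{BCError}_{sample} -
\mathrm{BCError}_{control},$$

has expectation $s\,\delta_{mod}$ — which is what makes
$\hat{s} = \Delta\mathrm{BCError}/\delta_{mod}$ an unbiased stoichiometry
estimator under the model. The normalized form divides by the control
BCError and is masked where the control is error-free. Because modification
states are assigned to molecules (not independently per read-position), the
model is the simplest one under which both the detection and the recovery
analyses are coherent.

## What counts as an error

A read contributes **at most one** error per reference position:

* a substitution at the position;
* a deletion spanning the position (deleted positions still count as
  covered);
* an insertion opening immediately 3' of the position, charged to the
  5'-adjacent aligned position. This attribution keeps every event inside
  the reference coordinate system without double counting; insertions with
  no 5' aligned position (e.g. after a leading soft clip) are not charged.

Soft-clipped bases contribute neither coverage nor error. Reverse-strand
alignments are dropped with a warning: DRS reads native RNA and is
sense-strand in transcript space. Coverage counts reads spanning the
position by match, mismatch or deletion. These rules bound BCError in
[0, 1] by construction and are verified exactly against a naive per-read,
per-position enumeration oracle in the test suite.

## Read filters

Reads are kept when primary, mapped, and with mean read quality strictly
greater than the class threshold: Q > 9 for mRNA-enriched (mRNAe)
libraries and Q > 5 for tRNA-seq libraries. Mean read quality is the
Phred transform of the mean per-base error probability,
$-10\log_{10}(\overline{10^{-Q/10}})$, the convention of read-QV filters.
Positions with coverage below 5 reads are masked in every downstream
stage; raising the depth threshold can only mask more positions.

# Threshold calibration

The classifier sweeps an ascending grid of thresholds (default 0 to 0.2 in
steps of 0.005); at each threshold the predicted positives are the
unmasked positions with $\Delta$BCError at or above it, optionally
restricted to externally called regions. Precision and recall are
evaluated against the curated table of 36 known modification positions on
the E. coli 16S and 23S rRNAs shipped with the package. The operating
threshold is the F1-maximizing grid value; ties resolve to the smallest
(most sensitive) threshold, and an explicit `tau` override is supported —
0.02 is the conventional operating point for mRNA/ncRNA classification in
this assay family. Known-site matching is exact-position by default; a
small tolerance window (0–2 nt) is configurable because
modification-induced error halos spread over neighboring positions, and
with a tolerance the precision numerator (matched predictions) and recall
numerator (recovered sites) are counted separately.

Replicate consensus intersects calls by exact (transcript, position)
across **all** replicate call sets and, when an external detector's
regions are supplied, additionally requires a call to fall inside a
region. Both restriction modes (all positions, or regions only) are
available in calibration because published analyses report the sweep both
ways.

# Annotation and metagene placement

GFF3 input/output uses 1-based closed intervals and BED 0-based half-open,
with conversion delegated to `rtracklayer` and covered by a round-trip
test. Every call receives exactly one region label with precedence CDS >
5'UTR > 3'UTR > ncRNA > intergenic; the precedence order is this module's
choice, as overlapping annotations have no canonical resolution. Relative
position within a segment is $(pos - start + 1)/length$, 1-based
inclusive, so the first base of a segment maps to $1/L$ and the last to 1.
Metagene histograms default to 50 bins and are normalized to unit area per
(condition, segment) group.

# tRNA analyses

Anticodon geometry comes from reference metadata (anticodon start in
mature coordinates), never from canonical-numbering inference, because
pre-tRNAs carry leaders and trailers of variable length. Canonical labels
are used for reporting: wobble = position 34, anticodon = 34–36,
anticodon loop = 32–38. The cumulative anticodon signal is the sum of
positionwise $\Delta$BCError over 34–36 by default (a `span = "loop"`
option sums 32–38). A tRNA is stress-responsive when the magnitude of its
replicate-averaged loop delta reaches 0.1 at some position with the same
sign in every replicate; the cutoff is a package default chosen to yield
responsive sets of realistic size on synthetic data.

Read-length distributions over 0–500 nt weight each (tRNA, replicate)
equally: per-unit densities are computed first with unit area, then
averaged, so a tRNA with 10 reads and one with 1000 contribute equally.
Reads longer than the range clip into the last bin. The maturity metric is
$\log_2$ of the ratio of condition mean read lengths (replicates pooled),
chosen over a difference because it is symmetric and scale-free; tRNAs
with fewer than 5 reads in either condition are excluded.

The maturity–modification association uses a normality-gated test:
Shapiro–Wilk on each variable at $\alpha = 0.05$, Pearson when both pass,
Spearman otherwise, two-sided p-values throughout.

# Codon scoring

Nine synonymous codon pairs are scored, each pairing a codon whose
decoding requires a wobble modification from the queuosine (Q) or Mnm
pathway with its modification-independent synonym. The shipped default
marks the U-ending codon dependent for the Q-decoded amino acids (Asn,
Asp, His, Tyr) and the G-ending codon for the Mnm-decoded ones (Arg, Gln,
Glu, Gly, Leu); the table is validated against the standard genetic code
(synonymy, third-position-only difference, 18 distinct codons) and is
replaceable by a user TSV, since published analyses may differ in the
exact pairs. Scanning is in-frame and non-overlapping; the abundance is
$n_{dep}/(n_{dep}+n_{ind})$, masked (not zero) when a CDS contains none
of the 18 codons; codons containing ambiguity characters are skipped;
premature stops are ordinary codons. Rank selection includes every
transcript tied at the boundary score, so a bottom-400 selection with a
tie across ranks 399–403 returns 403 transcripts. The
translational-efficiency comparison is a two-sided Mann–Whitney U with
midrank ties, checked exactly against full permutation enumeration for
small groups.

# The synthetic generator

The generator exists so every stage is testable without raw sequencing
data. It emulates: per-position error elevated at modified positions in
proportion to stoichiometry; an IVT condition whose stoichiometry is
exactly zero everywhere; two biological replicates per condition with
independent seeded substreams per (condition, replicate), so adding a
replicate never perturbs another; constant per-read quality strings drawn
from a configurable read-quality model; and pre-tRNA read populations
mixing mature (70–100 nt) and immature (100–500 nt) molecules. Error
events split into mismatch : deletion : insertion = 0.6 : 0.3 : 0.1 by
default (configurable) so all three channels are exercised; the true
composition of nanopore basecalling errors is instrument- and
basecaller-dependent and no single split is canonical. At the first and
last reference positions error events are realized as mismatches so
alignments never begin or end in an indel.

Defaults describe the emulated study conditions: $e_{base} = 0.03$,
$\delta_{mod} = 0.25$, 500× coverage, rRNA lengths 1542/2904 nt with the
36 curated site positions and stoichiometries spread over 0.2–0.9, a
+0.3 stoichiometry shift at Q/Mnm-pathway wobble sites under stress, and
per-tRNA mature-read weights drawn from 0.3–0.9 (tRNAs genuinely differ
in processing state). The immaturity factor multiplies the anticodon
modification probability of immature reads (0.3 by default); a factor of
1 makes length and modification state independent, which is the null used
to check the correlation test's type-I error.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: sequence-context-specific error profiles
(real modifications distort errors over a ~5-nt halo, not a single
position), raw signal, basecaller quality–error correlation, coverage
decay along transcripts, expression differences between transcripts, and
multi-site interactions. Calibration results on synthetic data therefore
demonstrate correctness of the machinery, not expected field performance.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical checks have comfortable margins:
calibration uses the full-length rRNA pair at 500× with two replicates per
arm; stoichiometry recovery uses 100 sites at 1000×; the
maturity–modification power/size check uses 30 tRNAs at the default 500×
coverage over 100 seeded replicates per regime. Degenerate inputs are
defined rather than left to chance: empty profiles pool as identities,
zero-coverage positions are masked with NA BCError, a zero control error
masks the normalized delta only, zero-length segments yield NA relative
positions with a warning, and empty TE classes, empty motif lists, empty
known-site tables and all-masked deltas are hard errors.

# Limitations

BCError detects modification presence and abundance change, not
modification identity. Exact-position matching understates recall of
detectors that report error halos. The maturity proxy conflates
transcription-unit context with processing state when operons place other
genes on the same read. The shipped codon table is a documented default,
not a claim about any particular published supplementary table.
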