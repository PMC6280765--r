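---
title: "Calling RNA 5'-end features and sRNA cleavage sites from paired 5P/BODY libraries"
author: "endkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA 5'-end features and sRNA cleavage sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Template-switching reverse transcription captures RNA 5' ends regardless of
their chemistry: genuine capped transcription start sites (TSS), processed
or degraded 5'-monophosphorylated ends, and sRNA-guided cleavage products
all appear in a 5'-end (5P) sequencing library. Three confounds make the
raw signal hard to interpret:

1. **Technical 5' ends.** Fragmentation, polymerase stalling and PCR bias
   generate spurious 5' ends throughout gene bodies.
2. **Strand invasion.** The template-switching oligo (TSO) can anneal
   internally at sites complementary to its 3' end and prime there, faking
   a 5' end.
3. **Cap ambiguity.** A read's position alone cannot say whether it came
   from a capped (Pol II primary) or noncapped (processed) 5' end.

endkit addresses each with its own device: a matched nonstranded gene-body
(BODY) library from the same sample serves as a background model; TSO
complementarity masks strand-invasion positions; and upstream untemplated
guanosine (uuG) — an extra G that template switching writes into cDNA when
it reads through a 7-methylguanosine cap — marks capped templates.

# Subtractive feature calling

Each library is reduced to sparse per-position weighted 5'-end counts
(`EndSignalTrack`). The expected per-position ratio between 5'-end signal
and body signal, under the idealisation that all RNA is full length and
fragments at mean length $F$, is the scaling factor

$$S \;=\; \frac{2F \times 10^6}{\sum_{i=1}^{n} \mathrm{TPM}_i\, L_i}\cdot
\frac{R_B}{R_E},$$

where $\mathrm{TPM}_i$ and $L_i$ are the abundance and length of transcript
$i$, and $R_B$, $R_E$ are the total mapped BODY and 5P reads. Transcript
abundances are estimated internally from BODY exonic coverage (reads per
exonic base, normalised to $10^6$), which keeps the pipeline free of an
external quantifier.

A Laplace kernel of bandwidth $b = 15$ nt is then fit over the signed point
set $(ER \cdot S) - BR$: scaled 5'-end counts push the density up, body
counts push it down. Maximal runs of strictly positive density become
discrete 5'-end features. Design choices worth knowing:

* **Truncation.** The Laplace kernel has infinite support, which would make
  "continuous positive density" ill-defined; we truncate at $4b = 60$ nt,
  where the kernel has decayed below $e^{-4}$ of its peak. The density is
  evaluated at every integer position within the truncation radius of any
  data point and is exactly zero beyond, so feature boundaries are well
  defined and the sparse evaluation is exact, not an approximation.
* **Nonstranded BODY.** Body counts subtract from both strands, because the
  BODY library does not preserve strand and must penalise spurious 5' ends
  in either orientation.
* **Strand-invasion masking** happens before density estimation: a 5P
  position is removed when the genomic 4-mer immediately upstream (in cDNA
  sense) matches the last four TSO bases with at most one mismatch.
* **Fragment length $F$** defaults to 500 nt, a typical tagmentation-scale
  cDNA fragment; it is a configuration parameter, not an estimate.
* Features are called per replicate and per strand, with no minimum width.

# Replicate merging and cap classification

Features reproducible in at least two replicates are retained. Merging is
*positional*: a genomic position survives when features from
$\geq$ `minSupport` distinct replicates cover it, and maximal surviving runs
become merged features. The alternative reading — any-overlap clustering of
whole features — was rejected because it makes merged boundaries depend on
the order in which overlaps are resolved; positional support is
order-independent and directly testable.

A merged feature is **capped** when at least 10% of all reads mapping
within it (pooled across replicates of the sample type — the pooled ratio
$\sum u_i / \sum r_i$, not a mean of per-replicate fractions) carry uuG;
the boundary is inclusive. Features with no reads remain unclassified.

# Transcript-level projection and cap-masking

For downstream cleavage analysis, 5P signal inside replicable *capped*
features is discarded ("cap-masking"), and the remainder is projected into
spliced transcript coordinates of each gene's dominant isoform — the
isoform whose exons contain the most BODY read mass, with ties broken by
exonic length and then transcript id. BODY coverage is used because it
tracks overall transcript abundance, whereas 5P signal concentrates at
termini. Antisense 5P signal is dropped during projection; only
sense-strand ends are meaningful for cleavage detection. A per-gene
cleaved-signal proportion, cleaved/(cleaved + capped), summarises how much
of a transcript's 5'-end signal is cleavage product.

# Cleavage-site detection

Candidate sRNA target sites are found by a windowed antisense scan: every
transcript window is aligned to the sRNA antiparallel, allowing
Watson-Crick pairs, G:U wobbles (penalty 0.5), mismatches (1.0), and a
single-nucleotide bulge on either strand (1.0), with penalties doubled at
sRNA positions 2-13. This position-weighted penalty total is the site's
score; sites scoring $\leq$ 10 are kept. The predicted cleavage coordinate
is the transcript base paired to sRNA position 10, i.e. the scissile bond
sits between the tenth and eleventh duplex nucleotides. A full
thermodynamic-folding predictor is deliberately out of scope: the
downstream statistic consumes only scores and coordinates, and the
windowed scan computes both exactly for the penalty model it implements.

At each candidate site the local enrichment is

$$\mathrm{FC} = \frac{\text{reads at site} + 1}
{\max(\text{reads at any single flanking offset}) + 1},$$

with flanks of $\pm 20$ or $\pm 50$ nt, offsets within 1 nt of the site
excluded (so slightly offset sRNA isoforms are not penalised), and windows
clipped at transcript bounds. Both window sizes are reported; the 50-nt
window gates significance by default.

The null model is empirical: each sRNA is shuffled 1000 times
(composition-preserving permutations), and every shuffle is pushed through
the *identical* prediction and quantification path on the same tracks. The
pooled null fold changes and scores give one-sided empirical p-values with
an add-one correction,

$$p_{FC} = \frac{1 + \#\{FC_{null} \geq FC\}}{1 + N}, \qquad
p_{AS} = \frac{1 + \#\{AS_{null} \leq AS\}}{1 + N},$$

which keeps p-values strictly positive — a requirement of the Fisher
combination $X = -2(\ln p_{FC} + \ln p_{AS}) \sim \chi^2_4$ that follows.
Combined p-values are Benjamini-Hochberg adjusted across all sites of all
sRNAs tested in the library (no per-sRNA grouping), and a site is called
significant when the adjusted p-value is below 0.05, FC exceeds 1, and the
site carries at least one read per ten million transcriptome-mapping reads
(RPTM $\geq$ 1). The add-one correction makes the empirical p-values
conservative (stochastically larger than uniform under the null), which is
the safe direction for discovery.

# Read-level preprocessing

* **Complexity filter.** Reads are scored by a distinct-substring-growth
  complexity: at position $i$ the number of new distinct substrings ending
  there is $i - l_i$ ($l_i$ = longest suffix already seen, overlaps
  allowed), and the score is $\sum_i \log_2(i - l_i)$ divided by read
  length. Homopolymer-like reads score near 0 and are removed at the
  default threshold 0.15; uniform-random 50-mers score far above it.
  Strictly periodic dimer repeats score around 1 bit/nt and pass the
  default threshold; the filter targets the degenerate homopolymer tail.
* **uuG extraction.** Soft-clipped bases upstream of the aligned 5' end
  are recorded in cDNA sense; a read is uuG when the single clipped base
  adjacent to the genome match is G. Extra TSO-derived Gs further upstream
  are ignored.
* **Multimapper rescue.** Uniquely mapping reads seed a coverage map;
  multimappers are processed in multiplicity bins 2-100, each read
  assigned proportionally to existing coverage at its candidate locations
  ($P_i = C_i / \sum_j C_j$), with immediate coverage updates, re-sweeping
  each bin until nothing changes, then assigning leftovers $1/n$. Reads
  within a bin are ordered from lowest genomic position to highest with
  read id as the final tie-break, so runs are bit-reproducible. Reads with
  multiplicity above 100 are discarded.
* **k-mer bias model (optional, off by default).** Observed 6-mer
  frequencies around exonic read 5' ends (window $-3..+2$, depth clipped
  to one read per position so expression does not masquerade as bias)
  against background frequencies over all exonic positions; per-read
  weight = background/observed, clipped to $[0.1, 10]$ to prevent
  unbounded reweighting. The upstream method this adapts was developed for
  DNA data and does not fix $k$, the window or caps for RNA; these
  defaults are this package's choices, and correction is optional so the
  statistical pipeline can be validated independently of it.

# The synthetic-data generator

`simulateDataset()` builds a genome, annotation, and paired 5P/BODY SAM
files with per-read truth labels, so every stage of the pipeline can be
tested closed-loop. What it emulates:

* log-normal transcript abundances (TPM), multinomial read allocation;
* capped 5' ends piling at the TSS with Gaussian jitter (sd 2 nt) and a
  15% uuG rate — the regime where uuG appears in roughly one read in
  seven;
* noncapped degradation 5' ends at a few discrete per-gene focal
  positions whose locations are drawn with linearly increasing density
  toward the 3' end, with nt-scale jitter and a 2% uuG rate. Focal
  (rather than fully diffuse) degradation is a deliberate modelling
  choice: diffuse ends at desk-scale depth never outweigh the scaled BODY
  background, so no noncapped feature would ever be called and the
  cap-classification checks would be vacuous. Real degradomes likewise
  concentrate at discrete processing and cleavage positions;
* planted sRNA cleavage products starting exactly at the duplex 10/11
  coordinate of a site written into the transcript;
* BODY fragments sampled proportionally to $\mathrm{TPM}_i \times L_i$
  with uniform starts;
* an exonuclease-treatment mode that removes a configured fraction
  (default 90%) of noncapped-label reads before writing, emulating
  5'→3' digestion of 5'-monophosphorylated RNA with capped ends spared.

Simulated genes are single-exon; spliced projection and multi-isoform
dominant-isoform selection are exercised by hand-built multi-exon fixtures
in the unit tests instead, since no statistic downstream depends on
simulated splicing. The generator does not model sequencing errors, PCR
duplicates, or promoter architecture — so passing tests demonstrate the
statistical machinery on its stated assumptions, not robustness to
real-library artifacts such as mis-mapping or chimeric reads.

# Problem sizes and numerical conventions

The validation suite runs three simulated replicates of 200,000 5P plus
200,000 BODY reads over 200 genes for feature calling, and cleavage
simulations of 6-10 transcripts of 500 nt with 20 sRNAs and 1000 shuffles
per sRNA for the empirical-null checks — sizes chosen so a full run
completes on a laptop-class single core in a few minutes while leaving
every per-gene quantity well populated.

Conventions: all internal coordinates are 0-based half-open with strand in
{+, −}; `GRanges` interfaces use the usual 1-based closed convention;
bedGraph output is 0-based half-open, one file per strand, equal-value
runs merged, values printed at full precision (17 significant digits) so
round-trips are exact. Track invariants (positive weights, unique
positions) are enforced by class validity. Empirical p-values are always
in (0, 1]; masses are conserved to 1e-9 across masking and projection.

# Known limitations

* The windowed duplex scan may enumerate marginal candidate sites slightly
  differently from thermodynamics-based predictors; scores for any given
  duplex follow the stated penalty table exactly.
* The complexity score is a documented contract (homopolymers removed at
  0.15, random reads kept), not a bit-exact reimplementation of any
  particular published scorer.
* $F$ is a configured constant unless estimated externally; the scaling
  factor inherits its error linearly.
* Bias correction assumes the 6-mer window captures the relevant priming
  bias; enzymes with longer footprints would need a wider window.
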