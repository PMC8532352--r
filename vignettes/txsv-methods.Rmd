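---
title: "Detecting novel transcribed variants with txsv: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting novel transcribed variants with txsv: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gene fusions, internal and partial tandem duplications, inversions, larger
indels and unannotated splicing all leave a signature in RNA-seq, but each
conventional caller targets only one of these shapes. `txsv` implements a
variant-agnostic strategy: reconstruct the case sample's transcripts by de
novo assembly (assembly itself is an input — any assembler's contigs can be
supplied), find the assembled sequence that is both *absent from the
reference transcriptome* and *over-expressed relative to controls*, and only
then ask what kind of variant it is. The unit of testing is the
pseudo-alignment equivalence class (EC): the set of sequences a read is
equally compatible with. An EC whose members are all assembled contigs — no
reference transcript — captures reads that the reference cannot explain;
these "novel ECs" are the statistical substrate.

The pipeline is: (i) assembly (external), (ii) k-mer quantification of reads
against contigs merged with the reference transcriptome, (iii) case-versus-
controls differential expression on novel ECs, (iv) annotation of the
retained contigs from their spliced genome alignments (external aligner;
ground-truth alignments for simulations) into eight classes: fusion,
intragenic rearrangement, deletion, insertion, novel/extended exon, novel
exon junction, retained intron, and unknown (unexplained soft clips).

# Quantification model

Contigs and reference transcripts are decomposed into k-mers (default
k = 31, odd, at most 31 under the 2-bit encoding; k must be below the read
length). A read is assigned per orientation by intersecting the id-sets of
its k-mers that are *present* in the index; absent k-mers are skipped, so a
single substitution error (which corrupts up to k k-mers) does not destroy
the assignment. An orientation is valid when at least `min_frac` (default
0.5) of the read's k-mers are present and the intersection is non-empty.
The orientation with more present k-mers wins. When both orientations are
valid and tie exactly — the normal situation for the reverse mate of an
unstranded library, and for reads inside an inverted segment, whose forward
sequence matches the variant contig while their reverse complement matches
the wild-type transcript — the read's EC is the union of the two compatible
sets. This union rule matters: a winner-take-all tie-break would route
wild-type control reads into contig-only ECs and mask inversions entirely,
while the union leaves inversion evidence to reads spanning the inversion
breakpoints, which match the contig in only one orientation.

Mates are assigned independently (single-end semantics), because a fragment
longer than a short contig would otherwise never count toward it. The
library size of a sample is its number of assigned read ends, recorded
before any filtering, so CPM values keep a fixed denominator through the
novel-EC and expression filters. ECs are matched across samples purely by
membership; a sample lacking an EC contributes a zero count.

# Differential expression

Each novel EC passing a light case-expression filter (case CPM strictly
greater than `cpm_min = 0.1`) is tested with a negative binomial GLM
likelihood-ratio test at *fixed* dispersion φ (default 0.1): log link,
log-library-size offset; the alternative fits one rate for the case (a
group of one) and one for the controls, the null a single shared rate, and
2·(Δ log-likelihood), floored at zero, is referred to χ²(1). With one case
sample there is nothing to estimate a dispersion from, which is why φ is
fixed rather than estimated; the acceptance suite verifies the resulting
test is calibrated (type-I error within [0.03, 0.07] at the nominal 0.05)
and that the fitted rates agree with an independent 1-D likelihood search
and with edgeR's fixed-dispersion GLM LRT.

Group-rate maximum likelihood has a closed form (total count over total
library size) when library sizes are equal within the group; otherwise a
Newton iteration on the log-rate solves the score equation
Σᵢ (yᵢ − μᵢ)/(1 + φμᵢ) = 0 (convergence tolerance 1e-10, at most 60
iterations; all-zero rows sit exactly at rate 0 with log-likelihood 0 and
are reported as logFC 0, p = 1).

The fold change is `logFC = log2((y_case + c)/L_case) −
log2((Σy_ctrl + c·N)/ΣL_ctrl)` with prior count c = 0.5 *per sample*; the
per-sample prior makes equal per-sample rates give exactly logFC 0. An EC
is significant when FDR < `fdr_max` (Benjamini–Hochberg, default 0.05) AND
logFC > `logfc_min` (default 2; large cohort screens typically raise this
to 5) — both strict inequalities, and the one-sided interest in
over-expression is enforced by the logFC threshold, not by halving p. All
contigs belonging to a significant EC are retained. Without controls no
test is run; novel ECs passing the CPM filter select their contigs
directly. Controls should be expression-matched samples believed not to
carry the variants of interest; identical variants present in a control
suppress detection by design.

# Annotation and classification

Retained contigs are classified from their spliced genome alignments
(SAM). A contig is kept when at least `min_aligned_bp = 30` bases and
`min_aligned_frac = 30%` of it align and at least one aligned block
overlaps a reference exon. Raw candidates are: I/D CIGAR ops of at least
`gap_min = 7` bp; soft/hard clips of at least `clip_min = 20` bp; N
junctions absent from the annotated junction set; and aligned blocks of at
least `block_min = 20` bp outside every reference exon. Consolidation then
applies, per contig:

* a novel junction whose two flanks lie in different genes (or a gene and
  an intergenic locus), or a pair of alignment records doing the same, is a
  **fusion**; record pairs within one gene that overlap, run out of
  transcriptional order, or disagree in strand are an **intragenic
  rearrangement**;
* a novel block flanked by at least one novel junction (with a valid donor
  or acceptor motif when motif checking is on) is a **novel/extended
  exon**; an unflanked intronic block whose edges coincide with the
  flanking exon boundaries is a **retained intron**;
* a novel junction cutting at least 20 bp into an annotated exon, or
  joining two annotated exon boundaries (a skipped exon), is a **novel exon
  junction**;
* insertions and deletions pass through as their own classes (a deletion
  whose gap shows valid splice motifs is flagged as a potential novel
  intron via its `motif_valid` column, but stays in the deletion class);
* remaining clips on single-record contigs become **unknown** calls; clips
  at the boundary between two records of one contig are considered
  explained by the split alignment.

Non-fusion calls must overlap a reference gene; a fusion may have one
intergenic side (the unpartnered-fusion shape). One contig may yield
several calls — a fusion with a novel exon at its boundary is reported as
both — mirroring how multi-signature events really look.

Splice motifs are valid when the intron-start dinucleotide matches GT or CT
and the intron-end matches AG or AC (both orientations of the canonical
pair, since contig orientation after assembly is arbitrary), each within
`motif_tolerance` (default 1) mismatches. Benchmark runs on simulated
variants disable motif checking because the simulator does not build motifs
into variant junctions.

## Expressed variant allele frequency

No canonical VAF formula exists for EC-level evidence, so the package
defines one from data the pipeline already has: `vaf = U/(U + W)` where U
is the case count of contig-only ECs containing the call's contig and W the
case count of ECs containing a reference transcript of the call's gene(s)
and no contig. Mixed contig+reference ECs are ambiguous and count toward
neither side. Under the heterozygous simulation (equal variant and
wild-type coverage) both U and W count breakpoint-window reads of their
respective haplotype, so indel VAFs concentrate around 0.5; the pipeline
tests assert the [0.35, 0.65] band rather than a point value because EC
leakage adds noise.

# The simulator: what it emulates

The benchmark generator builds, from a synthetic genome, 15 variant types
in three groups of five:

* **fusions** — canonical (first two exons of gene A joined to the last two
  of gene B), with an extended exon (30–199 bp of A's downstream intron
  appended to its second exon), with a novel exon (a 30–199 bp intronic
  block placed 30–199 bp downstream), with a 7–49 bp random insertion at
  the junction, and unpartnered (A's first two exons joined to a cryptic
  two-exon block in intergenic sequence at least 10 kb from any gene — the
  construction chosen to mirror reported unpartnered fusions into cryptic
  intergenic exons, since the general fusion recipe does not define this
  subtype);
* **transcribed structural variants** — insertions, deletions and internal
  tandem duplications of 7–49 bp placed at least 10 bp inside one exon, and
  partial tandem duplications / inversions of 1–3 whole exons in place
  (never the whole transcript, which would be a pure antisense copy);
* **novel splice variants** — extended exons (+30–199 bp of downstream
  intron), novel exons (30–199 bp blocks, 30–199 bp downstream, verified to
  overlap no annotated exon), truncations of two neighbouring exons at
  their facing ends by 30–199 bp each, skipped exons (a junction between a
  non-adjacent exon pair, verified unannotated), and retained introns
  (one full intron longer than 30 bp).

Only transcripts with at least 3 exons from genes overlapping no other gene
are eligible, and every variant consumes fresh genes. The case reference
contains, per variant, the variant sequence *and* its unaltered wild-type
transcript — the heterozygous design: at per-sequence coverage c the gene is
expressed at 2c total. The wild type of the 5' partner is the one added for
fusions, matching a case reference of exactly 2×(number of variants) +
background sequences. The control reference carries the wild-type sequences
only, at doubled per-sequence coverage so case and control gene-level
expression match; the 100 unaltered background genes are likewise doubled
(their coverage is exposed as the `coverage` scale vector, with "same total
as variant genes" as the default reading of an otherwise unspecified
choice).

Reads are 100 bp paired-end from 300 bp fragments sampled uniformly, with
independent per-base substitution errors (default 0.001) and constant
quality — deliberately simpler than a sequencing-machine error profile: no
indel errors, quality gradients, duplicates or strandedness. Sequences
shorter than the fragment length are skipped with a warning; a skipped-exon
variant of a short transcript can genuinely fall below 300 bp and then
yields no reads, which is one of the residual misses at full coverage and
the analogue of a real coverage failure.

The synthetic genome itself has non-overlapping single-isoform genes (4–7
exons of 120–300 bp, introns of 400–800 bp, 2 kb intergenic gaps, 250 genes
per chromosome followed by a 120 kb intergenic desert), with every intron
carrying GT..AG on the transcribed strand so motif checks *can* pass. What
the generator does not emulate: overlapping and multi-isoform genes,
repeats, paralogy and pseudogenes, GC and coverage bias, intron-size and
exon-size distributions of real genomes. Passing the benchmark therefore
shows the *method logic* is correct under its own assumptions; it does not
bound false-positive rates on real data, where homologous alignment is the
dominant error source.

## Ground-truth contigs and alignments

To study detection independently of assembly quality, `perfect_contigs()`
emits each variant transcript as a contig, and `truth_alignments()` derives
its spliced alignment from the simulator's own segment plans: colinear
same-chromosome, same-strand segments merge into one record; a gap lying
entirely within one annotated exon becomes a D op (an exonic deletion)
while any other gap up to 10 kb becomes an N op (a splice), a distinction a
splice-aware aligner makes from sequence context and that is needed here
because simulated deletion sizes (7–49 bp) overlap novel-exon gap sizes
(30–199 bp); larger gaps, strand flips and non-colinear jumps split the
alignment into supplementary records; an ITD's second copy is emitted as an
I op, the way short tandem insertions are reported in practice. Fusion
partners that land within 10 kb on one chromosome therefore merge into a
single spliced record — handled by the cross-gene junction rule — while
distant and cross-chromosome partners split — handled by the record-pair
rule; both paths are exercised in the tests.

# Numerical and interface choices

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only in the GTF and SAM readers/writers. Minus-strand
  transcripts store exons in genomic order; transcription order is derived.
* All writers sort their records, and every stochastic step takes a seed,
  so runs are reproducible byte for byte; the pipeline derives per-stage
  seeds from one top-level seed.
* Orientation ties take the union of compatible sets (see above); a strict
  presence winner takes all.
* Boundary conventions are strict throughout: CPM must exceed 0.1, FDR must
  be below 0.05, logFC must exceed 2; a 19 bp clip or 6 bp indel is
  ignored.
* Non-ACGTN characters in input sequence are mapped to N with a warning;
  k-mers containing N never match.
* The k-mer index holds an external pointer and is rebuilt rather than
  serialised.

The test and acceptance suites run the benchmark at two scales chosen to
keep a laptop run comfortable: a 20-variants-per-type benchmark (500-gene
genome, 50× heterozygous coverage, one matched control) for the recall and
classification checks, and the full 1,500-variant benchmark (2,100-gene
genome) at 5× variant coverage for the low-coverage check. Unit tests use
60–120-gene genomes and 1–2 variants per type.

# Known limitations

* The DE model is a deliberate simplification of an empirical-Bayes
  pipeline: fixed dispersion, no TMM normalisation, no quasi-likelihood
  moderation. With one case and few controls those refinements have little
  data to work with, and sensitivity to the dispersion choice is low until
  φ grows several-fold, but cohort-scale screens may prefer stricter logFC
  thresholds (5) to compensate.
* Classification precedence when one contig supports several classes is
  resolved by emitting multiple calls rather than ranking them; downstream
  consumers should expect more calls than events.
* The VAF estimator is EC-count based and undefined (NA) when neither
  contig-only nor reference-only evidence exists; it is a relative
  expression fraction, not a DNA allele frequency.
* Real-data error modes — mis-assembly, alignment to homologous loci,
  reference gaps — are outside the simulator's reach and must be assessed
  on real alignments.
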