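---
title: "Methods: comparative plastome structure, diversity, RNA editing and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome structure, diversity, RNA editing and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

This vignette documents the models, conventions and numerical choices
behind each analysis stage, what the synthetic-data generator does and
does not emulate, and the known limitations. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## The setting

Chloroplast genomes of closely related plant accessions are nearly
identical ~150 kb circular molecules with a conserved quadripartite
architecture: a Large and a Small Single-Copy region (LSC, SSC) separated
by two Inverted Repeats (IRa, IRb) that are exact or near-exact reverse
complements of each other. Intraspecific comparisons of such genomes ask
three kinds of question: where does the sequence vary (diversity windows,
microsatellites), how does the architecture vary (IR boundaries, gene
order, gene loss — notably the eleven *ndh* genes, variably lost across
*Utricularia*), and how does the functional readout vary (transcript
abundance, C-to-U RNA editing). The package implements one tested
pipeline over these questions, with a seeded generator so every stage is
verifiable against planted truth without downloads.

## Quadripartite detection

The partition is defined as the longest pair of **exact** reverse-
complement repeats consistent with a circular quadripartite tiling; the
shorter single-copy gap between the arms is the SSC. Exactness is
deliberate: biological IRs are near-identical, and an exact criterion
makes the detected arm boundaries reproducible and testable. The search
doubles the sequence so arms spanning the sequence origin are found, and
deduplicates hits modulo the genome length. Ties on arm length are broken
by the candidate minimizing `|len(SSC) − len(LSC)|`, then by the lowest
start coordinate. If no reverse-complement pair of at least `min_ir_len`
(default 1000 bp) exists, a typed `no_ir_detected` error is raised so
callers may treat the genome as IR-less.

One practical consequence of exactness: a single chance complementary
base flanking a junction extends the detected arm by one. The generator
therefore pins the four single-copy junction bases (see below) so that
planted and detected partitions agree to the base.

Region statistics report lengths, fraction of the genome, and
`%GC = (G+C)/(A+C+G+T) × 100` rounded half-up to one decimal. Published
tables occasionally print IR percentages on another denominator (for
example counting both IR copies); this report always uses
fraction-of-genome and leaves reconciliation to the reader.

## Repeats

**Microsatellites (cpSSRs).** A locus is a maximal perfect tandem run of
a primitive 1–6 bp unit, reported when its whole-copy count reaches the
per-unit-length thresholds 7, 4, 4, 3, 3, 3 (mono- through
hexanucleotide). "Primitive" means the unit is not itself a repetition of
a shorter unit, so a poly-A run is one mononucleotide SSR and never an
`AA` dinucleotide. Runs are truncated to whole copies
(`end − start + 1 = unit × copies`). Interrupted (compound) repeats are
*not* merged: each perfect run is a separate record, which is the
convention that makes per-unit-length counts well-defined; a
post-processor can merge if a study needs compound loci. `N` never
matches anything. Both repeat analyses conventionally run on the
IR-reduced sequence (`LSC + IRa + SSC`) to avoid double-counting the IR;
`ir_reduced_seq()` produces it and full-genome mode is simply passing the
full sequence.

**Long approximate repeats.** Arms of at least 30 bp within Hamming
distance 3, in four kinds: forward (direct), reverse (reversed, no
complement), complement (complemented, same orientation) and palindromic
(reverse complement). The definition of a reported pair: for every
distance k in 0..3, a maximal exact-k pair has its arms flanked by
mismatches or sequence ends (extending by one base would increase the
distance). Because one physical locus generates several overlapping
maximal pairs at different k, overlapping discoveries on the same
diagonal collapse to a single record preferring fewer mismatches, then
greater length, then the leftmost start — so a planted exact duplicate is
reported once, with zero mismatches, rather than as a fan of
three-mismatch extensions. Pairs whose arms are both strictly contained
in a no-worse pair of the same kind are dropped. Detection is
seed-and-extend: by pigeonhole any qualifying arm contains an exact seed
of `floor(min_len/(max_hamming+1))` bp (hence `min_len < 8` is refused —
the seed degenerates), and only seed neighbourhoods are scanned, grown
until `max_hamming + 1` mismatches separate the scan edge from the
outermost seeds. The test suite holds this implementation to exact
agreement with an independent exhaustive every-diagonal enumeration on
2 kb instances. Published tool totals are not promised bit-for-bit:
repeat finders differ in maximality and containment conventions, which is
exactly why the oracle, not a printed count, is the contract.

## Nucleotide diversity and identity

For a window (or feature) and rows *i < j*, a site is comparable when
both rows carry `A/C/G/T` there (pairwise deletion); the pair's ratio is
differences over comparable sites and

> π = mean over row pairs of (differences / comparable sites),

with pairs lacking comparable sites dropped from the mean and `NA` when
no pair has any. Choices worth stating:

- **No distance correction** (no Jukes–Cantor): π is the raw mean
  pairwise difference proportion, appropriate at intraspecific divergence
  and matching the common sliding-window practice.
- **Window = step = 500 bp** by default (tiling windows); the step is
  configurable but published per-500-bp tracks imply tiling. The trailing
  partial window is included.
- **Pairwise deletion** rather than complete deletion keeps signal in
  indel-rich intergenic spacers; `n_sites_used` (columns where at least
  one pair is comparable) flags windows resting on few sites.
- Coordinates are alignment columns with a projection to reference
  coordinates (`ref_start`, `ref_end`) for genome-positioned plots and
  BED output.

Hotspots are windows or features with π strictly above 0.02, sorted
descending — the conventional cut for proposing intraspecific marker
regions. Both window-level and feature-level π are provided because
published hotspot lists mix genes and spacers without stating which
crossed the threshold. The windowed identity track (percent matches over
comparable sites per window between two rows) gives the mVISTA-style
view; for two gap-free rows `π = 1 − identity/100` per window, which the
tests assert.

## Architecture comparison

Signed gene orders (one entry per feature copy, ascending start, strand
as sign) are matched by symbol, IR copy index and occurrence (so
trans-spliced loci stored as several features match positionally). Every
maximal contiguous block that appears in the second genome reversed in
order *and* strand relative to the first is one inversion; order
differences not explainable as a single block reversal are reported as
`translocation_or_other` — no sorting-by-reversals distance is computed,
because the biological case of interest (a petN/psbM-type inversion) is a
single block. Symbols private to one genome become presence/absence
records, and `presence_absence_matrix()` defaults to the eleven *ndh*
genes, counting only non-partial annotations as present. Junction reports
give, at each of the four single-copy/IR boundaries, the nearest feature
on each side (signed distance, negative before the junction) and, for
straddling genes, the overlap on each side.

## C-to-U editing calling

On the plus strand of the genome, a C-to-U edit is observed as `T` where
the reference has `C` for plus-strand genes, and as `A` where the
reference has `G` for minus-strand genes. A site is called when the
reference base is C on the strand of an overlapping CDS and the edited
base is observed at level > 0 with coverage ≥ 10× in at least 2
replicates; levels are reported for *all* replicates, zeros included,
since a replicate at level 0 is information, not absence. The editing
level is

> level = edited / (edited + reference) × 100,

excluding reads that support neither base (sequencing error) from the
denominator — this is what lets genuinely complete editing saturate at
100. Codon annotation extracts the codon from the spliced,
strand-oriented CDS (multi-exon genes use spliced coordinates;
trans-spliced rps12 requires all three parts, otherwise the effect is
`unresolved`), places `U` at the edited codon position, and translates
both codons under the bacterial/plant-plastid genetic code; synonymous
means identical amino acids, `stop_gained` means the edit creates a stop.
Edits in the start codon are flagged rather than rejected.

The physicochemical classification follows the C-to-U editing literature
convention as an enumerated table: S→L, S→F and R→C are
hydrophilic-to-hydrophobic changes; A→V, H→Y, L→F, P→F, P→L, P→S, R→W,
T→I and T→M are no-change. The table is applied verbatim and not
extrapolated — unlisted transitions return `NA`/`unlisted` — because the
convention itself is internally debatable (R→W is listed as no-change
although tryptophan is canonically hydrophobic) and silently "fixing" it
would make results incomparable with the literature.
`reclassify_codon_table()` re-derives amino acids and effects for a
printed site table from its codons and reports rows whose printed letters
disagree with what their codons encode, so transcription errors in
published tables are surfaced, never reproduced.

Limitations stated up front: known SNPs and reverse-transcription
artifacts are not masked (no DNA-Seq input is assumed); sites outside
annotated CDS are counted and logged but not annotated; U-to-C editing is
out of scope.

## Expression

Relative log expression (median-of-ratios): the per-gene reference is the
geometric mean across samples over genes with all-positive counts; each
sample's size factor is the median of its count/reference ratios over
those genes; normalized counts are raw counts divided by the size factor.
Genes with a zero anywhere are excluded from the reference but retained
in outputs. The implementation is the package's own; the test suite
cross-checks it against DESeq2's reference implementation to 1e-10.
Displayed values are `log2(normalized + 1)`. One exactness worth knowing:
multiplying one sample of *n* by *c* rescales the geometric-mean
reference by `c^(1/n)`, so that sample's factor picks up exactly
`c^(1−1/n)` and the others `c^(−1/n)`; all between-sample normalized
ratios are invariant, and that relative form is what the tests assert.

Profile clustering uses `1 − Pearson correlation` between sample profiles
with average linkage — a deliberate choice (the distance/linkage behind
published heat-map clusterings is rarely stated) that is insensitive to
remaining depth differences and standard for expression profiles; both
are configurable. Samples with zero variance make the correlation
undefined and raise an error naming the sample. The leaf order is
exported for heat-map reproduction and the tree as Newick via ape.
IR-duplicated genes are separate `_1`/`_2` rows and trans-spliced rps12
is analyzed as three rows, matching how chloroplast count tables are
built.

## The synthetic world

`sim_config()` states the simulated study design once; generator
functions are deterministic given the seed (the RNG state of the caller
is left untouched). The defaults mirror the emulated design where it is
stated — three haplotypes with RNA-Seq replicates 3/3/2, 500-bp hotspot
windows, editing levels and coverages in the range of published site
tables (levels 50–100%, coverage 15–40×), SSR/long-repeat plantings that
exercise every unit length and repeat kind — and use scaled-down genome
regions (LSC/IR/SSC = 20/6/6 kb instead of ~82/25/17 kb) so the full
pipeline runs in seconds; paper-scale lengths are a config change, not a
code change.

Construction details that make planted truth exact rather than
approximate:

- Background sequence is i.i.d. uniform A/C/G/T, then scanned and
  repaired until free of accidental SSRs above the census thresholds
  (accidental ≥ 30 bp repeat pairs within distance 3 have expected count
  ~1e-4 in these genome sizes and are not repaired). Repairs inside the
  IR are mirrored so IRa/IRb stay exact reverse complements.
- Planted SSR runs and repeat arms get pinned flanking bases so no
  pairing relation extends them by chance; planted mismatches are centred
  in the arm so no exact segment reaches the 30-bp minimum and the finder
  reports the full planted window at the planted distance.
- The four single-copy junction bases are pinned to `A` (an IR extension
  would need its mirror to be `T`), so detected and planted partitions
  agree exactly; these positions are excluded from mutation.
- Haplotype divergence is i.i.d. substitution at 0.001 per site (0.05 in
  hotspot intervals, aligned to the 500-bp window grid), applied to
  LSC+IRa+SSC with IRb re-mirrored; planted motifs are excluded so their
  truth holds in every haplotype. No indels by default, so the emitted
  alignment is the haplotypes themselves, gap-free.
- The two-gene inversion reverse-complements the psbM–petN block (±20 bp
  of intergenic margin) in the last haplotype and flips its features.
- Pileups draw edited reads `Binomial(coverage, level/100)` per carrying
  replicate; optional background positions add uniform read errors at a
  configurable rate, providing candidate false positives. Counts are
  negative binomial (dispersion 0.05) or Poisson, with per-sample library
  multipliers recorded in the truth.

What the generator does **not** emulate — hence what a green test does
not establish: real read-level artifacts (mapping bias, strand bias, PCR
duplicates), indel alignment, IR boundary shifts between haplotypes,
compound/interrupted SSRs, polyA-enrichment depletion of organellar
transcripts, and linked substitution processes. Tests on this generator
validate the *computational contracts*; they are not a claim that the
pipeline's biological error modes are fully characterized.

On the error-rate property: the replicate filter controls false positives
*per site*, and that is the form the tests assert (at 1% read error and
20× coverage a non-edited site passes the filter far less than 5% of the
time, estimated over seeds). Genome-wide, across hundreds of candidate C
positions at high coverage, some error-driven site will occasionally pass
any fixed two-replicate threshold; users scanning whole transcriptomes at
high depth should raise `min_level` or `min_replicates`.

## Numerical and formatting conventions

1-based inclusive coordinates everywhere in the public interface (BED
export converts to 0-based half-open); `%GC` and region fractions round
half-up to one decimal for table parity; π is reported unrounded;
`hclust` tie-breaking follows input order, making dendrograms
deterministic; all generator functions restore the caller's RNG state.
The pipeline manifest records package version, parameters, per-stage
status and output checksums; identical seeds reproduce identical output
bytes for the deterministic stages, which the test suite asserts.

## Limitations

Reading and writing GenBank is limited to the feature types plastome
records use (CDS/tRNA/rRNA with joins, complements, partial markers and
`/gene`, `/product`, `/pseudo` qualifiers); richer records should go
through FASTA+GFF3. The inversion detector classifies only single-block
reversals, at gene granularity. The repeat finder's collapse convention
is one defensible choice among several used by published tools; the
exhaustive-oracle tests pin down exactly which one this package
implements. Alignments are inputs — the package never computes one — and
editing calls are only as good as the upstream unique-read mapping the
pileups came from.
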