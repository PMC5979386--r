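---
title: "Methods: small RNA miRNA discovery and degradome-based target validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA miRNA discovery and degradome-based target validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

degradomiR re-implements, as a tested and reusable pipeline, the analysis
strategy commonly applied to plant species without a reference genome:
small-RNA libraries are cleaned and collapsed into unique tags; known
miRNAs are identified against a miRBase-style catalog of plant matures;
novel miRNAs are predicted by folding the unigene sequence flanking
perfectly mapped tags; expression is quantified in RPM and compared
between tissues by a fold-change rule; miRNA cleavage targets are
validated from degradome (PARE) libraries with CleaveLand-style scoring,
five-category site classification and permutation p-values; and target
gene sets are tested for GO term enrichment against the whole unigene set
as background. A first-class synthetic-data generator plants miRNA
precursors, tissue-specific expression and cleavage sites into random
unigenes and emits a machine-readable truth table, so the entire pipeline
can be exercised end-to-end with known answers.

# Preprocessing

Raw reads are trimmed at the leftmost 3' adaptor occurrence; adaptor
evidence is a full-adaptor match anywhere in the read or an exact match of
at least 5 nt of the adaptor 5' end at the read 3' end. The source
protocols do not define "junk reads" precisely, so the package uses an
explicit, testable substitute: reads containing N, or with a single
nucleotide making up at least 80% of the read, are junk. Survivors are
restricted to 18-30 nt — the gel size-selection window of typical sRNA
libraries — and collapsed into unique tags with per-library counts.

Each library's clean-read total is fixed at this point and is the RPM
denominator (`rpm = count / clean_total * 1e6`), so that the retained-tag
RPM sums to exactly $10^6$ per library when nothing further is removed.
Structural-RNA contaminants (rRNA, tRNA, snRNA, snoRNA) are then removed
by exact substring matching against the contaminant records on either
strand; exactness makes the rule deterministic and oracle-checkable,
standing in for the database searches (Rfam/GenBank) whose parameters the
protocols leave unstated.

# The folding engine

Novel-miRNA prediction and precursor validation need a secondary-structure
folder. The package ships its own: an exact dynamic program (in C++) over
non-crossing structures with Watson-Crick and G:U pairs, hairpin loops of
at least 3 nt, and a simplified nearest-neighbor energy model — a 6x6
stacking table of Turner-magnitude free energies (kcal/mol at 37C),
tabulated hairpin/bulge/internal loop initiations with
$1.75\,RT\,\log$ extrapolation, a linear asymmetry penalty capped at
3 kcal/mol, affine multiloops (3.4 close + 0.4 per branch + 0.1 per
unpaired base), and no dangling ends or terminal-AU terms. Internal and
bulge loops are capped at 30 unpaired bases, the standard restriction
that keeps folding $O(n^3)$.

Because the DP minimises exactly the same decomposition that
`structure_energy()` evaluates on an explicit dot-bracket string, the
folder can be checked against brute force: for sequences up to 12 nt all
structures are enumerable, and the DP energy must equal the enumeration
minimum everywhere. This oracle is part of the test suite (1,000 random
sequences). Since the stacking magnitudes are Turner-like, hairpin
stability thresholds stated in kcal/mol remain meaningful, and the
package keeps -18.2 kcal/mol — the ceiling observed across validated
plant precursor sets of this kind — as the default acceptance ceiling
rather than re-calibrating a model-specific one.

# Known miRNA identification

Identification follows four steps. (1) Tags are compared with the mature
catalog: full-length identity is a *perfect* hit; otherwise the best
ungapped offset must align tag and mature with a mismatch-free
overlapping span of at least 16 nt (*overlap* tier, accommodating
cross-species end variation). Whether internal mismatches should be
tolerated inside the overlap is not specified by the protocols this
mirrors; the package implements the stricter mismatch-free reading.
(2) Within each family — identifiers collapse by stripping the species
prefix, the -5p/-3p arm and letter/isoform suffixes, so ath-miR166a-3p
parses to miR166 — the most abundant member becomes the family template
(ties break lexicographically). (3) All tags are re-aligned to the
templates end-to-end without gaps, allowing at most 2 mismatches in the
overlap and at most 2 nt of tag overhang on either side ("free gaps" in
the source protocols is read as gap-free, since the named aligner is
ungapped in this mode); each tag counts toward its single best template.
Family expression is the summed count, converted to RPM, and a family is
accepted only above 2 RPM in at least two libraries. (4) The template is
located on the unigenes and its flanking sequence folded; families
without a validating hairpin are set aside as pseudo-miRNAs.

## Hairpin validation

A candidate precursor is accepted iff (a) one stem-loop holds at least
70% of all paired bases, where a stem-loop is a helix stack region:
consecutive pairs may be separated by at most 6 unpaired bases and no
multiloop branching; (b) the mature lies entirely on one arm, not
crossing the terminal loop; (c) at least 14 mature bases are paired; and
(d) the MFE is at or below the ceiling (-18.2 kcal/mol by default). The
6-nt gap bound in (a) operationalises "helix stack region": without it,
arbitrarily large interior loops would chain into one nominal stem and
shuffled sequences would pass far too often. Under these rules about
3-5% of mononucleotide shuffles of a typical (~150 nt) planted precursor
still validate — hairpins are easy to form by chance — which is why the
abundance cutoff and expression structure carry part of the specificity.

## Novel prediction, star and palindrome

Unannotated tags of 20-23 nt above the abundance cutoff are mapped
perfectly to the unigenes (both strands; tags hitting more than 20 loci
are discarded as repeat-derived). Around each locus, 250 nt of flanking
sequence per side is excised and folded; the stem-loop containing the
tag is localised in that fold, trimmed with growing context (10/25/45 nt)
and re-validated. If localisation fails — long windows sometimes refold
the mature into alternative context pairings — a small grid of
asymmetric windows of typical precursor extent around the mature is
tried instead. Accepted candidates are deduplicated by precursor locus,
most abundant tag first, which also absorbs star and isomiR reads of the
same hairpin, and loci of accepted known miRNAs are excluded.

The star span is derived from the pair table as the opposite-arm segment
pairing the mature with 2-nt 3' overhangs (partner of mature-end-2 to
partner of mature-start + 2); the star is *detected* when a sequenced
tag matches that span exactly, with up to 1 nt of slack per end. A locus
is flagged palindromic only when bidirectional transcription yields the
same hairpin: the reverse complement must itself validate with the
reverse-complemented mature *and* reproduce, after mirroring, at least
80% of the forward base pairs. The second condition matters: G:U pairs
map to unpairable C:A on the antisense strand, so ordinary wobble-bearing
precursors fail it, while a true palindrome passes trivially.

# Quantification and differential expression

RPM and FPKM follow their standard definitions. Differential calls
between tissue pairs use the fold-change rule appropriate when no
biological replicates are available: significant iff |log2 FC| > 1,
computed on RPM with a 0.01 RPM pseudocount. The pseudocount keeps
tissue-specific features (0 vs >2 RPM) significant while bounding the
fold change; the underlying count-based test of the original Expdiff
method is deliberately not reproduced, since the fold-change threshold
alone determines the calls here. Antisymmetry (swapping the pair negates
log2 FC exactly) and scale invariance are tested properties.

# Degradome target calling

Degradome tags are cleaned (>= 15 nt, no N, contaminant-free) and mapped
as exact sense-strand substrings of the unigenes; a tag hitting m
positions contributes count/m to each (fractional multireads). Profiles
are indexed by the tag 5' end: a pile-up at one position marks a
candidate cleavage site.

Complementarity is scored with the Allen penalty: per position against
the reverse complement of the miRNA, match 0, G:U 0.5, mismatch 1
(gap-free windows by default), doubled at miRNA positions 2-13.
Alignments scoring <= 7.0 are retained — constants follow the "standard
criteria" of CleaveLand-style pipelines and are configurable. The
cleavage position is the transcript coordinate opposite miRNA nucleotide
10 (the canonical 10-11 cut), and a candidate needs at least one tag at
that position.

Categories follow the five max/median rules: 0 — more than one tag at
the site, equal to the transcript maximum, unique maximum; 1 — as 0 but
the maximum is attained more than once; 2 — more than one tag, below the
maximum but above the median; 3 — more than one tag, at or below the
median; 4 — a single tag. The median is taken over nonzero positions
only; a zeros-inclusive median collapses to 0 on long transcripts and
would make category 3 unreachable.

The p-value is a permutation test (the exact null model of the original
pipeline differs across versions, so this is a stated substitute):
`n_perm` mononucleotide shuffles of the miRNA, counting shuffles that
achieve, anywhere on the transcript, a window scoring at most the
observed score whose cleavage position carries at least the observed tag
count, with the add-one estimator (1 + b)/(n_perm + 1). The null unit
used to check calibration is a random tagged position on a random
transcript (its implied window score being the observed statistic);
under that null the test is conservative, and its empirical size at 0.05
and 0.01 is verified by simulation in the test suite. Sites with
p <= 0.05 are reported, per library, as in per-tissue validation designs.

Specificity is assessed with decoy miRNAs (shuffles of the planted
matures that receive no reads). Chance complementarity can still give a
decoy an occasional score-<=7 window over a lone background tag —
a category-4 call with a small per-transcript p-value, since the best
window is selected across hundreds of transcripts while the p-value
conditions on one. Following the target-decoy convention, decoy calls
are therefore counted under exactly the same acceptance rule as the
planted sites they are compared against (category <= 1, p <= 0.05);
the any-category decoy count is reported alongside for transparency.

# GO enrichment

Each term annotating at least one target gene is tested with the exact
upper hypergeometric tail. The whole unigene set — annotated or not — is
the background N, and, symmetrically, the whole target set is the draw
size n. Keeping unannotated genes in the draw as well as in the
background is what makes the test calibrated under random labelling
(~5% of terms below p = 0.05), which the suite verifies by simulation;
counting only annotated targets in n while keeping all genes in N
would make the test anticonservative under the same simulation. Raw
p-values are primary, mirroring the convention of reporting unadjusted
enrichment; a Benjamini-Hochberg column is emitted as a clearly labelled
extension. GO-DAG ancestor propagation is out of scope.

# The synthetic study

`synthetic_config()` defaults describe the emulated design: three tissue
libraries (flowers, young fruit, ripe fruit) of 100,000 reads each; 30
planted known miRNAs (alternating perfect catalog matches and >= 16-nt
end-shift variants — substitution variants would leave no mismatch-free
overlap and could never be recovered under the matching rule), 20 novel
miRNAs with the 20/21/22/23-nt length mix observed in plant candidate
sets, and 20 decoy catalog entries (shuffles of planted matures,
receiving no reads). Planted precursors are stem-loops with the
mature/star duplex riding on an imperfect complementary lower-stem
extension, 70-160 nt overall, with 1-2 planted star mismatches and
several G:U wobbles; ~15% are planted on the minus strand. Expression is
log-uniform over 10-1000 RPM with flat/high/low/tissue-specific
patterns, floored so every planted miRNA exceeds the acceptance cutoff;
star reads are planted at 5% of the mature (capped at 8 RPM, below the
10 RPM ceiling typical of passenger strands). Reads carry the full 3'
adaptor; 5% are contaminant windows, 1% junk, and the rest noise (15%
unigene degradation fragments, the remainder random sequence with a
24/21-nt bimodal length profile). Degradome libraries place 80% of each
target transcript's tags exactly at the planted cleavage position
(expected category 0), the rest uniformly, plus global background,
contaminant and short-tag noise.

The generator emulates planted signal structure, not every property of
real libraries: there are no sequencing errors by default (an optional
per-base error rate exists; identification is exact-match/<= 2-mismatch,
so errors are a robustness add-on, and recovery tests run error-free),
no ligation or PCR biases, no isomiR spectrum beyond 1-nt end variants,
and unigene sequence is random rather than transcriptome-like. Passing
recovery tests therefore demonstrates correctness of the pipeline's
logic under its stated assumptions, not performance on real tissue
libraries.

# Numerical choices and problem sizes

All tie-breaks are deterministic (count descending, then lexicographic);
coordinates are 1-based inclusive, minus-strand loci stored as
plus-strand intervals with a strand flag; DNA is the on-disk alphabet
and RNA the folding alphabet, converted only at those boundaries.
Floating-point comparisons in the DP traceback and in category equality
use 1e-7/1e-9 tolerances. The test suite runs the full study at its
default scale (seed 42, 100k reads x 3 libraries) once and shares it
across recovery checks; determinism is demonstrated on a smaller bundle
(20k reads, 10 planted miRNAs) where two identical invocations must
reproduce the result tables byte for byte; folding-oracle and
p-value-calibration simulations use 1,000 and 500 replicates. These
sizes were chosen so the whole suite completes comfortably on one CPU
while every planted feature count stays large enough for the stated
tolerances to be meaningful.

# Known limitations

The energy model omits dangles, terminal-AU penalties, special hairpin
sequences and coaxial stacking, so absolute MFE values differ from full
Turner-model folders (an external thermodynamic folder can be swapped in
behind `fold_rna()`'s interface); the -18.2 kcal/mol ceiling was kept
because the stacking magnitudes match, but it is configurable. Known
matures that never map to a unigene are reported as pseudo-miRNAs rather
than rescued by genome context, since unigene space is the only mapping
space. Degradome evidence is required for every reported target; no
prediction without tags, and no translational-repression inference.
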