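# degradomiR

Small RNA miRNA discovery and degradome-based target validation for
plant species without a reference genome.

Many fruit crops (blueberry among them) have no usable genome assembly,
so their small-RNA biology is analysed against an assembled *unigene*
(transcript) set instead: sRNA-seq reads are cleaned and collapsed into
unique tags, known miRNAs are identified against the miRBase catalog of
plant matures, novel miRNAs are predicted by folding the unigene
sequence around perfectly mapped tags into stem-loop precursors, and
miRNA-guided mRNA cleavage is validated experimentally with degradome
(PARE) sequencing, in which a pile-up of 5'-monophosphate fragment ends
at one transcript position marks the cut site. degradomiR implements
that entire workflow as a tested R package, together with a
synthetic-data generator that plants miRNAs, expression patterns and
cleavage sites with a machine-readable truth table, so every stage can
be verified end-to-end against known answers.

## What it computes

* **Preprocessing** — 3' adaptor trimming, junk/length filtering
  (18–30 nt), collapsing into unique tags with per-library counts and
  RPM (`count / clean_total × 10⁶`), exact-substring removal of
  rRNA/tRNA/snRNA/snoRNA, length distributions.
* **Known miRNAs** — full-length identity to a catalog mature
  (*perfect* tier) or a mismatch-free ungapped overlap ≥ 16 nt
  (*overlap* tier); the most abundant member of each family becomes the
  quantification template; tags assign to templates with ≤ 2 mismatches
  and ≤ 2 nt terminal overhangs; families are accepted above 2 RPM in
  ≥ 2 libraries and must fold into a validated hairpin precursor
  (otherwise pseudo-miRNA).
* **Novel miRNAs** — unannotated 20–23-nt tags mapped perfectly to
  unigenes; flanking sequence folded with the built-in
  nearest-neighbor minimum-free-energy engine (exact dynamic
  programming, Watson–Crick + G:U, stacking + loop penalties); hairpins
  accepted when one stem holds ≥ 70 % of pairs, the mature sits on one
  arm with ≥ 14 bases paired, and MFE ≤ −18.2 kcal/mol. miRNA* spans
  (2-nt 3' overhang rule) and palindromic (bidirectionally transcribed)
  precursors are reported.
* **Quantification / DE** — RPM and FPKM; between-tissue calls by the
  replicate-free rule |log₂ FC| > 1 on pseudocounted RPM.
* **Degradome targets** — exact sense-strand tag mapping (fractional
  multireads), Allen complementarity scoring (match 0, G:U 0.5,
  mismatch 1, doubled at miRNA positions 2–13; keep ≤ 7.0), cleavage
  opposite miRNA nucleotide 10, five-category site classification
  (max/median rules), permutation p-values (≤ 0.05), per library;
  T-plot tables, text alignment reports and a Cytoscape-importable
  edge list.
* **GO enrichment** — exact hypergeometric upper tail per term with the
  whole unigene set as background; raw p-values primary, BH column as a
  labelled extension.

## Worked example

```r
library(degradomiR)

cfg <- synthetic_config(seed = 11, n_unigenes = 60, n_known_mirnas = 6,
                        n_novel_mirnas = 4, n_decoy_mirnas = 4,
                        reads_per_library = 20000, n_target_sites = 8,
                        degradome_tags_per_library = 6000,
                        outdir = file.path(tempdir(), "bundle"))
bundle <- generate_dataset(cfg)
run <- run_all(pipeline_config_from_bundle(
  bundle, outdir = file.path(tempdir(), "run"), seed = 7,
  params = list(degradome = list(n_perm = 200))))

run$summary$counts
#>  known_perfect known_variant novel targets_total targets_flowers
#>              3             3     6             9               5
#>  targets_young_fruit targets_ripe_fruit targets_shared_2 targets_shared_all
#>                    9                  7                4                  4
```

All 6 planted known miRNAs come back in their planted class (3
perfect-match, 3 ≥ 16-nt-overlap variants), the 4 planted novel
hairpins are among the novel calls, and none of the 4 shuffled decoy
catalog entries is accepted. The miRNA table carries expression,
precursor locus, MFE and star status:

```r
head(run$mirnas[, c("id", "class", "sequence", "rpm.flowers", "mfe")], 4)
#>      id         class              sequence rpm.flowers        mfe
#>  miR156 known_perfect AGGCAGCACATGTTTTCTCAC    252.5253 -113.20000
#>  miR157 known_variant TGGAATACCATAGGGTCGACG    757.5758  -42.08368
#>  miR159 known_perfect TGCAGTCTTGGAAAGCGTTGA    101.0101 -100.90000
#>  miR160 known_variant CGTCATGGTCGACCGCTGAAG    303.0303  -65.88368
```

Called cleavage sites report the supporting degradome tags, the
category (0 = unique transcript-wide maximum at the cut) and the
permutation p-value; the planted sites are recovered at category 0 with
p at the permutation floor:

```r
head(run$sites[, c("mirna_id", "transcript", "cleavage_pos",
                   "tags_at_site", "category", "p_value")], 3)
#>  mirna_id   transcript cleavage_pos tags_at_site category     p_value
#>    miR160 Unigene00002         1196           41        0 0.004975124
#>    miR164 Unigene00027          421           43        0 0.004975124
#> novel-001 Unigene00051          144           43        0 0.004975124
```

```
miR160 -> Unigene00002 | library flowers | category 0 | p = 0.004975 | score 0.0
             41
              v
5' CUUCAGCGGUCGACCAUGACG 3'  Unigene00002:1185-1205
   |||||||||||||||||||||
3' GAAGUCGCCAGCUGGUACUGC 5'  miR160
```

The number above the arrow is the count of degradome tags whose 5' end
sits exactly at the cleavage position. A command-line wrapper for the
same workflow lives in `inst/cli/degradomir.R`
(`simulate` and `all` subcommands with a YAML config).

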