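---
title: "pgxpipe methods: models, thresholds and the synthetic stated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pgxpipe methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The analysis

A proteogenomic re-annotation study asks three questions of a predicted
annotation: which predicted protein-coding genes are actually translated,
which predicted noncoding RNAs are misannotated and do code, and which
alternative transcript isoforms leave a protein-level trace. `pgxpipe`
answers them from two inputs: candidate sequences (gene models with exon
structure, lncRNAs, isoforms) and a peptide-spectrum-match (PSM) table from
any search engine. Spectrum scoring itself is out of scope — the PSM table
is the contract.

## Coordinate conventions

Genomic coordinates are 1-based closed (GFF3); mature-mRNA coordinates are
0-based half-open. Every conversion runs through `genomic_to_mrna()` /
`mrna_to_genomic()`, and a property test asserts the round trip is the
identity, so the nucleotide arithmetic that the NMD rule depends on lives
in one audited place.

## ORF calling

Forward strand only, three frames: long-read isoforms and annotated mRNAs
are orientation-resolved, and a six-frame search would double the decoy
space for no expected gain. ORFs start at ATG and run to the first in-frame
stop (or the transcript end, flagged `has_stop = FALSE`); nested starts
sharing a stop collapse to the most 5' ATG. 5'-partial ORFs (no ATG) are
off by default (`require_atg = FALSE` enables them). The lncRNA filter
"longer than 100 aa" is read strictly: an exactly-100-aa ORF is excluded
(`length_aa >= 101`); the boundary is tested. Codons containing N translate
to X and never terminate an ORF. Standard nuclear code, stops TAA/TAG/TGA.

## Peptide evidence

In-silico digestion is tryptic — cleave after K/R, suppressed before P (the
field default; configurable) — with up to 2 missed cleavages and a 7–50 aa
detectability window. The bounds are conventional, not taken from any
single study, and configurable. I and L are isobaric and collapsed on both
sides of every match, otherwise isoform uniqueness would be overstated.

Matching is plain substring search against three databases (annotated
proteins, lncRNA ORFs, isoform ORFs). Uniqueness is hierarchical: a peptide
mapping to exactly one lncRNA/isoform ORF entry is `isoform_unique`; one
whose mappings all belong to one gene is `gene_unique`; anything else is
`shared` — in particular a peptide found in both an annotated protein and a
lncRNA ORF validates neither. Unmapped peptides are kept and flagged (they
are the input to novel-reading-frame discovery), never an error.

FDR control is target-decoy with reversed sequences and the plain
`D/T` estimator; the cutoff is the smallest observed score keeping
`D/T` under the threshold, with ties accepted. Protein-level control
repeats the procedure on best-peptide scores. Two known properties are
documented rather than hidden: `D/T` (versus `(D+1)/T`) is slightly
anti-conservative, and taking the smallest qualifying cutoff selects a
favourable fluctuation, so at very small problem sizes the realized FDP
runs to roughly twice nominal (measured ≈ 0.02 at ~200 accepted
PSMs/world, ≈ 0.010–0.011 at realistic sizes; the acceptance suite checks
the pooled value across 20 simulated worlds).

A protein is validated with ≥ 2 distinct peptide keys. lncRNA/isoform ORFs
additionally need ≥ 1 isoform-unique peptide: an isoform sharing every
peptide with its gene's annotated protein is indistinguishable from it, so
counting it as "verified" would be unfalsifiable. Spectral counts of shared
peptides are credited to gene-level entries but not to isoform-level ones
(no double counting at isoform resolution).

## Quantification

NSAF per sample: `nsaf_i = (SpC_i/L_i) / Σ_j (SpC_j/L_j)`, normalized
within sample (the natural reading of "all identified proteins"; a union
denominator would mix the two samples' identification depths). Reported
NSAF is pseudocount-free and sums to 1 (tested to 1e-9). Fold changes are
computed on (+0.5 SpC) pseudocounted NSAF so that tissue-specific proteins
(SpC = 0 in one sample) get a finite, monotone fold change; thresholds
fold ≥ 4 / ≤ 0.25, boundary inclusive. With pseudocounts the direction
duality holds exactly: up(A→B) ⇔ down(B→A). No p-value is attached to DE
calls — the identification-level FDR is not a DE significance test, and the
fold-change rule is deliberately conservative. Between-sample correlation
is Pearson on log10 NSAF over jointly nonzero proteins (Spearman
available).

## NMD rule

`d = last_junction_pos − stop_end` in mature-mRNA space, where
`last_junction_pos` is the cumulative spliced length of all exons but the
last and `stop_end` is the exclusive end of the stop codon. `d ≥ 50` (the
literature's "at least ~50 nt" rule of thumb; threshold is a flag) flags
NMD; single-exon transcripts and stop-less ORFs never do. Measuring from
the stop codon's last base is a choice — the rule's source does not fix the
measuring point, and the alternative (first base) shifts `d` by 3 nt; the
boundary `d = 50` is classified NMD and tested on both sides.

## Domain categories

Domain sets (accession strings; copy number ignored — the comparison is
set-theoretic) of a gene's validated isoforms are compared pairwise:
identical / superset / partial overlap / disjoint, which provably
partitions all nonempty-set pairs (exhaustively tested over a 4-domain
universe). For > 2 isoforms the gene takes the label of its most divergent
pair (order: identical < superset < partial < disjoint) — an
interpretation, retained with the full pair list for audit, since per-gene
categories are otherwise undefined. Isoforms with no assigned domains are
dropped with a logged reason.

## Enrichment and report

Term enrichment is the upper-tail hypergeometric probability
(`phyper(k-1, K, N-K, n, lower.tail = FALSE)`) with a raw p < 0.05
headline filter, matching common annotation-tool practice; BH-adjusted
values are emitted alongside because uncorrected enrichment over many terms
is statistically fragile — both are in the output, labelled. Percent
formatting: integer percents for overlap shares, 1 decimal for
compositions, 2 decimals where convention prints two; rounding is half away
from zero, and composition comparisons in tests allow ±0.1 because printed
study values are sometimes truncated rather than rounded.

Protein molecular weights use average (not monoisotopic) residue masses
plus one water — the intact-protein convention — binned at 5 kDa.

# The synthetic stated world

`sim_config()` defaults are the conditions the analysis assumes, chosen
once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 300 | desk-scale but large enough for stable FDR/overlap behaviour |
| `n_lncrnas` | 60 | same |
| `frac_genes_detected` | 0.32 | roughly a third of an annotated proteome is seen in one study |
| `frac_lncrna_coding` | 0.5 | about half of predicted lncRNAs harbor a real ORF |
| `frac_isoform_nmd` | 0.22 | NMD-flagged share of an isoform catalogue |
| `frac_isoform_detected` | 0.035 | small fraction of isoforms with isoform-unique support |
| `mean_isoforms_per_gene` | 2 | kept low for desk scale (real catalogues run higher) |
| `decoy_score_shift` | 6 | clearly separable search scores (sd 1); FDR, not score overlap, is under test |
| `spc_dispersion` | 0.5 | substantial overdispersion typical of spectral counts |
| `tissue_effect_sd` | 0.8 | null biological variation between tissues |
| `frac_forced_de` | 0.1 | planted \|log2FC\| ≥ 2 effects for recovery tests |
| `frac_single_peptide` | 0.05 | exercises the two-peptide rule |
| `noise_psm_frac` | 0.05 | incorrect-target PSMs, matched 1:1 by decoys |

Genes get 4–6 exons, a 180–380 aa CDS, an ATG-free 5' UTR (so the designed
ORF is the ORF), and a last exon containing the stop. Isoforms are built by
three geometries: in-frame exon skipping (shorter protein, same stop,
non-NMD — and the source of isoform-unique junction peptides), frameshift
exon skipping (novel C-terminus, premature stop verified ≥ 50 nt upstream
of a remaining junction — an NMD isoform that is still MS-detectable), and
alternative last exons with the junction placed a controlled distance from
the stop (≥ 50 nt ⇒ NMD, < 50 ⇒ not). Noncoding lncRNAs are rejection-
sampled until they contain no ≥ 101 aa ORF. The generator re-derives each
isoform's realized ORF and NMD state from its own constructed geometry, so
truth labels are arithmetic facts about the sequences, not echoes of the
classifier (the classifier reaches them through GFF3 round trips and
coordinate conversion — a genuinely different path).

Abundances are log-normal (sdlog 0.7); spectral counts per tissue are
negative binomial with mean = abundance × protein length — the length
dependence NSAF exists to remove — and dispersion 0.5. A low total thins
the observed peptide set, possibly to zero in one tissue: absence is
informative and creates the tissue-specific identifications the overlap
report summarizes. No published abundance distribution was available for
this choice; it is a modeling convention, flagged here. Decoys come from
the pipeline's own `reverse_decoy()`, so the FDR stage sees exactly the
decoy space it models; incorrect-target PSMs (random peptides with
decoy-distributed scores, marked in an auxiliary `truth_correct` column the
pipeline never reads) are planted 1:1 with decoy PSMs, which is what makes
the D/T estimator calibrated and the realized FDP measurable.

**Preregistered DE-recovery bounds.** The log2-ratio noise SD implied by
the model is `sqrt(2 (1/μ + 1/size)) / ln 2 ≈ 1.5` at μ ≈ 17, size = 2.
Hence median absolute log2FC error ≈ 0.67 × 1.5 ≈ 1.0, sensitivity for
planted |log2FC| ≥ 2 effects ≈ 0.6, specificity ≈ 0.75. The frozen test
bounds — sensitivity ≥ 0.45, specificity ≥ 0.65, median |error| ≤ 1.4 —
are these predictions with sampling slack at ~100 quantifiable proteins.

**What a green test does not establish.** The generator emulates the
statistical structure the analysis assumes, not real data: no missed-
cleavage frequency model, no retention time or spectrum realism, no
homologous gene families (real shared-peptide ambiguity is much heavier),
uniform random nucleotide composition, two isoform geometries only, and
score distributions that are honest about rank but not about any engine's
score scale. Passing truth-recovery tests shows the pipeline implements
its stated rules exactly; it does not show those rules are optimal for any
particular instrument or genome.

# Numerical and degenerate-input choices

* FDR: error (not empty set) when no cutoff satisfies the threshold;
  acceptance is tie-inclusive at the cutoff; thresholds are monotone
  (tested).
* NSAF: all-zero samples are an error; zero-SpC proteins stay in the
  denominator trivially and report NSAF 0.
* Empty sequence → `find_orfs()` returns an empty table, `digest()` an
  empty set; empty domain sets are an error at pair level, a logged skip at
  gene level; empty transcript sets are an error in `nmd_composition()`.
* Determinism: one integer seed governs all generator randomness; outputs
  are hash-stable (manifest of md5s; tested by running twice).
* All writers are timestamp-free; GFF3 is written by a deterministic
  in-package formatter and read back via rtracklayer.

# Known limitations

* The D/T estimator's small-sample anti-conservatism (above).
* Protein-level FDR at small database sizes is coarse: with T target groups
  the first surviving decoy forces the cutoff above it whenever 1/T exceeds
  the threshold. At the default simulation scale T ≈ 180 and the effect
  vanishes; tiny worlds feel it.
* Shared-peptide spectral counts are credited to every gene-level group
  that contains them (no splitting); parsimony-style protein grouping is
  out of scope.
* `quantify` as a standalone subcommand lacks the GFF3-derived gene map and
  treats each protein as its own gene for uniqueness; `run-all` uses the
  full map.
* The NMD rule is the 50-nt last-junction heuristic only — no uORF, long
  3'-UTR, or EJC-deposition modelling.
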