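---
title: "Methods: subgenome assignment, marker design and comparative block mapping in allomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome assignment, marker design and comparative block mapping in allomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An allotetraploid crop such as Indian mustard carries two complete diploid
genomes (here called A and B). Its transcriptome therefore mixes three kinds
of sequence relatives: *homoeologues* (the A and B copies of the same gene,
separated since the two diploid lineages split), *paralogues* (copies within
one genome left over from an older whole-genome triplication), and *alleles*
(the variants segregating between two accessions). Designing co-dominant SNP
markers and building a genetic map requires separating these three layers:
an allelic SNP is mappable, while a homoeologue-specific variant (HSV) or
paralogue-specific variant (PSV) is a fixed difference that a genotyping
assay must tolerate, not score.

`allomap` implements that workflow end to end: contig-to-subgenome
assignment against dual diploid references, allelic SNP discovery with
HSV/PSV classification, KASP suitability filtering and marker formatting,
doubled-haploid (DH) linkage mapping with Kosambi distances, and painting of
the resulting linkage groups with the 24 ancestral crucifer gene blocks
(A--X) to compare block arrangement and fragmentation between the two
subgenomes. A simulator generates complete studies with known truth, so
every stage is testable without external data.

## The simulator: what it emulates

`simulate_allopolyploid()` builds a study in the order evolution did:

1. An ancestor of `n_blocks` blocks (default 24, labelled A--X) with
   `genes_per_block` genes; each gene gets an ortholog ID `At<chr>g<num>`
   laid out so each block is a contiguous, non-overlapping ID interval on
   one of five chromosomes.
2. Triplication into LF/MF1/MF2 copies with paralogue divergence (default
   0.12 substitutions/site between copies) -- the older event.
3. An A/B lineage split with homoeologue divergence (default 0.07) -- the
   younger event. The defaults keep the ratio of the two divergences close
   to the ratio of the commonly cited paralogue vs homoeologue divergence
   times for these genomes (~12 vs ~7 Mya).
4. Independent fractionation per lineage: per-class Bernoulli retention
   (defaults LF 0.85, MF1 0.55, MF2 0.35, least-fractionated highest).
   Independence between lineages is what creates the single-copy,
   two-copy and B-unique families that the marker categories (i/ii/iii)
   classify. The default retention probabilities reproduce a realistic
   mixture of one-, two- and three-copy families, with roughly 4% of
   families private to one genome.
5. Two accessions per genome with allelic divergence (defaults 0.005 for
   A, 0.003 for B: the A subgenome pair is the more variable one, the
   asymmetry the analysis must reproduce).
6. Layout of (block, class) segments over 10 A and 8 B linkage groups,
   followed by `n_rearrangements` logged translocation/split events per
   genome. Every split leaves at least two genes on each side so that
   two-marker evidence rules can in principle detect it; the event log
   replays deterministically, which is what "truth" means for the
   fragmentation tests.
7. Fragmentation of each accession transcript into one or two contigs
   (Beta-distributed covered fraction, mean `contig_coverage_mean` = 0.8)
   with Poisson per-contig read depth (mean 20, floor 1).
8. A DH genotype matrix simulated as one recombinant gamete per LG and
   individual: a Markov walk whose adjacent-interval recombination
   fraction is the inverse Kosambi transform r = 0.5·tanh(d/50) of the cM
   gap. This is a stationary renewal approximation -- it reproduces
   adjacent-interval rf exactly and imposes no additional interference
   structure beyond the Kosambi relation.

The substitution model is uniform random replacement (Jukes--Cantor-like),
no indels by default (`indel_rate = 0`) because the variant analysis counts
substitutions; transitions/transversions, rate heterogeneity, CDS selection
and sequencing error are deliberately not modelled. Depth is per contig,
not per base: the depth filter is applied per SNP and the contig mean is
the only depth a de novo assembly provides per contig. Exon structure
(1--5 exons, random junctions at least 50 bp from the ends) exists purely
to exercise the exon-junction screen; the A reference also gets a genomic
FASTA with random introns inserted, used by the orphan screen.

What passing tests on these data do *not* show: robustness to chimeric
contigs, assembly errors, organellar transcripts, paralogue-collapsed
assemblies or genotyping error -- none of these failure modes is simulated.

## Two-step subgenome assignment

Step 1 is a translated search of every contig against the A-genome protein
set: six-frame translation, candidate shortlisting by shared amino-acid
4-mers, local alignment (BLOSUM62, gap open 11 / extend 1), and
Karlin--Altschul E-values (gapped parameters lambda = 0.267, K = 0.041)
against the database residue count, thresholded at E <= 1e-5. The point of
this step is the E-value contract and the gene-family key, not BLAST
bit-reproducibility.

Step 2 compares each contig with a protein hit at the nucleotide level
against both reference sets and assigns it to the genome of its
maximum-identity hit. The keep rule is the contrapositive of the published
removal rule: a contig survives only if some hit exceeds 80% identity over
more than 100 aligned bases. An exact identity tie between the two genomes'
best hits is called `ambiguous` and excluded downstream -- the conservative
choice for marker design. Contigs without a protein hit go through the
orphan branch: matches to the A genomic sequence are removed (genomic,
e.g. intron-bearing fragments), remaining matches to the B transcriptome
become `B_specific`, the rest are removed as unclassified.

Engineering note: candidate search is one k-mer join per reference set
(12-mers for nucleotide, strand picked per candidate) and identity is first
estimated by anchoring on the modal shared-k-mer diagonal and comparing the
ungapped overlap -- the exact-match-anchoring idea of MUMmer-class engines.
True local alignment (match +1 / mismatch -1, gap open 4 / extend 2) is
always used to refine any hit that could change an outcome: weakly anchored
pairs, best identities inside a 40--90% band around the keep/remove
threshold, and near-ties (< 3 points) between the genomes' best identities.
All thresholds of the step (E-value 1e-5, 80%, 100 bp) are data, set in
`assign_config()`.

Gene models are keyed by the protein-step best hit for A-verdict contigs
(the family key the protein database provides) and by the nucleotide-step
best hit otherwise; the `step` field records which. Coverage of a gene
model is the union of its contigs' strand-normalised reference spans
(1-based, closed) over the reference length.

## Variants, classes and KASP filters

Per accession and gene model, contigs are projected onto the reference gene
and merged into a consensus (conflicting overlaps become `N`; depth at a
position is the maximum contig depth covering it). The allelic alignment of
the two accessions' consensus arrays yields one variant per substitution
column; indel and `N` columns are never variants.

Site classes follow the definitions: accessions differing within one
genome = allelic SNP; accessions concordant but the projected homoeologue
(itself accession-concordant) differing = HSV; a within-genome paralogue
differing = PSV. When both contrasts differ at one site the HSV label wins:
the cross-genome contrast is the one a co-dominant assay must tolerate
first. Homoeologue pairing uses the reference annotation's ortholog
families, taking the maximum-identity member in the other genome.

The KASP suitability filter passes a variant only if (i) read depth is at
least 7 in both accessions, (ii) the 50 alignment columns on each side are
present, gap-free and accession-identical (HSV/PSV sites do not violate
this -- they are cross-copy, not allelic, differences and are handled by
degeneracy), and (iii) no exon--intron junction falls inside the 101-base
window. A missing exon structure makes the junction check unevaluable and
fails the variant -- conservative. For B-genome models, which come from a
transcriptome without structural annotation, junctions of the A
homoeologue are projected through the reference-pair alignment; a B model
without an A homoeologue therefore cannot pass, which is the price of the
conservative reading. Another conservative reading: a second *allelic* SNP
inside the window also fails the flank rule; only HSV/PSV sites are
tolerated (as lower-case degeneracy), because two segregating sites in one
101-mer make allele-specific primers unreliable.

Marker sequences follow the published conventions: 101 bases centred on
the variable site, the site itself as `[X/Y]`, HSV/PSV sites inside the
window in lower case using the IUPAC code of the states to tolerate, all
other bases upper case; marker IDs get the `BJ_VH_` prefix. Copy
categories are i (single copy, one genome only), ii (one A copy + one B
homoeologue -- the source set for homoeology mapping) and iii (multiple
copies); an A-only single copy is reported as `i_A_unique` for symmetry
although the published three-way rule does not name it.

## DH linkage mapping

Markers are screened by a 1-df chi-square against 1:1 (alpha = 0.05, no
multiplicity correction -- none is stated in the mapping protocol this
mirrors, and the rate of chance exclusions, about 5%, matches the scale of
exclusions such protocols report). Pairwise recombination fractions are
recombinant counts over pairwise-complete individuals, capped at 0.5, with
the binomial DH LOD against independence. Grouping is connected components
of the LOD >= 4.0 graph. Ordering is explicitly a documented heuristic,
not a reimplementation of any commercial mapping engine: greedy
nearest-neighbour seeded at the most distal pair, refined by 2-opt on the
sum of adjacent rf, positions as cumulative Kosambi distances
d = 25·ln((1+2r)/(1−2r)) cM, orientation canonicalised by end-marker ID.
Map lengths are therefore comparable, not identical, to regression-mapping
outputs. Markers with more than 50% missing calls are dropped with a
warning; adjacent rf is clamped at 0.49 before the Kosambi transform to
keep positions finite when a group contains a near-unlinked join.

A design note on grouping power: with 123 DH individuals, the probability
that an unlinked marker pair reaches LOD 4 is pbinom(38, 123, 0.5) ≈
1.4e-5. The linkage-recovery simulations therefore use 90 markers (18 LGs
of 5), keeping the expected number of false cross-group edges near 0.05 so
that exact recovery is the overwhelmingly likely outcome; these sizes were
fixed by this power analysis, not tuned afterwards.

## Block painting, homoeology, fragmentation, motifs

Markers carry ortholog IDs; a block definition table (data, not code --
the simulator derives one from its rearranged A-genome layout, and a user
can supply the published table) assigns every marker all blocks whose
closed ID interval contains it, with the marker's subgenome class (known
from its source reference gene) disambiguating between classes. Along each
LG, maximal runs of same-(block, class) markers become calls under the
per-genome evidence rule: one marker suffices on the well-annotated A
genome, two are required on the B genome. A single intervening marker of
another block breaks a run. Orientation is the sign of the Kendall
correlation between ortholog order and cM order.

Homoeology links require calls of the same block and class with
overlapping ortholog spans sharing at least two single-copy (category-ii)
markers -- "same block region" is operationalised as span overlap, since
the qualitative published rule does not define it. Fragmentation compares
the merged segments of a (block, class) between genomes: `split_in_A` /
`split_in_B` when one genome holds two or more disjoint segments jointly
covered by fewer in the other, `duplicated` when two segments within one
genome overlap by at least half their ortholog span (our operationalisation
of "duplicated on two different LGs"), `absent_in_one`, otherwise
`intact_both`. Association motifs are the per-LG ordered block tuples;
shared motifs are contiguous sub-runs of length >= 2 found in one LG of
each genome, compared reversal-invariantly because LG orientation is
arbitrary.

One open corner is deliberately left to the data: a marker whose ID falls
in two overlapping published intervals of different classes is reported
with all candidates and resolved by the run structure, not by a guessed
rule.

## Reproducibility and problem sizes

Every stochastic function takes a seed; `run_pipeline()` derives per-stage
seeds from one top-level seed and a fixed seed makes all emitted files
byte-identical. The test suite and the acceptance script run simulated
studies at sizes chosen to exercise every rule while staying desk-scale:
a 24-block study of 504 genes (about 4,800 contigs) for assignment
recovery, 50 genes for the SNP-calling oracle, 1,000 synthetic variants
for the filter oracle, 18 LGs x 5 markers x 123 individuals for linkage
recovery and an 8-block, 6-rearrangement genome for fragmentation
recovery. The published study's absolute counts (hundreds of thousands of
reads-derived SNPs) are not reproducible from simulations at these sizes
and are checked only as arithmetic consistency of the printed funnel.

## Known limitations

* The classifier trusts the candidate shortlist; a contig whose true
  source shares no seed k-mers with it (possible only under divergence far
  beyond the study's) would be mis-shortlisted.
* Consensus building resolves contig conflicts to `N` rather than by
  depth-weighted voting; low-complexity chimeras are not modelled or
  handled.
* The ordering heuristic can locally invert very tight marker clusters
  (rf near 0); the Kendall-tau checks quantify this.
* B-genome markers without an A homoeologue cannot pass the junction
  screen (conservative fail), so B-unique (category-i) gene models yield
  no markers under default settings.
* The fragmentation classes assume segments are supported by at least two
  markers on the B side; single-marker B segments are invisible by the
  evidence rule, exactly as in the published protocol.
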