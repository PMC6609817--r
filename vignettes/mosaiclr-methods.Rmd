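---
title: "Calling mosaic SNVs from linked reads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mosaic SNVs from linked reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaiclr)
library(dplyr)
```

## The problem and the signal

A mosaic SNV arises after fertilisation and is carried by only a fraction of
an individual's cells, so in bulk sequencing it appears at an allele
fraction well below the heterozygous 50% — often 5–25% — where it competes
directly with sequencing error. The discriminating signal exploited here
comes from linked reads: every short read carries the molecular barcode of
the long (tens-of-kb) DNA fragment it was cut from, and those long fragments
can be assigned to one of the two assembled haplotypes whenever any of their
reads overlap a phased heterozygous germline variant. A genuine mosaic
variant lives on one haplotype: *all* of its alternate-allele reads, once
phased through their molecules, land on the same haplotype
("haplotype-discordant reads"). Sequencing errors are indifferent to
haplotype and split roughly 50/50. We quantify this as the **haplotype
concentration**: the majority-haplotype share among haplotype-assigned reads
carrying the candidate allele — 1.0 is the mosaic signature, ~0.5 the error
signature.

## Pipeline

1. **Molecule reconstruction and phasing** (`group_fragments()`,
   `assign_haplotypes()`). Reads sharing a barcode on a chromosome form one
   fragment unless consecutive reads are separated by more than `max_gap`
   (default 50 kb — standard molecule-reconstruction practice to guard
   against barcode reuse; the inputs carry no molecule annotation we trust).
   Each fragment votes at every phased het covered by one of its reads with
   base quality ≥ 20: a base matching the H1 allele votes H1, the H2 allele
   H2. Overlapping mates observing the same het count once (higher base
   quality wins). Assignment is by strict majority; ties are `unassigned`,
   never random. Votes are tallied per phase set — H1/H2 labels are only
   comparable within one — and a fragment spanning several phase sets takes
   its assignment from the set with the most votes, falling to `unassigned`
   when equally supported sets disagree.

2. **Candidate scan** (`scan_candidates()`). A site becomes a candidate when
   counted reads (not duplicate/secondary/supplementary, mapping quality
   ≥ 30, base quality ≥ 20) give: depth ≥ 16, at least 2 reads carrying the
   same non-reference base, allele fraction in [0.03, 0.75], phased
   fraction ≥ 0.25, and no germline variant call at the position (germline
   sites are the model's negatives, so they cannot simultaneously be
   candidates). The candidate allele is the most frequent non-reference
   base, ties broken alphabetically, for determinism. These thresholds are
   declared package defaults, exposed in `scan_config()`, chosen so a ~30X
   linked-read regime passes comfortably; they are not claimed to be
   faithful to any external tool's unpublished settings.

3. **Sample-specific training by spike-in** (`select_training_sites()`,
   `spike_in()`, `build_training_set()`). Positives are synthetic: at
   homozygous-reference sites that pass the depth/phasing filters before
   editing, a mosaic allele is written into the aligned reads at a target
   allele fraction drawn uniformly from [0.05, 0.5], on a uniformly chosen
   target haplotype. Editing is *fragment-granular*: a fragment on the
   target haplotype is selected with probability `min(1, 2·maf)`, an
   unassigned fragment with probability `maf`, and a fragment on the other
   haplotype never — all reads of one molecule come from one cell and must
   agree at the site, which is exactly what makes the haplotype signature
   appear in training data. The factor 2 makes the total-pileup allele
   fraction come out near `maf` in a balanced diploid pileup. Negatives are
   real germline calls, sampled evenly from heterozygous and
   homozygous-alt sites. Training sites keep ≥ 1 kb distance from any
   supplied evaluation truth (train/evaluation disjointness) and ≥ 500 bp
   from each other so edits never interact. Class balance is 1:1 by
   default — unspecified upstream; balanced classes keep the score
   interpretable — with 200 examples per class at the scales used here and
   5,000 suggested genome-scale.

4. **Forest scoring** (`train_model()`, `score_sites()`). A probability
   forest of 100 trees (the published ensemble size; other hyperparameters
   are the common defaults — unlimited depth, sqrt-features per split — and
   are recorded in the artifact) scores each candidate as the averaged
   per-tree probability of the positive class. The artifact stores mode,
   feature names, seed and version, and `score_sites()` refuses feature
   tibbles whose names or order differ.

5. **Filters** (`call_variants()`). PASS requires: score ≥ 0.5 (declared
   operating point; configurable), at least 4 haplotype-discordant reads
   (the published default), no overlap with repeat or copy-number masks,
   and survival of an alignment-error heuristic. That heuristic is this
   package's own: fail if >50% of candidate reads are soft-clipped ≥ 5 bp,
   if candidate reads average > 3 mismatches beyond the candidate base, if
   >50% are improperly paired, or if the site sits in a reference
   homopolymer ≥ 10 bp. No call is deleted by filtering — every scored
   candidate is emitted with PASS or its failed-filter labels, so filter
   provenance is conserved.

## Feature set

The exact feature list is this package's own design (the upstream families —
read quality, phasing, linked-read characteristics — are public, the
per-feature definitions are not). Site-level features, used by all model
variants: depth; candidate allele fraction; mean/SD base quality of
candidate vs other reads; mean mapping quality of both groups; fraction of
candidate reads on the reverse strand; mean normalised sequencing-cycle
position of the candidate allele; fraction of candidate reads soft-clipped;
mean per-read mismatch count excluding the candidate base. Fragment-level
features, used by `full` and `short_only`: phased fraction; candidate-read
counts and fractions per haplotype; discordant-read count; haplotype
concentration; candidate allele fraction within the majority haplotype;
number of distinct candidate-carrying fragments; mean het votes per
candidate fragment.

Undefined ratios (zero denominators) become 0 paired with a 0/1 presence
indicator (`has_alt`, `has_other`, `has_assigned_alt`, `has_major_hap`);
forests split on indicators naturally and no NaN can propagate. The list is
fixed, ordered, versioned inside the model artifact.

### Model variants

`full` phases reads through barcode-defined molecules. `short_only`
redefines fragments as paired-end read pairs — a read is assigned only when
one of its own ends overlaps a phased het — with otherwise identical feature
definitions, quantifying what the long molecules add. `no_phasing` drops the
fragment-level features entirely. Two contract adjustments keep the reduced
variants runnable: the scan's phased-fraction floor is not applied in
`no_phasing` mode (phased fraction is identically zero there), and the
discordant-read floor falls back to the candidate-read count (discordant
reads are undefined without phasing).

## The simulator

`simulate_genome()` and `simulate_linked_reads()` produce fully synthetic
data with complete truth: a random diploid reference with phased hets
(default rate 1e-3/bp, one phase set) and homozygous-alt sites (rate
0.6e-3/bp, roughly the human hom:het ratio, needed as training negatives);
mosaic sites placed ≥ 300 bp apart on one haplotype each; long fragments
with lognormal lengths (mean 16,176 bp, SD 54,387 bp — the heavy-tailed
empirical regime of a 10x-style library; lognormal is the simple heavy-tail
family matching those two moments) sequenced internally at 0.1-fold by
barcoded read pairs; i.i.d. substitution errors (default 0.002/base). A
fragment on a mosaic site's haplotype descends from the mutant cell lineage
with probability `2·maf`, and then *all* its reads covering the site carry
the allele — mirroring the spike-in model, as it must, since both emulate
the same biology. `simulate_deep_panel()` resamples allele counts
binomially at high depth as a stand-in for an orthogonal validation assay.

Reads carry true coordinates and a pure-match CIGAR: there is no aligner in
the loop, by design, to isolate caller logic from aligner behaviour. That
is also the simulator's main blind spot, and it bounds what green tests
mean: no mis-mapping, no chimeric molecules, no barcode collisions, no
GC/cycle error structure, uniform coverage. Passing the benchmark here
demonstrates the phasing logic, the spike-in machinery and the filters are
correct, not that real-genome precision of ~84% would be reproduced —
segmental duplications and repeats, which dominate real false positives,
are simply absent. The alignment-error filter and region masks are
exercised by construction (tests fuzz their predicates directly), not by
realistic alignment artifacts.

## Evaluation

`precision_recall()` matches calls to truth by exact position and allele
(no window rescue — SNVs are point events). Precision bins PASS calls by
their observed allele fraction, recall bins truth by true MAF; default bin
edges are (0, 0.05, ..., 0.5], right-closed — declared here, since
published figures do not print their edges. With `min_support = n`, the
recall denominator keeps only truth sites with ≥ n observed mosaic-allele
reads, the support-aware denominator appropriate when the caller itself
requires n supporting reads; both denominators can be reported side by
side. `wes_validate()` implements the orthogonal deep-coverage rule: ≥ 50
reads at the locus, ≥ 4 supporting the allele, not germline in either of
two germline call sets; shallower loci are `unevaluable`, not failures.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere internally; conversion
  happens only in the VCF/SAM/BED readers and writers, and boundary tests
  pin positions 0 and 1.
- All ties break deterministically (alphabetical alleles, `unassigned`
  haplotypes); a single global seed is split per stage by hashing stage
  names (`stage_seed()`), so identical seeds give byte-identical VCFs and
  model artifacts while stages stay independently reproducible.
- Duplicate, secondary and supplementary reads are kept in the data model
  but excluded from depth, allele counts and votes.
- Only biallelic SNVs are consumed from the germline VCF; indels and
  multi-allelic records are counted and skipped (indel calling is out of
  scope).
- Overlapping mates are deduplicated for haplotype votes (higher base
  quality wins) but both count toward depth; at the default insert
  geometry overlap is rare and the effect on allele fractions negligible.
- Benchmark scale: the acceptance suite simulates 2 Mb at 30X with 200
  mosaic sites, trains on 200 spike-ins, and expects precision ≥ 0.80 and
  recall ≥ 0.50 over truth sites with ≥ 4 mosaic-allele reads. These are
  implementation targets for the simulator's idealised conditions,
  deliberately stricter in recall and looser in precision than genome-scale
  results on real data, which face repeats and alignment error we do not
  simulate.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(region_length = 500000L, n_mosaic = 40L,
                  base_error_rate = 0.002, seed = 19)
g <- simulate_genome(cfg)
sim <- simulate_linked_reads(g, cfg)
paths <- write_sim_dataset(g, sim, "simdata")

res <- run_pipeline(
  bam = paths$bam, fasta = paths$fasta, vcf = paths$vcf,
  out_dir = "run1", mode = "full", seed = 7, n_train = 100L,
  exclude_training = g$truth$mosaic
)
ev <- precision_recall(res$calls, sim$mosaic_support, min_support = 4)
glance(ev)
autoplot(ev)
```

## Known limitations

Single-sample SNVs only: no indels, no tumor/normal or trio modes, no
structural variants, autosomal diploid assumptions throughout (no
sex-chromosome ploidy handling), phasing within — never across — phase
sets, and an evaluation harness that cannot stand in for benchmarking on
real linked-read genomes.
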