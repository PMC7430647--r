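---
title: "Classifying extracellular tRNA halves and Y RNA fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying extracellular tRNA halves and Y RNA fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exofrag)
```

## The biological problem

Cells release full-length mature tRNAs and Y RNAs into the extracellular
space, where secreted ribonucleases of the pancreatic family cleave them
into discrete fragments: tRNA *halves* produced by a cut in the anticodon
loop, and characteristic 5' and 3' Y RNA fragments.  Because the nuclease
also trims the nontemplated CCA tail of mature tRNAs — typically cutting
between the two cytidines and leaving a single nontemplated C — the 3'-end
chemistry of sequenced reads records the processing history of each
molecule.  Libraries from nuclease-active ("wild-type-like") material are
dominated by halves with trimmed tails, while nuclease-null material
yields mostly full-length molecules carrying the intact CCA.

`exofrag` implements the post-alignment half of this analysis: given
alignments of adapter-processed small-RNA reads, a genome and a customized
annotation (tRNA genes with introns and metadata, Y RNA genes, pseudogenes
and repeat-derived copies), it qualifies reads, classifies tRNA halves,
calls CCA-tail status, assigns Y RNA reads, and summarizes datasets.  A
seeded simulator generates all of these inputs with known ground truth, so
the full pipeline is exercisable and testable without downloads.

## The classification model

All classification rules run in **mature-transcript coordinates**:
position 1 is the mature 5' end regardless of genomic strand, introns are
excised, and the nontemplated CCA is *not* part of the mature length.  The
half windows (all bounds inclusive, configurable via `half_windows()`):

* a **5' half** starts no farther than nucleotide `max_start5 = 5` and
  ends within the anticodon-loop window `loop_lo..loop_hi = 29..41`;
* a **3' half** starts within `29..41` and ends within the last
  `end3_margin = 5` nucleotides of the mature annotation.

For tailed reads, `tend` is the last genome-annotated aligned base: tail
bases — whether soft-clipped or genome-templated — never extend `tend`.
The windows cannot overlap provided the mature length is at least
`loop_hi + end3_margin`; shorter transcripts raise a configuration error.

### The qualification cascade

A read enters the half/tail analysis only if it survives, in fixed order:

1. it is a **primary** alignment (multimappers contribute exactly one
   primary; the count of primaries is the denominator of all fractions);
2. it is not on a **mitochondrial tRNA** (kept in the annotation as the
   class `tRNA_mito` so the exclusion is observable, rather than dropped
   at load);
3. its CIGAR has **no insertions or deletions**, and any `N` gap coincides
   *exactly* with an annotated intron (anything else is an unannotated
   intron);
4. the **3' adapter** was found on the raw read (reads without an adapter
   may be truncated on their 3' side, making tail calls meaningless);
5. its trimmed length equals the **sum of CIGAR matches**, except that a
   read ending in exactly `C`, `CC` or `CCA` past the mature 3' end may be
   longer by the non-genome-matching part of that tail.  5' soft clips of
   any length disqualify — the length exception is stated only for 3'
   tails;
6. it does not overlap, by even one nucleotide, an **intron or sequence
   outside the mature annotation** (a pre-tRNA signature) — except when
   the only outside bases are a C/CC/CCA tail that happens to be templated
   by the downstream genomic sequence.  When a gene is followed in the
   genome by `CCA`, `CC` or `C`, a tail aligns as ordinary matches past
   the annotation end, and the tail interpretation always wins over the
   pre-tRNA interpretation.

Each read receives exactly one reason (`ok`, `mito`, `indel_or_intron`,
`no_adapter`, `length_mismatch`, `pre_trna`, `not_primary`, `no_gene`),
so reason counts over primaries always sum to the number of primaries.

### Tail status

For reads whose aligned bases reach the mature 3' end, the *tail* is the
read sequence beyond the annotation: genome-templated aligned bases first,
then the 3' soft clip.  Exactly `""`, `"C"`, `"CC"` or `"CCA"` give the
statuses `NONE`/`C`/`CC`/`CCA`; anything else is `OTHER` and is excluded
from the tail-status denominator, as are reads not reaching the end
(`NOT_TAILED`).  With no tailed reads the fractions are reported as
undefined (`NA`), never as zeros.

### Identity groups and reporting

tRNA genes occur in multiple copies, some with character-identical mature
sequences.  Reads mapped to any copy of an *identity group* (computed from
the spliced sequences at load time) are counted together; groups are named
after their lexicographically first member.  Reporting
(`summarize_fragments()`) aggregates Table-style abundance rows by
isoacceptor family (amino acid + anticodon), because multiple identity
groups can share a family.  The 5'/3' **imbalance** statistic is the
percentage of identity groups whose `max(c5, c3)/min(c5, c3)` ratio is
below 10:1; groups with fewer than `min_group_halves = 10` halves are
excluded from the denominator (the source analysis states no floor; a
floor avoids calling a 1-read group "imbalanced", and the value is
configurable and recorded in the report).

### Y RNA assignment

Y RNA reads are assigned strand-specifically with a fallback hierarchy:
genes first, then annotated pseudogenes, and — only for reads overlapping
*no* annotated feature of any class — RepeatMasker-style HY repeat
intervals (HY1/HY3/HY4/HY5 mapping to RNY1/RNY3/RNY4/RNY5).  Reads on all
pseudogenes or repeats of a family are grouped under that family.  Repeat
overlap is tested strand-specifically, matching the treatment of annotated
features; ties across features are broken by largest overlap, then
lexicographic id.  Y RNA reads do not pass through the tRNA qualification
cascade (those selection rules are specific to the tRNA analysis); only
primariness and strand are enforced.  No positional window rule is applied
to Y fragments — the characteristic 33-nt RNY5 5' fragment is identified
from the per-family length histograms, mirroring how it is identified from
read coverage in practice.

## The simulator

`build_toy_reference()` constructs a deterministic toy genome: nine
cytosolic tRNA genes over nine isoacceptor families (including two
Gly-GCC copies with identical mature sequences and one intron-containing
Tyr-GTA gene), a mitochondrial decoy, the four Y RNA genes (RNY5 84 nt),
two RNY5 pseudogenes and three HY repeat intervals, on both strands.
Mature tRNA lengths are 74–76 nt.  Several genes are deliberately followed
by genomic `CCA`, `CC` or `C` so that templated-tail handling is
exercised; others by non-C context so soft-clipped tails occur too.

`simulate_library()` draws molecules per read:

* **category** — tRNA half (`half_fraction`, default 0.173 wild-type /
  0.016 mutant), full-length tRNA, Y RNA read (0.25), unannotated
  background decoy (0.40) and mitochondrial decoy (0.005);
* **halves** — the 5'/3' type is drawn first with probability `split5`
  (default 0.53), then the family conditional on type, from per-family
  weights and 5' shares derived from the observed abundance ranking of
  extracellular halves (Asp-GTC almost entirely 3', Gly-GCC almost
  entirely 5', Glu-CTC mixed, ...).  Drawing the type first makes the
  overall generative split exactly `split5` while preserving the
  per-family 5'/3' dominance structure;
* **cleavage** — uniform over transcript positions 31–38 (the anticodon
  loop); real data shows gene-specific preferred sites, which can be
  emulated by narrowing the window, but no per-gene distribution is
  assumed;
* **tails** — molecules whose 3' end is the mature end draw from
  `tail_probs` (wild-type default `C`-dominant: CCA .05, CC .05, C .70,
  NONE .20; mutant CCA-dominant: CCA .90), reflecting trimming between
  the two cytidines of the CCA;
* **cloning biases** — cleavage leaves a 2'-3' cyclic phosphate and 5'
  hydroxyl that RNA ligases cannot join.  With `pnk_treated = FALSE`,
  each cleaved end is independently ligatable only with probability
  `p_spont_heal = 0.2`; 5' halves carry one cleaved end, 3' halves two
  (loop cut plus CCA trimming), so omitting PNK depletes 3' halves
  quadratically — the direction observed experimentally.  RT-blocking
  methylations (`p_methyl_block`, per-family) and 3' aminoacylation of
  CCA-ended molecules (`p_aminoacyl`) drop molecules unless the
  `demethylated`/`deacylated` pretreatments are set.  Both default to 0:
  the headline conditions describe PNK-treated libraries, and the
  methylation/acylation knobs exist to reproduce the pretreatment
  comparisons qualitatively;
* **adapters** — raw reads are `4N + insert + 4N + adapter` (randomized
  adapter ends); inserts of at least `long_insert = 70` nt lack a readable
  adapter with probability `frac_no_adapter = 0.3`, emulating full-length
  molecules running past the sequencing read.  Short fragments always
  expose the adapter, so adapter drop-out does not bias half recovery;
* **placement** — reads from an identical-copy group are placed on a
  seeded-random copy (plus one secondary record on another copy);
  alignments are emitted with exact CIGARs (N across the annotated intron,
  M-extension for genome-templated tail bases, soft clips otherwise).

Per-molecule ground truth (class, tail, gene, cloning fate) is emitted for
every molecule, cloned or not, which is what makes exact end-to-end oracle
tests and paired PNK comparisons possible: configurations differing only
in cloning flags share the identical molecule stream, because all random
draws happen in a fixed order before the cloning filter is applied.

### What the simulator does not model

No sequencing errors or aligner mismatch handling (the qualification rules
assume mismatch filtering happened upstream in the mapper); no quality
scores; no per-gene cleavage-site preferences; no partial/truncated
fragments outside the half windows beyond what the cleavage window
produces; no EV-versus-non-EV compartment structure; no contaminating
serum nuclease background; and the mutant is qualitative (mostly
full-length, CCA-intact) because residual fragment levels in a
nuclease-null background are not quantified.  Passing recovery tests on
this generator therefore demonstrates the correctness of the
classification logic and the internal consistency of the biogenesis model
— not performance on real libraries, where modification-induced RT stops,
structure-dependent cloning efficiency and aligner behaviour add biases
the generator only partially represents.

## Numerical and design choices

* Internal coordinates are 1-based inclusive transcript positions, because
  the window rules are stated that way; file formats keep their own
  conventions (GTF 1-based, BED half-open).
* Half windows are computed on spliced (mature) coordinates also for
  intron-containing genes; halves derive from mature tRNAs, and intron
  overlap disqualifies a read as a pre-tRNA before windows are ever
  tested.
* Assignment of a read to a tRNA gene is by largest strand-specific
  overlap with mature blocks, ties broken lexicographically; assignment
  strictly follows the primary alignment.
* `detect_adapter()` uses exact prefix matching (default
  `min_match = 6`) for determinism; mismatch-tolerant aligner-side
  clipping is out of scope.
* Percentages in rendered tables are conventionally read at one decimal
  place; machine-readable outputs (`write_report()`) keep full precision.
* Problem sizes in the shipped tests (libraries of 6 000–20 000 reads,
  windows enumerated exhaustively for mature lengths up to 100 nt) were
  chosen so the whole suite runs in minutes while keeping binomial
  recovery bands (3 SDs) tight enough to be informative.

## A worked run

```{r example, eval = FALSE}
ref <- build_toy_reference(seed = 1)
ann <- ref$annotation

cfg <- sim_config("WT", n_reads = 20000, seed = 3)
sim <- simulate_library(cfg, ann)

calls <- fragment_calls(sim$alignments, ann)
summarize_fragments(calls)
#> SummaryReport: 20000 mapped primaries, 5898 qualified, 3534 halves
#>   half fraction: 0.1767  (5' 53.4% / 3' 46.6%)
#>   tail status: NONE 20.2%  C 69.6%  CC 4.8%  CCA 5.3%
#>   groups < 10:1 imbalance: 66.7%
```

The README shows the printed output of this exact run.  For the
nuclease-null contrast, rerun with `sim_config("mutant", ...)`: the half
fraction collapses by an order of magnitude and the modal tail switches
from `C` to the intact `CCA`.

## Known limitations

* The pre-tRNA rule tests overlap against the loaded annotation only;
  leader/trailer boundaries beyond the mature annotation are treated as
  "outside" uniformly, with no explicit precursor models.
* Identity grouping requires exact sequence identity; near-identical
  copies (one substitution) form separate groups by design, which can
  split counts that a mismatch-tolerant analysis would merge.
* The SAM reader takes the adapter flag from a nonstandard `ZA` tag
  (written by the simulator); for external alignments lacking the tag,
  every read is assumed adapter-trimmed, and the no-adapter filter should
  be applied upstream.
* Smaller tRNA-derived fragment species (tRF-1/-3/-5 subtypes) are not
  classified; in the motivating data their counts are very low and no
  window rules are defined for them.
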