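---
title: "Simulating and diagnosing base-calling artifacts in bisulfite sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing base-calling artifacts in bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(bsartifact)
library(dplyr)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) estimates cytosine methylation from
base calls: after bisulfite treatment, unmethylated cytosine reads as T while
5-methylcytosine (5mC) survives as C. Library chemistry decides which base
carries the methylation signal in each mate. In PBAT (post-bisulfite adaptor
tagging) libraries the first read is complementary to the converted strand,
so 5mC appears as **G in R1** and **C in R2**; MethylC-seq is the mirror
image. Bisulfite libraries are low-diversity — after conversion one base
dominates — and sequencer base-calling software calibrated on balanced
libraries can misbehave on them. A systematic undercall of the minority base
G in the 5mC-coding mate directly depresses the estimated methylation level,
because every lost G is counted (as A) toward the unmethylated pool or
silently dropped.

`bsartifact` builds a fully controlled, desk-scale replica of this situation:
a synthetic reference, a bisulfite read simulator with a parameterized
artifact model, a three-letter aligner, a methylation caller, read-level QC,
windowed statistics, spike-in mixture calibration, and PMD calling. Because
every molecule's truth is known, the package can separate what an estimator
should see from what an artifact makes it see.

## Models and assumptions

### Methylome models

`methylome_spec()` supports three modes:

* **uniform** — every CpG cytosine has the same per-molecule Bernoulli
  probability `cpg_level`.
* **sssi** — emulates DNA methylated in vitro to near-completion with CpG
  methyltransferase (SssI). The default level is 0.979, the value validated
  by clone bisulfite sequencing of treated lambda DNA over 58 CpG sites.
  Complete methylation is deliberately *not* assumed; the 2.1% shortfall is
  part of the model.
* **mixture** — a physical mixture of two DNA pools. Each molecule is drawn
  wholly from the methylated component (probability `mixture_proportion`)
  or the unmethylated one. With the default component levels of 1 and 0,
  the predetermined level of the mixture equals the mixing proportion —
  the construction behind spike-in calibration series such as 10/44/88%.

The per-molecule component draw matters statistically: calls from one
molecule are perfectly correlated in mixture mode, so the sampling unit of
the global level estimate is the **molecule**, not the call. Recovery
checks in this package therefore use molecule-count binomial standard
deviations for mixture runs and call-count ones for per-site Bernoulli
runs.

Non-CpG cytosines (CpA, CpT, CpC) get `noncpg_level`, default 0 — typical
for somatic mammalian DNA and for lambda spike-ins.

### Read simulation

Fragments are drawn uniformly along the reference with lengths from a
normal distribution (default mean 300 bp, sd 30, truncated below at the
read length; no insert-size distribution is claimed by the experiments the
package emulates, so a generic short-insert model is used). A genomic
strand is chosen uniformly; every cytosine of that strand realizes its
methylation state per molecule, and unmethylated cytosines convert to T
with probability `conversion_rate`.

`conversion_rate` defaults to 1.0. Real libraries have near- but not
exactly complete conversion; since no conversion efficiency is attached to
the data the package emulates, complete conversion is the stated default
assumption and calibration runs set it explicitly.

Reads are 101 nt by default, paired, with a uniform Phred quality of 38.
PBAT: R1 is the first `read_len` bases of the reverse complement of the
converted fragment, R2 the first `read_len` bases of the fragment itself;
MethylC-seq swaps the roles. Sequencing error substitutes each base
uniformly to one of the other three with probability `error_rate`
(default 0), leaving qualities untouched — random error is deliberately
separated from the systematic, quality-linked artifacts below.

### The artifact model

`artifact_model()` has two components, both restricted to a target mate:

* **G undercall.** Each called G is miscalled with probability `q =
  g_to_a_rate` and its quality reduced by `g_quality_penalty` Phred points
  (floored at 2). The miscall target is **A** by default: at 5mC-coding
  positions A is exactly the unmethylated partner of G in both chemistries,
  so one parameter simultaneously produces (i) a depressed G fraction in
  base composition, (ii) a depressed methylation level, and (iii) quality
  drops at affected positions. A uniform-miscall variant is available
  (`uniform_miscall = TRUE`); it produces no-call bases instead of
  unmethylated calls at two-thirds of miscalled sites, which weakens the
  coupling between composition and level. With `quality_only = TRUE` the
  penalty also applies to Gs whose base call survives, which is the switch
  that reproduces low-quality-G profiles without changing any level.

  The closed form for the observed level under the artifact, with true
  level m: at a 5mC-coding site the G survives with probability
  m(1 − q) and an A is observed with probability (1 − m) + mq, so

  E[observed] = m(1 − q) / (m(1 − q) + 1 − m(1 − q)) = m(1 − q).

  This identity is exercised at over a million calls in the test suite and
  drives the expected calibration bias −100·π·q percentage points at
  mixture proportion π.

* **R2 quality collapse.** An optional density-dependent cap on all
  qualities of the target mate: the cap falls linearly from 41 toward
  `quality_floor` as cluster density approaches `density_saturation`
  (default 700 K clusters/mm², the top of the density range the model
  emulates). This reproduces a failure mode in which whole-mate quality
  collapses at high density without any base being miscalled.

### Alignment

The aligner is a three-letter, seed-and-count design operating on reduced
alphabets: the 5mC-as-G mate is reduced G→A, the converted-strand mate
C→T, and each read is scanned in both orientations against the matching
reduced reference view. Defaults: seed length 28, at most 1 mismatch in
the seed, at most 3 mismatches total. The seed parameters follow standard
bisulfite-alignment practice for ~100-base reads; the total cap of 3 is
this package's choice (the upstream tools it stands in for leave the
effective ceiling to their internals) and is small enough to keep random
placements off references of this scale.

Candidate loci are enumerated with an exact pigeonhole index: the seed is
split into two halves, and any locus with at most one seed mismatch must
match at least one half exactly, so looking both halves up in a k-mer
index enumerates a superset of all admissible loci, which full
verification filters. Results are therefore identical to an exhaustive
scan of every position — the test suite asserts this equivalence against
an independent brute-force scorer — while staying fast. A single
strictly-best locus is `unique`; ties are `ambiguous` and discarded from
all downstream analysis; reads trimmed by the default rule (4 bases from
the 5' end, 1 from the 3', 101 → 96) are what the aligner sees.

### Methylation calling and the weighted level

At each indexed cytosine covered by a unique alignment, the reference-
oriented read base is interpreted per view (C/T on the converted strand,
G/A on its complement). Any other base is a **no call**, never an
unmethylated call — a deliberate choice: counting mismatches as
unmethylated would double-book sequencing error as hypomethylation, and
the G-undercall artifact behaves per its closed form only because the
default miscall target A is a *bona fide* unmethylated call while
off-model mismatches drop out.

The weighted level is Σ meth / Σ (meth + unmeth) over the selected
cytosines, ×100 — depth-weighted, not a mean of per-site levels. A
selection with zero calls is an explicit error, not 0: silently returning
0% would fabricate a hypomethylation signal. R1 and R2 strata are kept
separate throughout and pooled by summation without mate-overlap
deduplication by default (mate-stratified analysis is the package's
primary surface; an overlapping pair double-covers only the few sites in
the fragment middle).

### Windows, comparison, density classes

Windowed statistics use non-overlapping tilings (100-kb scale for
between-run comparison, 10-kb for PMDs) with trailing partial windows
dropped so CpG counts are comparable across windows. Run comparison is
ordinary least squares of run A's window levels on run B's, with the
per-window difference Δ = A − B summarised overall and per CpG-density
class. Density classes are equal-count (quantile) bins on the window CpG
count, 9 by default; tied counts collapse into one class rather than
being split arbitrarily.

### PMD calling

Partially methylated domains follow the sliding-window rule set: 10-kb
windows; a window is *eligible* when at least ten CpG sites in it are
each covered at least once; an eligible window below 70% is a PMD window;
contiguous PMD windows merge; only merged domains **strictly longer than
100 kb** survive. Two readings of the eligibility phrase are possible
("ten covered CpGs" vs "all CpGs covered, at least ten"); the package
uses ≥10 covered CpG sites, the common reading in sliding-window PMD
callers, and exposes the threshold as `min_cpg`. An ineligible window
breaks contiguity — merging across unassessable gaps would manufacture
domain length from missing data.

## Parameter summary

| parameter | default | unit | rationale |
|---|---|---|---|
| `read_len` | 101 | nt | emulated instrument read length |
| `trim5`/`trim3` | 4 / 1 | nt | adapter remnants / last-cycle base; 101 → 96 |
| `fragment_len_mean`/`sd` | 300 / 30 | nt | generic short-insert library |
| `conversion_rate` | 1.0 | prob. | stated assumption; set explicitly in calibration |
| `error_rate` | 0 | prob./base | artifacts studied separately from noise |
| `base_quality` | 38 | Phred | modern high-quality calls |
| `sssi_level` | 0.979 | prob. | clone-validated SssI methylation level |
| mixture proportions | 0.10/0.44/0.88 | — | spike-in calibration series |
| `seed_len`/seed mm/total mm | 28 / 1 / 3 | — | bisulfite-aligner practice; cap is ours |
| drop threshold | 10 | Phred | "steep drop" definition (strictly greater) |
| quality classes | [0,10),[10,20),[20,30),[30,∞) | Phred | Q30 = 99.9% accuracy convention |
| PMD: window/CpGs/level/length | 10 kb / ≥10 covered / <70% / >100 kb | — | sliding-window PMD rule set |
| density classes `k` | 9 | — | CpG-density stratification |
| `density_saturation` | 700 | K/mm² | top of emulated cluster-density range |

## The synthetic calibration genome

`synthetic_genome()` generates a GC-balanced i.i.d. random sequence of
48,502 bp — the length of the lambda phage genome — under a fixed seed, so
no accession needs downloading and every session sees the same reference.
It reproduces lambda's length and a balanced composition, **not** its
sequence: CpG density is ~1/16 per position per strand (about 3,000 CpG
dyads), with none of lambda's compositional structure, repeats, or real
CpG spacing. It is labelled synthetic everywhere it appears.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: adapter read-through and index tags, PCR
duplicates, quality-by-cycle decay, indels, patterned-flow-cell or
two-color chemistry effects, mappability structure of mammalian genomes,
and real base-caller internals. The artifact model is a two-parameter
phenomenological stand-in (rate, penalty) for version-specific software
behavior; tests validate the pipeline's response to that model, not the
software it abstracts.

## Numerical choices and degenerate inputs

* Cytosines whose 3' neighbor (in their strand's direction) is N or
  absent get context `unknown` and are excluded from every methylation
  statistic.
* Undefined levels (zero calls) are errors at the scalar level and `NA`
  in tabular outputs (window levels, level report strata) — never 0.
* Identical genomic loci reachable through both alignment combos count as
  one locus, so palindromic edge cases do not spuriously become ambiguous.
* Quality penalties floor at Phred 2; encoded qualities stay within
  [2, 41] (Phred+33 `#`…`J`).
* Coordinates are 0-based half-open internally and in BED output; the
  per-cytosine report is 1-based, the common cytosine-report convention.
* Same seed → byte-identical FASTQ and report outputs; the pipeline's
  global seed fans out to per-stage seeds through a fixed affine map so
  stages can be rerun independently.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to make sampling error
small against the effects under test: mixture recovery uses 20,000
molecules (pairs) per point (≈230,000 CpG calls after trimming), the
closed-form artifact check uses ≈1.07 million R1 calls (170,000
single-end fragments), the conversion sanity check 100,000 reads, the
clone-validation analogue 58 sites × 1,000 clones, and the
oracle-equivalence checks use 1.5–2 kb genomes where exhaustive scanning
is affordable. The end-to-end `reproduce()` bundle defaults to 6,000
pairs per mixture condition.

## Worked sketch

```{r example}
genome <- synthetic_genome()
index <- index_cytosines(genome)

reads <- simulate_library(
  genome,
  methylome_spec("mixture", mixture_proportion = 0.44),
  n_fragments = 5000,
  sim_config("PBAT", seed = 7),
  index = index
)

trimmed <- trim_reads(reads)
aln <- align_reads(trimmed, genome)
calls <- extract_calls(aln, trimmed, index)
level_report(calls, reads = trimmed)

art <- apply_artifact(
  reads,
  artifact_model(g_to_a_rate = 0.08, g_quality_penalty = 20,
                 target_mate = "R1", quality_only = TRUE),
  seed = 8
)
art_trimmed <- trim_reads(art)
art_calls <- extract_calls(align_reads(art_trimmed, genome), art_trimmed, index)
level_report(art_calls, reads = art_trimmed)
g_drop_fraction(dplyr::filter(art_trimmed, mate == "R1"))
```

The clean run recovers ~44% in both mates; the artifact run shows R1 near
44 × 0.92 ≈ 40.5% with R2 unchanged, a depressed R1 G fraction, and
quality drops at Gs — the full diagnostic signature from a single
two-parameter artifact.

## Known limitations

The aligner is exhaustive-equivalent but desk-scale: it is meant for
spike-in-sized references (up to a few hundred kb), not mammalian
genomes. Indels are not modeled or aligned. Mate-overlap deduplication is
optional and off by default, so pooled levels at fragment middles weigh
double-covered sites twice. The R2-collapse model caps qualities without
altering base calls, which matches a calibration failure but not every
conceivable density effect. PMD calling is the threshold rule set only —
no HMM smoothing — and applies to every record of the provided reference,
since synthetic references have no sex chromosomes to exclude.
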