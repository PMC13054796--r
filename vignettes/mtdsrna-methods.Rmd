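---
title: "Quantifying mitochondrial double-stranded RNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial double-stranded RNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdsrna)
```

## Background and model

Mitochondrial DNA is transcribed from both strands: the heavy (H) strand
transcription unit covers most genes (both rRNAs, 12 of 13 mRNAs, most
tRNAs), while the light (L) strand unit produces a long transcript that is
normally degraded rapidly. Failure of that degradation leaves complementary
H- and L-strand RNA in the matrix, where it anneals into mitochondrial
double-stranded RNA (mtdsRNA). Two sequencing readouts quantify this
species:

1. **Stranded short-read RNA-seq.** Because stranded libraries preserve
   transcript orientation, the fraction of mitochondrial fragments in
   L-strand orientation, $f_L = n_L / (n_L + n_H)$, is a proxy for how
   much L-strand transcript persists — and therefore for mtdsRNA burden.
   In dsRNA-rich samples $f_L$ approaches 0.5 (both strands of the duplex
   recovered equally); in dsRNA-poor samples it approaches 0.
2. **J2 RIP-seq.** Immunoprecipitation with the J2 antibody (which
   recognizes duplexes of roughly ≥ 40 bp) followed by long-read
   sequencing recovers the dsRNA population directly. Reads are counted
   per annotated feature and summarized as per-strand coverage
   histograms; the fraction of reads mapping to the mitochondrial contig
   measures how much of the immunoprecipitated material is mitochondrial.

A-to-I editing ties the two together: ADAR1 deaminates adenosines in
double-stranded RNA, and inosine is read as guanosine by sequencers, so a
duplex that met cytosolic ADAR1 carries A→G mismatches relative to DNA.
Attributing an RNA-level A/G mixture to editing requires excluding the two
genomic explanations — a plain variant, and mitochondrial heteroplasmy
(two mtDNA alleles coexisting in one sample).

## Strand conventions

Whether the "light" strand is the FASTA plus or minus strand depends on
the reference orientation, so the package never hardcodes it. The heavy
reference strand is defined operationally as **the annotated strand of the
rRNA genes** (RNR1/RNR2 are H-strand transcripts); light is its opposite
(`derive_strand_convention()`). Flipping the annotation flips every
downstream label exactly — a property the test suite asserts.

For paired short reads the transcript strand follows from (alignment
strand, mate rank, chemistry): under the dUTP-style `RF` protocol read1
aligns antisense to the transcript, under `FR` sense; read2 is always the
complement of the read1 rule. The default protocol is `RF` (the common
stranded kit); `strict_paired` mode refuses single-end records rather than
guessing. RIP-seq long reads are single-stranded cDNA: their alignment
strand *is* the transcript strand, with no protocol transform.

Coordinates: feature intervals are 0-based half-open internally (GFF3's
1-based inclusive and BED's 0-based half-open dialects both convert to
it); single genomic positions in pileups, editing tables and reports are
1-based, matching the field's "position 2,617" style. This deliberately
deviates from an all-0-based internal convention; in R, 1-based point
coordinates are the idiom, and mixing conventions at the interval/point
boundary is where the bugs live, so the boundary is documented here and in
every signature.

## Filters and counting units

"Uniquely mapped" is implemented aligner-agnostically: a record passes
when it is mapped, primary (not secondary/supplementary), not a duplicate,
properly paired when paired, and unique — `NH == 1` when the tag is
present, else `mapq >= min_mapq` (default 1). The counting unit is the
**fragment**: both mates of a proper pair carry the same orientation
information, so pairs count once via read1 (`count_mates_separately =
TRUE` reproduces per-read counting; fractions are identical in both
modes, a tested invariant).

Coverage accumulates per aligned block — deletions and introns contribute
nothing. Normalization divides **both strands by the single sample-wide
maximum**, not per-strand maxima, so the relative asymmetry between heavy
and light coverage is preserved in the profile; per-strand normalization
would erase exactly the signal the profile exists to show. The same
contract applies to long-read histograms.

## Quartile stratification

`stratify_samples()` computes `Q1`/`Q3` of $f_L$ by linear interpolation
over sorted order statistics (`quantile(type = 7)`, R's default; the rule
name is recorded in the output for reproducibility). Boundary samples are
inclusive — exactly at `Q1` is `low`, exactly at `Q3` is `high` — since a
"bottom quartile" naturally includes its boundary. Samples with undefined
fractions (no mitochondrial reads) are excluded from quantile computation
and reported as tier `missing`; equal-valued cohorts (no spread) are all
`intermediate` with a warning rather than an arbitrary split. Requires at
least four defined samples; quartiles of fewer are not meaningful.

## Long-read feature counting

`count_features_longread()` reproduces the featureCounts configuration
used for RIP-seq bar graphs: a read is assigned to **every** feature its
aligned blocks intersect by at least `min_overlap = 6` bases
(`allow_multi_overlap`), multimappers are excluded
(`count_multimappers = FALSE`), and secondary/supplementary records never
count, so a chimeric read counts at most once per feature. Percentages
are shares of total *assignments* (a read assigned to $k$ features
contributes $k$), so they sum to 100 even with multi-overlap. Because
assignment is per-feature-independent, removing the tRNAs
(`strip_trnas()`) never changes any other feature's count — asserted as
an invariant, and the reason the tRNA-stripped annotation variant is
computed by removal rather than re-annotation.

## Editing caller

`build_pileup()` counts bases in **transcript-sense space**: SAM stores
bases in forward-reference space, so when the sense strand is the minus
strand every base is complemented. In this space an A→G edit appears as G
in the pileup column regardless of which strand each read aligned to —
sense-only and antisense-only reads of the same molecules give identical
columns (tested). The default sense strand is the heavy reference strand,
i.e. the annotated sense of the rRNA region where mitochondrial editing
is observed.

Candidate sites have $g = G/(A+G) \in (0.05, 0.95)$ (open interval) at
$A+G$ depth ≥ 10, per RNA replicate. The interval quantifies "partial G":
at or below the floor is indistinguishable from noise, at or above the
ceiling the base is presumed genomic G. $g$ deliberately ignores C, T and
deletions at the site — they indicate error, not editing. All three
thresholds are configuration-exposed. A consequence worth stating plainly:
a site whose true editing rate sits *at* the noise floor has a realized
$g$ that falls on either side of the threshold with roughly equal
probability per replicate, so such sites are not reliably callable at any
depth — the floor should be chosen below the rates one needs to detect.

Candidates are then cross-referenced against DNA replicate evidence, with
statuses assigned in precedence order:

| status | rule |
|---|---|
| `genomic_variant` | any DNA replicate's major allele ≠ A |
| `heteroplasmic` | majors all A, but minor-allele fraction ≥ `het_threshold` (0.05) in any replicate |
| `low_coverage` | DNA evidence missing, or the RNA shortfall is a depth failure |
| `unreproducible` | candidate in fewer than `min_replicates` RNA replicates (default: all supplied, mirroring the dismissal of non-replicated sites) |
| `edited` | everything above passes |

`mean_edited_fraction` averages $g$ over qualifying replicates. DNA
evidence comes in two kinds, and the difference matters: **consensus
FASTA** implies allele fraction 1.0 for the consensus base, so
heteroplasmy is *undetectable* from consensus input — the heteroplasmy
check requires allele tables. `composition_summary()` reports A/C/G/T
percentages of RNA bases at reference-A positions, the global readout
whose G share falls and A share rises when editing activity drops (e.g.
under ADAR1 knockdown).

## The synthetic world

The generator's defaults are a fixed statement of the scenario being
emulated, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| genome length | 16,569 bp | the human mitochondrial reference length |
| annotation | 38 features | human gene order: 1 D-loop, 2 rRNA, 13 mRNA, 22 tRNA; ND6 + 8 tRNAs on the minus strand |
| read length / fragment | 100 nt, 250 ± 30 | typical stranded paired-end bulk libraries |
| protocol | `RF` | the common dUTP chemistry |
| long reads | 40–300 nt | lower bound ≈ the minimal J2-detectable duplex |
| sequencing error | 0 | exact-recovery tests stay meaningful; an error mode exists for robustness tests |
| decoy contig | `nuc1`, 50 kb uniform random | mapping-fraction tests need a non-mitochondrial destination |
| editing rate regime | ~0.05–0.22 | the observed per-site edited fractions at the validated RNR2 site |

Each component draws from its own named RNG substream (seed + fixed
offset), so adding editing to a configuration does not perturb the read
placements; identical configs give byte-identical SAM output. The scaled
position equivalent of 2,617 is forced to reference A inside RNR2 so
editing tests always have a guaranteed target. Editing is a property of
the *molecule*: in forward-reference space an edit becomes G (plus-sense
site) or C (minus-sense site) in every covering read, so sense and
antisense reads agree by construction.

What the generator does **not** emulate: nanopore error profiles, polyA/
ligation artifacts, expression-level biological realism beyond per-feature
region weights, origin-spanning fragments (disabled by default to keep
oracle bookkeeping simple — and consequently the toy D-loop is a single
interval at the genome start rather than an origin-spanning pair), or
non-uniform fragment-length biology. A green test therefore establishes
correctness of the *computation* on ideally-behaved data — filters,
orientation logic, counting semantics, threshold logic, exact
truth-recovery — not robustness to platform noise, which must come from
real data.

## Numerical and degenerate-input choices

* Zero mitochondrial fragments: fractions are `NA` with a warning, never
  an exception; TSV output writes `.` for missing.
* All-zero coverage: normalized vectors all zero, with a warning (no 0/0).
* Candidate interval bounds are open on both sides; quartile tier bounds
  are closed on both sides. Both choices are asserted in tests.
* `aggregate`-based overlap summation is exact integer arithmetic; no
  floating-point tolerance is needed anywhere in counting.
* Reported positions are 1-based everywhere a human reads them.

## Limitations

* The heteroplasmy check is only as good as the DNA evidence: consensus
  input silently (but documentedly) disables it.
* Editing at sites whose rate sits at the candidate noise floor is not
  reliably detectable (see above); the caller reports what the thresholds
  imply rather than guessing.
* The m1A caveat: the prominently edited rRNA position is also a known
  m1A-modification site, and misincorporation at m1A can mimic editing.
  The caller reports the site; distinguishing modification-driven
  misincorporation from ADAR editing is interpretation, outside this
  package's scope.
* No hyper-editing cluster detection, ADAR isoform attribution, or
  retroelement editing; the pipeline is mitochondria-only by design.
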