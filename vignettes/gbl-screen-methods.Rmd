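---
title: "Designing and evaluating a degenerate PCR screen for gamma-butyrolactone systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a degenerate PCR screen for gamma-butyrolactone systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gamma-butyrolactones (GBLs) and related butenolide/furan autoregulators
control secondary metabolite production in *Streptomyces*. The biosynthetic
gene (an AfsA-family synthase, "ScbA-like") and the TetR-family receptor
("ScbR-like") are frequently collocated on the chromosome, most often in
divergent ("back-to-back") orientation, with the receptor's palindromic
operator — the autoregulatory response element (ARE) — in the shared
intergenic region. A PCR assay with one degenerate primer anchored in each
gene can detect such a locus, and amplify its intergenic region, without
whole-genome sequencing. `gblscreen` implements the complete in-silico side
of designing and evaluating such an assay:

1. **pair finding** — locate synthase/receptor homologue pairs in annotated
   genomes within a maximum intergenic distance and classify their
   orientation;
2. **conservation profiling** — align the homologue proteins, compute
   per-column information content, and select short conserved windows as
   primer anchors;
3. **primer design** — back-translate an anchor context into an IUPAC
   degenerate primer using a codon usage table, with the conserved motif at
   the primer's 3' end;
4. **efficacy estimation** — count anchor-motif variants across pairs and
   use motif co-occurrence as a proxy for amplification success;
5. **in-silico PCR** — match degenerate primers with 3'-aware mismatch
   rules, predict product sizes, and classify priming likelihood of
   variants;
6. **ARE discovery** — an EM (ZOOPS) motif finder over the amplified
   intergenic regions, with a palindromicity score and an empirical
   significance estimate.

A first-class synthetic fixture generator plants all of the above with
machine-readable ground truth, so every stage is testable end to end
without network access.

## Models and procedures

### Homologue pairs

Homology search is local alignment (Smith–Waterman, affine gaps, BLOSUM62;
engine: `Biostrings::pairwiseAlignment`) of the query protein against every
CDS translation. Significance uses the Karlin–Altschul formula
$E = K\,m\,n\,e^{-\lambda S}$ with ungapped BLOSUM62 parameters
($\lambda = 0.318$, $K = 0.13$) on an effective search space of query
length times summed proteome length. Applying ungapped parameters to gapped
scores is a deliberate approximation: we claim no threshold parity with
BLAST or cblaster, and the package's tests use fixtures with score margins
far from the default threshold (E < 0.02) so the approximation cannot flip
an outcome.

Two hits form a pair when they lie on the same contig with an inter-CDS gap
(bp between the two closest CDS boundaries, strand-agnostic; overlap counts
as 0) of at most 600 bp. Orientation is read from the strands of the
coordinate-left and -right feature: `-`/`+` is divergent, `+`/`-`
convergent, equal strands tandem. Pairs overlapping by more than 30 bp are
flagged ambiguous and excluded from the census. All coordinates in the
package are 1-based inclusive, the convention of every Bioconductor
container it interoperates with; readers convert GenBank/GFF3 coordinates
(already 1-based) directly.

### Conservation and anchor windows

Homologue sets are star-aligned: every sequence is globally aligned to the
reference and merged on reference coordinates. A full progressive MSA is
unnecessary because the downstream consumer is per-column statistics around
highly conserved anchors; star alignment is exact at and near such columns.
Per-column information content is
$IC = \mathrm{occupancy} \times (\log_2 20 - H)$, with $H$ the Shannon
entropy of residue frequencies after a pseudocount of 1/20 per residue. No
background-composition or small-sample correction is applied; at the
20-plus-sequence depths the screen works with, the small-sample bias is
well below the contrasts being ranked. Candidate anchor windows (length
4–6) are ranked by mean IC, ties toward the smaller column index, and
rendered as patterns in which a position whose modal residue falls below
50% frequency becomes the wildcard `x` — the threshold that turns a
position mixing I/L/V into the `x` of `ETxRQ` while keeping `YFHF` fully
specified.

Motif variants per homologue are read from the alignment columns of the
chosen window, not by re-scanning the unaligned sequence, so the variant
table is consistent with the profile that selected the window.

### Degenerate primers

A primer derives from an anchor context (motif first, e.g. `YFHFPSKER` or
`ET{ILV}RQSG`): the context is back-translated codon by codon under a
per-position policy, then reverse-complemented, so the primer is antisense
to the coding strand and its 3'-terminal base pairs with the first base of
the motif's first codon. Policy rules:

| rule | codons used |
|---|---|
| `full` | all synonymous codons, merged to the minimal IUPAC codon |
| `top2` | two most frequent codons by the usage table, merged |
| `top1` | single most frequent codon |
| `codon` | an explicitly pinned codon |
| `residue_set` | top-2 codons of each allowed residue, merged |

The bundled `scb_policies()` reproduce the published scb_F/scb_R primer
pair exactly (verified by string equality in the tests). One position —
the Arg of scb_F's context — is pinned explicitly to CGG, the
second-ranked Arg codon of the bundled table, because no frequency rule
yields CGG here while scb_R's Arg uses top-ranked CGC; the policy file is
the package's ground truth for the published sequences, not a claim about
how they were originally derived. The `residue_set` merge for {I,L,V}
yields VTB, which also admits ATG (Met): this over-coverage is intentional
and documented, and `verify_primer()` reports it.

The bundled codon usage table is a representative high-GC
*S. coelicolor*-style table shipped as a versioned TSV fixture
(`inst/extdata/codon_usage_streptomyces.tsv`); per-residue frequencies sum
to 1 and the rank order of the codons that matter to the bundled policies
(CCG>CCC, ACC>ACG, AGC top Ser, CGC>CGG, ATC>ATT, CTG>CTC, GTC>GTG, AAG,
GAG, CAG, GGC) follows published usage for the organism. Melting
temperature is reported only as the Wallace rule 2(A+T)+4(G+C) per
expansion, with GC% ranges; the assay this models ran at a fixed annealing
temperature and no thermodynamic model is implemented.

### In-silico PCR

A primer matches a template site when at most `max_mismatch` positions
fail IUPAC set-intersection compatibility and no failure lies within the
3'-terminal `three_prime_exact` bases (default 3) — 3' mismatches abolish
extension. `N` in the template never matches: nonspecific annealing is not
assumed. Both strands are scanned; every inward-facing plus/minus site
combination of the two primers with a product in [100, 3000] bp is
reported, the length measured 5'-most base to 5'-most base inclusive of
both primer footprints. The window is deliberately wider than the
500–700 bp the assay targets so that off-target products are visible
rather than silently dropped; predicting genuinely nonspecific products is
out of scope.

Priming likelihood of a binding-site variant is classified at the
nucleotide level, so conservative residue swaps with silent first/second
base agreement are scored fairly. For each motif position the minimum
number of incompatible bases between the variant residue's codons and the
primer's codon pattern is computed; then, worst outcome wins:

* **will_not_prime** — ≥ 2 incompatible bases within the first two motif
  codons (the primer's 3'-terminal six bases), or ≥ 3 overall;
* **might_not_prime** — one incompatible base in the first two codons, 1–2
  in interior codons, or an unknown (`x`) residue in the first two codons;
* **will_likely_prime** — `x` at an interior/last position, or
  incompatibilities confined to the motif's last codon (which sits at the
  primer's 5'-distal end);
* **will_prime** — fully compatible.

The thresholds were fixed from the principle that 3'-proximal mismatches
kill priming and calibrated once against the qualitative outcomes of the
validated variant table (a single-base change like S-for-T at codon 2 is
"might not prime"; a two-base change like H-for-F is "will not prime");
they are configurable nowhere because they define the class scale itself.

### ARE discovery

The motif finder fits a ZOOPS model per width $w$: each sequence carries at
most one motif occurrence (site prior $\gamma = 0.8$; OOPS sets
$\gamma = 1$), uniformly placed over both strands, against a 0-order
strand-symmetric background estimated from the input. Every distinct
w-mer of the input is scored as a seed with a single E-pass likelihood
(seed PWM: 0.6 on its own base), and the best seed is run to EM
convergence (LLR increase < 1e-6 or 200 iterations) — the classic
seed-screening heuristic of EM motif finders, adopted because running full
EM from every seed is quadratic-times-iterations in the input. The EM
monotonicity guarantee is asserted on every fitted trace in the test
suite.

Width selection across 15–30 uses an empirical calibration: the observed
best LLR per width is compared with the best LLR attainable on
dinucleotide-shuffled copies of the input (Altschul–Erikson shuffle,
preserving dinucleotide counts), and the width with the least attainable
observed LLR wins (ties: larger null z-score, then smaller width).
Significance is reported the same way:
$(1 + \#\{\text{null LLR} \ge \text{observed}\}) / (1 + n_\text{shuffles})$,
with resolution floor $1/(1+n)$. Null fits receive exactly the same seed
screen and EM effort as the observed fit. Because the shuffle conditions on
each sequence's dinucleotide counts, the null is somewhat narrower than the
marginal distribution of the statistic, and an occasional signal-free
dataset can reach the floor; calibration claims should therefore be read
per-median, not per-dataset. An analytic E-value in the style of MEME
is intentionally **not** reimplemented — the published E-value depends on
MEME internals and its specific Sanger inputs; this package's contract is
motif recovery and honest empirical calibration, not bit-parity.

Palindromicity of a PWM is $1 - \overline{TV}$, the mean per-column total
variation distance between the PWM and the reverse complement of its
column-reversed self: a perfect inverted repeat scores 1, poly-A scores 0.

## The synthetic fixture generator

`generate_pair_locus()` emits one contig: 70% GC order-0 background, a
receptor CDS (215 aa, anchor context at positions 25–33) and a synthase
CDS (310 aa, context at 55–61) in the requested orientation with the
requested gap, derived from deterministic synthetic stand-in query
proteins at a requested identity (anchor windows protected). Context
codons are sampled from the intersection of the residue's codons with the
primer's codon pattern whenever the variant permits, so primer-compatible
variants genuinely carry matchable sites; accidental extra primer sites or
anchor-pattern matches are removed by rejection sampling. Ground truth
(CDS intervals, variants, primer-site coordinates, expected product size,
planted operator position) is returned as a tibble and written as a
sidecar TSV next to the GenBank/GFF3/FASTA fixtures. Under the fixed
context placements the expected product size is `gap + 282` bp, which is
how `target_amplicon` specs (e.g. the 697/600/533/513 bp panel) set their
gaps.

`generate_cohort()` samples orientations and binding-site variants per
locus. The defaults emulate the screened corpus: 90.2% divergent pairs,
receptor variants at 86.2% YFHF / 7.3% YFHY / 1.3% YHHF (YFHx totalling
93.5%), synthase variants with ETxRx totalling 74.2% and ESxRQ at 10.8% —
the printed relative frequencies of the corpus the assay was designed
against, scaled to desk size. What the generator does *not* emulate:
sequencing error, PCR artifacts and chimeras, multi-copy targets per
genome, compositional heterogeneity along real replicons, and annotation
errors. Green tests on these fixtures therefore demonstrate algorithmic
correctness under the stated model, not robustness to dirty annotations.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data at
desk scale, the package's own choice of study size: cohorts of 40–120
loci (contigs ~2 kb), homologue sets of ~20 sequences for profiling, 5–7
sequences of 250–500 bp for motif discovery, 49 shuffles for significance
(floor 1/50) and 3–5 shuffles per width for width calibration. EM uses a
Dirichlet pseudocount of mass 0.1 times the background per PWM cell;
background frequencies are floored by a +1 count. Ties in seed ranking
resolve to the first-enumerated (smallest sequence, then offset) w-mer,
making every fit deterministic given the seed; all shuffle randomness
derives from an explicit `seed` argument and never touches the caller's
RNG state.

Degenerate inputs are handled explicitly: empty FASTA yields an empty
genome list; CDS outside their contig are skipped with a warning;
annotated translations that disagree with recomputation are kept (with a
message) because submitted annotations are authoritative for screening;
internal stop codons raise a pseudogene error; zero-width intergenic
intervals return empty strings.

## Known limitations

* The E-value model is a calibrated approximation, suitable for the large
  margins of this screen, not for borderline homology calls.
* Star alignment can misplace columns in low-identity regions far from
  anchors; only anchor-window columns are consumed downstream.
* The screen assumes annotated CDS; there is no gene calling.
* Corpus-scale statistics (assembly counts, absolute variant counts)
  depend on a historical database snapshot and are represented here only
  through the cohort generator's frequency defaults.
* Real nonspecific amplification (e.g. an off-size band from a
  partially-matching template) is not predicted.
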