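# gblscreen

Design and in-silico evaluation of degenerate PCR screens for
γ-butyrolactone (GBL) regulatory systems in *Streptomyces*.

GBLs and related butenolide autoregulators switch on secondary metabolite
production. The biosynthetic synthase gene (ScbA/AfsA family) and its
TetR-family receptor (ScbR family) are usually collocated, most often
divergently transcribed ("back-to-back"), with the receptor's palindromic
operator — the autoregulatory response element (ARE) — in the shared
intergenic region. A PCR assay with one degenerate primer anchored in a
conserved motif of each gene detects such loci, and amplifies their
intergenic region, without whole-genome sequencing. This package is for
microbiologists and bioinformaticians who want to design such an assay,
predict which strains it will detect, and mine the resulting amplicons for
operators.

## What it does

* **Genome I/O** — GenBank flat files or GFF3+FASTA; CDS extraction and
  bacterial (table 11) translation; IUPAC utilities (`revcomp()`,
  `expand_degenerate()`, `iupac_merge()`).
* **Pair finding** — Smith–Waterman/BLOSUM62 homology search
  (Karlin–Altschul E-values, default threshold E < 0.02), collocation
  within a maximum intergenic distance (default 600 bp), orientation
  classification (divergent / convergent / tandem) and intergenic
  extraction.
* **Conservation profiling** — star alignment of homologue proteins,
  per-column information content, anchor-window selection with wildcarding
  (`YFHF`, `ETxRQ`), motif-variant counting, and the motif co-occurrence
  estimate of primer efficacy.
* **Primer design** — codon-usage-aware back-translation of an anchor
  context into an antisense degenerate primer with the motif at its 3'
  end. The bundled policies and high-GC *Streptomyces* codon table
  reconstruct the published scb_F/scb_R pair exactly:

  scb_F `CCGCTCCTTGCTSGGRAARTGRAARTA` (degeneracy 32),
  scb_R `GCCGCTCTGGCGVABSGTYTC` (degeneracy 36).
* **In-silico PCR** — degenerate matching with IUPAC set-intersection
  semantics, a strict 3'-terminal window, amplicon size prediction, and a
  four-level priming-likelihood classification of binding-site variants
  (`will_prime` … `will_not_prime`).
* **ARE discovery** — a ZOOPS EM motif finder (widths 15–30, both
  strands, every distinct w-mer screened as a seed), with palindromicity
  scoring and an empirical dinucleotide-shuffle significance.
* **Synthetic fixtures** — `generate_pair_locus()` / `generate_cohort()`
  plant GC-rich loci with controlled orientations, motif variants,
  operators and full ground-truth tables; all tests run offline on them.

## Worked example

Design the primer pair, plant a divergent locus whose primer sites span
600 bp, and predict the product:

```r
library(gblscreen)

pol <- scb_policies(); tab <- codon_usage_table()
scb_F <- design_primer(pol$scb_F$context, pol$scb_F$policy, tab,
                       role = "receptor", name = "scb_F", motif_len = 4)
scb_R <- design_primer(pol$scb_R$context, pol$scb_R$policy, tab,
                       role = "synthase", name = "scb_R", motif_len = 5)
scb_F
#> <degenerate_primer> scb_F (receptor): 5'-CCGCTCCTTGCTSGGRAARTGRAARTA-3' (degeneracy 32, context YFHFPSKER)
scb_R
#> <degenerate_primer> scb_R (synthase): 5'-GCCGCTCTGGCGVABSGTYTC-3' (degeneracy 36, context ET{ILV}RQSG)

loc <- generate_pair_locus(plant_spec(target_amplicon = 600, seed = 9001,
                                      synthase_variant = "ETIRQ"))
loc$genome
#> <genome_record> synthfix_001: 2199 bp, 2 CDS

predict_amplicons(scb_F, scb_R, loc$genome$sequence)
#> # A tibble: 1 × 7
#>   contig_id start   end length fwd_primer rev_primer mismatches
#>   <chr>     <int> <int>  <int> <chr>      <chr>           <int>
#> 1 template    700  1299    600 scb_F      scb_R               0

classify_priming("YHHF", "YFHF", scb_F, tab)
#> [1] will_not_prime
#> 4 Levels: will_prime < will_likely_prime < ... < will_not_prime
```

The predicted product is a single 600 bp amplicon — the planted
outer-edge distance between the two primer sites — and a receptor whose
binding site reads `YHHF` instead of `YFHF` is classified
`will_not_prime`: its His-for-Phe substitution costs two incompatible
bases inside the primer's 3'-terminal six, which abolishes extension.

`run_screen()` chains every stage (homology → pairing → census → variant
table → primers → in-silico PCR → ARE discovery) over a set of genomes
and persists all intermediates as TSV/FASTA; `glance()` on the report
gives the one-row summary.

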