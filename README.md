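# barcodeAudit

Tools for auditing DNA-barcode species identification — written for
molecular ecologists and taxonomists who need to know not just *what*
a COI barcode dataset says, but *how far its analytical machinery can
be trusted*, especially for groups like marine planktonic copepods
where morphology is conserved, within-species diversity is high, and
sampling is wildly unbalanced.

The package implements the full assessment chain:

* **Alignment handling** — taxonomy-annotated FASTA I/O, the three
  standard analysis variants (*original* = everything; *standard* =
  records > 500 ungapped bp; *unique* = a trimmed column window with
  within-species haplotypes collapsed), length and taxon censuses.
* **Numt screening** — three-frame translation under the invertebrate
  mitochondrial code (internal stop codons ⇒ pseudogene) plus a robust
  divergence outlier rule (median conspecific K2P > species median +
  5·MAD).
* **Distances** — Kimura 2-parameter and p-distances with pairwise
  deletion, overlap gating and explicit *undefined* entries;
  per-taxonomic-level summaries with Mann–Whitney tests (exact
  enumeration for small samples); barcode-gap reports; sliding-window
  nucleotide diversity π; distance histograms.
* **Trees** — neighbour-joining (Saitou–Nei, with K2P distance
  d = −½·log[(1−2P−Q)·√(1−2Q)]), column-bootstrap support, newick I/O,
  midpoint rooting, monophyly classification.
* **PTP delimitation** — a single-rate Poisson tree processes model:
  speciation vs within-species coalescent branch classes, exponential
  rates fit by maximum likelihood, BIC-penalised search over
  transition-node sets.
* **MOTU clustering** — jMOTU-style single-linkage clustering on
  absolute sequence differences with overlap/identity gates, MOTU
  curves across cutoff grids, MOTU/OTU concordance.
* **Best close match** — leave-one-out species assignment against a
  dataset-calibrated intraspecific threshold, with
  correct / incorrect / ambiguous / no-identification verdicts.
* **ΦST** — distance-based AMOVA between sample groups with
  permutation tests.
* **A truth-known simulator** — taxonomy-structured barcode datasets
  under a K80 substitution process, with truncated reads, numt
  contaminants, forced zero-distance heterospecific pairs and cryptic
  5–7% conspecific splits, so every claim above is testable.

## Worked example

Simulate a 20-species survey (5 records each, one forced zero-distance
heterospecific pair — the known failure mode of distance-based
assignment) and run the whole assessment:

```r
library(barcodeAudit)

cfg <- run_config(
  sim = sim_config(n_genera_per_family = 4, n_species_per_genus = 5,
                   n_seqs_per_species = 5, n_zero_pairs = 1),
  variants = c("original", "unique"),
  seed = 7)
rep <- run_assessment(cfg, out_dir = "audit_out")
rep
#> Barcode assessment: 100 records in (1 numts removed)
#>   original    99 records, 20 MOTUs at cutoff, 20/20 exact OTU matches
#>   unique      94 records, 20 MOTUs at cutoff, 20/20 exact OTU matches
```

Reading the output: the divergence screen removed one record — the
zero-distance *receiver*, which carries another species' haplotype and
is therefore indistinguishable from a contaminated or misidentified
specimen. On the cleaned data, single-linkage clustering at the 3%
difference cutoff recovers exactly the 20 true species on both
alignment variants (20 MOTUs, 20/20 exact OTU matches), and best close
match assigns every remaining record to the right species:

```r
rep$variants$original$bcm_verdicts
#> correct=99 incorrect=0 ambiguous=0 no_id=0
round(rep$variants$unique$mean_pi, 3)
#> 0.21
rep$variants$unique$ptp_n_parts
#> 20
```

Mean nucleotide diversity over the trimmed unique alignment is 0.21
substitutions/site — diversity of that order is what makes copepod
barcodes so informative — and PTP on the midpoint-rooted NJ tree
likewise delimits 20 putative species. `audit_out/` holds the report
JSON plus TSVs (MOTU partitions and curves, gap reports, π series,
best-close-match verdicts, numt report) from which every reported count
can be recomputed.

Individual stages are exported directly (`distance_matrix()`,
`screen_numts()`, `neighbor_joining()`, `ptp_delimit()`,
`threshold_clusters()`, `best_close_match()`, `phi_st()`, ...) and
compose with `ape` phylo objects; externally estimated ML trees drop in
as newick via `run_config(tree = "mytree.nwk")`.

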