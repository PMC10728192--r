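# wormforge

Design and verification of multiplexed CRISPR stop-in knockout libraries,
plus the screen statistics used to phenotype them.

## The problem

Large receptor gene families — the *C. elegans* chemoreceptor and
neuropeptide GPCRs are the motivating case, with well over a thousand
genes — are dominated by recent paralogs with redundant functions, so
single-gene knockouts rarely show phenotypes. A practical mutant library
instead disrupts a *set of closely related genes in one strain*. Building
and using such a library takes four computational steps, and `wormforge`
implements all of them on top of standard gene models (FASTA + GFF3):

1. **Paralog grouping.** Proteins are clustered by global-alignment
   identity (identity = identical aligned positions / length of the
   shorter sequence) with greedy representative clustering at a strict
   `> 40%` cutoff, then packed into co-editing groups (≤ 6 genes per
   strain, one subfamily per strain, ≤ 3 genes per microinjection, with
   linkage- and name-order-based packing of leftovers, and reserved genes
   kept as singletons).
2. **Stop-in cassette design.** Per gene: a CDS protospacer/PAM scan (NGG,
   blunt cut 3 nt 5' of the PAM, earliest-truncating sites preferred), a
   7-nt deletion centered on the cut, and an ssODN of two 35-nt homology
   arms around an insert `TAAGTAAGTAA + enzyme site + TGATAA(+pad)` that
   carries a stop codon in all three reading frames *and* forces a
   frameshift (`(|insert| − del) mod 3 ≠ 0`), plus an RFLP genotyping
   assay: a 400–1000 bp amplicon whose edited form is cut once into two
   gel-resolvable fragments (each ≥ 100 nt, difference ≥ 50 nt) while the
   wild-type amplicon stays undigested.
3. **Edit verification.** Variant calls at targeted loci pass a confidence
   filter (> 8 supporting reads, shared by ≤ 6 samples), are aligned to the
   predicted edited locus (±20 bp flanks), and classified:
   0 mismatches → `disrupted_exact`, 1–2 → `disrupted_mismatch`,
   more with a structural flag → `disrupted_larger_cnv`, otherwise
   `needs_curation`; no variant → `unedited`. Gap columns count as
   mismatches.
4. **Screen statistics.** Chemotaxis indices
   `CI = (n_odor − n_control)/(n_odor + n_control)` (quadrant) and
   `(n_odor_circle − n_control_circle)/n_total` (distal), lawn avoidance
   and occupancy, relative changes `(mutant − wt)/wt`, single-worm sector
   scores, strict hit rules (repellent hits at `CI > −0.5`), photobleach
   correction by exponential fit on pre/post-stimulus windows, ΔF/F₀
   against a 5-s pre-onset baseline, and strain-by-strain response-profile
   correlations.

A synthetic-data module generates gene families with controlled identity,
toy genomes, simulated editing outcomes and simulated screens, so the whole
pipeline is exercised end to end by the test suite with no external data.

## Worked example

```r
library(wormforge)

## a synthetic 3-member family at ~60% identity clusters into one group
fam <- make_gene_family(ancestor_len_aa = 120, n = 3, target_identity = 0.6,
                        seed = 1, family_name = "srx", subfamily = "srx")
round(identity_matrix(fam$proteins), 2)
#>       srx-1 srx-2 srx-3
#> srx-1  1.00  0.51  0.67
#> srx-2  0.51  1.00  0.31
#> srx-3  0.67  0.31  1.00
cluster_by_identity(fam$proteins, threshold = 0.40)
#> [[1]]
#> [1] "srx-1" "srx-2" "srx-3"
```

Note `srx-2` vs `srx-3` fall below the cutoff (0.31): the greedy rule
clusters members via the *representative* (`srx-1`, the ancestor), exactly
how a duplicated family stays together even when its leaves have diverged
past the threshold.

```r
## simulate a small library, design every gene, edit in silico, verify
out <- file.path(tempdir(), "demo")
res <- run_pipeline(list(simulate = list(n_families = 2, family_size = 3)),
                    out_dir = out, seed = 7)
res$summary
#>   n_genes n_groups n_designs n_design_errors n_alleles
#> 1       6        2         6               0         6
res$designs[[1]]
#> ssodn_design fam01-1 : 93 nt, EcoRI site, deletion [ 516 , 523 )
res$assays[[1]]
#> genotyping_assay fam01-1 : WT 699 bp (uncut); edited 715 bp -> 197 + 518 bp with EcoRI
res$allele_calls[, c("strain_id", "gene_id", "mismatches", "status")]
#>   strain_id gene_id mismatches          status
#> 1    SIM001 fam01-1          0 disrupted_exact
#> 2    SIM002 fam01-2          0 disrupted_exact
#> 3    SIM003 fam01-3          0 disrupted_exact
#> 4    SIM004 fam02-1          0 disrupted_exact
#> 5    SIM005 fam02-2          0 disrupted_exact
#> 6    SIM006 fam02-3          0 disrupted_exact
```

The design line reads: a 93-nt oligo (35-nt arm + 23-nt insert + 35-nt
arm) replacing the 7 reference bases `[516, 523)` with a triple-frame stop
cassette carrying an EcoRI site; genotyping amplifies 699 bp from the
wild-type locus (undigested) versus 715 bp from the edited locus, which
EcoRI cuts into 197 + 518 bp. Every simulated perfect-HDR allele
round-trips to `disrupted_exact` with 0 mismatches.

The pipeline writes `groups.tsv`, `designs.tsv`, `ssodn.fa`,
`deleted.bed`, `calls.tsv`, `allele_calls.tsv`, `errors.tsv`, a per-stage
log and a `manifest.json` with parameters, seed and output checksums. A
thin command-line wrapper lives at `inst/scripts/forge.R`
(`Rscript forge.R run --config cfg.yaml --out dir --seed 1`).

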