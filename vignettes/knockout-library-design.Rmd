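---
title: "Designing and verifying multiplexed stop-in knockout libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying multiplexed stop-in knockout libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormforge)
```

## The problem

The *C. elegans* genome encodes well over a thousand G-protein-coupled
receptors, most of them chemoreceptors that arose by repeated gene
duplication. Because close paralogs are often functionally redundant,
knocking out one gene at a time rarely produces a phenotype; a practical
mutant library instead disrupts *sets of closely related genes in a single
strain*. `wormforge` implements the computational side of building and
exploiting such a library:

1. **Paralog grouping** — cluster receptor proteins by sequence identity and
   pack them into co-editing groups and injection rounds.
2. **Cassette design** — for each gene, design a stop-in ssODN repair
   template and an RFLP genotyping assay.
3. **Edit verification** — filter sequencing-derived variant calls at the
   targeted loci, align observed alleles to the expected edited product, and
   classify each allele.
4. **Screen statistics** — the chemotaxis, pathogen-avoidance, survival and
   calcium-imaging quantities used to call hits, with deterministic hit
   rules.
5. **Synthetic data** — generators for toy genomes, gene families with
   controlled identity, simulated editing outcomes and simulated screens, so
   that every stage is testable end to end without external data.

Internally all genomic coordinates are 0-based half-open on the reference
(+) strand; the 1-based inclusive convention appears only at the GFF3/BED
boundary. A single convention avoids off-by-one drift in the arm and cut
arithmetic, which is where such bugs would be most damaging.

## Paralog grouping

Identity between two proteins is computed from a global alignment (match
+1, mismatch 0, gap open 5, gap extend 1, end gaps penalized) as the number
of identically aligned positions divided by the length of the *shorter*
sequence — the convention of short-sequence clustering tools such as
CD-HIT. The clustering rule is greedy representative clustering: genes are
sorted by protein length (ties broken by gene id), each gene joins the
first cluster whose representative exceeds the identity threshold,
otherwise it seeds a new cluster. The threshold is strict (`> 0.40`): a
pair at exactly 40% identity does not merge.

```{r cluster-demo}
fam <- make_gene_family(ancestor_len_aa = 120, n = 3, target_identity = 0.6,
                        seed = 1, family_name = "srx", subfamily = "srx")
round(identity_matrix(fam$proteins), 2)
cluster_by_identity(fam$proteins, threshold = 0.40)
```

Groups are then assembled under the library's practical constraints:
multi-member identity clusters seed the groups (split into chunks of at
most `max_group_size`, default 6, i.e. two editing rounds of three genes);
leftover singletons join an existing same-subfamily group when they lie
within `linkage_window_bp` of one of its members on the same chromosome;
the remainder are packed by the numeric order of their gene names within
each subfamily; and genes flagged *reserved* (well-characterized receptors
that should be interpretable on their own) always become singleton strains.
Groups never mix subfamilies. The linkage window default of 50 kb is a
design choice — "closely linked" is inherently qualitative — and is an
explicit, logged parameter rather than a hidden constant. Phylogeny-based
rescue is supported only as a rationale tag for user-supplied pairings;
tree inference is out of scope.

## Stop-in cassette design

For each gene the designer scans the CDS for SpCas9 protospacers (20 nt +
NGG on either strand, blunt cut modeled 3 nt 5' of the PAM) and prefers
sites in the 5' half of the CDS so that truncation happens as early as
possible. Around the chosen cut it removes a short stretch of coding
sequence (default 7 nt, centered on the cut) and replaces it with an insert
flanked by two 35-nt homology arms copied verbatim from the reference.

The insert is built from a canonical stop block, `TAAGTAAGTAA`, followed by
a restriction site and `TGATAA`, padded so that the net length change is
not a multiple of 3. This gives three independent layers of disruption:

* a stop codon in **all three reading frames** of the insert itself,
* a **frameshift** for any translation that somehow reads through, and
* a **diagnostic restriction site** present once in the edited allele and
  absent from the wild-type amplicon, so a simple PCR + digest genotyping
  assay distinguishes edited from unedited animals.

The enzyme is chosen per locus: the first entry of a table of common
palindromic 6/8-cutters whose site does not occur in the wild-type
neighborhood (within 1 kb of the deletion, which bounds any genotyping
amplicon) and occurs exactly once after editing. The genotyping assay
places two exact-match primers (18–25 nt, GC 40–60%, no mononucleotide run
over 4 — composition rules only; thermodynamic modeling is deliberately out
of scope) so that the wild-type amplicon is 400–1000 bp and the digest of
the edited amplicon yields two fragments, each at least 100 nt and
differing by at least 50 nt, i.e. resolvable on a gel.

```{r design-demo}
set.seed(7)
fams <- simulate_gene_set(n_families = 1, family_size = 1,
                          target_identity = 1, ancestor_len_aa = 250)
toy <- build_toy_genome(fams, spacer_len = 500)
dir <- file.path(tempdir(), "vignette-lib")
write_sim_bundle(toy, dir, seed = 7)
genome <- read_genome(file.path(dir, "genome.fa"))
models <- read_gene_models(file.path(dir, "genes.gff3"), genome)
lib <- design_library(models, genome)
lib$designs[[1]]
lib$assays[[1]]
```

Every design is checked by `validate_design()`, which aggregates all the
invariants above into one pass/fail report; `design_library()` only returns
designs that pass, and records machine-readable failure reasons
(`no_cut_site`, `no_unique_site`, `no_amplicon`, `digest_unresolvable`,
`cut_near_boundary`, `ambiguous_reference`) for the rest.

## Verification of edited alleles

Variant calls at the targeted loci (from a structural-variant caller run
upstream; read mapping and CNV calling are consumed, not reimplemented)
pass a confidence filter first: a call needs **more than 8 supporting
reads** (strict) and may be shared by **at most 6 samples** (inclusive;
sibling strains can inherit the same parental edit). Surviving calls are
aligned globally against the predicted edited locus — the edited region
plus 20 bp of flanking sequence — and classified:

| mismatches | structural flag | status |
|---|---|---|
| 0 | – | `disrupted_exact` |
| 1–2 | – | `disrupted_mismatch` |
| >2 | yes | `disrupted_larger_cnv` |
| >2 | no | `needs_curation` |

Gap columns count toward the mismatch budget, so the "2 mismatches" limit
is unambiguous for indels. Records with no detected variant are `unedited`;
the confidence filter applies to records that carry a variant. The
`needs_curation` bucket is never auto-resolved: the output table carries an
empty `override` column for a human call, mirroring how ambiguous loci are
resolved by inspection in practice.

The central correctness property ties design and verification together:
for every valid design, the predicted edited allele must classify as
`disrupted_exact` with 0 mismatches. The test suite enforces this
round-trip on a simulated 60-gene library.

## Screen statistics

All assay indices are implemented exactly as defined by their formulas:
quadrant chemotaxis index `(n_odor - n_control) / (n_odor + n_control)`;
distal-spot index `(n_odor_circle - n_control_circle) / n_total` (animals
outside both circles stay in the denominator — forced by the formula);
lawn avoidance `n_off / n_total` with occupancy its exact complement;
relative change `(mutant - wt) / wt` for both avoidance and mean survival;
and the single-worm sector score with values 3, 2, 1, −1, −2, −3 for
sectors A–F.

Hit calling is deterministic and strict: in repellent assays a strain is
flagged when its CI exceeds −0.5 (a strain at exactly −0.5 is not
flagged); for relative-change screens the low/high 5% quantile tails are
flagged, again strictly. The quantile default is a parameter, not a claim
about any particular screen.

For calcium imaging, photobleaching is corrected by fitting
`y = a·exp(−b·t)` by ordinary least squares on log-transformed values over
the pre- and post-stimulus windows only (first 30 s and last 20 s of the
recording), never the response window, with `b` constrained non-negative;
the trace is divided by the fit. F₀ is the mean of the corrected trace
over the 5 s before odor onset, and ΔF/F₀ = (y − F₀)/F₀. Degenerate fits
(non-positive values, undefined slope) return the trace uncorrected with a
warning flag rather than fabricating a correction. Hypothesis testing
(Welch t, ANOVA/Tukey, log-rank) is deliberately left to standard
statistical routines — the package's contribution is the index and trace
computation and the deterministic flagging, not the tests.

```{r trace-demo}
tr <- simulate_fluor_trace(a = 100, b = 0.01, amp = -0.5, onset = 30,
                           dur = 30, noise_sd = 0.3, seed = 1)
dff <- delta_f_over_f0(bleach_correct(tr), odor_onset_t = 30)
mean(dff$y[dff$t >= 32 & dff$t < 58])   # planted amplitude was -0.5
```

## What the synthetic data emulates — and what it does not

The generator reproduces the *statistical structure* each stage assumes:

* **Gene families** are a random ancestor plus descendants mutated per site
  at rate `1 − target_identity` (substitutions to one of the 19 other
  residues), so identity to the ancestor matches the target in expectation;
  back-translation uses one fixed codon per amino acid, since identity
  targets live at the protein level. Families are re-sampled until every
  member has a protospacer cut site in the 5' half of its CDS, so every
  generated gene is designable.
* **Toy genomes** are single-exon genes with alternating strands separated
  by random spacers, with matching GFF3.
* **Editing outcomes** plant a controlled number of substitutions (or a
  structural flag, or nothing) into the predicted allele, with read support
  `10 + Poisson(20)` for confident calls — an invented distribution whose
  only relevant property is sitting clearly above the >8-read filter.
* **Screens** draw binomial worm placements (expected quadrant CI is
  `2p − 1`), Weibull survival times, and exponentially bleaching traces
  with a boxcar response plus Gaussian noise.

Real data differ in ways the generator does not model: multi-exon gene
structure (the designer handles multiple CDS intervals, but protospacers
spanning splice junctions are not considered), codon usage and nucleotide
composition bias, sequencing error profiles, alignment artifacts near
repeats, and non-stationary bleaching. Passing tests therefore demonstrate
the correctness of the arithmetic and the internal consistency of the
pipeline — not the error rates that would be observed on real sequencing
data.

Default study conditions used throughout the tests and the acceptance
script: 20 families × 3 members of 300-aa proteins (60 genes), identity
targets 0.60 (within families) and 0.20 (between), 150 worms per
chemotaxis plate, 30 animals per lawn plate, 90-s recordings at 4 Hz with
bleach rate 0.01 s⁻¹ and response amplitudes −0.5 and +1.0. These mirror
the assay geometry of the screens the package models and keep every
simulation comfortably inside interactive runtimes.

## Numerical and design choices

* **Alignment scoring** (match +1, mismatch 0, gap 5 + 1/nt, end gaps
  penalized) is fixed package-wide so identity values and mismatch counts
  are reproducible; identity counts only exact residue matches. For
  equal-length sequences with few differences the ungapped alignment is
  provably optimal under this scoring (a compensating insertion–deletion
  pair costs at least 12 while a substitution costs at most 1), and the
  implementation uses that fast path; the test suite checks it against an
  independent affine-gap dynamic-programming oracle.
* **Tie-breaks** are deterministic everywhere: longest isoform by CDS
  length then smallest transcript id; cluster order by protein length then
  gene id; cut sites by CDS offset; enzyme choice by table order; primer
  pairs by distance from a 700-bp target amplicon.
* **Deletion length** defaults to 7 nt (configurable 4–30), centered on the
  cut and shifted only to stay inside the CDS interval; the frameshift
  condition is enforced jointly with the insert length.
* **Enzyme-site uniqueness** is enforced within the amplicon-bounding 1-kb
  window, not genome-wide: the genotyping readout is an amplicon digest, so
  distant sites are irrelevant.
* **Degenerate inputs** fail loudly and specifically: empty sequences,
  RNA input, duplicate FASTA ids, CDS length not divisible by 3, windows
  outside a trace, zero denominators (NA with warning), identity edits
  (rejected as non-knockouts).

## Limitations

* Guide efficiency and off-target scoring are out of scope; cut-site
  choice is purely positional.
* Primer design uses composition rules, not melting-temperature models.
* The correlation heatmap uses Pearson correlation by default (Spearman by
  flag); with eight conditions the distinction rarely matters but the
  choice is exposed.
* Manual-curation outcomes are represented, not resolved.
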