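## fixed back-translation table: one codon per amino acid (identity targets
## are defined at the protein level, so codon usage is irrelevant)
codon_table <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(codon_table[aa], collapse = ""), "TAA")
}

## does this coding sequence have an NGG (or reverse-strand CCN) protospacer
## whose cut falls in its 5' half?
has_5prime_protospacer <- function(dna) {
  L <- nchar(dna)
  half <- L / 2
  for (j in 0:(L - 23L)) {
    if (substr(dna, j + 22L, j + 23L) == "GG" && j + 17L <= half) return(TRUE)
    if (substr(dna, j + 1L, j + 2L) == "CC" && j + 6L <= half) return(TRUE)
  }
  FALSE
}

#' Generate a paralogous gene family with controlled identity
#'
#' Emulates a family arisen by gene duplication: a random ancestor protein
#' plus descendants derived by per-site substitution at rate
#' `1 - target_identity` (substitutions drawn uniformly from the 19 other
#' residues, so realized identity to the ancestor matches the target in
#' expectation). The first residue is fixed at M; back-translated DNA uses a
#' fixed codon table with an ATG start and a single terminal stop.
#'
#' @param ancestor_len_aa Ancestor protein length (aa).
#' @param n Family size including the ancestor (the ancestor is member 1).
#' @param target_identity Target pairwise identity to the ancestor, in
#'   (0, 1].
#' @param seed Optional RNG seed.
#' @param family_name Stem for gene ids (`<family_name>-<i>`).
#' @param subfamily Subfamily label shared by the family.
#' @return List with `proteins` and `dna` (named character vectors),
#'   `subfamily`, and `ancestor` (the ancestor's gene id).
#' @export
make_gene_family <- function(ancestor_len_aa = 300L, n = 3L, target_identity,
                             seed = NULL, family_name = "fam01",
                             subfamily = "sra") {
  stopifnot(target_identity > 0, target_identity <= 1)
  if (!is.null(seed)) set.seed(seed)
  aas <- names(codon_table)
  ancestor <- c("M", sample(aas, ancestor_len_aa - 1L, replace = TRUE))
  prots <- list(paste(ancestor, collapse = ""))
  for (k in seq_len(n - 1L)) {
    desc <- ancestor
    mut <- which(runif(ancestor_len_aa - 1L) < 1 - target_identity) + 1L
    for (i in mut) desc[i] <- sample(setdiff(aas, desc[i]), 1L)
    prots[[k + 1L]] <- paste(desc, collapse = "")
  }
  ids <- sprintf("%s-%d", family_name, seq_len(n))
  proteins <- setNames(unlist(prots), ids)
  list(proteins = proteins,
       dna = setNames(vapply(proteins, back_translate, character(1)), ids),
       subfamily = subfamily, ancestor = ids[1])
}

#' Generate a set of gene families for a toy knockout library
#'
#' Families are re-sampled until every member's CDS carries at least one
#' protospacer with a cut site in its 5' half, so every gene is designable.
#'
#' @param n_families Number of families.
#' @param family_size Members per family (ancestor included).
#' @param target_identity Scalar or per-family vector of identity targets.
#' @param ancestor_len_aa Protein length.
#' @param seed RNG seed.
#' @param subfamilies Pool of subfamily labels cycled over families.
#' @return List of family objects (see [make_gene_family()]).
#' @export
simulate_gene_set <- function(n_families = 20L, family_size = 3L,
                              target_identity = 0.60, ancestor_len_aa = 300L,
                              seed = NULL,
                              subfamilies = c("sra", "srb", "srx", "dmsr", "flp")) {
  if (!is.null(seed)) set.seed(seed)
  target_identity <- rep_len(target_identity, n_families)
  lapply(seq_len(n_families), function(i) {
    for (attempt in 1:50) {
      fam <- make_gene_family(ancestor_len_aa, family_size, target_identity[i],
                              seed = NULL,
                              family_name = sprintf("fam%02d", i),
                              subfamily = subfamilies[(i - 1L) %% length(subfamilies) + 1L])
      if (all(vapply(fam$dna, has_5prime_protospacer, logical(1)))) return(fam)
    }
    stop("could not generate a designable family")
  })
}

#' Assemble gene families into a toy genome
#'
#' Concatenates the genes with random spacers on one chromosome, strands
#' alternating, and builds the matching gene/mRNA/CDS annotation (1-based
#' GFF3 convention) plus per-gene metadata.
#'
#' @param families List of families from [simulate_gene_set()].
#' @param spacer_len Random spacer length between genes (bp).
#' @param seed Optional RNG seed (spacer sequence only).
#' @param chrom Chromosome name.
#' @return List with `genome` (a `genome` object), `annotation` (a
#'   `GRanges` exportable as GFF3), `proteins` (named vector) and `meta`
#'   (data frame: `gene_id`, `subfamily`, `chrom`, `position`, `strand`,
#'   `reserved`).
#' @export
build_toy_genome <- function(families, spacer_len = 500L, seed = NULL,
                             chrom = "chrI") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(families) >= 0L)
  pieces <- character(0)
  rows <- list()
  cursor <- 0L   # 0-based
  gidx <- 0L
  for (fam in families) {
    for (id in names(fam$dna)) {
      gidx <- gidx + 1L
      spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE),
                      collapse = "")
      dna <- fam$dna[[id]]
      strand <- if (gidx %% 2L == 1L) "+" else "-"
      gseq <- if (strand == "+") dna else revcomp(dna)
      pieces <- c(pieces, spacer, gseq)
      start0 <- cursor + spacer_len
      end0 <- start0 + nchar(dna)
      rows[[gidx]] <- data.frame(gene_id = id, subfamily = fam$subfamily,
                                 chrom = chrom, start0 = start0, end0 = end0,
                                 strand = strand)
      cursor <- end0
    }
  }
  pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), spacer_len,
                                   replace = TRUE), collapse = ""))
  seq <- paste(pieces, collapse = "")
  genome <- structure(list(sequences = setNames(seq, chrom),
                           source = "<simulated>"), class = "genome")
  meta <- if (gidx > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(), subfamily = character(),
               chrom = character(), start0 = integer(), end0 = integer(),
               strand = character())
  annotation <- toy_annotation(meta, chrom)
  proteins <- unlist(lapply(families, `[[`, "proteins"))
  meta_out <- data.frame(gene_id = meta$gene_id, subfamily = meta$subfamily,
                         chrom = meta$chrom, position = meta$start0,
                         strand = meta$strand,
                         reserved = logical(nrow(meta)))
  list(genome = genome, annotation = annotation, proteins = proteins,
       meta = meta_out)
}

toy_annotation <- function(meta, chrom) {
  n <- nrow(meta)
  if (n == 0L) {
    return(GenomicRanges::GRanges())
  }
  per_gene <- lapply(seq_len(n), function(i) {
    gid <- meta$gene_id[i]
    gr <- GenomicRanges::GRanges(
      meta$chrom[i],
      IRanges::IRanges(start = rep(meta$start0[i] + 1L, 3L),
                       end = rep(meta$end0[i], 3L)),
      strand = meta$strand[i])
    gr$type <- c("gene", "mRNA", "CDS")
    gr$ID <- c(paste0("gene:", gid), paste0("tx:", gid, ".1"), NA)
    gr$Name <- c(gid, NA, NA)
    gr$Parent <- IRanges::CharacterList(list(character(0),
                                             paste0("gene:", gid),
                                             paste0("tx:", gid, ".1")))
    gr$subfamily <- c(meta$subfamily[i], NA, NA)
    gr$phase <- c(NA_integer_, NA_integer_, 0L)
    gr
  })
  do.call(c, per_gene)
}

#' Simulate one editing outcome at a designed locus
#'
#' Draws an observed locus sequence, read support and sample sharing under
#' one of the outcome modes seen in library verification: `exact` (perfect
#' HDR), `mm1`/`mm2` (HDR with 1-2 substitutions near the insert), `mm3plus_flagged`
#' (3-6 substitutions plus a structural flag), `unedited` (no variant) and
#' `under_supported` (perfect sequence with at most 8 supporting reads).
#' Read support for confident modes is `10 + Poisson(20)`, comfortably above
#' the >8-read filter.
#'
#' @param design An `ssodn_design`.
#' @param mode One of the modes above.
#' @param seed Optional RNG seed.
#' @param strain_id Strain label for the record.
#' @return A one-row variant-call record (data frame) with a `mode` column.
#' @export
simulate_edit_outcome <- function(design, mode, seed = NULL,
                                  strain_id = "simstrain") {
  if (!is.null(seed)) set.seed(seed)
  modes <- c("exact", "mm1", "mm2", "mm3plus_flagged", "unedited",
             "under_supported")
  if (!mode %in% modes) stop("unknown mode: ", mode)
  locus <- design$expected_edited_locus
  plant <- function(seq, k) {
    ins_len <- nchar(design$insert_seq)
    lo <- max(1L, 21L - 5L)
    hi <- min(nchar(seq), 20L + ins_len + 5L)
    pos <- sample(lo:hi, k)
    s <- strsplit(seq, "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    paste(s, collapse = "")
  }
  obs <- switch(mode,
    exact = locus,
    mm1 = plant(locus, 1L),
    mm2 = plant(locus, 2L),
    mm3plus_flagged = plant(locus, sample(3:6, 1L)),
    unedited = "",
    under_supported = locus)
  reads <- switch(mode,
    unedited = 0L,
    under_supported = sample(0:8, 1L),
    10L + rpois(1L, 20))
  samples <- if (mode == "unedited") 0L else 1L
  flags <- if (mode == "mm3plus_flagged") {
    sample(c("duplication", "inversion", "deletion_large", "complex"), 1L)
  } else character(0)
  rec <- variant_call_record(strain_id, design$gene_id, obs, reads, samples,
                             flags)
  rec$mode <- mode
  rec
}

#' Simulate quadrant chemotaxis plate counts
#'
#' Worm placement is binomial: each of `n_worms` animals lands on the
#' odorant side with probability `p_attract`, so the expected CI is
#' `2 * p_attract - 1`.
#'
#' @param p_attract Per-animal probability of choosing the odorant side.
#' @param n_worms Animals per plate.
#' @param n_plates Plates.
#' @param seed Optional RNG seed.
#' @return Data frame with `plate`, `n_odor`, `n_control`, `ci`.
#' @export
simulate_quadrant_counts <- function(p_attract, n_worms = 150L,
                                     n_plates = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_odor <- rbinom(n_plates, n_worms, p_attract)
  data.frame(plate = seq_len(n_plates), n_odor = n_odor,
             n_control = n_worms - n_odor,
             ci = (2 * n_odor - n_worms) / n_worms)
}

#' Simulate pathogen-lawn occupancy counts
#'
#' @param p_off Per-animal probability of leaving the lawn.
#' @param n_total Animals per plate.
#' @param n_plates Plates.
#' @param seed Optional RNG seed.
#' @return Data frame with `plate`, `n_off_lawn`, `n_total`, `avoidance`,
#'   `occupancy`.
#' @export
simulate_lawn_counts <- function(p_off, n_total = 30L, n_plates = 3L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off <- rbinom(n_plates, n_total, p_off)
  data.frame(plate = seq_len(n_plates), n_off_lawn = off, n_total = n_total,
             avoidance = off / n_total, occupancy = 1 - off / n_total)
}

#' Simulate survival times on a pathogen
#'
#' Weibull-distributed survival days with the scale set so the mean equals
#' `mean_days` (shape 3 approximates the sigmoidal slow-killing curves).
#'
#' @param mean_days Mean survival in days.
#' @param n_animals Animals.
#' @param shape Weibull shape.
#' @param seed Optional RNG seed.
#' @return Numeric vector of survival days.
#' @export
simulate_survival <- function(mean_days, n_animals = 30L, shape = 3,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rweibull(n_animals, shape = shape, scale = mean_days / gamma(1 + 1 / shape))
}

#' Simulate an exponentially bleaching fluorescence trace
#'
#' `y(t) = a * exp(-b t) * (1 + amp * boxcar(onset, onset + dur)) + noise`,
#' sampled at `hz` frames per second: a photobleaching baseline with a
#' step response during the stimulus window (negative `amp` models the
#' calcium decrease of an AWC-off-type response).
#'
#' @param a Initial fluorescence (arbitrary units).
#' @param b Bleach rate (1/s).
#' @param amp Response amplitude as a fraction of baseline.
#' @param onset,dur Stimulus onset and duration (s).
#' @param total Recording length (s).
#' @param hz Frame rate.
#' @param noise_sd Gaussian noise SD (same units as `a`).
#' @param seed Optional RNG seed.
#' @return A fluorescence `trace` with the stimulus window recorded.
#' @export
simulate_fluor_trace <- function(a = 100, b = 0.01, amp = -0.5, onset = 30,
                                 dur = 30, total = 90, hz = 4,
                                 noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, total, by = 1 / hz)
  box <- as.numeric(t >= onset & t < onset + dur)
  y <- a * exp(-b * t) * (1 + amp * box) + rnorm(length(t), sd = noise_sd)
  trace(t, y, kind = "fluorescence",
        stimulus_windows = list(c(onset, onset + dur)))
}

#' Write a simulated input bundle to a directory
#'
#' Emits `genome.fa`, `genes.gff3`, `proteins.fa`, `meta.tsv` from a toy
#' genome, all deterministic given the seed recorded in each TSV header.
#'
#' @param toy Output of [build_toy_genome()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the headers.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(toy, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(toy$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(toy$annotation, file.path(dir, "genes.gff3"),
                      format = "gff3")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(toy$proteins),
                              file.path(dir, "proteins.fa"))
  write_tsv_commented(toy$meta, file.path(dir, "meta.tsv"),
                      c("gene metadata: gene_id, subfamily, chrom, position (0-based), strand, reserved",
                        paste("seed:", seed)))
  invisible(dir)
}

## TSV with '#' comment header naming column semantics
write_tsv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
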