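#' Build a variant-call record
#'
#' One observed edited locus from a structural-variant caller: the edited
#' sequence with 20 bp flanks (empty when no variant was detected at the
#' locus), its read support, the number of library samples sharing the call
#' (sibling strains can carry the same parental edit), and any structural
#' flags.
#'
#' @param strain_id,gene_id Identifiers.
#' @param observed_locus_seq DNA string, `""` when no variant was detected.
#' @param supporting_reads Non-negative read count supporting the call.
#' @param n_samples_sharing Number of samples carrying the same call.
#' @param structural_flags Character vector, subset of `insertion`,
#'   `deletion_large`, `duplication`, `inversion`, `complex`.
#' @return A one-row data frame (flags comma-joined).
#' @export
variant_call_record <- function(strain_id, gene_id, observed_locus_seq,
                                supporting_reads, n_samples_sharing,
                                structural_flags = character(0)) {
  if (supporting_reads < 0) stop("supporting_reads must be >= 0")
  allowed <- c("insertion", "deletion_large", "duplication", "inversion", "complex")
  if (length(structural_flags) && !all(structural_flags %in% allowed)) {
    stop("unknown structural flag")
  }
  if (nzchar(observed_locus_seq) && n_samples_sharing < 1) {
    stop("n_samples_sharing must be >= 1 when a variant exists")
  }
  data.frame(strain_id = strain_id, gene_id = gene_id,
             observed_locus_seq = observed_locus_seq,
             supporting_reads = as.integer(supporting_reads),
             n_samples_sharing = as.integer(n_samples_sharing),
             structural_flags = paste(structural_flags, collapse = ","))
}

#' Confidence filter for a variant call
#'
#' High-confidence calls need strictly more than `min_reads_exclusive`
#' supporting reads and must be shared by at most `max_samples` samples.
#'
#' @param rec A variant-call record (one-row data frame or list).
#' @param min_reads_exclusive Exclusive read-support threshold (default 8:
#'   more than 8 reads are required).
#' @param max_samples Inclusive sample-sharing cap (default 6).
#' @return `"pass"` or `"low_confidence"`.
#' @export
filter_call <- function(rec, min_reads_exclusive = 8L, max_samples = 6L) {
  if (rec$supporting_reads < 0 || rec$n_samples_sharing < 0) {
    stop("negative counts")
  }
  if (rec$supporting_reads > min_reads_exclusive &&
      rec$n_samples_sharing <= max_samples) "pass" else "low_confidence"
}

#' Mismatches between an observed locus and the expected edited allele
#'
#' Global alignment of the observed sequence against the design's expected
#' edited locus (same scoring as [pairwise_identity()]); the mismatch count
#' is the number of substituted columns plus gap columns, so indels count
#' toward the mismatch budget.
#'
#' @param observed Observed DNA (edited region with 20 bp flanks).
#' @param design An `ssodn_design`.
#' @return Integer mismatch count.
#' @export
compare_to_ssodn <- function(observed, design) {
  if (!nzchar(observed)) stop("empty observed sequence")
  if (nchar(observed) < 20L) stop("window_too_short")
  expected <- design$expected_edited_locus
  ## equal-length sequences with few substitutions: the ungapped alignment
  ## is provably optimal under this scoring (a compensating insertion +
  ## deletion costs at least 12 while a substitution costs at most 1), so
  ## the mismatch count is the Hamming distance
  if (nchar(observed) == nchar(expected)) {
    h <- sum(charToRaw(observed) != charToRaw(expected))
    if (h <= 12L) return(as.integer(h))
  }
  st <- alignment_columns(align_global(observed, expected))
  as.integer(st$mismatches + st$gaps)
}

#' Classify an edited allele
#'
#' A record with no detected variant is `unedited`; a variant failing the
#' confidence filter is `low_confidence`. Otherwise the observed locus is
#' aligned to the expected edited allele: 0 mismatches -> `disrupted_exact`;
#' 1-2 -> `disrupted_mismatch`; more than 2 with a structural flag ->
#' `disrupted_larger_cnv`; more than 2 without a flag -> `needs_curation`
#' (the bucket resolved by manual inspection, never auto-resolved here).
#'
#' @param rec A variant-call record.
#' @param design The gene's `ssodn_design`.
#' @param max_mismatches Mismatch budget for `disrupted_mismatch` (default 2).
#' @param min_reads_exclusive,max_samples Passed to [filter_call()].
#' @return A one-row data frame: `strain_id`, `gene_id`, `mismatches`
#'   (NA when not aligned), `status`, `notes`.
#' @export
classify_allele <- function(rec, design, max_mismatches = 2L,
                            min_reads_exclusive = 8L, max_samples = 6L) {
  out <- function(status, mism = NA_integer_, notes = "") {
    data.frame(strain_id = rec$strain_id, gene_id = rec$gene_id,
               mismatches = mism, status = status, notes = notes)
  }
  if (!nzchar(rec$observed_locus_seq)) return(out("unedited"))
  if (filter_call(rec, min_reads_exclusive, max_samples) == "low_confidence") {
    return(out("low_confidence",
               notes = sprintf("reads=%d samples=%d", rec$supporting_reads,
                               rec$n_samples_sharing)))
  }
  m <- compare_to_ssodn(rec$observed_locus_seq, design)
  flags <- rec$structural_flags
  has_flag <- !is.null(flags) && nzchar(flags)
  if (m == 0L) return(out("disrupted_exact", 0L))
  if (m <= max_mismatches) return(out("disrupted_mismatch", m))
  if (has_flag) return(out("disrupted_larger_cnv", m, notes = flags))
  out("needs_curation", m, notes = "manual review required")
}

#' Classify a batch of variant-call records
#'
#' @param records Data frame of variant-call records.
#' @param designs Named list of `ssodn_design` objects (by `gene_id`).
#' @param ... Passed to [classify_allele()].
#' @return Data frame of allele calls with an empty `override` column for
#'   manual curation.
#' @export
classify_batch <- function(records, designs, ...) {
  calls <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    d <- designs[[rec$gene_id]]
    if (is.null(d)) {
      return(data.frame(strain_id = rec$strain_id, gene_id = rec$gene_id,
                        mismatches = NA_integer_, status = "needs_curation",
                        notes = "no design for gene"))
    }
    classify_allele(rec, d, ...)
  }))
  calls$override <- ""
  calls
}

#' In silico genotyping by PCR and restriction digest
#'
#' Simulates primer landing and digestion on one or two allele sequences:
#' an amplicon carrying the diagnostic site once yields two fragments
#' (edited), an amplicon without the site stays as one band (wild type), and
#' a mixed allele pair shows the three-band heterozygous-like pattern.
#'
#' @param alleles Character vector of one or two allele sequences, each
#'   spanning the amplicon region.
#' @param assay A `genotyping_assay`.
#' @param design The matching `ssodn_design`.
#' @return A list with `call` (`edited`, `wild_type` or
#'   `heterozygous_like`) and `bands` (sorted unique fragment lengths).
#' @export
insilico_genotype <- function(alleles, assay, design) {
  site <- design$enzyme$site
  per_allele <- lapply(alleles, function(seq) {
    f <- regexpr(assay$fwd_primer, seq, fixed = TRUE)
    r <- regexpr(revcomp(assay$rev_primer), seq, fixed = TRUE)
    if (f == -1L || r == -1L) stop("primer_dropout")
    amp <- substr(seq, f, r + nchar(assay$rev_primer) - 1L)
    nsite <- count_site(site, amp)
    if (nsite == 1L) {
      pos0 <- regexpr(site, amp, fixed = TRUE) - 1L
      cutpos <- pos0 + site_cut_offset(design, site)
      list(edited = TRUE, bands = c(cutpos, nchar(amp) - cutpos))
    } else {
      list(edited = FALSE, bands = nchar(amp))
    }
  })
  edited <- vapply(per_allele, `[[`, logical(1), "edited")
  bands <- sort(unique(unlist(lapply(per_allele, `[[`, "bands"))))
  call <- if (all(edited)) "edited" else if (!any(edited)) "wild_type"
          else "heterozygous_like"
  list(call = call, bands = bands)
}

#' Read variant-call records from TSV
#'
#' Expected columns: `strain_id`, `gene_id`, `observed_locus_seq`,
#' `supporting_reads`, `n_samples_sharing`, `structural_flags`. Lines
#' starting with `#` are ignored.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_variant_calls <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strain_id", "gene_id", "observed_locus_seq", "supporting_reads",
            "n_samples_sharing", "structural_flags")
  if (!all(need %in% names(df))) {
    stop("variant-call TSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$observed_locus_seq[is.na(df$observed_locus_seq)] <- ""
  df$structural_flags[is.na(df$structural_flags)] <- ""
  df
}
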