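## Global (Needleman-Wunsch) alignment with the package-wide scoring used for
## both protein identity and edited-locus comparison: match +1, mismatch 0,
## affine gap cost 5 (open) + 1 per position. End gaps are penalized.

align_global <- function(a, b) {
  alphabet <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  m <- matrix(0, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- 1
  Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                gapOpening = 5, gapExtension = 1,
                                type = "global")
}

## Column-wise alignment statistics. Biostrings' nindel() ignores terminal
## gaps, so matches/mismatches/gap columns are counted from the aligned
## strings directly.
alignment_columns <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  match <- !gap & p == s
  list(length = length(p), matches = sum(match),
       mismatches = sum(!gap & !match), gaps = sum(gap),
       score = Biostrings::score(aln))
}
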