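#' Read a genome from a FASTA file
#'
#' Loads every record, uppercases the sequence, and validates the DNA
#' alphabet (`A`, `C`, `G`, `T`, `N`). RNA input (containing `U`) and
#' duplicated record ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome`: a list with `sequences` (named
#'   character vector, one element per chromosome) and `source` (the path).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path)
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  if (any(grepl("U", seqs, fixed = TRUE))) {
    stop("RNA alphabet (U) not accepted; supply DNA")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC-DNA character in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  structure(list(sequences = seqs, source = path), class = "genome")
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome` object (see [read_genome()]).
#' @param path Output FASTA path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome"))
  x <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$sequences), "sequence(s),",
      sum(nchar(x$sequences)), "bp total\n")
  invisible(x)
}

## 0-based half-open slice of a reference chromosome
ref_slice <- function(genome, chrom, start0, end0) {
  seq <- genome$sequences[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  if (start0 < 0 || end0 > nchar(seq) || start0 > end0) {
    stop("interval [", start0, ",", end0, ") out of bounds for ", chrom)
  }
  substr(seq, start0 + 1L, end0)
}

## reverse complement; chartr avoids per-call S4 dispatch overhead on the
## many short fragments handled during primer search
revcomp <- function(dna) {
  if (!nzchar(dna)) return(dna)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]), collapse = "")
}

#' Translate a DNA sequence with the standard genetic code
#'
#' Stop codons are rendered `*`; any codon containing an ambiguous base is
#' rendered `X`.
#'
#' @param dna Coding-strand DNA string.
#' @param truncate If `TRUE`, a trailing remainder shorter than one codon is
#'   dropped; otherwise non-multiple-of-3 input is an error.
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna, truncate = FALSE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  r <- n %% 3L
  if (r != 0L) {
    if (!truncate) stop("DNA length ", n, " not divisible by 3")
    dna <- substr(dna, 1L, n - r)
    n <- n - r
  }
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a gene model
#'
#' A protein-coding gene with genomic coordinates, strand, CDS and translated
#' protein. `cds_intervals` are 0-based half-open reference intervals, ordered
#' 5'->3' in gene orientation (decreasing reference position on the minus
#' strand). The spliced CDS must begin with `ATG`, be a multiple of 3 long,
#' and contain no internal stop; a terminal stop codon is allowed and is not
#' part of `protein`.
#'
#' @param gene_id,subfamily,chrom,strand,cds_intervals Gene annotation;
#'   `cds_intervals` is a 2-column matrix of (start, end).
#' @param genome A `genome` object used to splice and validate the CDS.
#' @return An object of class `gene_model` with fields `gene_id`,
#'   `subfamily`, `chrom`, `strand`, `cds_intervals`, `cds_seq`, `protein`.
#' @export
gene_model <- function(gene_id, subfamily, chrom, strand, cds_intervals, genome) {
  stopifnot(strand %in% c("+", "-"), is.matrix(cds_intervals),
            ncol(cds_intervals) == 2L)
  colnames(cds_intervals) <- c("start", "end")
  ref_order <- order(cds_intervals[, "start"])
  ints <- cds_intervals[ref_order, , drop = FALSE]
  if (nrow(ints) > 1L && any(ints[-1L, "start"] < ints[-nrow(ints), "end"])) {
    stop("overlapping CDS intervals in ", gene_id)
  }
  chrom_len <- nchar(genome$sequences[[chrom]])
  if (is.null(chrom_len)) stop("unknown chromosome ", chrom, " for ", gene_id)
  if (any(ints[, "start"] < 0L) || any(ints[, "end"] > chrom_len) ||
      any(ints[, "start"] >= ints[, "end"])) {
    stop("CDS outside chromosome bounds in ", gene_id)
  }
  pieces <- vapply(seq_len(nrow(ints)), function(i) {
    ref_slice(genome, chrom, ints[i, "start"], ints[i, "end"])
  }, character(1))
  cds_seq <- paste(pieces, collapse = "")
  if (strand == "-") {
    cds_seq <- revcomp(cds_seq)
    ints <- ints[rev(seq_len(nrow(ints))), , drop = FALSE]  # 5'->3' in gene orientation
  }
  if (nchar(cds_seq) %% 3L != 0L) {
    stop("CDS length not divisible by 3 in ", gene_id)
  }
  if (substr(cds_seq, 1L, 3L) != "ATG") {
    stop("CDS of ", gene_id, " does not begin with ATG")
  }
  aa <- translate_dna(cds_seq)
  protein <- sub("\\*$", "", aa)
  if (grepl("*", protein, fixed = TRUE)) {
    stop("internal stop codon in CDS of ", gene_id)
  }
  structure(list(gene_id = gene_id, subfamily = subfamily, chrom = chrom,
                 strand = strand, cds_intervals = ints, cds_seq = cds_seq,
                 protein = protein),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, paste0("[", x$subfamily, "]"),
      x$chrom, x$strand, paste0(nchar(x$protein), " aa\n"))
  invisible(x)
}

## subfamily from a gene name such as "srx-64" -> "srx"; otherwise "NA"
subfamily_from_name <- function(name) {
  ifelse(grepl("^[A-Za-z0-9.]+-[0-9]+$", name), sub("-[0-9]+$", "", name), "NA")
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features, converts 1-based inclusive GFF3 coordinates
#' to internal 0-based half-open, splices (reverse-complementing minus-strand
#' genes) and keeps the longest isoform per gene (ties broken by
#' lexicographically smallest transcript id). The gene subfamily is taken
#' from a `subfamily` attribute when present, otherwise inferred from the
#' gene name prefix (e.g. "srx-64" -> "srx"), else `"NA"`.
#'
#' @param gff_path Path to a GFF3 file.
#' @param genome A `genome` object.
#' @return A named list of `gene_model` objects.
#' @export
read_gene_models <- function(gff_path, genome) {
  gff <- rtracklayer::import(gff_path, format = "gff3")
  typ <- as.character(gff$type)
  genes <- gff[typ == "gene"]
  mrnas <- gff[typ == "mRNA"]
  cdss  <- gff[typ == "CDS"]
  if (length(mrnas) == 0L) stop("no mRNA features in ", gff_path)
  cds_parent <- as.character(S4Vectors::unstrsplit(cdss$Parent, ","))
  mrna_parent <- as.character(S4Vectors::unstrsplit(mrnas$Parent, ","))

  gene_name <- genes$Name
  if (is.null(gene_name)) gene_name <- genes$ID
  gene_name[is.na(gene_name)] <- genes$ID[is.na(gene_name)]
  sub_attr <- genes$subfamily
  names(gene_name) <- genes$ID
  subfam <- if (is.null(sub_attr)) subfamily_from_name(gene_name) else {
    ifelse(is.na(sub_attr), subfamily_from_name(gene_name), sub_attr)
  }
  names(subfam) <- genes$ID

  models <- list()
  for (gid in genes$ID) {
    tx_ids <- mrnas$ID[mrna_parent == gid]
    if (length(tx_ids) == 0L) next
    build <- function(tx) {
      sel <- cds_parent == tx
      if (!any(sel)) return(NULL)
      cd <- cdss[sel]
      ints <- cbind(start = GenomicRanges::start(cd) - 1L,
                    end = GenomicRanges::end(cd))
      list(ints = ints, len = sum(ints[, "end"] - ints[, "start"]),
           strand = as.character(GenomicRanges::strand(cd))[1],
           chrom = as.character(GenomicRanges::seqnames(cd))[1])
    }
    cand <- Filter(Negate(is.null), setNames(lapply(tx_ids, build), tx_ids))
    if (length(cand) == 0L) next
    lens <- vapply(cand, `[[`, numeric(1), "len")
    best <- sort(names(cand)[lens == max(lens)])[1]  # tie: smallest tx id
    ci <- cand[[best]]
    nm <- gene_name[[gid]]
    models[[nm]] <- gene_model(nm, subfam[[gid]], ci$chrom, ci$strand,
                               ci$ints, genome)
  }
  models
}

#' Export designed loci as BED
#'
#' Writes 0-based half-open intervals (BED convention) for a set of designs.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  write.table(intervals[, c("chrom", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
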