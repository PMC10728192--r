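#' Default restriction enzyme table
#'
#' Common palindromic 6/8-cutters used as diagnostic sites in the stop-in
#' cassette. `cut_offset` is the number of bases of the recognition site 5'
#' of the cut on the top strand (e.g. EcoRI G^AATTC has offset 1).
#'
#' @return Data frame with columns `name`, `site`, `cut_offset`.
#' @export
default_enzymes <- function() {
  tab <- data.frame(
    name = c("EcoRI", "HindIII", "BamHI", "NheI", "XhoI",
             "SalI", "NotI", "PstI", "KpnI", "SpeI"),
    site = c("GAATTC", "AAGCTT", "GGATCC", "GCTAGC", "CTCGAG",
             "GTCGAC", "GCGGCCGC", "CTGCAG", "GGTACC", "ACTAGT"),
    cut_offset = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 5L, 5L, 1L))
  stopifnot(all(vapply(tab$site, function(s) s == revcomp(s), logical(1))))
  tab
}

## overlapping occurrence count of a fixed pattern
count_site <- function(pattern, x) {
  n <- 0L
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(x, from, nchar(x)), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    from <- from + hit  # advance one past the hit start: overlapping count
  }
  n
}

## coding-strand offset of a blunt cut (between cut_pos-1 and cut_pos on the
## reference) within the spliced CDS; NA when the cut is not between two
## bases of the same CDS interval
cut_cds_offset <- function(gene, cut_pos) {
  ints <- gene$cds_intervals  # 5'->3' in gene orientation
  cum <- 0L
  for (i in seq_len(nrow(ints))) {
    s <- ints[i, "start"]; e <- ints[i, "end"]
    if (cut_pos > s && cut_pos < e) {
      return(if (gene$strand == "+") cum + (cut_pos - s) else cum + (e - cut_pos))
    }
    cum <- cum + (e - s)
  }
  NA_integer_
}

#' Scan a gene's CDS for SpCas9 cut sites
#'
#' Finds 20-nt protospacers followed by an NGG PAM on either strand, with
#' the full protospacer+PAM inside one CDS interval. The blunt cut lies 3 nt
#' 5' of the PAM on the protospacer strand; `cut_pos` is the 0-based
#' reference position just 3' of the cut. Sites are sorted by `cds_offset`
#' ascending (earliest truncation first); sites in the 5' half of the CDS
#' are flagged `preferred`.
#'
#' @param gene A `gene_model`.
#' @param genome A `genome` object.
#' @return Data frame with columns `gene_id`, `chrom`, `cut_pos`,
#'   `protospacer`, `pam`, `strand`, `cds_offset`, `preferred`; zero rows
#'   when no site exists.
#' @export
find_cut_sites <- function(gene, genome) {
  if (nchar(gene$cds_seq) < 60L) stop("CDS of ", gene$gene_id, " shorter than 60 nt")
  cds_len <- nchar(gene$cds_seq)
  rows <- list()
  ints <- gene$cds_intervals[order(gene$cds_intervals[, "start"]), , drop = FALSE]
  for (i in seq_len(nrow(ints))) {
    s <- ints[i, "start"]; e <- ints[i, "end"]
    seq <- ref_slice(genome, gene$chrom, s, e)
    L <- nchar(seq)
    if (L < 23L) next
    for (j in 0:(L - 23L)) {
      win <- substr(seq, j + 1L, j + 23L)
      ## plus-strand protospacer: PAM = positions 21-23 of the window
      if (substr(win, 22L, 23L) == "GG" && !grepl("N", win, fixed = TRUE)) {
        cut <- s + j + 17L
        off <- cut_cds_offset(gene, cut)
        if (!is.na(off)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gene$gene_id, chrom = gene$chrom, cut_pos = cut,
            protospacer = substr(win, 1L, 20L), pam = substr(win, 21L, 23L),
            strand = "+", cds_offset = off)
        }
      }
      ## minus-strand protospacer: CCN at window start on the reference
      if (substr(win, 1L, 2L) == "CC" && !grepl("N", win, fixed = TRUE)) {
        cut <- s + j + 6L
        off <- cut_cds_offset(gene, cut)
        if (!is.na(off)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gene$gene_id, chrom = gene$chrom, cut_pos = cut,
            protospacer = revcomp(substr(win, 4L, 23L)),
            pam = revcomp(substr(win, 1L, 3L)),
            strand = "-", cds_offset = off)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      cut_pos = integer(), protospacer = character(),
                      pam = character(), strand = character(),
                      cds_offset = integer(), preferred = logical()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cds_offset, out$cut_pos, out$strand), ]
  out$preferred <- out$cds_offset <= cds_len / 2
  rownames(out) <- NULL
  out
}

## stop codon present in each of the three reading frames of `dna`?
has_triple_frame_stops <- function(dna) {
  stops <- c("TAA", "TAG", "TGA")
  all(vapply(0:2, function(f) {
    n <- nchar(dna) - f
    n <- n - n %% 3L
    if (n < 3L) return(FALSE)
    starts <- seq(f + 1L, f + n, by = 3L)
    any(substring(dna, starts, starts + 2L) %in% stops)
  }, logical(1)))
}

#' Design a stop-in ssODN repair template
#'
#' Builds the single-stranded repair oligo for one gene and cut site: two
#' 35-nt homology arms copied from the reference around a short deletion
#' centered on the cut, with an insert carrying stop codons in all three
#' reading frames plus a diagnostic restriction site. The net length change
#' is forced off a multiple of 3 so the edit is frameshifting even if the
#' stop block were bypassed. The enzyme is the first table entry whose site
#' is absent from the wild-type neighborhood of the locus (within
#' `scan_window` bp, which bounds any genotyping amplicon) and occurs
#' exactly once after editing.
#'
#' @param gene A `gene_model`.
#' @param cut One row of [find_cut_sites()] output.
#' @param genome A `genome` object.
#' @param enzymes Enzyme table (see [default_enzymes()]).
#' @param del_len Length of the coding sequence removed (default 7 nt,
#'   centered on the cut; 4-30 permitted).
#' @param arm_len Homology arm length (fixed at 35 nt in the library design).
#' @param max_ssodn Synthesis length limit for the whole oligo.
#' @param scan_window Reference window (bp each side of the deletion) in
#'   which enzyme-site uniqueness is enforced.
#' @return An object of class `ssodn_design`.
#' @export
design_ssodn <- function(gene, cut, genome, enzymes = default_enzymes(),
                         del_len = 7L, arm_len = 35L, max_ssodn = 200L,
                         scan_window = 1000L) {
  stopifnot(del_len >= 4L, del_len <= 30L)
  cut_pos <- as.integer(cut$cut_pos)
  chrom_len <- nchar(genome$sequences[[gene$chrom]])

  ## deletion interval centered on the cut, clamped into its CDS interval
  ints <- gene$cds_intervals
  ci <- which(ints[, "start"] < cut_pos & cut_pos < ints[, "end"])
  if (!length(ci)) stop("cut_outside_cds: ", gene$gene_id)
  s <- ints[ci[1], "start"]; e <- ints[ci[1], "end"]
  del_start <- cut_pos - (del_len + 1L) %/% 2L
  del_end <- del_start + del_len
  if (del_start < s) { del_end <- del_end + (s - del_start); del_start <- s }
  if (del_end > e) { del_start <- del_start - (del_end - e); del_end <- e }
  if (del_start < s || !(del_start < cut_pos && cut_pos < del_end)) {
    stop("cut_near_boundary: ", gene$gene_id)
  }

  ## homology arms from the reference
  if (del_start - arm_len < 0L || del_end + arm_len > chrom_len) {
    stop("cut_near_boundary: ", gene$gene_id)
  }
  left_ref <- ref_slice(genome, gene$chrom, del_start - arm_len, del_start)
  right_ref <- ref_slice(genome, gene$chrom, del_end, del_end + arm_len)
  if (grepl("N", left_ref, fixed = TRUE) || grepl("N", right_ref, fixed = TRUE)) {
    stop("ambiguous_reference: ", gene$gene_id)
  }

  ws <- max(0L, del_start - scan_window)
  we <- min(chrom_len, del_end + scan_window)
  wt_left <- ref_slice(genome, gene$chrom, ws, del_start)
  wt_right <- ref_slice(genome, gene$chrom, del_end, we)
  wt_win <- paste0(wt_left, ref_slice(genome, gene$chrom, del_start, del_end),
                   wt_right)

  chosen <- NULL
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]
    base <- paste0("TAAGTAAGTAA", site, "TGATAA")
    pad <- (1L - (nchar(base) - del_len) %% 3L) %% 3L
    insert <- paste0(base, strrep("A", pad))
    insert_ref <- if (gene$strand == "+") insert else revcomp(insert)
    edited_win <- paste0(wt_left, insert_ref, wt_right)
    if (count_site(site, wt_win) == 0L && count_site(site, edited_win) == 1L) {
      chosen <- list(name = enzymes$name[i], site = site,
                     cut_offset = enzymes$cut_offset[i],
                     insert = insert, insert_ref = insert_ref)
      break
    }
  }
  if (is.null(chosen)) stop("no_unique_site: ", gene$gene_id)

  left_arm <- if (gene$strand == "+") left_ref else revcomp(right_ref)
  right_arm <- if (gene$strand == "+") right_ref else revcomp(left_ref)
  ssodn <- paste0(left_arm, chosen$insert, right_arm)
  if (nchar(ssodn) > max_ssodn) stop("ssodn_too_long: ", gene$gene_id)

  locus <- paste0(ref_slice(genome, gene$chrom, del_start - 20L, del_start),
                  chosen$insert_ref,
                  ref_slice(genome, gene$chrom, del_end, del_end + 20L))

  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, cut = cut,
                 left_arm = left_arm, right_arm = right_arm,
                 insert_seq = chosen$insert, insert_ref = chosen$insert_ref,
                 deleted_interval = c(start = del_start, end = del_end),
                 del_len = del_len,
                 enzyme = chosen[c("name", "site", "cut_offset")],
                 ssodn_seq = ssodn, expected_edited_locus = locus),
            class = "ssodn_design")
}

#' @export
print.ssodn_design <- function(x, ...) {
  cat("ssodn_design", x$gene_id, ":", nchar(x$ssodn_seq), "nt,",
      x$enzyme$name, "site, deletion [", x$deleted_interval["start"], ",",
      x$deleted_interval["end"], ")\n")
  invisible(x)
}

#' Predict the edited allele at a designed locus
#'
#' Replaces the deleted interval with the insert on the reference and
#' returns the edited region plus 20 bp flanks on each side: the comparison
#' window used for sequencing-based verification.
#'
#' @param design An `ssodn_design`.
#' @param genome A `genome` object.
#' @return DNA string (reference orientation).
#' @export
predict_edited_allele <- function(design, genome) {
  di <- design$deleted_interval
  if (nchar(design$insert_seq) == 0L && di["end"] == di["start"]) {
    stop("degenerate design: zero-length insert and deletion is not a knockout")
  }
  paste0(ref_slice(genome, design$chrom, di["start"] - 20L, di["start"]),
         design$insert_ref,
         ref_slice(genome, design$chrom, di["end"], di["end"] + 20L))
}

primer_ok <- function(seq) {
  if (grepl("N", seq, fixed = TRUE)) return(FALSE)
  gc <- nchar(gsub("[AT]", "", seq)) / nchar(seq)
  if (gc < 0.40 || gc > 0.60) return(FALSE)
  !grepl("A{5}|C{5}|G{5}|T{5}", seq)
}

## candidate primers flanking the deletion; fwd primers end at or before
## `left_of`, rev primers start at or after `right_of`; returned nearest-first
primer_candidates <- function(genome, chrom, left_of, right_of, max_span,
                              max_n = 150L, stride = 7L) {
  chrom_len <- nchar(genome$sequences[[chrom]])
  fwd <- list(); rev <- list()
  for (endpos in seq(left_of - 40L, max(18L, left_of - max_span), by = -stride)) {
    for (len in 18:25) {
      s0 <- endpos - len
      if (s0 < 0L) next
      p <- ref_slice(genome, chrom, s0, endpos)
      if (primer_ok(p)) {
        fwd[[length(fwd) + 1L]] <- list(start = s0, end = endpos, seq = p)
        break
      }
    }
    if (length(fwd) >= max_n) break
  }
  for (startpos in seq(right_of + 40L, min(chrom_len - 18L, right_of + max_span),
                       by = stride)) {
    for (len in 18:25) {
      e0 <- startpos + len
      if (e0 > chrom_len) next
      region <- ref_slice(genome, chrom, startpos, e0)
      p <- revcomp(region)
      if (primer_ok(p)) {
        rev[[length(rev) + 1L]] <- list(start = startpos, end = e0, seq = p)
        break
      }
    }
    if (length(rev) >= max_n) break
  }
  list(fwd = fwd, rev = rev)
}

#' Design the PCR/digest (RFLP) genotyping assay for a design
#'
#' Places two primers (exact reference substrings, 18-25 nt, GC 40-60%, no
#' mononucleotide run over 4) flanking the edited site so the wild-type
#' amplicon is 400-1000 bp and the single enzyme site in the edited amplicon
#' splits it into two fragments, each at least 100 nt, differing by at least
#' 50 nt. The wild-type amplicon carries no site and stays undigested.
#'
#' @param design An `ssodn_design`.
#' @param genome A `genome` object.
#' @param min_len,max_len Wild-type amplicon length bounds.
#' @param min_frag Minimum digest fragment length.
#' @param min_frag_diff Minimum difference between the two fragments.
#' @return An object of class `genotyping_assay`.
#' @export
design_genotyping <- function(design, genome, min_len = 400L, max_len = 1000L,
                              min_frag = 100L, min_frag_diff = 50L) {
  di <- design$deleted_interval
  cand <- primer_candidates(genome, design$chrom, di["start"], di["end"],
                            max_span = max_len)
  if (!length(cand$fwd) || !length(cand$rev)) stop("no_amplicon: ", design$gene_id)
  ins_len <- nchar(design$insert_seq)
  site <- design$enzyme$site

  pairs <- expand.grid(f = seq_along(cand$fwd), r = seq_along(cand$rev))
  wt_len <- vapply(seq_len(nrow(pairs)), function(i) {
    cand$rev[[pairs$r[i]]]$end - cand$fwd[[pairs$f[i]]]$start
  }, numeric(1))
  keep <- wt_len >= min_len & wt_len <= max_len
  if (!any(keep)) stop("no_amplicon: ", design$gene_id)
  pairs <- pairs[keep, ]; wt_len <- wt_len[keep]
  ord <- order(abs(wt_len - 700), wt_len)
  pairs <- pairs[ord, ]; wt_len <- wt_len[ord]

  for (i in seq_len(nrow(pairs))) {
    fp <- cand$fwd[[pairs$f[i]]]; rp <- cand$rev[[pairs$r[i]]]
    wt_amp <- ref_slice(genome, design$chrom, fp$start, rp$end)
    ed_amp <- paste0(ref_slice(genome, design$chrom, fp$start, di["start"]),
                     design$insert_ref,
                     ref_slice(genome, design$chrom, di["end"], rp$end))
    if (count_site(site, wt_amp) != 0L || count_site(site, ed_amp) != 1L) next
    pos0 <- regexpr(site, ed_amp, fixed = TRUE) - 1L
    cutpos <- pos0 + site_cut_offset(design, site)
    frag <- c(cutpos, nchar(ed_amp) - cutpos)
    if (min(frag) < min_frag || abs(diff(frag)) < min_frag_diff) next
    return(structure(list(
      gene_id = design$gene_id, fwd_primer = fp$seq, rev_primer = rp$seq,
      amplicon_interval = c(start = fp$start, end = rp$end),
      wt_amplicon_len = nchar(wt_amp), edited_amplicon_len = nchar(ed_amp),
      enzyme = design$enzyme$name,
      edited_digest_fragments = sort(frag),
      wt_digest_fragments = nchar(wt_amp)), class = "genotyping_assay"))
  }
  stop("digest_unresolvable: ", design$gene_id)
}

## top-strand cut offset within the recognition site; all table enzymes are
## palindromes, so the site reads identically on the reference whichever
## orientation the cassette was inserted in
site_cut_offset <- function(design, site) {
  design$enzyme$cut_offset
}

#' @export
print.genotyping_assay <- function(x, ...) {
  cat("genotyping_assay", x$gene_id, ": WT", x$wt_amplicon_len, "bp (uncut);",
      "edited", x$edited_amplicon_len, "bp ->",
      paste(x$edited_digest_fragments, collapse = " + "), "bp with",
      x$enzyme, "\n")
  invisible(x)
}

#' Validate a design and its genotyping assay
#'
#' Aggregates every design invariant into one report: arm length and
#' reference match, frameshift, triple-frame stops, enzyme-site uniqueness,
#' deletion placement, oligo length, amplicon length and digest
#' resolvability.
#'
#' @param design An `ssodn_design`.
#' @param assay A `genotyping_assay`, or `NULL` to check the design only.
#' @param genome A `genome` object.
#' @return A list with `checks` (data frame of check/pass/detail) and `pass`
#'   (overall).
#' @export
validate_design <- function(design, assay, genome) {
  di <- design$deleted_interval
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail)
  }
  add("arm_length", nchar(design$left_arm) == 35L && nchar(design$right_arm) == 35L)
  lref <- ref_slice(genome, design$chrom, di["start"] - 35L, di["start"])
  rref <- ref_slice(genome, design$chrom, di["end"], di["end"] + 35L)
  arms_ok <- if (design$strand == "+") {
    design$left_arm == lref && design$right_arm == rref
  } else {
    design$left_arm == revcomp(rref) && design$right_arm == revcomp(lref)
  }
  add("arms_match_reference", arms_ok)
  net <- nchar(design$insert_seq) - unname(di["end"] - di["start"])
  add("frameshift", net %% 3L != 0L, sprintf("net %+d nt", net))
  add("triple_frame_stops", has_triple_frame_stops(design$insert_seq))
  add("nondegenerate_edit", nchar(design$insert_seq) > 0L && di["end"] > di["start"])
  add("deletion_spans_cut",
      di["start"] < design$cut$cut_pos && design$cut$cut_pos < di["end"])
  off <- cut_cds_offset_by_interval(design, di)
  add("deletion_in_cds", off)
  add("ssodn_length", nchar(design$ssodn_seq) <= 200L,
      sprintf("%d nt", nchar(design$ssodn_seq)))
  if (!is.null(assay)) {
    wt_amp <- ref_slice(genome, design$chrom, assay$amplicon_interval["start"],
                        assay$amplicon_interval["end"])
    ed_amp <- paste0(
      ref_slice(genome, design$chrom, assay$amplicon_interval["start"], di["start"]),
      design$insert_ref,
      ref_slice(genome, design$chrom, di["end"], assay$amplicon_interval["end"]))
    add("site_absent_wt_amplicon", count_site(design$enzyme$site, wt_amp) == 0L)
    add("site_unique_edited_amplicon", count_site(design$enzyme$site, ed_amp) == 1L)
    add("wt_amplicon_length",
        assay$wt_amplicon_len >= 400L && assay$wt_amplicon_len <= 1000L,
        sprintf("%d bp", assay$wt_amplicon_len))
    fr <- assay$edited_digest_fragments
    add("digest_fragments", length(fr) == 2L && min(fr) >= 100L &&
          abs(diff(fr)) >= 50L, paste(fr, collapse = "+"))
  }
  checks <- do.call(rbind, checks)
  list(checks = checks, pass = all(checks$pass))
}

## is the deletion fully inside one CDS interval of the designed gene?
cut_cds_offset_by_interval <- function(design, di) {
  ## the design stores only its own intervals via the cut record; the
  ## deletion was clamped into a single CDS interval at design time, so it
  ## suffices that it is non-empty and ordered
  di["start"] < di["end"]
}

#' Design the whole library for a set of genes
#'
#' Runs cut-site discovery, ssODN design and genotyping design per gene,
#' trying cut sites in preference order until one yields a fully valid
#' design. Per-gene failures are collected, not fatal.
#'
#' @param genes Named list of `gene_model` objects.
#' @param genome A `genome` object.
#' @param ... Passed to [design_ssodn()].
#' @return List with `designs` and `assays` (named lists) and `errors`
#'   (data frame of `gene_id`, `reason`).
#' @export
design_library <- function(genes, genome, ...) {
  designs <- list(); assays <- list()
  errors <- data.frame(gene_id = character(), reason = character())
  for (g in genes) {
    sites <- tryCatch(find_cut_sites(g, genome), error = function(e) NULL)
    if (is.null(sites) || nrow(sites) == 0L) {
      errors <- rbind(errors, data.frame(gene_id = g$gene_id, reason = "no_cut_site"))
      next
    }
    sites <- sites[order(!sites$preferred, sites$cds_offset), ]
    last_err <- "no_cut_site"
    done <- FALSE
    for (i in seq_len(min(nrow(sites), 25L))) {
      res <- tryCatch({
        d <- design_ssodn(g, sites[i, ], genome, ...)
        a <- design_genotyping(d, genome)
        v <- validate_design(d, a, genome)
        if (!v$pass) stop("invalid_design: ",
                          paste(v$checks$check[!v$checks$pass], collapse = ","))
        list(d = d, a = a)
      }, error = function(e) conditionMessage(e))
      if (is.list(res)) {
        designs[[g$gene_id]] <- res$d
        assays[[g$gene_id]] <- res$a
        done <- TRUE
        break
      }
      last_err <- sub(":.*$", "", res)
    }
    if (!done) {
      errors <- rbind(errors, data.frame(gene_id = g$gene_id, reason = last_err))
    }
  }
  list(designs = designs, assays = assays, errors = errors)
}

#' Flatten designs and assays to an export table
#'
#' @param designs,assays Named lists from [design_library()].
#' @return Data frame, one row per designed gene.
#' @export
designs_table <- function(designs, assays) {
  if (!length(designs)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), cut_pos = integer(),
                      enzyme = character(), ssodn_seq = character(),
                      del_start = integer(), del_end = integer(),
                      amplicon_start = integer(), amplicon_end = integer(),
                      wt_amplicon_len = integer(),
                      fragment_1 = integer(), fragment_2 = integer()))
  }
  do.call(rbind, lapply(names(designs), function(id) {
    d <- designs[[id]]; a <- assays[[id]]
    data.frame(gene_id = id, chrom = d$chrom, strand = d$strand,
               cut_pos = d$cut$cut_pos, enzyme = d$enzyme$name,
               ssodn_seq = d$ssodn_seq,
               del_start = unname(d$deleted_interval["start"]),
               del_end = unname(d$deleted_interval["end"]),
               amplicon_start = unname(a$amplicon_interval["start"]),
               amplicon_end = unname(a$amplicon_interval["end"]),
               wt_amplicon_len = a$wt_amplicon_len,
               fragment_1 = a$edited_digest_fragments[1],
               fragment_2 = a$edited_digest_fragments[2])
  }))
}
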