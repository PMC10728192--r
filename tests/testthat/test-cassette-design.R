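## a single-exon plus-strand toy gene whose CDS is an explicit string
toy_gene <- function(cds, flank_left = 300, flank_right = 300, strand = "+",
                     seed = 99) {
  set.seed(seed)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  gseq <- if (strand == "+") cds else revcomp_chr(cds)
  ref <- paste0(pad(flank_left), gseq, pad(flank_right))
  fa <- write_tiny_fasta(list(chrI = ref))
  genome <- read_genome(fa)
  gene <- gene_model("toy-1", "toy", "chrI", strand,
                     cbind(flank_left, flank_left + nchar(cds)), genome)
  list(gene = gene, genome = genome, ref = ref,
       cds_start = flank_left, cds_end = flank_left + nchar(cds))
}

test_that("cut sites match the exhaustive sliding-window oracle", {
  lib <- toy_library()
  for (m in lib$models[1:4]) {
    ints <- m$cds_intervals
    s <- min(ints[, "start"]); e <- max(ints[, "end"])
    got <- find_cut_sites(m, lib$genome)
    got <- got[order(got$cut_pos, got$strand), c("cut_pos", "strand")]
    orc <- pam_scan_oracle(lib$genome$sequences[[m$chrom]], s, e)
    rownames(got) <- rownames(orc) <- NULL
    orc$cut_pos <- as.integer(orc$cut_pos)
    expect_identical(got, orc)
  }
})

test_that("a 23-nt window with a terminal PAM cuts between offsets 16|17", {
  ## CDS with one plus-strand protospacer whose PAM sits at CDS offsets 20-22
  cds <- paste0("ATG", "AAAAAAAAAAAAAAAAA", "CGG",
                "TTATTATCATTATCATTATCATTATCATTATTATTAA")
  stopifnot(nchar(cds) %% 3 == 0)
  tg <- toy_gene(cds)
  sites <- find_cut_sites(tg$gene, tg$genome)
  plus <- sites[sites$strand == "+" & sites$pam == "CGG", ]
  expect_equal(plus$cds_offset[1], 17)               # cut between 16 and 17
  expect_equal(plus$cut_pos[1], tg$cds_start + 17)
  expect_identical(plus$protospacer[1], substr(cds, 1, 20))
})

test_that("PAM-free sequence yields no cut sites", {
  ## alternating AT codons contain no GG/CC anywhere
  cds <- paste0("ATG", strrep("ATA", 25), "TAA")
  tg <- toy_gene(cds, flank_left = 100, flank_right = 100, seed = 7)
  ## flanks may carry GG/CC but the scan is CDS-internal
  sites <- find_cut_sites(tg$gene, tg$genome)
  expect_equal(nrow(sites), 0)
})

test_that("reverse-strand protospacers are reported with strand '-'", {
  ## CCN at CDS offsets 3-5 gives a minus-strand protospacer, cut at offset 9
  cds <- paste0("ATG", "CCA", strrep("ATA", 17), "TAA")
  tg <- toy_gene(cds, seed = 13)
  sites <- find_cut_sites(tg$gene, tg$genome)
  minus <- sites[sites$strand == "-", ]
  expect_gte(nrow(minus), 1)
  expect_equal(minus$cut_pos[1], tg$cds_start + 3 + 6)
  ## protospacer is the reverse complement of the reference downstream of CCN
  expect_identical(minus$protospacer[1],
                   revcomp_chr(substr(cds, 7, 26)))
  expect_identical(minus$pam[1], revcomp_chr(substr(cds, 4, 6)))
})

test_that("designs have the 35+insert+35 structure and a frameshifting stop-in insert", {
  lib <- toy_library()
  expect_gt(length(lib$designs), 0)
  for (d in lib$designs) {
    expect_equal(nchar(d$left_arm), 35)
    expect_equal(nchar(d$right_arm), 35)
    expect_identical(d$ssodn_seq, paste0(d$left_arm, d$insert_seq, d$right_arm))
    net <- nchar(d$insert_seq) - unname(d$deleted_interval["end"] -
                                          d$deleted_interval["start"])
    expect_true(net %% 3 != 0)
    ## stop codon in all three frames of the insert, on the coding strand
    expect_true(wormforge:::has_triple_frame_stops(d$insert_seq))
    expect_lte(nchar(d$ssodn_seq), 200)
  }
})

test_that("an enzyme whose site is already in the locus is skipped", {
  ## plant an EcoRI site in the wild-type amplicon region of a designable gene
  cds <- paste0("ATG", "GAATTC", strrep("CAT", 30),
                strrep("A", 18), "CGG", strrep("CAT", 30), "TAA")
  stopifnot(nchar(cds) %% 3 == 0)
  tg <- toy_gene(cds, flank_left = 600, flank_right = 600, seed = 23)
  sites <- find_cut_sites(tg$gene, tg$genome)
  d <- design_ssodn(tg$gene, sites[1, ], tg$genome)
  expect_false(d$enzyme$name == "EcoRI")
  ## the chosen site occurs once in the edited locus window, never in WT
  expect_equal(wormforge:::count_site(d$enzyme$site, tg$ref), 0)
})

test_that("predicted edited allele carries the insert once and truncates translation", {
  lib <- toy_library()
  d <- lib$designs[[1]]
  m <- lib$models[[d$gene_id]]
  allele <- predict_edited_allele(d, lib$genome)
  expect_identical(allele, d$expected_edited_locus)
  expect_equal(nchar(allele), 20 + nchar(d$insert_seq) + 20)
  expect_equal(wormforge:::count_site(d$enzyme$site, allele), 1)

  ## rebuild the full edited CDS and check for a premature stop
  di <- d$deleted_interval
  ints <- m$cds_intervals
  cs <- min(ints[, "start"]); ce <- max(ints[, "end"])
  chrom <- lib$genome$sequences[[m$chrom]]
  edited_genomic <- paste0(substr(chrom, cs + 1, di["start"]),
                           d$insert_ref,
                           substr(chrom, di["end"] + 1, ce))
  edited_cds <- if (m$strand == "+") edited_genomic else revcomp_chr(edited_genomic)
  aa <- translate_dna(edited_cds, truncate = TRUE)
  first_stop <- regexpr("*", aa, fixed = TRUE)
  expect_gt(first_stop, 0)
  expect_lt(first_stop, nchar(m$protein) + 1)  # earlier than the WT stop
})

test_that("genotyping assays obey amplicon and digest constraints", {
  lib <- toy_library()
  for (id in names(lib$assays)) {
    a <- lib$assays[[id]]; d <- lib$designs[[id]]
    expect_gte(a$wt_amplicon_len, 400)
    expect_lte(a$wt_amplicon_len, 1000)
    expect_equal(a$edited_amplicon_len,
                 a$wt_amplicon_len + nchar(d$insert_seq) -
                   unname(d$deleted_interval["end"] - d$deleted_interval["start"]))
    fr <- a$edited_digest_fragments
    expect_length(fr, 2)
    expect_equal(sum(fr), a$edited_amplicon_len)
    expect_gte(min(fr), 100)
    expect_gte(abs(diff(fr)), 50)
    expect_identical(a$wt_digest_fragments, a$wt_amplicon_len)
    for (p in c(a$fwd_primer, a$rev_primer)) {
      expect_gte(nchar(p), 18); expect_lte(nchar(p), 25)
      gc <- nchar(gsub("[AT]", "", p)) / nchar(p)
      expect_gte(gc, 0.40); expect_lte(gc, 0.60)
      expect_false(grepl("A{5}|C{5}|G{5}|T{5}", p))
    }
  }
})

test_that("digest fragment arithmetic follows the site position", {
  lib <- toy_library()
  for (id in head(names(lib$assays), 4)) {
    a <- lib$assays[[id]]; d <- lib$designs[[id]]
    chrom <- lib$genome$sequences[[d$chrom]]
    di <- d$deleted_interval
    ed_amp <- paste0(substr(chrom, a$amplicon_interval["start"] + 1, di["start"]),
                     d$insert_ref,
                     substr(chrom, di["end"] + 1, a$amplicon_interval["end"]))
    pos0 <- regexpr(d$enzyme$site, ed_amp, fixed = TRUE) - 1
    cutpos <- pos0 + d$enzyme$cut_offset
    expect_equal(a$edited_digest_fragments,
                 sort(c(cutpos, nchar(ed_amp) - cutpos)))
  }
})

test_that("validate_design passes compliant designs and flags forced violations", {
  lib <- toy_library()
  d <- lib$designs[[1]]; a <- lib$assays[[1]]
  v <- validate_design(d, a, lib$genome)
  expect_true(v$pass)
  expect_true(all(v$checks$pass))

  ## force an in-frame (non-frameshifting) edit
  bad <- d
  bad$insert_seq <- paste0(d$insert_seq, strrep("A", 3 - nchar(d$insert_seq) %% 3))
  net <- nchar(bad$insert_seq) - unname(d$deleted_interval["end"] -
                                          d$deleted_interval["start"])
  if (net %% 3 != 0) {
    bad$insert_seq <- paste0(bad$insert_seq, strrep("A", (3 - net %% 3) %% 3))
  }
  vb <- validate_design(bad, NULL, lib$genome)
  expect_false(vb$checks$pass[vb$checks$check == "frameshift"])

  ## corrupt an arm so it no longer matches the reference
  bad2 <- d
  substr(bad2$left_arm, 1, 1) <- if (substr(bad2$left_arm, 1, 1) == "A") "C" else "A"
  v2 <- validate_design(bad2, NULL, lib$genome)
  expect_false(v2$checks$pass[v2$checks$check == "arms_match_reference"])
  expect_false(v2$pass)
})

test_that("degenerate identity edits are rejected", {
  lib <- toy_library()
  d <- lib$designs[[1]]
  d$insert_seq <- ""
  d$insert_ref <- ""
  d$deleted_interval["end"] <- d$deleted_interval["start"]
  expect_error(predict_edited_allele(d, lib$genome), "degenerate")
})
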