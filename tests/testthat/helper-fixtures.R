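## Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

## small simulated library: 4 families x 3 members, written to disk and read
## back through the package's own FASTA/GFF3 path
toy_library <- function() {
  if (!is.null(.fixture_cache$lib)) return(.fixture_cache$lib)
  set.seed(4242)
  fams <- simulate_gene_set(n_families = 4, family_size = 3,
                            target_identity = 0.60, ancestor_len_aa = 250)
  toy <- build_toy_genome(fams, spacer_len = 500)
  dir <- file.path(tempdir(), "wormforge-fixture")
  write_sim_bundle(toy, dir, seed = 4242)
  genome <- read_genome(file.path(dir, "genome.fa"))
  models <- read_gene_models(file.path(dir, "genes.gff3"), genome)
  lib <- design_library(models, genome)
  .fixture_cache$lib <- list(fams = fams, toy = toy, dir = dir,
                             genome = genome, models = models,
                             designs = lib$designs, assays = lib$assays,
                             errors = lib$errors)
  .fixture_cache$lib
}

## write a tiny FASTA + GFF3 by hand for genome_io unit tests
write_tiny_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n) {
    c(paste0(">", n), records[[n]])
  })), path)
  path
}

write_tiny_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
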