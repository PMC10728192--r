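#' Default pipeline configuration
#'
#' Every tunable parameter of the workflow surfaces here with its
#' module default: identity threshold 0.40 (strict), group capacity 6 with
#' 3 genes per injection, 50 kb linkage window, 7-nt deletion, >8-read /
#' <=6-sample confidence filter, and an all-exact editing-outcome mix.
#'
#' @return Nested list of per-stage parameters.
#' @export
default_config <- function() {
  list(
    simulate = list(n_families = 6L, family_size = 3L, target_identity = 0.60,
                    ancestor_len_aa = 300L, spacer_len = 500L,
                    edit_mode_mix = c(exact = 1)),
    group = list(threshold = 0.40, max_group_size = 6L,
                 max_per_injection = 3L, linkage_window_bp = 50000L),
    design = list(del_len = 7L),
    verify = list(min_reads_exclusive = 8L, max_samples = 6L),
    screen = list(enabled = FALSE, p_attract = 0.9, n_worms = 150L,
                  n_plates = 3L))
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  merged <- default_config()
  for (sec in names(config)) {
    merged[[sec]] <- if (is.list(merged[[sec]]) && is.list(config[[sec]])) {
      modifyList(merged[[sec]], config[[sec]])
    } else config[[sec]]
  }
  merged
}

#' Run the knockout-library pipeline end to end
#'
#' Chains the stages: input generation (or loading), paralog grouping, ssODN
#' and genotyping design, editing-outcome simulation (or loading of variant
#' calls), allele classification, and (optionally) a simulated chemotaxis
#' screen. Per-gene failures are data, not exceptions: they are logged,
#' written to `errors.tsv` and skipped. Every run writes a `manifest.json`
#' recording the tool version, parameters, seed and output checksums.
#'
#' @param config A nested list (see [default_config()]) or path to a
#'   YAML/JSON file with per-stage sections. Supplying
#'   `inputs = list(genome=, gff=, meta=)` skips simulation; supplying
#'   `inputs$calls` skips outcome simulation.
#' @param out_dir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @return Invisibly, a list with the main stage outputs and a `summary`
#'   data frame. Raises an error only when a non-empty gene set yields zero
#'   successful designs.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "log.txt")
  loglines <- character(0)
  logmsg <- function(...) loglines <<- c(loglines, paste0(...))
  set.seed(seed)

  ## --- inputs -------------------------------------------------------------
  if (!is.null(cfg$inputs)) {
    genome <- read_genome(cfg$inputs$genome)
    models <- read_gene_models(cfg$inputs$gff, genome)
    meta <- read.delim(cfg$inputs$meta, comment.char = "#")
    proteins <- setNames(vapply(models, `[[`, character(1), "protein"),
                         names(models))
  } else {
    sim <- cfg$simulate
    fams <- if (sim$n_families > 0) {
      simulate_gene_set(sim$n_families, sim$family_size, sim$target_identity,
                        sim$ancestor_len_aa)
    } else list()
    toy <- build_toy_genome(fams, spacer_len = sim$spacer_len)
    indir <- file.path(out_dir, "inputs")
    write_sim_bundle(toy, indir, seed = seed)
    genome <- read_genome(file.path(indir, "genome.fa"))
    models <- if (length(fams)) {
      read_gene_models(file.path(indir, "genes.gff3"), genome)
    } else list()
    meta <- toy$meta
    proteins <- toy$proteins
  }
  for (g in names(models)) logmsg("io\t", g, "\tok")

  ## --- grouping -----------------------------------------------------------
  groups <- list()
  gtab <- NULL
  if (length(proteins)) {
    clusters <- cluster_by_identity(proteins, cfg$group$threshold)
    groups <- assign_groups(clusters, meta,
                            max_group_size = cfg$group$max_group_size,
                            max_per_injection = cfg$group$max_per_injection,
                            linkage_window_bp = cfg$group$linkage_window_bp)
    gtab <- merge(groups_table(groups),
                  meta[, c("gene_id", "subfamily")], by = "gene_id",
                  sort = FALSE)
    gtab <- gtab[, c("group_id", "gene_id", "subfamily", "rationale",
                     "round_index")]
    gtab <- gtab[order(gtab$group_id, gtab$round_index, gtab$gene_id), ]
    for (g in gtab$gene_id) logmsg("group\t", g, "\tok")
  } else {
    gtab <- data.frame(group_id = character(), gene_id = character(),
                       subfamily = character(), rationale = character(),
                       round_index = integer())
  }
  write_tsv_commented(gtab, file.path(out_dir, "groups.tsv"),
                      c("co-editing groups: group_id, gene_id, subfamily, rationale, injection round",
                        paste("seed:", seed)))

  ## --- design -------------------------------------------------------------
  lib <- design_library(models, genome, del_len = cfg$design$del_len)
  for (g in names(lib$designs)) logmsg("design\t", g, "\tok")
  if (nrow(lib$errors)) {
    for (i in seq_len(nrow(lib$errors))) {
      logmsg("design\t", lib$errors$gene_id[i], "\t", lib$errors$reason[i])
    }
  }
  write_tsv_commented(designs_table(lib$designs, lib$assays),
                      file.path(out_dir, "designs.tsv"),
                      c("stop-in ssODN + RFLP assay designs; coordinates 0-based half-open",
                        paste("seed:", seed)))
  write_tsv_commented(lib$errors, file.path(out_dir, "errors.tsv"),
                      "per-gene design failures with machine-readable reason codes")
  if (length(lib$designs)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      setNames(vapply(lib$designs, `[[`, character(1), "ssodn_seq"),
               names(lib$designs))),
      file.path(out_dir, "ssodn.fa"))
    bed <- do.call(rbind, lapply(lib$designs, function(d) {
      data.frame(chrom = d$chrom, start = unname(d$deleted_interval["start"]),
                 end = unname(d$deleted_interval["end"]), name = d$gene_id)
    }))
    write_bed(bed, file.path(out_dir, "deleted.bed"))
  }
  if (length(models) > 0 && length(lib$designs) == 0) {
    writeLines(loglines, logfile)
    stop("pipeline failed: zero designs succeeded")
  }

  ## --- verification -------------------------------------------------------
  calls <- NULL
  allele_calls <- data.frame()
  if (!is.null(cfg$inputs$calls)) {
    calls <- read_variant_calls(cfg$inputs$calls)
  } else if (length(lib$designs)) {
    mix <- cfg$simulate$edit_mode_mix
    modes <- sample(names(mix), length(lib$designs), replace = TRUE,
                    prob = unlist(mix))
    calls <- do.call(rbind, lapply(seq_along(lib$designs), function(i) {
      simulate_edit_outcome(lib$designs[[i]], modes[i],
                            strain_id = sprintf("SIM%03d", i))
    }))
    write_tsv_commented(calls, file.path(out_dir, "calls.tsv"),
                        c("simulated variant-call records per designed locus",
                          paste("seed:", seed)))
  }
  if (!is.null(calls) && nrow(calls)) {
    allele_calls <- classify_batch(calls, lib$designs,
                                   min_reads_exclusive = cfg$verify$min_reads_exclusive,
                                   max_samples = cfg$verify$max_samples)
    for (i in seq_len(nrow(allele_calls))) {
      logmsg("verify\t", allele_calls$gene_id[i], "\t", allele_calls$status[i])
    }
    write_tsv_commented(allele_calls, file.path(out_dir, "allele_calls.tsv"),
                        c("allele classification: strain_id, gene_id, mismatches, status, notes, override",
                          paste("seed:", seed)))
  }

  ## --- screen (optional simulated chemotaxis) -----------------------------
  screen_records <- NULL
  if (isTRUE(cfg$screen$enabled) && length(groups)) {
    p <- rep_len(cfg$screen$p_attract, length(groups))
    screen_records <- do.call(rbind, lapply(seq_along(groups), function(i) {
      counts <- simulate_quadrant_counts(p[i], cfg$screen$n_worms,
                                         cfg$screen$n_plates)
      data.frame(strain_id = groups[[i]]$group_id, ci = mean(counts$ci))
    }))
    write_tsv_commented(screen_records, file.path(out_dir, "screen_records.tsv"),
                        c("per-strain mean quadrant chemotaxis index",
                          paste("seed:", seed)))
    for (s in screen_records$strain_id) logmsg("screen\t", s, "\tok")
  }

  writeLines(loglines, logfile)
  write_manifest(out_dir, cfg, seed)
  invisible(list(genome = genome, models = models, groups = groups,
                 designs = lib$designs, assays = lib$assays,
                 errors = lib$errors, calls = calls,
                 allele_calls = allele_calls, screen = screen_records,
                 summary = data.frame(
                   n_genes = length(models), n_groups = length(groups),
                   n_designs = length(lib$designs),
                   n_design_errors = nrow(lib$errors),
                   n_alleles = nrow(allele_calls))))
}

write_manifest <- function(out_dir, cfg, seed) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(tool = "wormforge",
                   version = as.character(packageVersion("wormforge")),
                   subcommand = "run", seed = seed, parameters = cfg,
                   checksums = as.list(setNames(unname(sums), files)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
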