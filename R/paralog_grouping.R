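#' Pairwise protein sequence identity
#'
#' Global alignment (match +1, mismatch 0, gap open 5, gap extend 1, end gaps
#' penalized); identity is the number of identically aligned positions
#' divided by the length of the shorter sequence (the convention of
#' short-sequence clustering tools such as CD-HIT).
#'
#' @param a,b Non-empty protein (or DNA) strings.
#' @return Fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  st <- alignment_columns(align_global(a, b))
  st$matches / min(nchar(a), nchar(b))
}

#' All-against-all identity matrix
#'
#' @param proteins Named character vector of protein sequences.
#' @return Symmetric matrix of identity fractions with unit diagonal.
#' @export
identity_matrix <- function(proteins) {
  n <- length(proteins)
  ids <- names(proteins)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- pairwise_identity(proteins[[i]], proteins[[j]])
    }
  }
  m
}

#' Greedy representative clustering by protein identity
#'
#' Genes are sorted by protein length descending (ties broken by gene id);
#' each gene joins the first existing cluster whose *representative* (the
#' seeding, longest member) has pairwise identity strictly greater than
#' `threshold`, otherwise it seeds a new cluster. The canonical sort makes
#' the result independent of input order.
#'
#' @param proteins Named character vector (gene id -> protein sequence).
#' @param threshold Identity cutoff in (0, 1); comparison is strict (`>`).
#' @return List of clusters, each a character vector of gene ids (the first
#'   element is the representative).
#' @export
cluster_by_identity <- function(proteins, threshold = 0.40) {
  stopifnot(threshold > 0, threshold < 1)
  if (length(proteins) == 0L) return(list())
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("proteins must be uniquely named by gene id")
  }
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0)
  clusters <- list()
  for (g in names(proteins)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(proteins[[g]], proteins[[reps[k]]]) > threshold) {
        clusters[[k]] <- c(clusters[[k]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, g)
      clusters <- c(clusters, list(g))
    }
  }
  clusters
}

## numeric suffix of a gene name ("srx-64" -> 64); NA when absent
gene_numeric_order <- function(name) {
  suppressWarnings(as.numeric(sub("^.*-([0-9]+)$", "\\1",
                                  ifelse(grepl("-[0-9]+$", name), name, NA))))
}

new_paralog_group <- function(group_id, members, rationale) {
  structure(list(group_id = group_id, members = members,
                 rationale = setNames(rationale, members),
                 injection_rounds = NULL),
            class = "paralog_group")
}

#' Pack clustered genes into co-editing groups
#'
#' Builds the per-strain gene sets: (1) multi-member identity clusters become
#' seed groups, split in cluster order into chunks of at most
#' `max_group_size` (rationale `identity`); (2) remaining singletons whose
#' locus lies within `linkage_window_bp` of a member of an existing
#' same-subfamily group on the same chromosome join that group if capacity
#' allows (`linkage`); (3) leftovers are packed by numeric order of gene
#' names within each subfamily (`numeric_order`); (4) genes flagged reserved
#' (well-characterized genes kept alone) become singleton groups
#' (`reserved_singleton`). Groups never mix subfamilies.
#'
#' @param clusters List of character vectors from [cluster_by_identity()].
#' @param metadata Data frame with columns `gene_id`, `subfamily`, `chrom`,
#'   `position` (representative locus coordinate, bp) and logical `reserved`.
#' @param max_group_size Maximum genes per strain (default 6, i.e. two
#'   editing rounds of three).
#' @param max_per_injection Genes per microinjection (default 3).
#' @param linkage_window_bp Distance on the same chromosome within which a
#'   leftover singleton is considered "closely linked" (default 50 kb).
#' @return List of `paralog_group` objects with injection rounds assigned.
#' @export
assign_groups <- function(clusters, metadata, max_group_size = 6L,
                          max_per_injection = 3L, linkage_window_bp = 50000L) {
  all_genes <- unlist(clusters, use.names = FALSE)
  missing <- setdiff(all_genes, metadata$gene_id)
  if (length(missing)) {
    stop("gene(s) missing metadata: ", paste(missing, collapse = ", "))
  }
  meta <- metadata[match(all_genes, metadata$gene_id), ]
  rownames(meta) <- meta$gene_id

  groups <- list()
  leftovers <- character(0)

  ## reserved genes are always singletons
  reserved <- meta$gene_id[isTRUE_vec(meta$reserved)]
  for (cl in clusters) {
    res_in <- intersect(cl, reserved)
    if (length(res_in) && length(cl) > 1L) {
      warning("reserved gene(s) ", paste(res_in, collapse = ", "),
              " removed from a multi-gene identity cluster")
    }
  }
  clusters <- lapply(clusters, setdiff, y = reserved)
  clusters <- Filter(length, clusters)

  ## (1) identity clusters -> seed groups, subfamily-homogeneous, chunked
  for (cl in clusters) {
    if (length(cl) == 1L) {
      leftovers <- c(leftovers, cl)
      next
    }
    for (sub in unique(meta[cl, "subfamily"])) {
      part <- cl[meta[cl, "subfamily"] == sub]
      if (length(part) == 1L) {
        leftovers <- c(leftovers, part)
        next
      }
      chunks <- split(part, ceiling(seq_along(part) / max_group_size))
      for (ch in chunks) {
        groups[[length(groups) + 1L]] <-
          new_paralog_group(NA_character_, ch, rep("identity", length(ch)))
      }
    }
  }

  ## (2) linkage rescue of singletons into existing groups
  still <- character(0)
  for (g in leftovers) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      mem <- groups[[k]]$members
      if (length(mem) >= max_group_size) next
      if (meta[mem[1], "subfamily"] != meta[g, "subfamily"]) next
      same_chr <- mem[meta[mem, "chrom"] == meta[g, "chrom"]]
      if (!length(same_chr)) next
      d <- abs(meta[same_chr, "position"] - meta[g, "position"])
      if (any(d <= linkage_window_bp)) {
        groups[[k]]$members <- c(mem, g)
        groups[[k]]$rationale <- c(groups[[k]]$rationale, setNames("linkage", g))
        placed <- TRUE
        break
      }
    }
    if (!placed) still <- c(still, g)
  }

  ## (3) leftovers packed by numeric order of gene names within subfamily
  for (sub in unique(meta[still, "subfamily"])) {
    gs <- still[meta[still, "subfamily"] == sub]
    num <- gene_numeric_order(gs)
    gs <- gs[order(is.na(num), num, gs)]
    chunks <- split(gs, ceiling(seq_along(gs) / max_group_size))
    for (ch in chunks) {
      groups[[length(groups) + 1L]] <-
        new_paralog_group(NA_character_, ch, rep("numeric_order", length(ch)))
    }
  }

  ## (4) reserved genes
  for (g in reserved) {
    groups[[length(groups) + 1L]] <-
      new_paralog_group(NA_character_, g, "reserved_singleton")
  }

  for (k in seq_along(groups)) {
    groups[[k]]$group_id <- sprintf("G%03d", k)
    groups[[k]] <- plan_injections(groups[[k]], max_per_injection)
  }
  groups
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Partition a group's members into injection rounds
#'
#' Members are split, in listed order, into consecutive rounds of at most
#' `max_per_injection` genes (up to three genes are co-injected; larger
#' groups need multiple sequential editing rounds).
#'
#' @param group A `paralog_group`.
#' @param max_per_injection Genes per microinjection (default 3).
#' @return The group with `injection_rounds` filled in.
#' @export
plan_injections <- function(group, max_per_injection = 3L) {
  stopifnot(inherits(group, "paralog_group"), length(group$members) >= 1L)
  idx <- ceiling(seq_along(group$members) / max_per_injection)
  group$injection_rounds <- unname(split(group$members, idx))
  group
}

#' @export
print.paralog_group <- function(x, ...) {
  cat("paralog_group", x$group_id, ":", paste(x$members, collapse = ", "),
      sprintf("(%d round(s))\n", length(x$injection_rounds)))
  invisible(x)
}

#' Flatten paralog groups to a table
#'
#' @param groups List of `paralog_group` objects.
#' @return Data frame with columns `group_id`, `gene_id`, `rationale`,
#'   `round_index`.
#' @export
groups_table <- function(groups) {
  do.call(rbind, lapply(groups, function(g) {
    rnd <- rep(seq_along(g$injection_rounds),
               lengths(g$injection_rounds))[match(g$members,
                                                  unlist(g$injection_rounds))]
    data.frame(group_id = g$group_id, gene_id = g$members,
               rationale = unname(g$rationale[g$members]),
               round_index = rnd, row.names = NULL)
  }))
}
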