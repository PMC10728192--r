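## Independent oracles used to check the package implementation.
## These deliberately share no code with wormforge internals.

## Affine-gap Needleman-Wunsch (Gotoh) oracle: match +1, mismatch 0, a gap
## run of length L costs 5 + L, end gaps penalized. Returns the optimal
## score plus the max and min number of identical aligned pairs achievable
## among optimal alignments.
nw_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  S <- array(NEG, c(n + 1, m + 1, 3))      # states: 1=M aligned, 2=X gap-in-b, 3=Y gap-in-a
  Mx <- array(0, c(n + 1, m + 1, 3))       # max matches at optimal
  Mn <- array(0, c(n + 1, m + 1, 3))       # min matches at optimal
  S[1, 1, 1] <- 0
  for (i in seq_len(n)) S[i + 1, 1, 2] <- -(5 + i)
  for (j in seq_len(m)) S[1, j + 1, 3] <- -(5 + j)
  best_of <- function(scores, mx, mn) {
    s <- max(scores)
    keep <- which(scores == s)
    list(s = s, mx = max(mx[keep]), mn = min(mn[keep]))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- as.integer(av[i] == bv[j])
      p <- best_of(S[i, j, ], Mx[i, j, ], Mn[i, j, ])
      S[i + 1, j + 1, 1] <- p$s + hit
      Mx[i + 1, j + 1, 1] <- p$mx + hit
      Mn[i + 1, j + 1, 1] <- p$mn + hit
      p <- best_of(S[i, j + 1, ] - c(6, 1, 6), Mx[i, j + 1, ], Mn[i, j + 1, ])
      S[i + 1, j + 1, 2] <- p$s; Mx[i + 1, j + 1, 2] <- p$mx
      Mn[i + 1, j + 1, 2] <- p$mn
      p <- best_of(S[i + 1, j, ] - c(6, 6, 1), Mx[i + 1, j, ], Mn[i + 1, j, ])
      S[i + 1, j + 1, 3] <- p$s; Mx[i + 1, j + 1, 3] <- p$mx
      Mn[i + 1, j + 1, 3] <- p$mn
    }
  }
  fin <- best_of(S[n + 1, m + 1, ], Mx[n + 1, m + 1, ], Mn[n + 1, m + 1, ])
  list(score = fin$s, max_matches = fin$mx, min_matches = fin$mn)
}

## identity fraction per the package's definition, computed with the oracle
oracle_identity <- function(a, b) {
  nw_oracle(a, b)$max_matches / min(nchar(a), nchar(b))
}

## exhaustive sliding-window protospacer scan over a reference interval
## [s, e) (0-based half-open), using regex lookahead instead of the
## package's explicit window loop; returns a data frame of cut positions
pam_scan_oracle <- function(refseq, s, e) {
  region <- substr(refseq, s + 1, e)
  hits <- list()
  gg <- gregexpr("(?=GG)", region, perl = TRUE)[[1]]
  if (gg[1] != -1) {
    for (p in gg) {  # GG at p, p+1 (1-based); PAM N at p-1
      pam_start <- p - 1  # 1-based index of the N of NGG
      if (pam_start - 20 >= 1 && pam_start + 2 <= nchar(region)) {
        hits[[length(hits) + 1]] <- data.frame(
          cut_pos = s + (pam_start - 1) - 3, strand = "+")
      }
    }
  }
  cc <- gregexpr("(?=CC)", region, perl = TRUE)[[1]]
  if (cc[1] != -1) {
    for (p in cc) {  # CCN at p..p+2 (1-based), protospacer 20 nt after
      if (p + 22 <= nchar(region)) {
        hits[[length(hits) + 1]] <- data.frame(
          cut_pos = s + (p - 1) + 6, strand = "-")
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(cut_pos = integer(), strand = character()))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$cut_pos, out$strand), , drop = FALSE]
}

## independent run of the greedy representative clustering rule, driven by
## the oracle identity (usable for short peptides)
greedy_cluster_oracle <- function(proteins, threshold) {
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0); clusters <- list()
  for (g in names(proteins)) {
    k <- 0
    for (r in seq_along(reps)) {
      if (oracle_identity(proteins[[g]], proteins[[reps[r]]]) > threshold) {
        k <- r; break
      }
    }
    if (k > 0) clusters[[k]] <- c(clusters[[k]], g)
    else { reps <- c(reps, g); clusters <- c(clusters, list(g)) }
  }
  clusters
}

## reverse complement for building test sequences
revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}
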