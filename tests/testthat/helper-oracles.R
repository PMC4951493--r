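# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and separate from the implementation paths they check.

# random toy genome: k genes with random non-overlapping-ish coordinates
random_toy_genome <- function(n_genes = 8, contig_len = 5000, id = "toy") {
  starts <- sort(sample.int(contig_len - 100, n_genes))
  ends <- pmin(starts + sample(30:120, n_genes, replace = TRUE), contig_len)
  # drop genes swallowed by the previous one so start < end holds and order
  # by start is unambiguous
  keep <- c(TRUE, diff(starts) > 0)
  starts <- starts[keep]; ends <- ends[keep]
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_along(starts)),
    contig_id = "c1", start = starts, end = ends,
    strand = sample(c("+", "-"), length(starts), replace = TRUE))
  annotated_genome(id, c(c1 = random_dna(1, contig_len)), genes)
}

# brute-force intergenic distances (independent re-derivation)
bf_intergenic <- function(genome) {
  g <- genome$genes
  out <- integer(0)
  for (ctg in unique(g$contig_id)) {
    gi <- g[g$contig_id == ctg, ]
    gi <- gi[order(gi$start), ]
    if (nrow(gi) < 2) next
    for (k in 2:nrow(gi)) out <- c(out, gi$start[k] - gi$end[k - 1])
  }
  out
}

# brute-force rescoring scan: score every window on both strands explicitly
bf_scan <- function(motif, seq, threshold) {
  w <- motif$width
  out <- NULL
  for (p in seq_len(nchar(seq) - w + 1)) {
    win <- substr(seq, p, p + w - 1)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") win else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      sc <- score_site(motif, s)
      if (sc >= threshold) {
        out <- rbind(out, data.frame(position = p - 1L, strand = strand,
                                     score = sc))
      }
    }
  }
  if (is.null(out)) return(data.frame(position = integer(0),
                                      strand = character(0),
                                      score = numeric(0)))
  if (motif$is_palindromic) {
    dup <- out$strand == "-" & out$position %in% out$position[out$strand == "+"]
    out <- out[!dup, ]
  }
  out[order(out$position, out$strand), ]
}

# brute-force operon prediction: recompute the mean, re-merge directons
bf_operons <- function(genome) {
  g <- genome$genes
  mean_igd <- mean(bf_intergenic(genome))
  membership <- integer(nrow(g))
  op <- 0
  for (ctg in unique(g$contig_id)) {
    idx <- which(g$contig_id == ctg)
    idx <- idx[order(g$start[idx])]
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (k == 1) {
        op <- op + 1
      } else {
        j <- idx[k - 1]
        merge <- g$strand[i] == g$strand[j] &&
          (g$start[i] - g$end[j]) < mean_igd
        if (!merge) op <- op + 1
      }
      membership[i] <- op
    }
  }
  split(g$gene_id, membership)
}

# Gotoh affine-gap Smith-Waterman, plain O(n*m) dynamic programming
bf_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- regulonscout:::blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(0, n + 1, m + 1)
  X[] <- Y[] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + S[av[i - 1], bv[j - 1]])
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

random_aa <- function(n) {
  paste(sample(regulonscout:::AA_CANONICAL, n, replace = TRUE),
        collapse = "")
}

# tiny hand-built genome from a gene table and explicit contig
make_genome <- function(genes, contig, id = "toy") {
  annotated_genome(id, c(c1 = contig), cbind(genes, contig_id = "c1"))
}
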