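# De novo palindromic motif discovery: expectation-maximization over a
# zero-or-one-occurrence-per-sequence (ZOOPS) model with an optional
# palindromic constraint, replacing an external motif-discovery tool.
#
# Model: each sequence carries a motif occurrence with probability gamma, at
# a position/strand uniform over all windows; non-site positions follow a
# 0-order background estimated from the input. The palindromic constraint is
# imposed by averaging the expected count matrix with its reverse complement
# after every M-step, the maximum-likelihood update under the constraint
# f(b, l) = f(complement(b), W + 1 - l).

em_seed_matrix <- function(wmer, strong = 0.55) {
  codes <- dna_to_int(wmer)
  f <- matrix((1 - strong) / 3, nrow = 4, ncol = length(codes),
              dimnames = list(DNA_BASES, NULL))
  for (l in seq_along(codes)) {
    if (codes[l] <= 4) f[codes[l], l] <- strong else f[, l] <- 0.25
  }
  f
}

#' Run ZOOPS expectation-maximization for a fixed motif width
#'
#' @param seqs Character vector of DNA sequences (all at least `width` long).
#' @param width Motif width (>= 4).
#' @param palindromic Impose the palindromic (reverse-complement symmetric)
#'   constraint after every M-step.
#' @param seed_sites Initialization: a single W-mer, a 4 x W frequency
#'   matrix, or `NULL` (first W-mer of the first sequence).
#' @param max_iter,tol Convergence controls on the expected log-likelihood
#'   ratio (bits of improvement per iteration).
#' @param pseudocount Dirichlet regularization added to expected counts.
#' @return A `discovery_result`: the fitted `binding_motif`, per-sequence
#'   `site_assignments` (`position` 0-based, `strand`, `posterior`; `NA`
#'   when the sequence is inferred site-free), `llr` (log-likelihood ratio
#'   against the background-only model), `significance` (BIC-penalized,
#'   lower is better), `gamma`, and the `ll_trace` across iterations.
#' @export
run_em_zoops <- function(seqs, width, palindromic = TRUE, seed_sites = NULL,
                         max_iter = 200L, tol = 1e-6, pseudocount = 0.25) {
  stopifnot(width >= 4)
  seqs <- toupper(seqs)
  short <- which(nchar(seqs) < width)
  if (length(short) > 0) {
    stop("sequence(s) shorter than the motif width: ",
         paste(utils::head(short, 5), collapse = ", "))
  }
  n <- length(seqs)
  codes <- lapply(seqs, dna_to_int)
  # 0-order background from the input
  tab <- tabulate(unlist(codes), 4L)
  q <- tab / sum(tab)
  logq <- log(q)
  m <- vapply(codes, length, integer(1)) - width + 1L
  # per-sequence window-code matrices (m_i x W) and their base indicators,
  # fixed across iterations: counts accumulate as z %*% indicator
  idx_list <- lapply(seq_len(n), function(i) {
    outer(seq_len(m[i]), seq_len(width) - 1L, `+`)
  })
  Cmat <- lapply(seq_len(n), function(i) {
    matrix(codes[[i]][idx_list[[i]]], nrow = m[i])
  })
  Ind <- lapply(seq_len(n), function(i) {
    lapply(1:4, function(b) Cmat[[i]] == b)
  })

  f <- if (is.matrix(seed_sites)) {
    stopifnot(nrow(seed_sites) == 4, ncol(seed_sites) == width)
    seed_sites
  } else if (is.character(seed_sites)) {
    stopifnot(nchar(seed_sites[1]) == width)
    em_seed_matrix(seed_sites[1])
  } else {
    em_seed_matrix(substr(seqs[1], 1, width))
  }
  if (palindromic) f <- (f + revcomp_matrix(f)) / 2
  gamma <- 0.5

  # per-sequence per-window log likelihood-ratio contributions; row l of the
  # W x 5 matrix holds log(f/q) for motif position l (5th column: ambiguous
  # base, neutral).
  window_loglr <- function(f) {
    lwt <- t(rbind(log(f) - logq, N = 0))  # w x 5
    lwt_rc <- lwt[width:1, c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
    list(fwd = lwt, rev = lwt_rc)
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    lw <- window_loglr(f)
    counts <- matrix(0, nrow = 4, ncol = width,
                     dimnames = list(DNA_BASES, NULL))
    ll <- 0
    zsum_total <- 0
    z_best <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- codes[[i]]
      lr_f <- scan_one_strand(lw$fwd, ci, width)
      lr_r <- scan_one_strand(lw$rev, ci, width)
      loglr <- c(lr_f, lr_r)
      # log responsibilities: background vs (position, strand)
      lp <- c(log(1 - gamma), log(gamma) - log(2 * m[i]) + loglr)
      mx <- max(lp)
      p <- exp(lp - mx)
      tot <- sum(p)
      ll <- ll + mx + log(tot)       # log-lik ratio vs background-only
      z <- p[-1] / tot
      zf <- z[seq_len(m[i])]
      zr <- z[m[i] + seq_len(m[i])]
      zsum_total <- zsum_total + sum(z)
      # accumulate expected counts; the minus-strand window at offset j
      # contributes the reverse complement of the plus-strand window
      Ii <- Ind[[i]]
      for (b in 1:4) {
        counts[b, ] <- counts[b, ] + as.vector(zf %*% Ii[[b]]) +
          rev(as.vector(zr %*% Ii[[5L - b]]))
      }
      j <- which.max(z)
      z_best[[i]] <- c(post = 1 - p[1] / tot,
                       pos = if (j > m[i]) j - m[i] - 1 else j - 1,
                       strand = if (j > m[i]) -1 else 1,
                       zmax = z[j])
    }
    ll_trace <- c(ll_trace, ll)
    counts_reg <- counts + pseudocount * q
    if (palindromic) counts_reg <- (counts_reg + revcomp_matrix(counts_reg)) / 2
    f <- sweep(counts_reg, 2, colSums(counts_reg), `/`)
    gamma <- min(max(zsum_total / n, 1e-6), 1 - 1e-6)
    if (iter > 1 && ll - ll_prev < tol && ll >= ll_prev - 1e-8) break
    ll_prev <- ll
  }

  motif <- new_binding_motif(f, counts = counts, nsites = zsum_total,
                             background = q, pseudocount = pseudocount)
  llr <- ll_trace[length(ll_trace)] / log(2)  # bits
  total_pos <- sum(2 * m)
  k <- if (palindromic) 3 * ceiling(width / 2) + 1 else 3 * width + 1
  sig <- -2 * ll_trace[length(ll_trace)] + k * log(total_pos)
  assign_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    zb <- z_best[[i]]
    has <- zb[["post"]] > 0.5
    data.frame(seq = i,
               position = if (has) as.integer(zb[["pos"]]) else NA_integer_,
               strand = if (has) ifelse(zb[["strand"]] > 0, "+", "-")
                        else NA_character_,
               posterior = zb[["post"]])
  }))
  structure(list(motif = motif, site_assignments = assign_df, llr = llr,
                 significance = sig, gamma = gamma, width = width,
                 iterations = length(ll_trace), ll_trace = ll_trace,
                 significant = sig < 0),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("Discovered motif: width %d, consensus %s\n", x$width,
              x$motif$consensus))
  cat(sprintf("  LLR %.1f bits, significance (BIC) %.1f [%s], gamma %.2f, %d EM iterations\n",
              x$llr, x$significance,
              if (x$significant) "significant" else "not significant",
              x$gamma, x$iterations))
  if (!is.null(x$width_scan)) {
    cat("  width scan:\n")
    print.data.frame(x$width_scan, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# Seed W-mers: most frequent words (pooling reverse complements) plus random
# W-mers drawn from the data.
seed_wmers <- function(seqs, width, n_seeds) {
  all_w <- unlist(lapply(seqs, function(s) {
    m <- nchar(s) - width + 1L
    if (m < 1) return(character(0))
    substring(s, 1:m, width:nchar(s))
  }))
  all_w <- all_w[!grepl("[^ACGT]", all_w)]
  if (length(all_w) == 0) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_w)))
  canon <- ifelse(rc < all_w, rc, all_w)
  tab <- sort(table(canon), decreasing = TRUE)
  n_top <- min(ceiling(n_seeds / 2), length(tab))
  top <- names(tab)[seq_len(n_top)]
  n_rand <- n_seeds - n_top
  rand <- if (n_rand > 0 && length(all_w) > 0) {
    sample(all_w, min(n_rand, length(all_w)))
  } else character(0)
  unique(c(top, rand))
}

#' Discover the most significant palindromic motif across a width range
#'
#' For each width in `[w_min, w_max]` the ZOOPS EM is started from
#' `n_seeds` seed W-mers (most frequent words plus random restarts under the
#' given RNG seed); short runs rank the seeds and the best are refined to
#' convergence. Model selection across widths uses the BIC-penalized
#' log-likelihood ratio `-2 * LLR + params * ln(total positions)` (lower is
#' better), which penalizes the extra columns of wider motifs.
#'
#' @param seqs Character vector of at least 2 promoter sequences.
#' @param w_min,w_max Width range to scan (the conventional palindromic
#'   search range is 8 to 20 bp).
#' @param palindromic Impose the palindromic constraint.
#' @param n_seeds Seed starts per width.
#' @param seed Integer RNG seed; identical inputs and seed give an identical
#'   result.
#' @param max_iter,tol Convergence controls for the final refinement runs.
#' @return The best `discovery_result`, with a `width_scan` table
#'   (`width`, `llr`, `significance`) attached.
#' @export
discover_motifs <- function(seqs, w_min = 8L, w_max = 20L, palindromic = TRUE,
                            n_seeds = 20L, seed = 1L, max_iter = 200L,
                            tol = 1e-6) {
  if (w_min > w_max) stop("w_min must not exceed w_max")
  if (length(seqs) < 2) stop("need at least 2 sequences")
  seqs <- toupper(seqs)
  with_seed(seed, {
    best <- NULL
    scan_tab <- data.frame(width = integer(0), llr = numeric(0),
                           significance = numeric(0))
    for (w in seq(w_min, w_max)) {
      if (any(nchar(seqs) < w)) next
      seeds <- seed_wmers(seqs, w, n_seeds)
      shorts <- lapply(seeds, function(s) {
        run_em_zoops(seqs, w, palindromic = palindromic, seed_sites = s,
                     max_iter = 15L, tol = 1e-4)
      })
      llrs <- vapply(shorts, `[[`, numeric(1), "llr")
      refine <- order(llrs, decreasing = TRUE)[seq_len(min(3, length(shorts)))]
      cands <- lapply(refine, function(i) {
        run_em_zoops(seqs, w, palindromic = palindromic, seed_sites = seeds[[i]],
                     max_iter = max_iter, tol = tol)
      })
      res_w <- cands[[which.min(vapply(cands, `[[`, numeric(1), "significance"))]]
      scan_tab <- rbind(scan_tab,
                        data.frame(width = w, llr = res_w$llr,
                                   significance = res_w$significance))
      if (is.null(best) || res_w$significance < best$significance) best <- res_w
    }
    if (is.null(best)) stop("no width in range fits the input sequences")
    best$width_scan <- scan_tab
    best
  })
}
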