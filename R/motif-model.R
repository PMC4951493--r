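# Binding-motif model and the sequence-information (Ri) scoring machinery.
#
# The per-position weights are individual-information weights
# Riw(b, l) = 2 + log2 f(b, l), so a site scores
# Ri = sum_l Riw(seq_l, l) bits; the consensus attains the maximum.

new_binding_motif <- function(freq, counts, nsites, background, pseudocount) {
  w <- ncol(freq)
  rownames(freq) <- DNA_BASES
  weights <- 2 + log2(freq)
  consensus <- consensus_from_freq(freq)
  pal <- isTRUE(all.equal(unname(freq), unname(revcomp_matrix(freq)),
                          tolerance = 1e-9))
  structure(list(width = w, nsites = nsites, counts = counts, freq = freq,
                 weights = weights, background = background,
                 consensus = consensus, is_palindromic = pal,
                 pseudocount = pseudocount),
            class = "binding_motif")
}

revcomp_matrix <- function(m) {
  out <- m[4:1, ncol(m):1, drop = FALSE]
  dimnames(out) <- dimnames(m)
  out
}

consensus_from_freq <- function(freq) {
  iupac <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                    Biostrings::IUPAC_CODE_MAP)
  paste(vapply(seq_len(ncol(freq)), function(l) {
    f <- freq[, l]
    top <- which(f >= max(f) - 1e-9)
    key <- paste(sort(DNA_BASES[top]), collapse = "")
    iupac[[key]]
  }, character(1)), collapse = "")
}

#' Build a binding-motif model from aligned sites
#'
#' Column frequencies are pseudocount-regularized,
#' `f(b,l) = (n(b,l) + pseudocount * q(b)) / (N + pseudocount)`, and the
#' information weights are `Riw(b,l) = 2 + log2 f(b,l)` (bits). The motif is
#' flagged palindromic when its count matrix equals its own reverse
#' complement, the hallmark of a site bound symmetrically by a homodimer.
#'
#' @param sites Character vector of equal-length A/C/G/T site sequences.
#' @param pseudocount Total pseudocount mass distributed as the background.
#' @param background Numeric length-4 base probabilities (A, C, G, T).
#' @return A `binding_motif`.
#' @export
build_motif <- function(sites, pseudocount = 1, background = rep(0.25, 4)) {
  stopifnot(length(sites) >= 1, length(background) == 4,
            abs(sum(background) - 1) < 1e-6)
  sites <- check_dna(sites, "site")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must all have the same length")
  n <- length(sites)
  mat <- do.call(rbind, lapply(sites, dna_to_int))
  counts <- vapply(seq_len(w), function(l) tabulate(mat[, l], 4L),
                   integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  freq <- sweep(counts + pseudocount * background, 2,
                n + pseudocount, `/`)
  new_binding_motif(freq, counts, n, background, pseudocount)
}

#' Build a motif model directly from an IUPAC consensus
#'
#' Constructs column frequencies so that each non-degenerate column carries
#' `bits_per_column` bits of information content (under a uniform background),
#' degenerate columns split that information over their base set, and `N`
#' columns are exactly uniform (0 bits). Useful for simulating site ensembles
#' from a consensus such as `"TGTTC-N4-GAACA"`.
#'
#' @param consensus IUPAC consensus, optionally in dashed `GAAC-N4-GTTC` form.
#' @param bits_per_column Information content (bits) of a fully specified
#'   column; 2 gives an invariant column.
#' @param background Base probabilities used for the weights.
#' @return A `binding_motif` (with `nsites = NA`; frequencies are exact).
#' @export
motif_from_consensus <- function(consensus, bits_per_column = 1.8,
                                 background = rep(0.25, 4)) {
  stopifnot(bits_per_column > 0, bits_per_column <= 2)
  consensus <- expand_consensus(consensus)
  sets <- iupac_sets(consensus)
  freq <- vapply(sets, function(s) {
    k <- length(s)
    if (k == 4) return(rep(0.25, 4))
    if (bits_per_column >= 2 - 1e-12 && k == 1) {
      p <- 1 - 1e-12  # keep log2 finite
    } else {
      ic <- function(P) {
        f <- numeric(4)
        f[s] <- P / k
        f[-s] <- (1 - P) / (4 - k)
        2 + sum(ifelse(f > 0, f * log2(f), 0))
      }
      lo <- k / 4 + 1e-9
      p <- stats::uniroot(function(P) ic(P) - bits_per_column,
                          lower = lo, upper = 1 - 1e-12, tol = 1e-12)$root
    }
    f <- numeric(4)
    f[s] <- p / k
    f[-s] <- (1 - p) / (4 - k)
    f
  }, numeric(4))
  new_binding_motif(freq, counts = NULL, nsites = NA_integer_,
                    background = background, pseudocount = 0)
}

#' @export
print.binding_motif <- function(x, ...) {
  cat(sprintf("Binding motif: width %d, consensus %s%s\n", x$width,
              x$consensus, if (x$is_palindromic) " (palindromic)" else ""))
  if (!is.na(x$nsites)) cat(sprintf("  built from %d sites\n", x$nsites))
  cat(sprintf("  max Ri score: %.2f bits, total information: %.2f bits\n",
              max_score(x), sum(information_content(x))))
  invisible(x)
}

#' @export
summary.binding_motif <- function(object, ...) {
  ic <- information_content(object)
  out <- data.frame(position = seq_len(object$width),
                    consensus = strsplit(object$consensus, "")[[1]],
                    information_bits = ic,
                    t(object$freq))
  class(out) <- c("summary.binding_motif", "data.frame")
  out
}

#' @export
print.summary.binding_motif <- function(x, ...) {
  cat("Per-position base frequencies and information content (bits):\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Per-position information content
#'
#' `IC(l) = 2 + sum_b f(b,l) log2 f(b,l)` bits, the quantity a sequence logo
#' displays.
#'
#' @param motif A `binding_motif`.
#' @return Numeric vector of length `width`.
#' @export
information_content <- function(motif) {
  apply(motif$freq, 2, function(f) 2 + sum(ifelse(f > 0, f * log2(f), 0)))
}

#' Maximum achievable Ri score of a motif
#'
#' @param motif A `binding_motif`.
#' @return Score in bits of the best possible W-mer.
#' @export
max_score <- function(motif) {
  sum(apply(motif$weights, 2, max))
}

#' @export
plot.binding_motif <- function(x, ...) {
  ic <- information_content(x)
  graphics::barplot(ic, names.arg = strsplit(x$consensus, "")[[1]],
                    ylab = "information (bits)", xlab = "motif position",
                    ylim = c(0, 2), border = NA, col = "steelblue", ...)
  invisible(x)
}

# Weight matrix extended with a 5th row for ambiguous bases, scored with the
# column-average weight (draft assemblies contain Ns).
weights_with_ambig <- function(motif) {
  rbind(motif$weights, N = colMeans(motif$weights))
}

#' Score a single site with the Ri method
#'
#' `Ri = sum_l Riw(seq_l, l)` bits. Ambiguous bases (`N`) score with the
#' column-average weight.
#'
#' @param motif A `binding_motif`.
#' @param seq A W-mer.
#' @return Score in bits.
#' @export
score_site <- function(motif, seq) {
  if (nchar(seq) != motif$width) {
    stop(sprintf("site length %d does not match motif width %d",
                 nchar(seq), motif$width))
  }
  wm <- weights_with_ambig(motif)
  codes <- dna_to_int(seq)
  sum(wm[cbind(codes, seq_len(motif$width))])
}

scan_one_strand <- function(wm, codes, w) {
  m <- length(codes) - w + 1L
  if (m < 1) return(numeric(0))
  sc <- numeric(m)
  for (l in seq_len(w)) {
    sc <- sc + unname(wm[l, ])[codes[l:(l + m - 1L)]]
  }
  sc
}

#' Scan a sequence for motif occurrences
#'
#' Every position (optionally on both strands) scoring at least `threshold`
#' bits is reported, sorted by position. For a palindromic motif the plus and
#' minus strand scores coincide at every position and each physical site is
#' reported once, with the plus strand as representative.
#'
#' @param motif A `binding_motif`.
#' @param seq DNA sequence (may contain `N`).
#' @param threshold Minimum Ri score in bits (default 0: any
#'   positive-information site).
#' @param both_strands Scan the reverse strand as well.
#' @param contig_id,context Optional annotations carried into the hit table.
#' @return `data.frame` of class `site_hits` with columns `contig`,
#'   `position` (0-based start on the scanned sequence), `strand`,
#'   `sequence` (match orientation), `score`, `context`.
#' @export
scan_sequence <- function(motif, seq, threshold = 0, both_strands = TRUE,
                          contig_id = NA_character_, context = NA_character_) {
  w <- motif$width
  seq <- toupper(seq)
  codes <- dna_to_int(seq)
  wm <- weights_with_ambig(motif)
  # row l = motif position, column b = base code
  wmt <- t(wm)           # w x 5
  sc_plus <- scan_one_strand(wmt, codes, w)
  hits <- data.frame(position = integer(0), strand = character(0),
                     score = numeric(0))
  if (length(sc_plus) > 0) {
    keep <- which(sc_plus >= threshold)
    hits <- data.frame(position = keep - 1L, strand = rep("+", length(keep)),
                       score = sc_plus[keep])
  }
  if (both_strands && length(sc_plus) > 0) {
    # minus-strand window at position j is the reverse complement of the
    # plus-strand window: score it with the complemented, reversed weights.
    wmt_rc <- wmt[w:1, c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
    sc_minus <- scan_one_strand(wmt_rc, codes, w)
    keep <- which(sc_minus >= threshold)
    if (length(keep) > 0) {
      hits <- rbind(hits,
                    data.frame(position = keep - 1L,
                               strand = rep("-", length(keep)),
                               score = sc_minus[keep]))
    }
    if (motif$is_palindromic && nrow(hits) > 0) {
      dup <- hits$strand == "-" &
        hits$position %in% hits$position[hits$strand == "+"]
      hits <- hits[!dup, ]
    }
  }
  hits <- hits[order(hits$position, hits$strand), ]
  rownames(hits) <- NULL
  hits$sequence <- vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(seq, hits$position[i] + 1L, hits$position[i] + w)
    if (hits$strand[i] == "-") revcomp(s) else s
  }, character(1))
  out <- data.frame(contig = rep(contig_id, nrow(hits)),
                    position = hits$position, strand = hits$strand,
                    sequence = hits$sequence, score = hits$score,
                    context = rep(context, nrow(hits)),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_hits", "data.frame")
  out
}

#' In-silico saturation mutagenesis of a site
#'
#' For every position `l` and alternative base `b'`, computes
#' `delta(l, b') = Ri(site) - Ri(site with position l set to b')`, the score
#' penalty of a single-nucleotide substitution. Positions whose worst
#' substitution costs at most `tolerance_bits` are classified `tolerant`
#' (spacer/flank behaviour), the rest `essential` (the dyad arms).
#'
#' @param motif A `binding_motif`.
#' @param site A W-mer, typically the consensus.
#' @param tolerance_bits Classification threshold in bits (default 0:
#'   only exactly score-neutral positions are tolerant).
#' @return A list of class `saturation_scan` with `delta` (W x 3 matrix),
#'   `max_delta` per position, `classification`, and the site.
#' @export
saturation_scan <- function(motif, site, tolerance_bits = 0) {
  if (nchar(site) != motif$width) {
    stop(sprintf("site length %d does not match motif width %d",
                 nchar(site), motif$width))
  }
  site <- check_dna(site, "site")
  codes <- dna_to_int(site)
  w <- motif$width
  delta <- matrix(NA_real_, nrow = w, ncol = 3,
                  dimnames = list(NULL, paste0("alt", 1:3)))
  alts <- matrix("", nrow = w, ncol = 3)
  for (l in seq_len(w)) {
    alt <- setdiff(1:4, codes[l])
    delta[l, ] <- motif$weights[codes[l], l] - motif$weights[alt, l]
    alts[l, ] <- DNA_BASES[alt]
  }
  maxd <- apply(delta, 1, max)
  cls <- ifelse(maxd <= tolerance_bits + 1e-9, "tolerant", "essential")
  structure(list(site = site, delta = delta, alt_bases = alts,
                 max_delta = maxd, classification = cls,
                 tolerance_bits = tolerance_bits),
            class = "saturation_scan")
}

#' @export
print.saturation_scan <- function(x, ...) {
  cat(sprintf("Saturation scan of %s\n", x$site))
  df <- data.frame(position = seq_along(x$max_delta),
                   base = strsplit(x$site, "")[[1]],
                   max_delta_bits = round(x$max_delta, 3),
                   class = x$classification)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Length of the contiguous internal run of substitution-tolerant positions
#'
#' Counts the longest run of `tolerant` positions that does not touch either
#' end of the site: for a spaced-dyad motif with uninformative spacer columns
#' this is the spacer length.
#'
#' @param scan A [saturation_scan()] result.
#' @return Integer run length (0 if none).
#' @export
tolerant_spacer_length <- function(scan) {
  tol <- scan$classification == "tolerant"
  n <- length(tol)
  r <- rle(tol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  internal <- r$values & starts > 1 & ends < n
  if (!any(internal)) 0L else max(r$lengths[internal])
}

#' Expand balanced site sequences from an IUPAC consensus
#'
#' Degenerate positions cycle through their base set so that every base of
#' the set occurs equally often in every column (requires `n` divisible by
#' the set sizes); `N` columns come out exactly uniform, which is what makes
#' spacer positions carry zero information in the resulting motif.
#'
#' @param consensus IUPAC consensus (dashed form accepted).
#' @param n Number of sites (use a multiple of 4 for `N` columns).
#' @return Character vector of `n` concrete sites.
#' @export
consensus_sites <- function(consensus, n = 4L) {
  consensus <- expand_consensus(consensus)
  sets <- iupac_sets(consensus)
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_along(sets), function(l) {
      s <- sets[[l]]
      DNA_BASES[s[((i - 1 + l) %% length(s)) + 1]]
    }, character(1)), collapse = "")
  }, character(1))
}

#' Sample site sequences from a motif model
#'
#' Each position is drawn independently from the motif's column frequencies.
#'
#' @param motif A `binding_motif`.
#' @param n Number of sites.
#' @return Character vector of site sequences.
#' @export
sample_sites <- function(motif, n) {
  f <- motif$freq
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(motif$width), function(l) {
      sample(DNA_BASES, 1, prob = f[, l])
    }, character(1)), collapse = "")
  }, character(1))
}

#' Library of experimentally characterized LexA-binding motifs
#'
#' The dyad consensus patterns reported for the major bacterial groups,
#' with their repeat geometry (inverted repeat = palindromic dimer site,
#' direct repeat otherwise).
#'
#' @return `data.frame` with columns `name`, `pattern` (dashed consensus),
#'   `expanded` (plain IUPAC string), `geometry`.
#' @export
known_motif_library <- function() {
  df <- data.frame(
    name = c("firmicutes_actinobacteria", "gammaproteobacteria",
             "alphaproteobacteria", "verrucomicrobia"),
    pattern = c("GAAC-N4-GTTC", "CTGT-N8-ACAG",
                "GTTC-N7-GTTC", "TGTTC-N4-GAACA"),
    geometry = c("inverted", "inverted", "direct", "inverted"),
    stringsAsFactors = FALSE)
  df$expanded <- vapply(df$pattern, expand_consensus, character(1))
  df
}

#' Expand a dashed dyad consensus into a plain IUPAC string
#'
#' `"GAAC-N4-GTTC"` becomes `"GAACNNNNGTTC"`; already-plain strings are
#' validated and returned upper case.
#'
#' @param pattern Dashed or plain IUPAC consensus.
#' @return Plain IUPAC string.
#' @export
expand_consensus <- function(pattern) {
  pattern <- toupper(gsub("\\s", "", pattern))
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  out <- paste(vapply(parts, function(p) {
    if (grepl("^N[0-9]+$", p)) {
      strrep("N", as.integer(sub("^N", "", p)))
    } else p
  }, character(1)), collapse = "")
  if (grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                   collapse = "")), out)) {
    stop("invalid IUPAC consensus: ", pattern)
  }
  out
}

# Base sets (integer codes) for each position of an IUPAC string.
iupac_sets <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(strsplit(pattern, "")[[1]], function(ch) {
    which(DNA_BASES %in% strsplit(map[[ch]], "")[[1]])
  })
}

#' Read aligned binding sites from FASTA or a plain site list
#'
#' FASTA input (detected by a leading `>`) is read with Biostrings; otherwise
#' one site per line is expected (CollecTF-style export).
#'
#' @param path Input file.
#' @return Character vector of site sequences.
#' @export
read_sites <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    toupper(as.character(Biostrings::readDNAStringSet(path)))
  } else {
    x <- trimws(readLines(path))
    toupper(x[nzchar(x)])
  }
}

#' Export scan hits as BED6
#'
#' 0-based half-open intervals; the BED score column is the Ri score in
#' centibits (bits x 100, rounded).
#'
#' @param hits A `site_hits` table from [scan_sequence()].
#' @param path Output path.
#' @param width Motif width (taken from the hit sequences if omitted).
#' @export
write_hits_bed <- function(hits, path, width = NULL) {
  if (is.null(width)) width <- nchar(hits$sequence[1])
  bed <- data.frame(chrom = hits$contig,
                    start = hits$position,
                    end = hits$position + width,
                    name = ifelse(is.na(hits$context), ".", hits$context),
                    score = round(hits$score * 100),
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a motif in MEME minimal format
#'
#' Emits the version line, alphabet, background frequencies and the
#' letter-probability matrix, for interoperability with motif tools.
#'
#' @param motif A `binding_motif`.
#' @param path Output path.
#' @param name Motif name used in the `MOTIF` line.
#' @export
write_meme_minimal <- function(motif, path, name = motif$consensus) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       motif$background[1], motif$background[2],
                       motif$background[3], motif$background[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
                       motif$width,
                       ifelse(is.na(motif$nsites), "20", motif$nsites))),
             con)
  for (l in seq_len(motif$width)) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f", motif$freq[1, l],
                       motif$freq[2, l], motif$freq[3, l], motif$freq[4, l]),
               con)
  }
  invisible(path)
}

#' Write a motif count matrix as TSV
#'
#' @param motif A `binding_motif`.
#' @param path Output path.
#' @export
write_motif_tsv <- function(motif, path) {
  m <- if (is.null(motif$counts)) motif$freq else motif$counts
  df <- data.frame(position = seq_len(motif$width), t(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
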