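# Tandem binding-site arrangements and the junction motifs they generate.
#
# Two closely spaced sites for a dyad-binding repressor create, across their
# junction, new arm arrangements that can constitute an instance of a
# different known dyad motif -- the combinatorial core of the tandem-site
# model for binding-motif evolution. Only same-orientation pairs are
# considered: the arrangements of interest are head-to-tail repeats of a
# palindromic motif, for which orientation is representational.

#' Detect tandem site arrangements among scan hits of one promoter
#'
#' All ordered same-orientation hit pairs with an inter-site gap in
#' `[0, max_gap]` and a secondary (downstream) site scoring at least
#' `min_secondary_score` are reported, sorted by gap. The secondary threshold
#' is deliberately permissive: tandem arrangements frequently pair a
#' conserved site with a degenerate one.
#'
#' @param hits A `site_hits` table from [scan_sequence()] with positions on
#'   one promoter sequence.
#' @param promoter_seq The promoter sequence the hits refer to (supplies the
#'   inter-site gap bases of the junction).
#' @param max_gap Maximum inter-site gap in bp (tandem repressor sites are
#'   typically 1-10 bp apart).
#' @param min_secondary_score Minimum Ri score of the downstream site.
#' @return `data.frame` of class `tandem_arrangements` with columns
#'   `site1_pos`, `site2_pos`, `gap`, `strand`, `score1`, `score2`,
#'   `junction` (sequence spanning both sites, length `2W + gap`).
#' @export
find_tandem_sites <- function(hits, promoter_seq, max_gap = 10L,
                              min_secondary_score = -Inf) {
  w <- if (nrow(hits) > 0) nchar(hits$sequence[1]) else 0L
  out <- data.frame(site1_pos = integer(0), site2_pos = integer(0),
                    gap = integer(0), strand = character(0),
                    score1 = numeric(0), score2 = numeric(0),
                    junction = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) >= 2) {
    hits <- hits[order(hits$position), ]
    for (i in seq_len(nrow(hits) - 1)) {
      for (j in seq(i + 1, nrow(hits))) {
        if (hits$strand[i] != hits$strand[j]) next
        gap <- hits$position[j] - (hits$position[i] + w)
        if (gap < 0 || gap > max_gap) next
        if (hits$score[j] < min_secondary_score) next
        junction <- substr(promoter_seq, hits$position[i] + 1L,
                           hits$position[j] + w)
        out <- rbind(out, data.frame(
          site1_pos = hits$position[i], site2_pos = hits$position[j],
          gap = gap, strand = hits$strand[i],
          score1 = hits$score[i], score2 = hits$score[j],
          junction = junction, stringsAsFactors = FALSE))
      }
    }
    out <- out[order(out$gap, out$site1_pos), ]
    rownames(out) <- NULL
  }
  class(out) <- c("tandem_arrangements", "data.frame")
  out
}

# IUPAC bitmasks (A=1, C=2, G=4, T=8) for guaranteed-match semantics.
iupac_masks <- function(pattern) {
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(unique(chars), names(map))
  if (length(bad) > 0) stop("invalid IUPAC character(s): ",
                            paste(bad, collapse = ", "))
  vapply(chars, function(ch) {
    sum(bit[strsplit(map[[ch]], "")[[1]]])
  }, integer(1), USE.NAMES = FALSE)
}

revcomp_iupac <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

# Guaranteed IUPAC match: every realization of the (possibly degenerate)
# subject char is covered by the pattern char, i.e. subject set is a subset
# of the pattern set. On a concrete subject this is ordinary IUPAC matching.
iupac_find <- function(subject, pattern) {
  sm <- iupac_masks(subject)
  pm <- iupac_masks(pattern)
  n <- length(sm) - length(pm) + 1L
  if (n < 1) return(integer(0))
  which(vapply(seq_len(n), function(o) {
    all(bitwAnd(sm[o:(o + length(pm) - 1L)], bitwNot(pm)) == 0L)
  }, logical(1))) - 1L
}

#' Emergent motif instances within a tandem-site junction
#'
#' Tests every offset of the junction, on both strands, against every pattern
#' of a known-motif library. Matching uses guaranteed-instance semantics: a
#' degenerate junction position (e.g. an `N` spacer base of a consensus)
#' only matches a pattern position that covers all its realizations, so a
#' reported instance is guaranteed by the conserved site positions alone.
#'
#' @param arrangement One row of a `tandem_arrangements` table, or a plain
#'   junction string.
#' @param library A motif library as returned by [known_motif_library()].
#' @return `data.frame` with columns `name`, `offset` (0-based within the
#'   junction), `strand`, `matched`.
#' @export
junction_instances <- function(arrangement, library = known_motif_library()) {
  junction <- if (is.character(arrangement)) arrangement else
    arrangement$junction
  junction <- toupper(junction[1])
  out <- data.frame(name = character(0), offset = integer(0),
                    strand = character(0), matched = character(0),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(library))) {
    pat <- library$expanded[r]
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp_iupac(pat)
      offs <- iupac_find(junction, p)
      if (length(offs) > 0) {
        out <- rbind(out, data.frame(
          name = library$name[r], offset = offs, strand = strand,
          matched = substring(junction, offs + 1L, offs + nchar(p)),
          stringsAsFactors = FALSE))
      }
    }
  }
  # a self-palindromic pattern matches identically on both strands; report once
  out <- out[!duplicated(out[, c("name", "offset", "matched")]), ]
  rownames(out) <- NULL
  out
}

#' Gaps at which a tandem consensus pair generates an emergent motif
#'
#' For each candidate gap `g`, builds the junction of two copies of the site
#' consensus separated by `g` unspecified bases and reports the gaps at which
#' at least one guaranteed instance of `emergent_pattern` appears. For the
#' canonical arms (an inverted `GAACA`/`TGTTC` dyad followed by its repeat),
#' the emergent spacer is `k = g + 2`: the instance spans the last four bases
#' of the upstream site's downstream arm (`GAAC`), the arm's trailing base
#' plus the `g` gap bases plus the leading base of the downstream site
#' (spacer `g + 2`), and four bases of the downstream site's upstream arm
#' (`GTTC`).
#'
#' @param site_consensus IUPAC consensus of the tandem-repeated site
#'   (dashed form accepted, e.g. `"TGTTC-N4-GAACA"`).
#' @param emergent_pattern IUPAC pattern to search for (e.g.
#'   `"GAAC-N4-GTTC"`).
#' @param gaps Integer vector of gaps to test.
#' @return Integer vector: the gaps yielding at least one instance.
#' @export
emergence_spacing <- function(site_consensus, emergent_pattern, gaps = 0:10) {
  site <- expand_consensus(site_consensus)
  pat <- expand_consensus(emergent_pattern)
  lib <- data.frame(name = "emergent", pattern = emergent_pattern,
                    geometry = NA_character_, expanded = pat,
                    stringsAsFactors = FALSE)
  hit <- vapply(gaps, function(g) {
    junction <- paste0(site, strrep("N", g), site)
    nrow(junction_instances(junction, lib)) > 0
  }, logical(1))
  as.integer(gaps[hit])
}

#' Tandem-arrangement report over a set of promoters
#'
#' Convenience wrapper: scans each promoter, detects tandem arrangements and
#' annotates them with emergent junction motifs.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param motif A `binding_motif` used for scanning.
#' @param threshold Scan threshold (bits) for candidate sites.
#' @param max_gap,min_secondary_score Passed to [find_tandem_sites()].
#' @param library Known-motif library for junction annotation.
#' @return `data.frame` with one row per arrangement: `promoter_id`,
#'   `site1_pos`, `site2_pos`, `gap`, `emergent_motifs` (comma-separated).
#' @export
tandem_report <- function(promoters, motif, threshold = 0, max_gap = 10L,
                          min_secondary_score = -Inf,
                          library = known_motif_library()) {
  rows <- lapply(names(promoters), function(id) {
    hits <- scan_sequence(motif, promoters[[id]], threshold = threshold)
    tand <- find_tandem_sites(hits, promoters[[id]], max_gap,
                              min_secondary_score)
    if (nrow(tand) == 0) return(NULL)
    tand$promoter_id <- id
    tand$emergent_motifs <- vapply(seq_len(nrow(tand)), function(i) {
      ji <- junction_instances(tand$junction[i], library)
      paste(unique(ji$name), collapse = ",")
    }, character(1))
    tand[, c("promoter_id", "site1_pos", "site2_pos", "gap",
             "emergent_motifs")]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(promoter_id = character(0), site1_pos = integer(0),
                      site2_pos = integer(0), gap = integer(0),
                      emergent_motifs = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
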