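# Motif model: count/frequency/weight matrices, Ri scoring, scanning and
# saturation mutagenesis.

test_that("frequencies and weights follow the pseudocount formulas", {
  m <- build_motif(rep("TGTTC", 4), pseudocount = 1,
                   background = rep(0.25, 4))
  # f(cons) = (4 + 1*0.25) / (4 + 1) = 0.85; Riw = 2 + log2(0.85)
  expect_equal(unname(m$freq["T", 1]), 0.85)
  expect_equal(unname(m$weights["T", 1]), 2 + log2(0.85))
  expect_equal(colSums(m$freq), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$nsites, 4)
  expect_equal(m$consensus, "TGTTC")
})

test_that("a uniform column scores zero for every base", {
  m <- build_motif(c("ATTT", "CTTT", "GTTT", "TTTT"), pseudocount = 0.4)
  expect_equal(unname(m$freq[, 1]), rep(0.25, 4))
  expect_equal(unname(m$weights[, 1]), rep(0, 4))
})

test_that("palindromy is detected from the count matrix", {
  m <- build_motif(consensus_sites("TGTTC-N4-GAACA", 8))
  expect_true(m$is_palindromic)
  expect_equal(m$consensus, "TGTTCNNNNGAACA")
  m2 <- build_motif(rep("TGTTC", 4))
  expect_false(m2$is_palindromic)
})

test_that("site validation rejects malformed input", {
  expect_error(build_motif(c("ACGT", "ACG")), "same length")
  expect_error(build_motif(c("ACGT", "ACGU")), "non-ACGT")
  m <- build_motif(rep("TGTTC", 4))
  expect_error(score_site(m, "TGTT"), "width")
  expect_error(saturation_scan(m, "TG"), "width")
})

test_that("Ri scores sum per-position weights and peak at the consensus", {
  m <- build_motif(rep("TGTTC", 4), pseudocount = 1)
  expect_equal(score_site(m, "TGTTC"), 5 * (2 + log2(0.85)))
  expect_equal(score_site(m, "TGTTC"), max_score(m))
  # every single-substitution variant scores no higher than the consensus
  for (l in 1:5) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr("TGTTC", l, l))) {
      v <- "TGTTC"
      substr(v, l, l) <- b
      expect_lte(score_site(m, v), score_site(m, "TGTTC"))
    }
  }
  # uniform motif: everything scores 0
  mu <- build_motif(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  expect_equal(score_site(mu, "ACGT"), 0)
})

test_that("ambiguous bases score with the column-average weight", {
  m <- build_motif(rep("TGTTC", 4), pseudocount = 1)
  expect_equal(score_site(m, "NGTTC"),
               mean(m$weights[, 1]) + sum(m$weights[cbind(c(3, 4, 4, 2), 2:5)]))
})

test_that("palindromic motifs score a site and its reverse complement equally", {
  m <- build_motif(consensus_sites("TGTTC-N4-GAACA", 8))
  set.seed(11)
  for (s in random_dna(20, 14)) {
    expect_equal(score_site(m, s),
                 score_site(m, as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s)))))
  }
})

test_that("adding a consensus site never decreases the consensus score", {
  sites <- c("TGTTC", "TGATC", "TGTCC", "AGTTC")
  m1 <- build_motif(sites)
  m2 <- build_motif(c(sites, "TGTTC"))
  expect_gte(score_site(m2, "TGTTC"), score_site(m1, "TGTTC"))
})

test_that("scanning finds an embedded consensus and honours the threshold", {
  set.seed(7)
  m <- motif_from_consensus("TGTTC-N4-GAACA", 1.9)
  seq <- random_dna(1, 120, 0.5)
  substr(seq, 38, 51) <- "TGTTCAGTCGAACA"  # 0-based position 37
  hits <- scan_sequence(m, seq, threshold = 0.9 * max_score(m))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 37L)
  expect_equal(nrow(scan_sequence(m, seq, threshold = max_score(m) + 1)), 0)
  # hit score equals independent rescoring of the reported sequence
  expect_equal(hits$score, score_site(m, hits$sequence))
})

test_that("scanning a reverse-complemented sequence mirrors palindromic hits", {
  set.seed(8)
  m <- motif_from_consensus("TGTTC-N4-GAACA", 1.9)
  seq <- random_dna(1, 100)
  substr(seq, 21, 34) <- "TGTTCGGGGGAACA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_sequence(m, seq, threshold = 0.8 * max_score(m))
  h2 <- scan_sequence(m, rc, threshold = 0.8 * max_score(m))
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(nchar(seq) - 14 - h1$position), sort(h2$position))
  expect_equal(sort(h1$score), sort(h2$score))
})

test_that("scan_sequence equals the exhaustive rescoring oracle", {
  set.seed(9)
  for (rep in 1:100) {
    w <- sample(4:8, 1)
    m <- build_motif(random_dna(sample(3:6, 1), w),
                     pseudocount = runif(1, 0.3, 2))
    seq <- random_dna(1, sample(30:60, 1))
    thr <- runif(1, -3, 3)
    got <- scan_sequence(m, seq, threshold = thr)
    want <- bf_scan(m, seq, thr)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("saturation scan separates essential arms from the tolerant spacer", {
  m <- build_motif(consensus_sites("TGTTC-N4-GAACA", 8), pseudocount = 1)
  sc <- saturation_scan(m, "TGTTCACGTGAACA")
  expect_equal(sc$classification,
               c(rep("essential", 5), rep("tolerant", 4), rep("essential", 5)))
  expect_equal(tolerant_spacer_length(sc), 4L)
  expect_equal(unname(sc$delta[6, ]), rep(0, 3))   # spacer: no score change
  # substituting away from the consensus never raises the score
  expect_true(all(sc$delta >= -1e-9))
})

test_that("arm substitution penalties follow the weight difference", {
  m <- build_motif(rep("TGTTC", 4), pseudocount = 1)
  sc <- saturation_scan(m, "TGTTC")
  want <- (2 + log2(0.85)) - (2 + log2(0.05))
  expect_equal(unname(sc$delta[1, ]), rep(want, 3))
  expect_equal(want, 4.0874628, tolerance = 1e-6)
})

test_that("consensus expansion and the known-motif library parse correctly", {
  expect_equal(expand_consensus("GAAC-N4-GTTC"), "GAACNNNNGTTC")
  expect_equal(expand_consensus("tgttcnnnngaaca"), "TGTTCNNNNGAACA")
  expect_error(expand_consensus("GA-N2-XX"), "IUPAC")
  lib <- known_motif_library()
  expect_setequal(lib$geometry, c("inverted", "direct"))
  expect_equal(lib$expanded[lib$name == "verrucomicrobia"], "TGTTCNNNNGAACA")
  expect_equal(lib$geometry[lib$name == "alphaproteobacteria"], "direct")
})

test_that("motif_from_consensus hits the requested information content", {
  m <- motif_from_consensus("TGTTC-N4-GAACA", 1.8)
  ic <- information_content(m)
  expect_equal(unname(ic[1:5]), rep(1.8, 5), tolerance = 1e-6)
  expect_equal(unname(ic[6:9]), rep(0, 4), tolerance = 1e-9)
  expect_true(m$is_palindromic)
})

test_that("site and motif I/O round-trips", {
  dir <- withr::local_tempdir()
  sites <- consensus_sites("TGTTC-N4-GAACA", 4)
  writeLines(sites, file.path(dir, "sites.txt"))
  expect_equal(read_sites(file.path(dir, "sites.txt")), sites)
  dna <- Biostrings::DNAStringSet(sites)
  names(dna) <- paste0("s", 1:4)
  Biostrings::writeXStringSet(dna, file.path(dir, "sites.fasta"))
  expect_equal(read_sites(file.path(dir, "sites.fasta")), sites,
               ignore_attr = TRUE)
  m <- build_motif(sites)
  write_meme_minimal(m, file.path(dir, "motif.meme"))
  txt <- readLines(file.path(dir, "motif.meme"))
  expect_true(any(grepl("^MEME version", txt)))
  expect_equal(sum(grepl("^ [0-9]", txt)), m$width)
  hits <- scan_sequence(m, paste(sites, collapse = ""), threshold = 0,
                        contig_id = "c1")
  write_hits_bed(hits, file.path(dir, "hits.bed"))
  bed <- read.delim(file.path(dir, "hits.bed"), header = FALSE)
  expect_equal(nrow(bed), nrow(hits))
  expect_equal(bed$V2, hits$position)
  expect_equal(bed$V5, round(hits$score * 100))
})
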