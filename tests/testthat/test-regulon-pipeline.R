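# Operon prediction, promoter search, revision and the regulon matrix.

test_that("the mean-distance rule reproduces the worked operon example", {
  # distances 50 and 20, mean 35: gap 50 >= 35 splits, strand switch splits
  g <- make_genome(data.frame(gene_id = c("a", "b", "c"),
                              start = c(0L, 150L, 320L),
                              end = c(100L, 300L, 500L),
                              strand = c("+", "+", "-")), random_dna(1, 600))
  ops <- predict_operons(g)
  expect_equal(length(ops), 3)
  expect_equal(attr(ops, "mean_igd"), 35)
})

test_that("overlapping same-strand genes merge; strand switches always split", {
  g <- make_genome(data.frame(gene_id = c("a", "b", "c"),
                              start = c(0L, 90L, 210L),
                              end = c(100L, 200L, 300L),
                              strand = c("+", "+", "-")), random_dna(1, 400))
  # distances: -10 and 10; mean 0: -10 < 0 merges a+b; c splits on strand
  ops <- predict_operons(g)
  expect_equal(length(ops), 2)
  expect_equal(ops[[1]]$genes, c("a", "b"))

  g2 <- make_genome(data.frame(gene_id = c("a", "b"),
                               start = c(0L, 100L), end = c(100L, 200L),
                               strand = c("+", "-")), random_dna(1, 300))
  expect_equal(length(predict_operons(g2)), 2)
})

test_that("operon prediction equals the brute-force oracle on random genomes", {
  set.seed(13)
  for (rep in 1:100) {
    g <- random_toy_genome(n_genes = sample(3:12, 1))
    got <- lapply(predict_operons(g), `[[`, "genes")
    want <- bf_operons(g)
    expect_equal(length(got), length(want))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("minus-strand operons lead with their rightmost gene", {
  g <- make_genome(data.frame(gene_id = c("a", "b", "far"),
                              start = c(0L, 110L, 700L),
                              end = c(100L, 200L, 800L),
                              strand = c("-", "-", "+")), random_dna(1, 1000))
  ops <- predict_operons(g)  # mean distance (10+500)/2 = 255: a+b merge
  expect_equal(length(ops), 2)
  expect_equal(ops[[1]]$genes, c("a", "b"))
  expect_equal(ops[[1]]$lead, "b")
})

planted_single_gene_genome <- function(site, rel, strand = "+",
                                       contig_len = 2000, seed = 17) {
  regulonscout:::with_seed(seed, {
    contig <- random_dna(1, contig_len)
    start <- 1000L; end <- 1300L
    tls <- if (strand == "+") start else end - 1L
    w <- nchar(site)
    if (strand == "+") {
      substr(contig, tls + rel + 1L, tls + rel + w) <- site
    } else {
      gs <- tls - rel - w + 1L
      substr(contig, gs + 1L, gs + w) <-
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
    }
    make_genome(data.frame(gene_id = "lead", start = start, end = end,
                           strand = strand), contig)
  })
}

test_that("a consensus site planted at -80 is found at the maximum score", {
  motif <- motif_from_consensus("TGTTC-N4-GAACA", 2)
  for (strand in c("+", "-")) {
    g <- planted_single_gene_genome("TGTTCACGTGAACA", -80L, strand)
    ops <- search_operon_promoters(g, predict_operons(g), motif)
    hit <- ops[[1]]$best_hit
    expect_equal(hit$score, max_score(motif), tolerance = 1e-9)
    expect_equal(hit$position_rel, -80L)
  }
})

test_that("a fully clamped promoter window yields no best hit", {
  g <- make_genome(data.frame(gene_id = "edge", start = 0L, end = 300L,
                              strand = "+"), random_dna(1, 400))
  motif <- motif_from_consensus("TGTTC-N4-GAACA", 2)
  ops <- search_operon_promoters(g, predict_operons(g), motif,
                                 upstream = 250, downstream = 0)
  expect_null(ops[[1]]$best_hit)
})

# three same-strand genes close enough to form one operon (a distant filler
# gene keeps the genome mean intergenic distance above the 20 bp gaps), with
# optional consensus sites planted upstream of chosen members
operon_fixture <- function(sites_before = character(0), strand = "+",
                           seed = 19) {
  regulonscout:::with_seed(seed, {
    glen <- 400L; gap <- 20L
    starts <- 500L + (0:2) * (glen + gap)
    contig <- random_dna(1, 3000)
    genes <- data.frame(gene_id = c("gA", "gB", "gC"), start = starts,
                        end = starts + glen, strand = strand)
    if (strand == "-") {
      genes$gene_id <- c("gC", "gB", "gA")  # reading order right-to-left
    }
    genes <- rbind(genes,
                   data.frame(gene_id = "gZ", start = 2320L, end = 2500L,
                              strand = if (strand == "+") "-" else "+"))
    g <- make_genome(genes, contig)
    for (gene in sites_before) {
      row <- g$genes[g$genes$gene_id == gene, ]
      tls <- gene_tls(row)
      site <- "TGTTCACGTGAACA"
      if (strand == "+") {
        substr(g$contigs[["c1"]], tls - 80 + 1L, tls - 80 + 14L) <- site
      } else {
        gs <- tls + 80 - 14 + 1L
        substr(g$contigs[["c1"]], gs + 1L, gs + 14L) <-
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
      }
    }
    g
  })
}

test_that("revision splits before internal genes with high-scoring sites", {
  motif <- motif_from_consensus("TGTTC-N4-GAACA", 2)
  g <- operon_fixture("gB")
  ops <- predict_operons(g)
  expect_equal(length(ops), 2)   # [gA,gB,gC] plus the filler
  before <- search_operon_promoters(g, ops, motif)
  # before revision the operon's best hit still comes from the lead window,
  # which does not contain the planted site
  bh <- before[[1]]$best_hit
  expect_true(is.null(bh) || bh$score < 0.75 * max_score(motif))
  rev1 <- revise_operons(g, ops, motif)
  gene_sets <- lapply(rev1, `[[`, "genes")
  expect_true(any(vapply(gene_sets, identical, TRUE, "gA")))
  expect_true(any(vapply(gene_sets, identical, TRUE, c("gB", "gC"))))
  split_op <- rev1[[which(vapply(gene_sets, identical, TRUE, c("gB", "gC")))]]
  expect_equal(split_op$lead, "gB")
  expect_equal(split_op$best_hit$score, max_score(motif), tolerance = 1e-9)
})

test_that("a high-scoring site before the lead gene does not split", {
  motif <- motif_from_consensus("TGTTC-N4-GAACA", 2)
  g <- operon_fixture("gA")
  rev1 <- revise_operons(g, predict_operons(g), motif)
  expect_equal(length(rev1), 2)  # [gA,gB,gC] intact plus the filler
  expect_true(any(vapply(lapply(rev1, `[[`, "genes"), function(x)
    identical(sort(x), c("gA", "gB", "gC")), TRUE)))
})

test_that("revision reaches a fixpoint and is idempotent", {
  motif <- motif_from_consensus("TGTTC-N4-GAACA", 2)
  for (strand in c("+", "-")) {
    g <- operon_fixture(c("gB", "gC"), strand = strand)
    rev1 <- revise_operons(g, predict_operons(g), motif)
    expect_equal(length(rev1), 4)  # three singleton-led operons + filler
    expect_setequal(vapply(rev1, `[[`, "", "lead"), c("gA", "gB", "gC", "gZ"))
    rev2 <- revise_operons(g, rev1, motif)
    expect_equal(lapply(rev2, `[[`, "genes"), lapply(rev1, `[[`, "genes"))
  }
})

test_that("genes are conserved across prediction and revision", {
  motif <- motif_from_consensus("TGTTC-N4-GAACA", 1.8)
  cm <- generate_community(community_config(seed = 23, genes_per_genome = 25))
  for (sp in names(cm$genomes)) {
    g <- cm$genomes[[sp]]
    ops <- predict_operons(g)
    expect_setequal(unlist(lapply(ops, `[[`, "genes")), g$genes$gene_id)
    rev1 <- revise_operons(g, ops, motif)
    expect_setequal(unlist(lapply(rev1, `[[`, "genes")), g$genes$gene_id)
  }
})

test_that("the regulon matrix flags lost orthologs as absent and normalizes", {
  cfg <- community_config(n_species = 3, genes_per_genome = 15, seed = 29,
                          bits_per_column = 2)
  cm <- generate_community(cfg)
  # delete the recA ortholog from sp02
  g2 <- cm$genomes$sp02
  keep <- g2$genes$gene_id != "sp02_recA"
  cm$genomes$sp02 <- annotated_genome("sp02", g2$contigs, g2$genes[keep, ])
  rm <- build_regulon_matrix(cm$genomes, "sp01", cfg$motif, "sp01_lexA")
  expect_true(is.na(rm$raw["sp01_recA", "sp02"]))
  expect_false(anyNA(rm$raw[, "sp01"]))
  # normalization: unique max exactly 1, unique min exactly 0
  expect_equal(max(rm$norm, na.rm = TRUE), 1)
  expect_equal(min(rm$norm, na.rm = TRUE), 0)
  expect_equal(dim(rm$raw), dim(rm$norm))
  # species columns follow the TF tree leaf order
  expect_setequal(colnames(rm$raw), c("sp01", "sp02", "sp03"))
  expect_equal(colnames(rm$raw), tree_leaf_order(rm$tree))
})

test_that("core regulon rows score near the analysis maximum in all species", {
  cfg <- community_config(n_species = 3, seed = 31, bits_per_column = 2)
  cm <- generate_community(cfg)
  rm <- build_regulon_matrix(cm$genomes, "sp01", cfg$motif, "sp01_lexA")
  core <- paste0("sp01_", c("lexA", "recA", "imuA", "imuB", "dnaE2"))
  expect_false(anyNA(rm$norm[core, ]))
  expect_true(all(rm$norm[core, ] >= 0.9))
})

test_that("a species without the TF is excluded from tree and matrix", {
  cfg <- community_config(n_species = 3, genes_per_genome = 12, seed = 37)
  cm <- generate_community(cfg)
  g3 <- cm$genomes$sp03
  keep <- g3$genes$gene_id != "sp03_lexA"
  cm$genomes$sp03 <- annotated_genome("sp03", g3$contigs, g3$genes[keep, ])
  rm <- build_regulon_matrix(cm$genomes, "sp01", cfg$motif, "sp01_lexA")
  expect_equal(rm$excluded, "sp03")
  expect_false("sp03" %in% colnames(rm$raw))
  expect_error(build_regulon_matrix(cm$genomes, "sp01", cfg$motif, "nope"),
               "TF gene")
})

test_that("the regulon matrix serializes to TSV and newick", {
  cfg <- community_config(n_species = 2, genes_per_genome = 10, seed = 41)
  cm <- generate_community(cfg)
  rm <- build_regulon_matrix(cm$genomes, "sp01", cfg$motif, "sp01_lexA")
  dir <- withr::local_tempdir()
  write_regulon_matrix(rm, file.path(dir, "m.tsv"), file.path(dir, "t.nwk"))
  back <- read.delim(file.path(dir, "m.tsv"), check.names = FALSE)
  expect_equal(nrow(back), nrow(rm$norm))
  expect_s3_class(ape::read.tree(file.path(dir, "t.nwk")), "phylo")
})
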