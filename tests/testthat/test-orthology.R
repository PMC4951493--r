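# Protein comparison, reciprocal best hits, ortholog groups and the
# distance-based TF tree.

test_that("self-alignment gives 100% identity and a vanishing expect value", {
  set.seed(1)
  p <- random_aa(100)
  al <- align_pair(p, p)
  expect_equal(al$identity, 100)
  expect_lt(al$evalue, 1e-20)
  expect_equal(al$align_length, 100L)
})

test_that("alignment input is validated", {
  expect_error(align_pair("", "MKV"), "empty")
  expect_error(align_pair("MKV", "MKB"), "non-canonical")
})

test_that("alignment scores match a brute-force dynamic-programming oracle", {
  set.seed(2)
  for (rep in 1:50) {
    a <- random_aa(sample(8:30, 1))
    b <- random_aa(sample(8:30, 1))
    expect_equal(align_pair(a, b)$score, bf_sw_score(a, b))
  }
})

test_that("unrelated proteins rarely pass the ortholog expect threshold", {
  set.seed(3)
  above <- 0
  for (rep in 1:100) {
    e <- align_pair(random_aa(100), random_aa(100))$evalue
    above <- above + (e > 1e-20)
  }
  expect_gte(above, 95)
})

two_genomes <- function(prots_a, prots_b) {
  mk <- function(id, prots) {
    n <- length(prots)
    annotated_genome(id, c(c1 = random_dna(1, 100 * n + 200)),
                     data.frame(gene_id = names(prots), contig_id = "c1",
                                start = seq(0, by = 100, length.out = n),
                                end = seq(50, by = 100, length.out = n),
                                strand = "+", protein = unname(prots)))
  }
  list(a = mk("A", prots_a), b = mk("B", prots_b))
}

test_that("identical proteomes yield one reciprocal pair per protein", {
  set.seed(4)
  prots <- setNames(vapply(1:5, function(i) random_aa(120), ""), paste0("p", 1:5))
  g <- two_genomes(prots, setNames(prots, paste0("q", 1:5)))
  rbh <- reciprocal_best_hits(g$a, g$b)
  expect_equal(nrow(rbh), 5)
  expect_equal(rbh$gene_b[match(paste0("p", 1:5), rbh$gene_a)],
               paste0("q", 1:5))
})

test_that("a replaced protein loses its pair; the rest stay intact", {
  set.seed(5)
  prots <- setNames(vapply(1:5, function(i) random_aa(120), ""), paste0("p", 1:5))
  prots_b <- setNames(prots, paste0("q", 1:5))
  prots_b[3] <- random_aa(120)
  g <- two_genomes(prots, prots_b)
  rbh <- reciprocal_best_hits(g$a, g$b)
  expect_false("p3" %in% rbh$gene_a)
  expect_equal(nrow(rbh), 4)
})

test_that("ties on the best score are conservatively dropped", {
  set.seed(6)
  prots <- setNames(vapply(1:3, function(i) random_aa(120), ""), paste0("p", 1:3))
  prots_b <- setNames(c(prots, prots[1]), c(paste0("q", 1:3), "q1dup"))
  g <- two_genomes(prots, prots_b)
  rbh <- reciprocal_best_hits(g$a, g$b)
  expect_false("p1" %in% rbh$gene_a)   # duplicated identical partner: tie
  expect_setequal(rbh$gene_a, c("p2", "p3"))
})

test_that("reciprocal best hits are symmetric", {
  cm <- generate_community(community_config(n_species = 2,
                                            genes_per_genome = 12, seed = 77))
  ab <- reciprocal_best_hits(cm$genomes$sp01, cm$genomes$sp02)
  ba <- reciprocal_best_hits(cm$genomes$sp02, cm$genomes$sp01)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$gene_a, ab$gene_b), paste(ba$gene_b, ba$gene_a))
})

test_that("ortholog groups are reference-anchored with at most one member per species", {
  set.seed(8)
  mk <- function(id, prots) {
    n <- length(prots)
    annotated_genome(id, c(c1 = random_dna(1, 100 * n + 200)),
                     data.frame(gene_id = names(prots), contig_id = "c1",
                                start = seq(0, by = 100, length.out = n),
                                end = seq(50, by = 100, length.out = n),
                                strand = "+", protein = unname(prots)))
  }
  fam <- vapply(1:4, function(i) random_aa(130), "")
  genomes <- list(
    A = mk("A", setNames(fam, paste0("p", 1:4))),
    B = mk("B", setNames(fam, paste0("b", 1:4))),
    C = mk("C", setNames(c(fam[c(1, 3, 4)], random_aa(130)),
                         c("c1g", "c3g", "c4g", "cx"))))
  groups <- build_ortholog_groups(genomes, "A")
  expect_s3_class(groups, "ortholog_groups")
  expect_error(build_ortholog_groups(genomes, "Z"), "reference")
  tab <- table(groups$group_id, groups$species)
  expect_true(all(tab <= 1))
  # species C lost family 2: recorded as absent from that group
  expect_false("C" %in% groups$species[groups$group_id == "p2"])
  # the reference-less paralog appears in no group
  expect_false("cx" %in% groups$gene_id)
  # complete families carry all three species
  expect_equal(sum(groups$group_id == "p1"), 3)
  expect_equal(groups$gene_id[groups$group_id == "p3" & groups$species == "C"],
               "c3g")
})

test_that("identical sequences get zero-length pendant edges", {
  set.seed(9)
  p <- random_aa(150)
  q <- random_aa(150)
  nw <- tf_distance_tree(c(x = p, y = p, z = q))
  tr <- ape::read.tree(text = nw)
  pend <- tr$edge.length[match(match(c("x", "y"), tr$tip.label),
                               tr$edge[, 2])]
  expect_equal(pend, c(0, 0))
  zlen <- tr$edge.length[match(match("z", tr$tip.label), tr$edge[, 2])]
  expect_gt(zlen, 0)
})

test_that("a two-species tree splits the distance across both branches", {
  set.seed(10)
  p <- random_aa(150)
  q <- evolve_protein(p, 0.2)
  id <- align_pair(p, q)$identity
  nw <- tf_distance_tree(c(a = p, b = q))
  tr <- ape::read.tree(text = nw)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(sum(tr$edge.length), 1 - id / 100, tolerance = 1e-9)
})

test_that("neighbor joining recovers additive four-taxon topologies", {
  set.seed(11)
  for (rep in 1:100) {
    # additive distances from a random ((A,B),(C,D)) tree with positive
    # internal branch
    e <- runif(5, 0.05, 0.5)   # pendant a,b,c,d + internal
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d["a", "b"] <- d["b", "a"] <- e[1] + e[2]
    d["c", "d"] <- d["d", "c"] <- e[3] + e[4]
    for (i in c("a", "b")) for (j in c("c", "d")) {
      d[i, j] <- d[j, i] <- e[match(i, letters)] + e[match(j, letters)] + e[5]
    }
    tr <- ape::read.tree(text = regulonscout:::nj_newick(d))
    # neighbor joining is exact on additive distances: the patristic
    # distances must reproduce the input matrix, which pins the topology
    coph <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
    expect_equal(coph, d, tolerance = 1e-9)
  }
})

test_that("ortholog groups serialize as TSV", {
  cm <- generate_community(community_config(n_species = 2,
                                            genes_per_genome = 8, seed = 12))
  groups <- build_ortholog_groups(cm$genomes, "sp01")
  dir <- withr::local_tempdir()
  write_ortholog_groups(groups, file.path(dir, "groups.tsv"))
  back <- read.delim(file.path(dir, "groups.tsv"))
  expect_equal(nrow(back), nrow(groups))
})
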