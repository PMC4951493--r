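# Pairwise protein comparison, reciprocal-best-hit orthology and the
# distance-based transcription-factor tree.
#
# Local alignment is Smith-Waterman with affine gaps (BLOSUM62, gap open 11,
# extend 1, the common protein-search defaults) through
# Biostrings::pairwiseAlignment; expect values use Karlin-Altschul statistics
# with the declared gapped constants (lambda = 0.267, K = 0.041) on the raw
# search space m*n. A pluggable backend could swap in an external aligner;
# the built-in route keeps tests deterministic and dependency-free.

KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local alignment of two proteins with search statistics
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gap penalties.
#' Percent identity is computed over all alignment columns (gaps included);
#' the expect value is `E = K * m * n * exp(-lambda * score)` on the search
#' space `m * n` (product of the sequence lengths unless overridden).
#'
#' @param protein_a,protein_b Amino-acid sequences (20 canonical residues).
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param search_space Optional `m * n` override for the E-value.
#' @return List of class `alignment_result`: `query_id`, `subject_id`,
#'   `score` (raw), `bit_score`, `evalue`, `identity` (percent),
#'   `align_length`.
#' @export
align_pair <- function(protein_a, protein_b, gap_open = 11, gap_extend = 1,
                       search_space = NULL) {
  a <- check_protein(protein_a, "protein_a")
  b <- check_protein(protein_b, "protein_b")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(al)
  mn <- search_space %||% (nchar(a) * nchar(b))
  structure(list(query_id = NA_character_, subject_id = NA_character_,
                 score = s,
                 bit_score = (KA_LAMBDA * s - log(KA_K)) / log(2),
                 evalue = KA_K * mn * exp(-KA_LAMBDA * s),
                 identity = Biostrings::pid(al, type = "PID1"),
                 align_length = nchar(as.character(Biostrings::alignedPattern(al)))),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Local alignment: score %.0f (%.1f bits), E = %.3g, identity %.1f%% over %d columns\n",
              x$score, x$bit_score, x$evalue, x$identity, x$align_length))
  invisible(x)
}

# All-vs-all raw SW scores between two protein sets (named character
# vectors); one vectorized pairwiseAlignment call per subject. The local
# alignment score is symmetric, so one matrix serves both search directions.
protein_score_matrix <- function(prot_a, prot_b, gap_open = 11, gap_extend = 1) {
  pa <- Biostrings::AAStringSet(prot_a)
  sc <- matrix(NA_real_, nrow = length(prot_a), ncol = length(prot_b),
               dimnames = list(names(prot_a), names(prot_b)))
  for (j in seq_along(prot_b)) {
    sc[, j] <- Biostrings::pairwiseAlignment(
      pa, Biostrings::AAString(prot_b[[j]]), type = "local",
      substitutionMatrix = blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
  }
  sc
}

genome_proteins <- function(genome) {
  g <- genome$genes
  keep <- !is.na(g$protein) & nzchar(g$protein)
  setNames(g$protein[keep], g$gene_id[keep])
}

#' Reciprocal best hits between two genomes
#'
#' A pair `(a, b)` is reported when `b` is `a`'s unique best-scoring hit,
#' `a` is `b`'s unique best-scoring hit, and both expect values pass the
#' threshold. Ties on the best score are treated conservatively: no pair.
#'
#' @param genome_a,genome_b [annotated_genome] objects with protein products.
#' @param e_threshold Expect-value threshold (default `1e-20`, the
#'   conservative cutoff used for cross-species ortholog calls).
#' @return `data.frame` with columns `gene_a`, `gene_b`, `score`, `evalue_ab`,
#'   `evalue_ba`, `identity` (percent identity of the pair's alignment is not
#'   recomputed here; use [align_pair()] when needed).
#' @export
reciprocal_best_hits <- function(genome_a, genome_b, e_threshold = 1e-20) {
  pa <- genome_proteins(genome_a)
  pb <- genome_proteins(genome_b)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), evalue_ab = numeric(),
                      evalue_ba = numeric(), stringsAsFactors = FALSE)
  if (length(pa) == 0 || length(pb) == 0) return(empty)
  sc <- protein_score_matrix(pa, pb)
  best_of_row <- unique_best(sc)
  best_of_col <- unique_best(t(sc))
  pairs <- which(!is.na(best_of_row))
  out <- lapply(pairs, function(i) {
    j <- best_of_row[i]
    if (is.na(best_of_col[j]) || best_of_col[j] != i) return(NULL)
    s <- sc[i, j]
    e_ab <- KA_K * nchar(pa[[i]]) * nchar(pb[[j]]) * exp(-KA_LAMBDA * s)
    if (e_ab > e_threshold) return(NULL)
    data.frame(gene_a = names(pa)[i], gene_b = names(pb)[j], score = s,
               evalue_ab = e_ab, evalue_ba = e_ab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# Index of the unique maximum of each row; NA when the best score is tied.
unique_best <- function(m) {
  apply(m, 1, function(r) {
    j <- which(r >= max(r) - 1e-9)
    if (length(j) == 1) j else NA_integer_
  })
}

#' Reference-anchored ortholog groups across genomes
#'
#' One group per reference gene; the member from species `S` is the
#' reciprocal-best-hit partner of the anchor gene in `S`, if any (star
#' topology, no transitive closure).
#'
#' @param genomes Named list of [annotated_genome] objects.
#' @param reference Name of the reference genome in `genomes`.
#' @param genes Optional subset of reference gene ids to anchor on
#'   (default: all reference genes with a protein product).
#' @param e_threshold Expect-value threshold for the underlying RBH calls.
#' @return `data.frame` of class `ortholog_groups` with columns `group_id`
#'   (anchor gene id), `species`, `gene_id`; the anchor itself appears as a
#'   member of the reference species.
#' @export
build_ortholog_groups <- function(genomes, reference, genes = NULL,
                                  e_threshold = 1e-20) {
  if (!reference %in% names(genomes)) {
    stop("reference genome '", reference, "' not in the genome list")
  }
  ref <- genomes[[reference]]
  anchors <- genes %||% names(genome_proteins(ref))
  others <- setdiff(names(genomes), reference)
  rows <- data.frame(group_id = anchors, species = reference,
                     gene_id = anchors, stringsAsFactors = FALSE)
  for (sp in others) {
    rbh <- reciprocal_best_hits(ref, genomes[[sp]], e_threshold)
    hit <- rbh$gene_b[match(anchors, rbh$gene_a)]
    ok <- !is.na(hit)
    if (any(ok)) {
      rows <- rbind(rows, data.frame(group_id = anchors[ok], species = sp,
                                     gene_id = hit[ok],
                                     stringsAsFactors = FALSE))
    }
  }
  rows <- rows[order(match(rows$group_id, anchors), rows$species), ]
  rownames(rows) <- NULL
  attr(rows, "reference") <- reference
  class(rows) <- c("ortholog_groups", "data.frame")
  rows
}

#' Distance-based transcription-factor tree
#'
#' Pairwise distances are `1 - identity/100` from optimal local alignments of
#' the TF protein sequences; the tree is built by neighbor joining, with
#' negative branch lengths clamped to zero. Species are processed in
#' lexicographic order so that ties resolve deterministically.
#'
#' @param tf_proteins Named character vector (species -> TF protein sequence),
#'   at least 2 entries.
#' @return Newick string.
#' @export
tf_distance_tree <- function(tf_proteins) {
  if (length(tf_proteins) < 2) stop("need at least 2 species for a TF tree")
  tf_proteins <- tf_proteins[order(names(tf_proteins))]
  n <- length(tf_proteins)
  d <- matrix(0, n, n, dimnames = list(names(tf_proteins), names(tf_proteins)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      id <- align_pair(tf_proteins[[i]], tf_proteins[[j]])$identity
      d[i, j] <- d[j, i] <- 1 - id / 100
    }
  }
  nj_newick(d)
}

# Neighbor joining on a symmetric distance matrix; negative branch lengths
# clamped to zero, two-taxon case split evenly.
nj_newick <- function(d) {
  n <- nrow(d)
  if (n == 2) {
    return(sprintf("(%s:%.12g,%s:%.12g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}

#' Leaf order of a newick tree
#'
#' Tips in the order they would appear in a plotted (cladewise) layout; used
#' to order the species columns of the regulon matrix.
#'
#' @param newick Newick string.
#' @return Character vector of tip labels.
#' @export
tree_leaf_order <- function(newick) {
  tr <- ape::read.tree(text = newick)
  tr <- ape::reorder.phylo(tr, "cladewise")
  tips <- tr$edge[, 2][tr$edge[, 2] <= ape::Ntip(tr)]
  tr$tip.label[tips]
}

#' Write ortholog groups as TSV
#'
#' @param groups An `ortholog_groups` table.
#' @param path Output path.
#' @export
write_ortholog_groups <- function(groups, path) {
  utils::write.table(as.data.frame(groups), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
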