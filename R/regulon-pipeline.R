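# Pipeline core: operon prediction from intergenic distances, site search in
# operon promoters, operon revision driven by high-scoring internal sites,
# and the cross-species comparative regulon matrix.

#' Predict operons from intergenic distances
#'
#' Directons (maximal runs of consecutive same-strand genes per contig) are
#' split into operons by the genome's mean intergenic distance: two adjacent
#' directon genes belong to the same operon iff their intergenic distance is
#' strictly below the mean (computed over all adjacent gene pairs, overlaps
#' included). Every gene belongs to exactly one operon. The lead gene is the
#' 5'-most member in reading orientation.
#'
#' @param genome An [annotated_genome].
#' @return List of class `operon_set`; each element has `operon_id`,
#'   `contig_id`, `strand`, `genes` (genomic order), `lead`. Attributes
#'   `genome_id` and `mean_igd` record the genome and its mean intergenic
#'   distance.
#' @export
predict_operons <- function(genome) {
  g <- genome$genes
  igd <- intergenic_distances(genome)
  mean_igd <- if (nrow(igd) > 0) mean(igd$distance) else Inf
  dist_after <- setNames(igd$distance, igd$gene_a)
  operons <- list()
  for (ctg in unique(g$contig_id)) {
    idx <- which(g$contig_id == ctg)
    idx <- idx[order(g$start[idx])]
    cur <- idx[1]
    for (k in seq_along(idx)[-1]) {
      prev <- idx[k - 1]
      this <- idx[k]
      same_strand <- g$strand[prev] == g$strand[this]
      dd <- g$start[this] - g$end[prev]
      if (same_strand && dd < mean_igd) {
        cur <- c(cur, this)
      } else {
        operons[[length(operons) + 1]] <- cur
        cur <- this
      }
    }
    operons[[length(operons) + 1]] <- cur
  }
  out <- lapply(seq_along(operons), function(i) {
    idx <- operons[[i]]
    strand <- g$strand[idx[1]]
    genes <- g$gene_id[idx]
    list(operon_id = sprintf("%s_op%03d", genome$genome_id, i),
         contig_id = g$contig_id[idx[1]], strand = strand, genes = genes,
         lead = if (strand == "+") genes[1] else genes[length(genes)],
         promoter = NULL, best_hit = NULL)
  })
  structure(out, class = "operon_set", genome_id = genome$genome_id,
            mean_igd = mean_igd)
}

#' @export
print.operon_set <- function(x, ...) {
  sizes <- vapply(x, function(o) length(o$genes), integer(1))
  cat(sprintf("Operon set for '%s': %d operons over %d genes (mean intergenic distance %.1f bp)\n",
              attr(x, "genome_id"), length(x), sum(sizes), attr(x, "mean_igd")))
  invisible(x)
}

#' @export
as.data.frame.operon_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(o) {
    data.frame(operon_id = o$operon_id, contig_id = o$contig_id,
               strand = o$strand, gene_id = o$genes,
               lead = o$genes == o$lead,
               best_score = if (is.null(o$best_hit)) NA_real_
                            else o$best_hit$score,
               stringsAsFactors = FALSE)
  }))
}

# Best hit in a gene's promoter window; NULL when the window is empty.
best_promoter_hit <- function(genome, gene_id, motif, upstream, downstream,
                              threshold = -Inf) {
  prom <- extract_promoter(genome, gene_id, upstream, downstream)
  if (!nzchar(prom$seq) || nchar(prom$seq) < motif$width) return(NULL)
  hits <- scan_sequence(motif, prom$seq, threshold = threshold,
                        both_strands = TRUE, contig_id = prom$contig_id,
                        context = gene_id)
  if (nrow(hits) == 0) return(NULL)
  best <- hits[hits$score >= max(hits$score) - 1e-9, ]
  best <- best[which.min(best$position), ]  # ties: 5'-most in reading orientation
  list(position = best$position,
       position_rel = best$position - prom$tls_offset,
       strand = best$strand, sequence = best$sequence, score = best$score,
       contig_id = prom$contig_id)
}

#' Search operon promoters for binding sites
#'
#' Scans the promoter window of each operon's lead gene on both strands and
#' records the best-scoring hit (ties resolved to the 5'-most position).
#' Sites identified in the lead gene are thereby assigned to every operon
#' member.
#'
#' @param genome An [annotated_genome].
#' @param operons An `operon_set` from [predict_operons()].
#' @param motif A `binding_motif`.
#' @param upstream,downstream Promoter window around the lead TLS.
#' @param threshold Minimum score for a hit to be recorded (`-Inf` keeps the
#'   best raw score regardless).
#' @return The `operon_set` with `promoter` and `best_hit` filled
#'   (`best_hit` absent when the window is fully clamped away).
#' @export
search_operon_promoters <- function(genome, operons, motif, upstream = 250L,
                                    downstream = 50L, threshold = -Inf) {
  out <- lapply(operons, function(o) {
    o$promoter <- extract_promoter(genome, o$lead, upstream, downstream)
    o$best_hit <- best_promoter_hit(genome, o$lead, motif, upstream,
                                    downstream, threshold)
    o
  })
  attributes(out) <- attributes(operons)
  out
}

#' Revise operon predictions using internal high-scoring sites
#'
#' A non-lead operon member whose own promoter window contains a site scoring
#' at least `revision_threshold` marks an internal promoter: the operon is
#' split immediately before that gene (reading orientation), which becomes
#' the lead of a new operon. Splits are applied left-to-right, once per
#' operon per pass, and passes repeat to a fixpoint; promoters and best hits
#' are then recomputed.
#'
#' @param genome An [annotated_genome].
#' @param operons An `operon_set`.
#' @param motif A `binding_motif`.
#' @param revision_threshold Score defining "high-scoring" (default
#'   0.75 x the maximum achievable motif score).
#' @param upstream,downstream Promoter window used both for member windows
#'   and for the final rescan.
#' @return A revised `operon_set` with promoters and best hits recomputed.
#' @export
revise_operons <- function(genome, operons, motif,
                           revision_threshold = 0.75 * max_score(motif),
                           upstream = 250L, downstream = 50L) {
  ops <- lapply(operons, function(o) o[c("operon_id", "contig_id", "strand",
                                         "genes", "lead")])
  repeat {
    changed <- FALSE
    nxt <- list()
    for (o in ops) {
      genes_reading <- if (o$strand == "+") o$genes else rev(o$genes)
      split_at <- 0L
      if (length(genes_reading) > 1) {
        for (k in seq_along(genes_reading)[-1]) {
          hit <- best_promoter_hit(genome, genes_reading[k], motif,
                                   upstream, downstream)
          if (!is.null(hit) && hit$score >= revision_threshold) {
            split_at <- k
            break
          }
        }
      }
      if (split_at > 0) {
        changed <- TRUE
        head_r <- genes_reading[seq_len(split_at - 1)]
        tail_r <- genes_reading[seq(split_at, length(genes_reading))]
        for (part in list(head_r, tail_r)) {
          genes_genomic <- if (o$strand == "+") part else rev(part)
          nxt[[length(nxt) + 1]] <- list(
            operon_id = NA_character_, contig_id = o$contig_id,
            strand = o$strand, genes = genes_genomic,
            lead = part[1])
        }
      } else {
        nxt[[length(nxt) + 1]] <- o
      }
    }
    ops <- nxt
    if (!changed) break
  }
  for (i in seq_along(ops)) {
    ops[[i]]$operon_id <- sprintf("%s_op%03d", attr(operons, "genome_id"), i)
  }
  out <- structure(ops, class = "operon_set",
                   genome_id = attr(operons, "genome_id"),
                   mean_igd = attr(operons, "mean_igd"))
  search_operon_promoters(genome, out, motif, upstream, downstream)
}

#' Cross-species comparative regulon matrix
#'
#' Runs the full comparative pipeline: TF orthology across species, a
#' distance-based TF tree, reference-anchored ortholog groups, per-species
#' operon prediction (with revision) and promoter site search. Each
#' species x ortholog-group cell holds the best promoter score of the operon
#' containing the ortholog, or `NA` when no ortholog was identified.
#' Scores are also normalized to `[0, 1]` over all non-absent cells of the
#' analysis (the best-scoring cell of the whole analysis is 1, the worst 0).
#' Species without a TF ortholog are excluded from the tree and flagged.
#'
#' @param genomes Named list of [annotated_genome] objects.
#' @param reference Name of the reference genome.
#' @param motif A `binding_motif`.
#' @param tf_gene_id Gene id of the transcription factor in the reference.
#' @param genes Optional subset of reference gene ids to anchor groups on.
#' @param upstream,downstream Promoter window.
#' @param revise Apply operon revision before scoring.
#' @param revision_threshold Passed to [revise_operons()].
#' @param e_threshold RBH expect-value threshold.
#' @return List of class `regulon_matrix`: `raw` and `norm` matrices
#'   (rows = groups in reference order, columns = species in TF-tree leaf
#'   order), `tree` (newick), `species`, `excluded`, `groups`, `operons`
#'   (per species), `reference`.
#' @export
build_regulon_matrix <- function(genomes, reference, motif, tf_gene_id,
                                 genes = NULL, upstream = 250L,
                                 downstream = 50L, revise = TRUE,
                                 revision_threshold = NULL,
                                 e_threshold = 1e-20) {
  if (!reference %in% names(genomes)) {
    stop("reference genome '", reference, "' not in the genome list")
  }
  ref <- genomes[[reference]]
  if (!tf_gene_id %in% ref$genes$gene_id) {
    stop("TF gene '", tf_gene_id, "' not found in the reference genome")
  }
  groups <- build_ortholog_groups(genomes, reference, genes = genes,
                                  e_threshold = e_threshold)
  # species with a TF ortholog
  tf_rows <- groups[groups$group_id == tf_gene_id, ]
  included <- tf_rows$species
  excluded <- setdiff(names(genomes), included)
  if (length(included) < 1) stop("no species retains the TF")
  tf_prot <- vapply(included, function(sp) {
    gid <- tf_rows$gene_id[tf_rows$species == sp]
    genomes[[sp]]$genes$protein[match(gid, genomes[[sp]]$genes$gene_id)]
  }, character(1))
  tree <- if (length(included) >= 2) tf_distance_tree(tf_prot) else
    sprintf("(%s);", included)
  species_order <- if (length(included) >= 2) tree_leaf_order(tree) else included

  anchors <- unique(groups$group_id)
  raw <- matrix(NA_real_, nrow = length(anchors),
                ncol = length(species_order),
                dimnames = list(anchors, species_order))
  operon_sets <- list()
  for (sp in species_order) {
    gnm <- genomes[[sp]]
    ops <- predict_operons(gnm)
    ops <- if (revise) {
      thr <- revision_threshold %||% (0.75 * max_score(motif))
      revise_operons(gnm, ops, motif, revision_threshold = thr,
                     upstream = upstream, downstream = downstream)
    } else {
      search_operon_promoters(gnm, ops, motif, upstream, downstream)
    }
    operon_sets[[sp]] <- ops
    gene2op <- do.call(rbind, lapply(seq_along(ops), function(i) {
      data.frame(gene = ops[[i]]$genes, op = i, stringsAsFactors = FALSE)
    }))
    sp_rows <- groups[groups$species == sp, ]
    for (r in seq_len(nrow(sp_rows))) {
      opi <- gene2op$op[match(sp_rows$gene_id[r], gene2op$gene)]
      if (is.na(opi)) next
      hit <- ops[[opi]]$best_hit
      raw[sp_rows$group_id[r], sp] <- if (is.null(hit)) NA_real_ else hit$score
    }
  }
  vals <- raw[!is.na(raw)]
  norm <- raw
  if (length(vals) > 0) {
    rng <- range(vals)
    norm[] <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else 1
  }
  structure(list(raw = raw, norm = norm, tree = tree,
                 species = species_order, excluded = excluded,
                 groups = groups, operons = operon_sets,
                 reference = reference, tf_gene_id = tf_gene_id),
            class = "regulon_matrix")
}

#' @export
print.regulon_matrix <- function(x, ...) {
  cat(sprintf("Regulon matrix: %d ortholog groups x %d species (reference '%s')\n",
              nrow(x$raw), ncol(x$raw), x$reference))
  if (length(x$excluded) > 0) {
    cat("  species without a TF ortholog (excluded): ",
        paste(x$excluded, collapse = ", "), "\n")
  }
  cat(sprintf("  non-absent cells: %d of %d; raw score range %.2f..%.2f bits\n",
              sum(!is.na(x$raw)), length(x$raw),
              suppressWarnings(min(x$raw, na.rm = TRUE)),
              suppressWarnings(max(x$raw, na.rm = TRUE))))
  invisible(x)
}

#' Call regulon membership from a regulon matrix
#'
#' A species x group pair is called regulated when its best promoter score
#' reaches `fraction` of the maximum achievable motif score. The default
#' fraction (0.6) sits between the 0-bit site-listing floor and the stricter
#' 0.75 operon-revision threshold; it accepts a sharply conserved site with
#' one substituted arm position while rejecting chance background matches.
#'
#' @param rm A `regulon_matrix`.
#' @param motif The `binding_motif` used to build it.
#' @param fraction Fraction of the maximum achievable score.
#' @return `data.frame` with columns `species`, `group_id`, `score`.
#' @export
regulon_calls <- function(rm, motif, fraction = 0.6) {
  thr <- fraction * max_score(motif)
  idx <- which(!is.na(rm$raw) & rm$raw >= thr, arr.ind = TRUE)
  data.frame(species = colnames(rm$raw)[idx[, 2]],
             group_id = rownames(rm$raw)[idx[, 1]],
             score = rm$raw[idx], stringsAsFactors = FALSE)
}

#' Write a regulon matrix as TSV (+ newick tree)
#'
#' @param rm A `regulon_matrix`.
#' @param tsv_path Output TSV (normalized scores; absent cells `NA`).
#' @param newick_path Optional output file for the TF tree.
#' @export
write_regulon_matrix <- function(rm, tsv_path, newick_path = NULL) {
  df <- data.frame(group_id = rownames(rm$norm), rm$norm,
                   check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(newick_path)) writeLines(rm$tree, newick_path)
  invisible(tsv_path)
}
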