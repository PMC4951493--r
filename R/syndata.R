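# Synthetic multi-species genome communities with planted regulons: the
# benchmarking substrate for the pipeline. Genomes carry ortholog families
# diverged along a species tree, operon structures with a bimodal
# intergenic-distance distribution, and binding sites sampled from a motif
# model planted in the promoter windows of regulated operons (optionally in
# tandem arrangements). Ground truth for every planted feature is returned
# alongside the genomes.

# Robinson-Robinson amino-acid background frequencies.
AA_FREQ <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
             Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
             L = 0.090, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
             S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.066)

# BLOSUM62-conditional substitution distribution: P(b | a) proportional to
# p_b * exp(lambda * S(a, b)) for b != a, with lambda = ln(2)/2 (half-bit
# matrix). Cached 20 x 20 row-stochastic matrix.
substitution_matrix_cond <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      aa <- names(AA_FREQ)
      S <- blosum62()[aa, aa]
      M <- AA_FREQ[col(S)] * exp(log(2) / 2 * S)
      dim(M) <- dim(S)
      dimnames(M) <- dimnames(S)
      diag(M) <- 0
      cache <<- M / rowSums(M)
    }
    cache
  }
})

#' Random DNA sequences with a given GC content
#'
#' @param n Number of sequences.
#' @param length Length of each sequence (bp).
#' @param gc GC content in `[0, 1]`.
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, length, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Random protein from background amino-acid frequencies
#'
#' @param length Number of residues.
#' @return Amino-acid string.
#' @export
random_protein <- function(length) {
  paste(sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

#' Evolve a protein by independent per-site substitution
#'
#' Each site substitutes with probability `1 - exp(-rate)`; the replacement
#' residue is drawn from the BLOSUM62-conditional frequencies of the original
#' residue (never the residue itself). Length is preserved.
#'
#' @param sequence Amino-acid string (20 canonical residues).
#' @param rate Expected substitutions per site (>= 0).
#' @param seed Optional RNG seed; `NULL` uses the current RNG stream.
#' @return The evolved sequence.
#' @export
evolve_protein <- function(sequence, rate, seed = NULL) {
  stopifnot(rate >= 0)
  sequence <- check_protein(sequence, "sequence")
  with_seed(seed, {
    res <- strsplit(sequence, "")[[1]]
    hit <- stats::runif(length(res)) < (1 - exp(-rate))
    if (any(hit)) {
      M <- substitution_matrix_cond()
      res[hit] <- vapply(res[hit], function(a) {
        sample(colnames(M), 1, prob = M[a, ])
      }, character(1))
    }
    paste(res, collapse = "")
  })
}

# Reverse-translate a protein into a CDS (uniform synonymous codon choice,
# TAA stop appended). The bacterial code and the standard code agree on the
# codon -> residue map used here.
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    cand <- names(gc)[gc == a]
    cand[sample.int(length(cand), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

#' Configuration for a synthetic genome community
#'
#' Defaults describe the benchmark community: 3 species diverged along a
#' random tree, 45 gene families per genome, a regulon made of the shared
#' SOS core (*lexA*, *recA* and the *imuA-imuB-dnaE2* mutagenesis cassette)
#' planted with sites from the 14 bp `TGTTC-N4-GAACA` dyad motif, and a
#' bimodal intergenic-distance model (within-operon gaps Geom(mean 20) bp;
#' between-operon gaps offset + Geom so that the between mode is separated
#' from zero while keeping a 200 bp mean).
#'
#' @param n_species Number of species.
#' @param tree `"random"` or a newick string whose tips are `sp01`, `sp02`,
#'   ... with branch lengths in expected substitutions per site.
#' @param divergence Mean branch length (expected substitutions/site) of the
#'   random tree.
#' @param genes_per_genome Gene families per genome (includes the regulon).
#' @param operon_size_probs Named numeric: probabilities of operon sizes for
#'   the unregulated families.
#' @param within_mean,between_mean,between_offset Intergenic model (bp):
#'   within-operon gaps are Geom(`within_mean`); between-operon gaps are
#'   `between_offset + Geom(between_mean - between_offset)`. The offset
#'   keeps the between-operon mode separated from the genome mean (which
#'   the regulated-promoter gaps inflate), so the distance-threshold operon
#'   rule remains testable.
#' @param gc GC content of intergenic background DNA.
#' @param motif `binding_motif` sites are sampled from, or an IUPAC consensus
#'   string (then built via [motif_from_consensus()] with
#'   `bits_per_column`).
#' @param bits_per_column Arm-column information content when `motif` is a
#'   consensus string.
#' @param regulon List of character vectors: each element one regulated
#'   operon (family names in reading order).
#' @param site_window Site placement window relative to the TLS (reading
#'   orientation), default `c(-200, -20)` so sites fall inside both the
#'   `[-250, 0]` discovery and `[-250, +50]` search windows.
#' @param tandem_fraction Fraction of regulated promoters receiving a
#'   secondary site in tandem.
#' @param tandem_gaps Candidate inter-site gaps (bp) for tandem promoters.
#' @param protein_length Range (min, max) of family protein lengths (aa).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `community_config`.
#' @export
community_config <- function(n_species = 3L, tree = "random",
                             divergence = 0.05, genes_per_genome = 45L,
                             operon_size_probs = c(`1` = 0.3, `2` = 0.3,
                                                   `3` = 0.25, `4` = 0.15),
                             within_mean = 20, between_mean = 200,
                             between_offset = 150, gc = 0.5,
                             motif = "TGTTC-N4-GAACA", bits_per_column = 1.8,
                             regulon = list(lexA = "lexA", recA = "recA",
                                            imu = c("imuA", "imuB", "dnaE2")),
                             site_window = c(-200L, -20L),
                             tandem_fraction = 0.25, tandem_gaps = 1:2,
                             protein_length = c(100L, 250L), seed = 1L) {
  if (!(within_mean < between_mean)) {
    stop("within-operon mean intergenic distance must be below the ",
         "between-operon mean; otherwise operon structure is untestable")
  }
  stopifnot(between_offset >= 0, between_offset < between_mean,
            gc >= 0, gc <= 1,
            tandem_fraction >= 0, tandem_fraction <= 1,
            all(operon_size_probs >= 0), sum(operon_size_probs) > 0,
            site_window[1] < site_window[2], site_window[2] <= 0,
            n_species >= 1, genes_per_genome >= length(unlist(regulon)))
  if (is.character(motif)) {
    motif <- motif_from_consensus(motif, bits_per_column)
  }
  stopifnot(inherits(motif, "binding_motif"))
  structure(list(n_species = as.integer(n_species), tree = tree,
                 divergence = divergence,
                 genes_per_genome = as.integer(genes_per_genome),
                 operon_size_probs = operon_size_probs,
                 within_mean = within_mean, between_mean = between_mean,
                 between_offset = between_offset, gc = gc, motif = motif,
                 regulon = regulon, site_window = as.integer(site_window),
                 tandem_fraction = tandem_fraction,
                 tandem_gaps = as.integer(tandem_gaps),
                 protein_length = as.integer(protein_length),
                 seed = as.integer(seed)),
            class = "community_config")
}

rgeom_mean <- function(n, mean) {
  stats::rgeom(n, prob = 1 / (1 + mean))
}

# Tip sequences after evolving an ancestor along the tree (preorder walk).
evolve_along_tree <- function(tr, ancestor) {
  n_tip <- length(tr$tip.label)
  tr <- ape::reorder.phylo(tr, "cladewise")
  seqs <- character(n_tip + tr$Nnode)
  seqs[n_tip + 1] <- ancestor
  for (e in seq_len(nrow(tr$edge))) {
    seqs[tr$edge[e, 2]] <- evolve_protein(seqs[tr$edge[e, 1]],
                                          tr$edge.length[e])
  }
  setNames(seqs[seq_len(n_tip)], tr$tip.label)
}

# Overwrite contig characters at genomic interval [start, start + n) with s.
splice_in <- function(contig, start, s) {
  paste0(substr(contig, 1, start), s,
         substr(contig, start + nchar(s) + 1, nchar(contig)))
}

#' Generate a synthetic annotated genome community with a planted regulon
#'
#' See [community_config()] for the generative model. Each ortholog family
#' descends from one ancestor protein evolved along the species tree; operon
#' structure and order are shared across species while intergenic gaps are
#' redrawn per species; regulated operons receive one site sampled from the
#' motif model, placed uniformly in the placement window of the lead gene
#' (always in intergenic sequence: the gap 5' of a regulated operon is drawn
#' large enough to hold the window), and tandem promoters receive a
#' secondary site at the configured gap. Deterministic given the seed.
#'
#' @param config A [community_config()].
#' @return List of class `community`: `genomes` (named list of
#'   [annotated_genome]), `truth` (list of `data.frame`s: `sites`, `operons`,
#'   `families`, `regulon`), `tree` (newick or `NA` for one species),
#'   `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, {
    n_sp <- config$n_species
    species <- sprintf("sp%02d", seq_len(n_sp))
    motif <- config$motif
    w <- motif$width

    tr <- NULL
    if (n_sp >= 2) {
      if (identical(config$tree, "random")) {
        tr <- ape::rtree(n_sp, tip.label = species)
        tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / config$divergence)
      } else {
        tr <- ape::read.tree(text = config$tree)
        if (!setequal(tr$tip.label, species)) {
          stop("tree tips must be ", paste(species, collapse = ", "))
        }
      }
    }

    # community-level operon structure (shared gene order across species)
    reg_fams <- unlist(config$regulon, use.names = FALSE)
    n_unreg <- config$genes_per_genome - length(reg_fams)
    unreg_fams <- if (n_unreg > 0) sprintf("fam%03d", seq_len(n_unreg)) else
      character(0)
    sizes <- as.integer(names(config$operon_size_probs))
    pool <- unreg_fams
    unreg_ops <- list()
    while (length(pool) > 0) {
      s <- sizes[sample.int(length(sizes), 1, prob = config$operon_size_probs)]
      s <- min(s, length(pool))
      unreg_ops[[length(unreg_ops) + 1]] <- pool[seq_len(s)]
      pool <- pool[-seq_len(s)]
    }
    ops_fams <- c(unname(config$regulon), unreg_ops)
    regulated <- c(rep(TRUE, length(config$regulon)),
                   rep(FALSE, length(unreg_ops)))
    ord <- sample(length(ops_fams))
    ops_fams <- ops_fams[ord]
    regulated <- regulated[ord]
    strands <- sample(c("+", "-"), length(ops_fams), replace = TRUE)

    # family ancestors and tip proteins
    fams <- c(reg_fams, unreg_fams)
    ancestors <- setNames(vapply(fams, function(f) {
      random_protein(sample(seq(config$protein_length[1],
                                config$protein_length[2]), 1))
    }, character(1)), fams)
    tips <- lapply(ancestors, function(a) {
      if (is.null(tr)) setNames(a, species) else evolve_along_tree(tr, a)
    })

    pad <- 300L
    win <- config$site_window
    reg_gap_min <- -win[1] + 20L      # window fully intergenic
    resid <- config$between_mean - config$between_offset

    genomes <- list()
    t_sites <- t_operons <- t_families <- t_regulon <- list()
    for (sp in species) {
      # draw inter-operon gaps by category. A regulated operon's 5' gap must
      # hold the whole placement window (>= window + margin); when the
      # neighbour across that gap transcribes divergently, its own search
      # window shares the gap and the gap must be wide enough that the
      # planted (palindromic) site cannot fall inside the neighbour's
      # window: window span + search window + margin.
      n_ops <- length(ops_fams)
      gaps <- integer(n_ops)          # gap preceding each operon (gaps[1] unused)
      div_gap_min <- reg_gap_min + 250L
      for (k in seq_len(n_ops)[-1]) {
        left_faces_gap <- strands[k - 1] == "-"   # left lead's promoter in gap
        right_faces_gap <- strands[k] == "+"      # right lead's promoter in gap
        reg_left <- regulated[k - 1] && left_faces_gap
        reg_right <- regulated[k] && right_faces_gap
        gaps[k] <- if ((reg_right && left_faces_gap) ||
                       (reg_left && right_faces_gap)) {
          div_gap_min + rgeom_mean(1, resid)
        } else if (reg_right || reg_left) {
          reg_gap_min + rgeom_mean(1, resid)
        } else {
          config$between_offset + rgeom_mean(1, resid)
        }
      }
      # lay out genes left to right
      cursor <- pad
      gene_rows <- list()
      gene_dna <- list()
      op_index <- integer(0)
      for (k in seq_len(n_ops)) {
        if (k > 1) cursor <- cursor + gaps[k]
        fams_k <- ops_fams[[k]]
        genomic_fams <- if (strands[k] == "+") fams_k else rev(fams_k)
        for (j in seq_along(genomic_fams)) {
          f <- genomic_fams[j]
          if (j > 1) cursor <- cursor + rgeom_mean(1, config$within_mean)
          prot <- tips[[f]][[sp]]
          cds <- reverse_translate(prot)
          if (strands[k] == "-") cds <- revcomp(cds)
          gene_rows[[length(gene_rows) + 1]] <- data.frame(
            gene_id = paste0(sp, "_", f), contig_id = "chr",
            start = cursor, end = cursor + nchar(cds), strand = strands[k],
            protein = prot, family = f, operon = k, stringsAsFactors = FALSE)
          gene_dna[[length(gene_dna) + 1]] <- cds
          cursor <- cursor + nchar(cds)
        }
      }
      genes <- do.call(rbind, gene_rows)
      contig_len <- cursor + pad
      contig <- random_dna(1, contig_len, config$gc)
      for (i in seq_len(nrow(genes))) {
        contig <- splice_in(contig, genes$start[i], gene_dna[[i]])
      }

      # plant sites in regulated lead promoters
      site_rows <- list()
      for (k in which(regulated)) {
        idx <- which(genes$operon == k)
        lead_i <- if (strands[k] == "+") idx[1] else idx[length(idx)]
        tls <- if (strands[k] == "+") genes$start[lead_i] else
          genes$end[lead_i] - 1L
        tandem <- stats::runif(1) < config$tandem_fraction
        gap_t <- if (tandem) {
          config$tandem_gaps[sample.int(length(config$tandem_gaps), 1)]
        } else 0L
        span <- if (tandem) 2L * w + gap_t else w
        # reading-orientation start; the arrangement spans [rel, rel+span-1]
        # and stays inside the placement window
        cand <- seq(win[1], win[2] - span + 1L)
        rel <- cand[sample.int(length(cand), 1)]
        seq1 <- sample_sites(motif, 1)
        seqs <- seq1
        rels <- rel
        roles <- "primary"
        if (tandem) {
          seqs <- c(seqs, sample_sites(motif, 1))
          rels <- c(rels, rel + w + gap_t)
          roles <- c(roles, "secondary")
        }
        for (sidx in seq_along(seqs)) {
          r <- rels[sidx]
          if (strands[k] == "+") {
            gstart <- tls + r
            contig <- splice_in(contig, gstart, seqs[sidx])
          } else {
            gstart <- tls - r - w + 1L
            contig <- splice_in(contig, gstart, revcomp(seqs[sidx]))
          }
          site_rows[[length(site_rows) + 1]] <- data.frame(
            species = sp, gene_id = genes$gene_id[lead_i],
            operon = k, contig_id = "chr", position = gstart,
            strand = strands[k], sequence = seqs[sidx], rel = r,
            role = roles[sidx], stringsAsFactors = FALSE)
        }
      }

      genomes[[sp]] <- annotated_genome(
        sp, c(chr = contig),
        genes[, c("gene_id", "contig_id", "start", "end", "strand",
                  "protein")])
      t_sites[[sp]] <- do.call(rbind, site_rows)
      t_operons[[sp]] <- data.frame(
        species = sp, operon_id = sprintf("%s_t_op%02d", sp, genes$operon),
        gene_id = genes$gene_id,
        lead = genes$gene_id == vapply(genes$operon, function(k) {
          idx <- which(genes$operon == k)
          if (strands[k] == "+") genes$gene_id[idx[1]] else
            genes$gene_id[idx[length(idx)]]
        }, character(1)), stringsAsFactors = FALSE)
      t_families[[sp]] <- data.frame(species = sp, gene_id = genes$gene_id,
                                     family = genes$family,
                                     stringsAsFactors = FALSE)
      t_regulon[[sp]] <- data.frame(
        species = sp,
        family = unlist(ops_fams[regulated], use.names = FALSE),
        stringsAsFactors = FALSE)
    }

    truth <- list(sites = do.call(rbind, unname(t_sites)),
                  operons = do.call(rbind, unname(t_operons)),
                  families = do.call(rbind, unname(t_families)),
                  regulon = do.call(rbind, unname(t_regulon)))
    rownames(truth$sites) <- rownames(truth$operons) <-
      rownames(truth$families) <- rownames(truth$regulon) <- NULL
    structure(list(genomes = genomes, truth = truth,
                   tree = if (is.null(tr)) NA_character_ else
                     ape::write.tree(tr),
                   config = config),
              class = "community")
  })
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("Synthetic community: %d species, %d genes/genome, %d planted sites (seed %d)\n",
              length(x$genomes), nrow(x$genomes[[1]]$genes),
              nrow(x$truth$sites), x$config$seed))
  invisible(x)
}

#' Write a community to disk
#'
#' Per-species FASTA + GFF3 (via [write_genome()]), ground-truth TSV tables
#' and the species tree.
#'
#' @param community A `community`.
#' @param outdir Output directory (created if needed).
#' @export
write_community <- function(community, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(community$genomes)) {
    write_genome(community$genomes[[sp]],
                 file.path(outdir, paste0(sp, ".fasta")),
                 file.path(outdir, paste0(sp, ".gff3")))
  }
  for (tab in names(community$truth)) {
    utils::write.table(community$truth[[tab]],
                       file.path(outdir, paste0("truth_", tab, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.na(community$tree)) {
    writeLines(community$tree, file.path(outdir, "species_tree.nwk"))
  }
  invisible(outdir)
}

#' Background promoters with one planted motif site each
#'
#' Generates `n` i.i.d. background promoter sequences (TLS at the right end)
#' and plants one site sampled from the motif model per sequence, uniformly
#' within the placement window relative to the TLS. The standard input for
#' benchmarking motif discovery.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp.
#' @param motif A `binding_motif` sites are sampled from.
#' @param gc Background GC content.
#' @param window Placement window relative to the TLS (reading orientation).
#' @param seed Optional RNG seed.
#' @return List: `seqs` (character), `positions` (0-based site starts),
#'   `sites` (planted sequences).
#' @export
planted_promoter_set <- function(n, length = 250L, motif, gc = 0.5,
                                 window = c(-200L, -20L), seed = NULL) {
  w <- motif$width
  stopifnot(length + window[1] >= 0, window[2] - window[1] + 1 >= w)
  with_seed(seed, {
    seqs <- random_dna(n, length, gc)
    sites <- sample_sites(motif, n)
    rel_cand <- seq(window[1], window[2] - w + 1L)
    rel <- rel_cand[sample.int(base::length(rel_cand), n, replace = TRUE)]
    pos <- length + rel  # 0-based start; TLS sits at offset `length`
    for (i in seq_len(n)) {
      substr(seqs[i], pos[i] + 1L, pos[i] + w) <- sites[i]
    }
    list(seqs = seqs, positions = pos, sites = sites)
  })
}

#' Map regulon-matrix calls to ortholog families using ground truth
#'
#' Regulon calls are keyed by reference anchor gene; the generator's truth
#' table maps genes to families, giving the (species, family) pairs that
#' [evaluate_recovery()] consumes.
#'
#' @param calls Output of [regulon_calls()].
#' @param truth The `truth` element of a `community`.
#' @return `data.frame` with columns `species`, `family`.
#' @export
calls_to_regulon <- function(calls, truth) {
  fam <- truth$families$family[match(calls$group_id, truth$families$gene_id)]
  out <- unique(data.frame(species = calls$species, family = fam,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Precision and recall of predicted regulon membership
#'
#' Compares predicted regulated (species, family) pairs against the planted
#' truth. Undefined ratios (zero denominators) are reported as `NA`, never
#' as 0.
#'
#' @param predicted `data.frame` with columns `species`, `family`.
#' @param truth The `truth` element of a `community` (or a `data.frame` with
#'   `species`, `family`).
#' @return List: `precision`, `recall`, `tp`, `fp`, `fn`, and `confusion`
#'   (per-family `data.frame`).
#' @export
evaluate_recovery <- function(predicted, truth) {
  truth_reg <- if (is.data.frame(truth)) truth else truth$regulon
  stopifnot(all(c("species", "family") %in% names(predicted)),
            all(c("species", "family") %in% names(truth_reg)))
  truth_species <- if (is.data.frame(truth)) unique(truth$species) else
    unique(truth$families$species)
  bad <- setdiff(predicted$species, truth_species)
  if (length(bad) > 0) {
    stop("predicted species not present in truth: ",
         paste(bad, collapse = ", "))
  }
  key <- function(d) paste(d$species, d$family)
  p <- unique(key(predicted))
  t <- unique(key(truth_reg))
  tp <- length(intersect(p, t))
  fp <- length(setdiff(p, t))
  fn <- length(setdiff(t, p))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  fams <- sort(unique(c(predicted$family, truth_reg$family)))
  confusion <- do.call(rbind, lapply(fams, function(f) {
    pf <- p[grepl(paste0(" ", f, "$"), p)]
    tf <- t[grepl(paste0(" ", f, "$"), t)]
    data.frame(family = f, tp = length(intersect(pf, tf)),
               fp = length(setdiff(pf, tf)), fn = length(setdiff(tf, pf)),
               stringsAsFactors = FALSE)
  }))
  list(precision = ratio(tp, tp + fp), recall = ratio(tp, tp + fn),
       tp = tp, fp = fp, fn = fn, confusion = confusion)
}
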