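# Annotated-genome data model: contigs, strand-aware gene annotations and the
# coordinate arithmetic (promoter windows, intergenic distances) the regulon
# pipeline is built on. All internal coordinates are 0-based half-open;
# GFF3 I/O converts from/to the 1-based inclusive convention.

#' Construct an annotated genome
#'
#' Bundles contig sequences with CDS annotations. Genes are stored sorted by
#' (contig, start); gene identifiers must be unique and every gene interval
#' must lie within its contig.
#'
#' @param genome_id Character scalar naming the assembly.
#' @param contigs Named character vector of DNA sequences.
#' @param genes `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`) and optionally
#'   `protein` (amino-acid sequence, `NA` for non-coding features).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, contigs, genes) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"protein" %in% names(genes)) genes$protein <- NA_character_
  req <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  if (!all(req %in% names(genes))) {
    stop("genes must have columns: ", paste(req, collapse = ", "))
  }
  genes <- genes[, req]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene intervals must satisfy start < end")
  missing_ctg <- setdiff(genes$contig_id, names(contigs))
  if (length(missing_ctg) > 0) {
    stop("feature(s) reference contig(s) absent from the assembly: ",
         paste(missing_ctg, collapse = ", "))
  }
  clen <- nchar(contigs)[genes$contig_id]
  if (any(genes$start < 0 | genes$end > clen)) {
    stop("gene interval(s) extend beyond their contig")
  }
  ok <- !is.na(genes$protein)
  genes$protein[ok] <- vapply(seq_len(sum(ok)), function(i) {
    check_protein(genes$protein[ok][i], genes$gene_id[ok][i])
  }, character(1))
  genes <- genes[order(match(genes$contig_id, names(contigs)), genes$start), ]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("Annotated genome '%s': %d contig(s), %.1f kb, %d gene(s)\n",
              x$genome_id, length(x$contigs), sum(nchar(x$contigs)) / 1000,
              nrow(x$genes)))
  invisible(x)
}

#' Translational start site of a gene
#'
#' The TLS is the first transcribed/translated base of the CDS: `start` for a
#' plus-strand gene, `end - 1` for a minus-strand gene.
#'
#' @param gene One row of the `genes` table of an [annotated_genome].
#' @return Integer 0-based genomic position.
#' @export
gene_tls <- function(gene) {
  if (gene$strand == "+") gene$start else gene$end - 1L
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Loads contigs from `fasta_path` and CDS features from `gff3_path`
#' (1-based inclusive coordinates, converted to 0-based half-open). The
#' protein product is taken from a `translation` attribute when present and
#' otherwise translated from the CDS using the bacterial genetic code
#' (translation table 11). Non-CDS features are ignored.
#'
#' @param fasta_path,gff3_path Paths to the assembly FASTA and its GFF3.
#' @param genome_id Assembly name; defaults to the FASTA file name.
#' @return An [annotated_genome].
#' @export
read_genome <- function(fasta_path, gff3_path,
                        genome_id = sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))) {
  ctg <- Biostrings::readDNAStringSet(fasta_path)
  names(ctg) <- sub("\\s.*$", "", names(ctg))
  contigs <- toupper(as.character(ctg))
  gr <- rtracklayer::import(gff3_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", gff3_path)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  missing_ctg <- setdiff(unique(seqid), names(contigs))
  if (length(missing_ctg) > 0) {
    stop("GFF3 feature(s) on contig(s) absent from FASTA: ",
         paste(missing_ctg, collapse = ", "))
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("every CDS feature needs an ID attribute")
  transl <- if ("translation" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$translation)
  } else {
    rep(NA_character_, length(gr))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("CDS feature(s) without strand: ",
                               paste(ids[strand == "*"], collapse = ", "))
  need <- which(is.na(transl) | !nzchar(transl))
  for (i in need) {
    cds <- substr(contigs[seqid[i]], start0[i] + 1L, end0[i])
    if (nchar(cds) %% 3 != 0) {
      stop("CDS length not divisible by 3 for feature: ", ids[i])
    }
    if (strand[i] == "-") cds <- revcomp(cds)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "solve"))
    transl[i] <- sub("\\*$", "", aa)
  }
  annotated_genome(genome_id, contigs,
                   data.frame(gene_id = ids, contig_id = seqid, start = start0,
                              end = end0, strand = strand, protein = transl,
                              stringsAsFactors = FALSE))
}

#' Write an annotated genome as FASTA + GFF3
#'
#' The inverse of [read_genome()]: FASTA wrapped at 70 columns and GFF3 CDS
#' features with `ID` and `translation` attributes. A write/read round trip
#' reproduces coordinates, strands and proteins exactly.
#'
#' @param genome An [annotated_genome].
#' @param fasta_path,gff3_path Output paths.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta_path, width = 70L)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$source <- "regulonscout"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- g$gene_id
  gr$translation <- g$protein
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(genome)
}

get_gene <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  genome$genes[i, ]
}

#' Extract a promoter window around the translational start site
#'
#' Returns the window `[-upstream, +downstream)` relative to the TLS, in
#' reading orientation (reverse-complemented for minus-strand genes) and
#' clamped at contig edges.
#'
#' @param genome An [annotated_genome].
#' @param gene_id Gene whose promoter to extract.
#' @param upstream,downstream Non-negative window extents in bp. The default
#'   `(250, 50)` is the regulon-search window; motif discovery conventionally
#'   uses `(250, 0)`.
#' @return A `promoter_region`: list with `id`, `contig_id`, `start`, `end`
#'   (genomic, 0-based half-open), `strand`, `seq` (reading orientation) and
#'   `tls_offset` (position of the TLS within `seq`).
#' @export
extract_promoter <- function(genome, gene_id, upstream = 250L, downstream = 50L) {
  stopifnot(upstream >= 0, downstream >= 0)
  gene <- get_gene(genome, gene_id)
  clen <- nchar(genome$contigs[[gene$contig_id]])
  t <- gene_tls(gene)
  if (gene$strand == "+") {
    s <- max(0L, t - upstream)
    e <- min(clen, t + downstream)
  } else {
    s <- max(0L, t - downstream + 1L)
    e <- min(clen, t + upstream + 1L)
  }
  seq <- if (e > s) substr(genome$contigs[[gene$contig_id]], s + 1L, e) else ""
  if (gene$strand == "-") {
    seq <- if (nzchar(seq)) revcomp(seq) else seq
    tls_offset <- (e - 1L) - t
  } else {
    tls_offset <- t - s
  }
  structure(list(id = gene$gene_id, contig_id = gene$contig_id,
                 start = s, end = e, strand = gene$strand, seq = seq,
                 tls_offset = tls_offset),
            class = "promoter_region")
}

#' Intergenic distances between consecutive genes
#'
#' For every pair of genes adjacent in genome order on the same contig
#' (regardless of strand), `distance = start(next) - end(prev)`; negative for
#' overlapping genes. Pairs never span contigs.
#'
#' @param genome An [annotated_genome].
#' @return `data.frame` with columns `gene_a`, `gene_b`, `contig_id`,
#'   `distance` (possibly zero rows).
#' @export
intergenic_distances <- function(genome) {
  g <- genome$genes
  out <- lapply(split(seq_len(nrow(g)), g$contig_id), function(idx) {
    if (length(idx) < 2) return(NULL)
    idx <- idx[order(g$start[idx])]
    a <- idx[-length(idx)]
    b <- idx[-1]
    data.frame(gene_a = g$gene_id[a], gene_b = g$gene_id[b],
               contig_id = g$contig_id[a],
               distance = g$start[b] - g$end[a],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      contig_id = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Export promoter regions as FASTA
#'
#' Headers follow `>{id}|{contig}:{start}-{end}({strand})`.
#'
#' @param promoters List of `promoter_region` objects.
#' @param path Output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- vapply(promoters, `[[`, character(1), "seq")
  hdr <- vapply(promoters, function(p) {
    sprintf("%s|%s:%d-%d(%s)", p$id, p$contig_id, p$start, p$end, p$strand)
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- hdr
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}
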