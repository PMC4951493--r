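# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Integer encoding used by the scanners: A=1, C=2, G=3, T=4, anything else
# (ambiguity codes, currently only N is expected in assemblies) = 5.
dna_to_int <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  x[is.na(x)] <- 5L
  x
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", toupper(seqs))
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(toupper(seqs))
}

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(seq, id = "protein") {
  if (is.na(seq) || !nzchar(seq)) {
    stop(sprintf("empty protein sequence for %s", id), call. = FALSE)
  }
  seq <- sub("\\*$", "", toupper(seq))
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), AA_CANONICAL)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-canonical residues: %s", id,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  seq
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
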