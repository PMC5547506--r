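#' @keywords internal
"_PACKAGE"

#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement matchPattern quality
#'   QualityScaledDNAStringSet PhredQuality
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom BiocGenerics start end width
#' @importFrom methods is as
#' @importFrom S4Vectors mcols `mcols<-`
#' @importFrom IRanges IRanges
#' @importFrom stats rpois runif rnorm wilcox.test kruskal.test p.adjust
#'   pnorm lm coef
#' @importFrom utils head tail write.table read.table
NULL

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards so simulations do not perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' A, C, G, T, N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based start positions of every (possibly overlapping) occurrence of
# `motif` in the sequence string `seq`.
motif_starts <- function(seq, motif) {
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  BiocGenerics::start(m) - 1L
}

is_palindromic_motif <- function(motif) {
  identical(motif, revcomp(motif))
}

validate_motif <- function(motif, what = "motif") {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop(what, " must be a non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", motif))
    stop(what, " may contain only A, C, G, T", call. = FALSE)
  invisible(motif)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (plain text, wrapped or unwrapped).
#' @param assembly_label free-text label stored with the genome.
#' @return a [Biostrings::DNAStringSet] with an `assembly_label` attribute.
#' @export
read_genome <- function(path, assembly_label = basename(path)) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  validate_genome(g)
  attr(g, "assembly_label") <- assembly_label
  g
}

#' Write a genome to FASTA
#'
#' @param genome a `DNAStringSet` (or named character vector of sequences).
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

# Coerce a named character vector to DNAStringSet, passing sets through.
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stop("genome sequences must be named by chromosome", call. = FALSE)
    genome <- Biostrings::DNAStringSet(genome)
  }
  validate_genome(genome)
  genome
}

validate_genome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet", call. = FALSE)
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("chromosome names must be unique and non-empty", call. = FALSE)
  if (any(BiocGenerics::width(genome) == 0L))
    stop("chromosome sequences must be non-empty", call. = FALSE)
  letters <- Biostrings::uniqueLetters(genome)
  if (!all(letters %in% c("A", "C", "G", "T", "N")))
    stop("genome alphabet restricted to A, C, G, T, N", call. = FALSE)
  invisible(genome)
}

# Plain-character view of one chromosome (cached conversions are cheap at
# the genome sizes this package targets).
chrom_string <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  as.character(genome[[chrom]])
}
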