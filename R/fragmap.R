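#' In-silico double restriction digestion
#'
#' Cuts every chromosome immediately before each occurrence of the
#' first-cutter motif (NlaIII's CATG by default), so that every non-initial
#' fragment begins with the motif — the convention under which 4C read
#' prefixes align to fragment starts. Each fragment is additionally flagged
#' for the presence of the second-cutter motif (DpnII's GATC by default).
#'
#' Both default motifs are palindromic, so a forward scan covers both
#' strands; for non-palindromic user motifs, cut sites from the reverse
#' complement occurrences are included as well.
#'
#' @param genome a `DNAStringSet` (or named character vector) of chromosome
#'   sequences; see [read_genome()].
#' @param first_motif recognition sequence of the fragmenting enzyme.
#' @param second_motif recognition sequence of the secondary enzyme,
#'   recorded as a per-fragment flag.
#' @return a `fragment_map`: a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), `index` (0-based rank within chromosome)
#'   and `has_second_cutter`, with the motifs and chromosome lengths kept
#'   as attributes.
#' @examples
#' g <- c(chrA = "AAACATGTTTTTGATCCATGAA")
#' digest(g)
#' @export
digest <- function(genome, first_motif = "CATG", second_motif = "GATC") {
  validate_motif(first_motif, "first_motif")
  validate_motif(second_motif, "second_motif")
  genome <- as_genome(genome)

  per_chrom <- lapply(names(genome), function(chrom) {
    seq <- chrom_string(genome, chrom)
    L <- nchar(seq)
    occ <- motif_starts(seq, first_motif)
    if (!is_palindromic_motif(first_motif))
      occ <- sort(unique(c(occ, motif_starts(seq, revcomp(first_motif)))))
    cuts <- unique(c(0L, occ))
    starts <- cuts
    ends <- c(cuts[-1L], L)

    occ2 <- motif_starts(seq, second_motif)
    if (!is_palindromic_motif(second_motif))
      occ2 <- sort(unique(c(occ2, motif_starts(seq, revcomp(second_motif)))))
    # a fragment carries the flag iff one occurrence lies fully inside it
    k2 <- nchar(second_motif)
    has2 <- logical(length(starts))
    if (length(occ2)) {
      frag_of <- findInterval(occ2, starts)         # 1-based fragment rank
      inside <- occ2 + k2 <= ends[frag_of]
      has2[unique(frag_of[inside])] <- TRUE
    }
    data.frame(chrom = chrom, start = starts, end = ends,
               index = seq_along(starts) - 1L, has_second_cutter = has2,
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, per_chrom)
  new_fragment_map(frags, first_motif, second_motif,
                   stats::setNames(BiocGenerics::width(genome), names(genome)))
}

new_fragment_map <- function(frags, first_motif, second_motif, chrom_lengths) {
  rownames(frags) <- NULL
  structure(frags,
            first_motif = first_motif,
            second_motif = second_motif,
            chrom_lengths = chrom_lengths,
            class = c("fragment_map", "data.frame"))
}

validate_fragment_map <- function(map) {
  stopifnot(inherits(map, "fragment_map"))
  for (chrom in unique(map$chrom)) {
    f <- map[map$chrom == chrom, ]
    if (any(f$start >= f$end)) stop("empty fragment in map", call. = FALSE)
    if (!identical(f$index, seq_len(nrow(f)) - 1L))
      stop("fragment indices must be consecutive 0..n-1", call. = FALSE)
    if (is.unsorted(f$start, strictly = TRUE))
      stop("fragments must be sorted by start", call. = FALSE)
    if (any(f$start[-1L] != f$end[-nrow(f)]))
      stop("fragments must tile the chromosome without gaps", call. = FALSE)
  }
  invisible(map)
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d fragments on %d chromosome(s) [%s / %s]\n",
              nrow(x), length(unique(x$chrom)),
              attr(x, "first_motif"), attr(x, "second_motif")))
  NextMethod()
}

# Subset of the map for one chromosome, preserving attributes needed
# downstream.
chrom_fragments <- function(map, chrom) {
  f <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(f) == 0L) stop("unknown chromosome: ", chrom, call. = FALSE)
  f
}

#' Locate the fragment containing a position
#'
#' Binary-search lookup of the unique fragment whose half-open interval
#' contains `pos`.
#'
#' @param map a `fragment_map` from [digest()].
#' @param chrom chromosome name.
#' @param pos 0-based position(s); vectorised.
#' @return integer fragment index (0-based) for each position.
#' @export
locate <- function(map, chrom, pos) {
  f <- chrom_fragments(map, chrom)
  L <- f$end[nrow(f)]
  if (any(pos < 0L | pos >= L))
    stop("position out of range [0, ", L, ")", call. = FALSE)
  findInterval(pos, f$start) - 1L
}

#' Write/read a fragment map as BED
#'
#' Fragments are serialized as BED6 records (0-based half-open) with
#' `name` = fragment index and `score` = the second-cutter flag as 0/1.
#'
#' @param map a `fragment_map`.
#' @param path BED file path.
#' @return `read_fragments()` returns the reconstructed `fragment_map`.
#' @export
write_fragments <- function(map, path) {
  if (nrow(map) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = map$chrom,
    ranges = IRanges::IRanges(start = map$start + 1L, end = map$end),
    name = as.character(map$index),
    score = as.integer(map$has_second_cutter))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @param first_motif,second_motif motifs to record on the reconstructed
#'   map (the BED itself does not carry them).
#' @rdname write_fragments
#' @export
read_fragments <- function(path, first_motif = "CATG", second_motif = "GATC") {
  if (file.size(path) == 0L) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), index = integer(),
                        has_second_cutter = logical())
    return(new_fragment_map(empty, first_motif, second_motif, integer(0)))
  }
  gr <- rtracklayer::import(path, format = "BED")
  frags <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    index = as.integer(gr$name),
    has_second_cutter = as.logical(gr$score),
    stringsAsFactors = FALSE)
  # keep the file's chromosome order (no lexicographic reshuffle)
  frags <- frags[order(match(frags$chrom, unique(frags$chrom)),
                       frags$start), ]
  for (chrom in unique(frags$chrom)) {
    f <- frags[frags$chrom == chrom, ]
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
      stop("overlapping BED intervals", call. = FALSE)
  }
  lens <- tapply(frags$end, frags$chrom, max)
  map <- new_fragment_map(frags, first_motif, second_motif,
                          lens[unique(frags$chrom)])
  validate_fragment_map(map)
  map
}
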