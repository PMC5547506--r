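# Exact-match mapping of first-cutter-anchored query sequences.
#
# Every query handled by the 4C pipelines begins with the first-cutter motif
# (CATG), and every occurrence of such a query in the genome — forward or as
# a reverse complement — must align a CATG to a cut site. Candidate loci are
# therefore enumerable: forward candidates start at a cut site; reverse
# candidates end 4 bp past one (the palindromic CATG read on the minus
# strand). The index hashes a fixed-length key at every candidate locus and
# verifies candidates by full substring comparison, giving genome-wide
# exact-occurrence counts without a sliding scan. Semantics are identical
# to matching the query and its reverse complement over the whole genome
# (tested against Biostrings::matchPattern).

ANCHOR_KEY_LEN <- 20L

#' Build an exact-match index over first-cutter sites
#'
#' @param genome a `DNAStringSet` or named character vector.
#' @param map the `fragment_map` from [digest()] of the same genome.
#' @return an opaque index object consumed by [map_segment()] and
#'   [assign_reads()].
#' @export
capture_index <- function(genome, map) {
  genome <- as_genome(genome)
  motif <- attr(map, "first_motif")
  k <- ANCHOR_KEY_LEN
  klen <- nchar(motif)
  entries <- list()
  seqs <- list()
  for (chrom in unique(map$chrom)) {
    s <- chrom_string(genome, chrom)
    L <- nchar(s)
    seqs[[chrom]] <- s
    f <- chrom_fragments(map, chrom)
    # anchor sites: every cut position, including 0 iff the chromosome
    # itself starts with the motif
    anchors <- f$start[-1L]
    if (startsWith(s, motif)) anchors <- c(0L, anchors)
    if (length(anchors) == 0L) next
    fa <- anchors[anchors + k <= L]
    fwd <- if (length(fa)) {
      data.frame(key = substring(s, fa + 1L, fa + k),
                 chrom = chrom, anchor = fa, orient = "+",
                 stringsAsFactors = FALSE)
    } else NULL
    ra <- anchors[anchors + klen - k >= 0L]
    rev <- if (length(ra)) {
      data.frame(key = revcomp(substring(s, ra + klen - k + 1L, ra + klen)),
                 chrom = chrom, anchor = ra, orient = "-",
                 stringsAsFactors = FALSE)
    } else NULL
    entries[[chrom]] <- rbind(fwd, rev)
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(key = character(), chrom = character(),
               anchor = integer(), orient = character())
  structure(list(entries = entries,
                 lookup = split(seq_len(nrow(entries)), entries$key),
                 seqs = seqs,
                 motif = motif,
                 map = map),
            class = "capture_index")
}

# Count and localise the exact occurrences (both strands) of a single
# CATG-prefixed query. Returns a data.frame of hits (chrom, pos, strand).
index_hits <- function(idx, query) {
  k <- ANCHOR_KEY_LEN
  n <- nchar(query)
  if (n < k) return(NULL)
  cand <- idx$lookup[[substr(query, 1L, k)]]
  if (is.null(cand)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  }
  e <- idx$entries[cand, , drop = FALSE]
  klen <- nchar(idx$motif)
  hits <- lapply(seq_len(nrow(e)), function(i) {
    s <- idx$seqs[[e$chrom[i]]]
    L <- nchar(s)
    if (e$orient[i] == "+") {
      p <- e$anchor[i]
      if (p + n <= L && substring(s, p + 1L, p + n) == query)
        return(data.frame(chrom = e$chrom[i], pos = p, strand = "+"))
    } else {
      p <- e$anchor[i] + klen - n
      if (p >= 0L && revcomp(substring(s, p + 1L, p + n)) == query)
        return(data.frame(chrom = e$chrom[i], pos = p, strand = "-"))
    }
    NULL
  })
  hits <- Filter(Negate(is.null), hits)
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), pos = integer(), strand = character())
}

#' Map a read segment by unique exact match
#'
#' A segment maps iff it (or its reverse complement) occurs exactly once in
#' the genome and is at least `min_len` long; otherwise it is unmapped.
#' Mirrors unique-alignment (`-m 1`) semantics for error-free reads.
#'
#' @param segment DNA string (one segment).
#' @param idx a [capture_index()], or a genome for direct scanning.
#' @param min_len minimum mappable segment length.
#' @return a one-row data.frame `(chrom, pos, strand, fragment_index)` or
#'   `NULL` if unmapped. `pos` is the leftmost 0-based mapped coordinate and
#'   `fragment_index` the fragment containing it.
#' @export
map_segment <- function(segment, idx, min_len = 20L) {
  if (is.null(segment) || is.na(segment) || nchar(segment) < min_len)
    return(NULL)
  if (inherits(idx, "capture_index") && startsWith(segment, idx$motif) &&
      nchar(segment) >= ANCHOR_KEY_LEN) {
    hits <- index_hits(idx, segment)
  } else {
    hits <- scan_hits(segment, idx)
  }
  if (is.null(hits) || nrow(hits) != 1L) return(NULL)
  map <- if (inherits(idx, "capture_index")) idx$map else attr(idx, "map")
  hits$fragment_index <- if (!is.null(map))
    locate(map, hits$chrom, hits$pos) else NA_integer_
  hits
}

# Fallback full scan (both strands) for segments without the motif prefix;
# also the independent route used to validate the anchored index.
scan_hits <- function(segment, idx) {
  genome <- if (inherits(idx, "capture_index"))
    Biostrings::DNAStringSet(unlist(idx$seqs)) else as_genome(idx)
  rc <- revcomp(segment)
  out <- lapply(names(genome), function(chrom) {
    subj <- genome[[chrom]]
    fw <- BiocGenerics::start(Biostrings::matchPattern(segment, subj)) - 1L
    rv <- BiocGenerics::start(Biostrings::matchPattern(rc, subj)) - 1L
    rbind(
      if (length(fw)) data.frame(chrom = chrom, pos = fw, strand = "+"),
      if (length(rv)) data.frame(chrom = chrom, pos = rv, strand = "-"))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), strand = character())
}
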