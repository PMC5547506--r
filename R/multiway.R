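# Tripartite-contact detection from long (250-bp) single-end 4C reads.
#
# A read that traversed two ligation junctions contains three restriction
# fragments: the viewpoint (removed up to its CATG), a "mid" segment (X)
# and a "third" segment (Y). The pipeline demultiplexes by exact barcode,
# strips the viewpoint primer, quality/adapter-trims, splits at the first
# internal CATG, maps both segments by unique exact match (rescuing a
# failed third by re-splitting), drops undigested collinear products,
# deduplicates on the exact position+strand 6-tuple, and accumulates the
# surviving unique viewpoint-X-Y triples into a symmetric binned matrix.

#' Demultiplex reads by exact barcode prefix
#'
#' @param reads a reads data.frame `(id, sequence, quality)`.
#' @param barcodes named character vector `sample -> barcode` (or an
#'   unnamed vector; samples are then named S1, S2, ...). Barcodes must be
#'   equal length and pairwise distinct; matching is exact with the
#'   barcode removed from assigned reads.
#' @return named list of per-sample reads data.frames plus an
#'   `"unassigned"` element.
#' @export
demultiplex <- function(reads, barcodes) {
  if (anyDuplicated(barcodes))
    stop("duplicate barcode in table", call. = FALSE)
  if (length(unique(nchar(barcodes))) > 1L)
    stop("barcodes must have equal length", call. = FALSE)
  if (is.null(names(barcodes)))
    names(barcodes) <- paste0("S", seq_along(barcodes))
  bw <- nchar(barcodes[1L])
  prefix <- substr(reads$sequence, 1L, bw)
  hit <- match(prefix, barcodes)
  out <- lapply(seq_along(barcodes), function(i) {
    r <- reads[which(hit == i), , drop = FALSE]
    r$sequence <- substring(r$sequence, bw + 1L)
    r$quality <- substring(r$quality, bw + 1L)
    rownames(r) <- NULL
    r
  })
  names(out) <- names(barcodes)
  out$unassigned <- reads[is.na(hit), , drop = FALSE]
  out
}

#' Strip the viewpoint primer, keeping the first CATG
#'
#' Removes everything up to (but not including) the first CATG that
#' follows the viewpoint primer tag at the start of the read. Reads that
#' do not start with the tag, or have no CATG after it, are discarded.
#'
#' @param reads a per-sample reads data.frame.
#' @param vp a [viewpoint_spec()].
#' @return `list(reads, n_discarded)`.
#' @export
strip_viewpoint <- function(reads, vp) {
  tag <- vp$primer_tag
  ok <- startsWith(reads$sequence, tag)
  rest <- substring(reads$sequence, nchar(tag) + 1L)
  catg <- regexpr("CATG", rest, fixed = TRUE)
  keep <- ok & catg > 0L
  cut_at <- nchar(tag) + catg          # 1-based position of the kept CATG
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substring(out$sequence, cut_at[keep])
  out$quality <- substring(out$quality, cut_at[keep])
  rownames(out) <- NULL
  list(reads = out, n_discarded = sum(!keep))
}

# 3' quality trimming: walking from the 3' end, accumulate
# (q_threshold - q); the removed suffix is the maximal one over which the
# running sum stays positive.
quality_trim_length <- function(quals, q_threshold = 10L) {
  q <- utf8ToInt(quals) - 33L
  n <- length(q)
  s <- 0
  cut <- n + 1L
  for (j in rev(seq_len(n))) {
    s <- s + (q_threshold - q[j])
    if (s > 0) cut <- j else break
  }
  cut - 1L                            # kept length
}

#' Quality- and adapter-trim stripped reads
#'
#' 3' low-quality tails are removed by the running-sum rule (threshold
#' `q_threshold`), then each read is truncated at the first occurrence of
#' the second-cutter adapter (GATC and everything 3' of it removed).
#' Reads shorter than `min_len` after trimming are discarded.
#'
#' @param reads a per-sample reads data.frame (post [strip_viewpoint()]).
#' @param q_threshold Phred quality threshold.
#' @param adapter adapter sequence to truncate at.
#' @param min_len minimum retained read length.
#' @return `list(reads, n_discarded)`.
#' @export
trim_reads <- function(reads, q_threshold = 10L, adapter = "GATC",
                       min_len = 24L) {
  if (nrow(reads) == 0L) return(list(reads = reads, n_discarded = 0L))
  # fast path: reads whose final base passes the threshold lose nothing
  last_q <- utf8ToInt(paste0(substr(reads$quality,
                                    nchar(reads$quality),
                                    nchar(reads$quality)), collapse = "")) - 33L
  keep_len <- nchar(reads$sequence)
  recheck <- which(last_q < q_threshold)
  for (i in recheck)
    keep_len[i] <- quality_trim_length(reads$quality[i], q_threshold)
  seqs <- substr(reads$sequence, 1L, keep_len)
  ad <- regexpr(adapter, seqs, fixed = TRUE)
  keep_len <- ifelse(ad > 0L, ad - 1L, nchar(seqs))
  out <- reads
  out$sequence <- substr(seqs, 1L, keep_len)
  out$quality <- substr(reads$quality, 1L, keep_len)
  long_enough <- nchar(out$sequence) >= min_len
  list(reads = out[long_enough, , drop = FALSE],
       n_discarded = sum(!long_enough))
}

#' Split a read at its first internal ligation junction
#'
#' @param sequence read sequence(s) beginning with CATG; vectorised.
#' @return data.frame with columns `mid` and `third` (`NA` when the read
#'   has no internal CATG). The third begins with CATG.
#' @export
split_read <- function(sequence) {
  inner <- regexpr("CATG", substring(sequence, 2L), fixed = TRUE)
  pos <- ifelse(inner > 0L, inner + 1L, NA_integer_)  # 1-based split point
  data.frame(mid = ifelse(is.na(pos), sequence,
                          substr(sequence, 1L, pos - 1L)),
             third = ifelse(is.na(pos), NA_character_,
                            substring(sequence, pos)),
             stringsAsFactors = FALSE)
}

#' Rescue an unmapped third segment
#'
#' Re-splits the third at its first internal CATG and maps only the 5'
#' part; returns the hit or `NULL` if there is no internal CATG or the 5'
#' part still fails to map uniquely.
#'
#' @param third the third segment sequence.
#' @param idx a [capture_index()] (or genome).
#' @param min_len minimum mappable length.
#' @return a segment hit data.frame or `NULL`.
#' @export
rescue_third <- function(third, idx, min_len = 20L) {
  inner <- regexpr("CATG", substring(third, 2L), fixed = TRUE)
  if (inner <= 0L) return(NULL)
  map_segment(substr(third, 1L, inner), idx, min_len = min_len)
}

#' Undigested-product test for a mapped segment pair
#'
#' A mid/third pair is an undigested (incomplete digestion) artifact iff
#' the third is the collinear genomic continuation of the mid: same
#' chromosome, same strand, and the next fragment downstream in read
#' orientation (index + 1 on the plus strand, index - 1 on the minus
#' strand). With `strand_aware = FALSE`, any same-chromosome pair of
#' adjacent fragments (|Δindex| = 1) is dropped regardless of strand.
#'
#' @param mid,third one-row segment-hit data.frames from [map_segment()].
#' @param strand_aware use the collinear (strand-aware) rule.
#' @return `TRUE` if the pair should be dropped as undigested.
#' @export
is_undigested <- function(mid, third, strand_aware = TRUE) {
  if (mid$chrom != third$chrom) return(FALSE)
  if (!strand_aware)
    return(abs(third$fragment_index - mid$fragment_index) == 1L)
  if (mid$strand != third$strand) return(FALSE)
  off <- if (mid$strand == "+") 1L else -1L
  third$fragment_index == mid$fragment_index + off
}

#' Deduplicate tripartite contacts
#'
#' Contacts are grouped by the exact 6-tuple (X chrom/pos/strand, Y
#' chrom/pos/strand); the first occurrence of each group is kept, in
#' first-occurrence order — the positional PCR-duplicate removal of the
#' multiway protocol.
#'
#' @param contacts a contacts data.frame with columns `x_chrom, x_pos,
#'   x_strand, y_chrom, y_pos, y_strand` (extra columns pass through).
#' @return the deduplicated contacts data.frame.
#' @export
deduplicate <- function(contacts) {
  if (nrow(contacts) == 0L) return(contacts)
  key <- paste(contacts$x_chrom, contacts$x_pos, contacts$x_strand,
               contacts$y_chrom, contacts$y_pos, contacts$y_strand)
  out <- contacts[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin unique contacts into a symmetric matrix
#'
#' Contacts with both partners inside `region` are assigned to
#' `binsize`-bp bins (`floor((pos - start)/binsize)`); cell `[i, j]` and
#' its mirror are incremented once per contact (the diagonal once when
#' both partners share a bin).
#'
#' @param contacts deduplicated contacts data.frame.
#' @param region `list(chrom, start, end)` analysis region.
#' @param binsize bin width in bp.
#' @return a `tripartite_matrix`: list with the symmetric integer
#'   `matrix`, `bin_starts`, `region`, `binsize` and the in-region
#'   `contacts`.
#' @export
build_matrix <- function(contacts, region, binsize = 20000L) {
  if (region$end <= region$start) stop("empty region", call. = FALSE)
  n_bins <- ceiling((region$end - region$start) / binsize)
  m <- matrix(0L, n_bins, n_bins)
  inside <- contacts$x_chrom == region$chrom &
    contacts$y_chrom == region$chrom &
    contacts$x_pos >= region$start & contacts$x_pos < region$end &
    contacts$y_pos >= region$start & contacts$y_pos < region$end
  kept <- contacts[inside, , drop = FALSE]
  if (nrow(kept)) {
    bi <- floor((kept$x_pos - region$start) / binsize) + 1L
    bj <- floor((kept$y_pos - region$start) / binsize) + 1L
    for (k in seq_along(bi)) {
      m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1L
      if (bi[k] != bj[k]) m[bj[k], bi[k]] <- m[bj[k], bi[k]] + 1L
    }
  }
  structure(list(matrix = m, region = region, binsize = as.integer(binsize),
                 bin_starts = region$start + (seq_len(n_bins) - 1L) * binsize,
                 contacts = kept),
            class = "tripartite_matrix")
}

#' Fraction of zone bins engaged in at least one tripartite contact
#'
#' @param tm a [build_matrix()] result.
#' @param zone `list(start, end)` interval inside the matrix region; zone
#'   bins are those whose interval overlaps it.
#' @return percentage (0-100) of zone bins whose matrix row has a nonzero
#'   entry.
#' @export
zone_fraction <- function(tm, zone) {
  bs <- tm$bin_starts
  be <- bs + tm$binsize
  zone_bins <- which(bs < zone$end & be > zone$start)
  if (length(zone_bins) == 0L) stop("zone covers no bin", call. = FALSE)
  touched <- rowSums(tm$matrix[zone_bins, , drop = FALSE] > 0L) > 0L
  100 * sum(touched) / length(zone_bins)
}

#' Run the full multiway pipeline
#'
#' Demultiplex, strip, trim, split, map (with third rescue), filter
#' undigested products, deduplicate per sample, and classify every input
#' read into exactly one QC class.
#'
#' @param reads the 250-bp library reads data.frame.
#' @param map a `fragment_map`.
#' @param genome the genome (or a prebuilt [capture_index()]).
#' @param vp a [viewpoint_spec()].
#' @param barcodes sample barcodes (see [demultiplex()]).
#' @param min_len minimum mappable segment length.
#' @param min_read_len minimum read length after trimming.
#' @param q_threshold quality-trim threshold.
#' @param strand_aware_undigested collinear undigested rule (see
#'   [is_undigested()]).
#' @return list with `contacts` (per-sample deduplicated tripartite
#'   contacts, rbind-ed with a `sample` column), `all_contacts` (before
#'   deduplication), `dropped_undigested` (read ids), and `qc` (read
#'   class counts summing to the input).
#' @export
run_multiway <- function(reads, map, genome, vp, barcodes,
                         min_len = 20L, min_read_len = 24L,
                         q_threshold = 10L,
                         strand_aware_undigested = TRUE) {
  idx <- if (inherits(genome, "capture_index")) genome else
    capture_index(genome, map)
  bins <- demultiplex(reads, barcodes)
  qc <- c(unassigned = nrow(bins$unassigned), no_primer = 0L,
          too_short = 0L, mid_unmapped = 0L, third_missing = 0L,
          third_unmapped = 0L, undigested = 0L, duplicate = 0L,
          unique_contact = 0L)
  contacts <- list()
  all_contacts <- list()
  dropped_undig <- character()
  samples <- setdiff(names(bins), "unassigned")
  seg_cache <- new.env(parent = emptyenv())
  cached_map <- function(seg) {
    if (is.null(seg) || is.na(seg)) return(NULL)
    if (!is.null(h <- seg_cache[[seg]])) return(if (is.logical(h)) NULL else h)
    h <- map_segment(seg, idx, min_len = min_len)
    seg_cache[[seg]] <- if (is.null(h)) FALSE else h
    h
  }
  for (sample in samples) {
    stripped <- strip_viewpoint(bins[[sample]], vp)
    qc["no_primer"] <- qc["no_primer"] + stripped$n_discarded
    trimmed <- trim_reads(stripped$reads, q_threshold = q_threshold,
                          min_len = min_read_len)
    qc["too_short"] <- qc["too_short"] + trimmed$n_discarded
    r <- trimmed$reads
    if (nrow(r) == 0L) next
    parts <- split_read(r$sequence)
    n_r <- nrow(r)
    keep <- logical(n_r)
    xh <- yh <- vector("list", n_r)
    for (i in seq_len(n_r)) {
      mid_hit <- cached_map(parts$mid[i])
      if (is.null(mid_hit)) { qc["mid_unmapped"] <- qc["mid_unmapped"] + 1L; next }
      if (is.na(parts$third[i])) {
        qc["third_missing"] <- qc["third_missing"] + 1L; next
      }
      third_hit <- cached_map(parts$third[i])
      if (is.null(third_hit))
        third_hit <- rescue_third(parts$third[i], idx, min_len = min_len)
      if (is.null(third_hit)) {
        qc["third_unmapped"] <- qc["third_unmapped"] + 1L; next
      }
      if (is_undigested(mid_hit, third_hit,
                        strand_aware = strand_aware_undigested)) {
        qc["undigested"] <- qc["undigested"] + 1L
        dropped_undig <- c(dropped_undig, r$id[i])
        next
      }
      keep[i] <- TRUE
      xh[[i]] <- mid_hit
      yh[[i]] <- third_hit
    }
    sc <- if (any(keep)) {
      ki <- which(keep)
      data.frame(
        read_id = r$id[ki], sample = sample, viewpoint = vp$name,
        x_chrom = vapply(xh[ki], `[[`, "", "chrom"),
        x_pos = vapply(xh[ki], `[[`, 0L, "pos"),
        x_strand = vapply(xh[ki], `[[`, "", "strand"),
        x_index = vapply(xh[ki], `[[`, 0L, "fragment_index"),
        y_chrom = vapply(yh[ki], `[[`, "", "chrom"),
        y_pos = vapply(yh[ki], `[[`, 0L, "pos"),
        y_strand = vapply(yh[ki], `[[`, "", "strand"),
        y_index = vapply(yh[ki], `[[`, 0L, "fragment_index"),
        stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(sc)) {
      uniq <- deduplicate(sc)
      qc["duplicate"] <- qc["duplicate"] + (nrow(sc) - nrow(uniq))
      qc["unique_contact"] <- qc["unique_contact"] + nrow(uniq)
      all_contacts[[sample]] <- sc
      contacts[[sample]] <- uniq
    }
  }
  empty <- data.frame(read_id = character(), sample = character(),
                      viewpoint = character(), x_chrom = character(),
                      x_pos = integer(), x_strand = character(),
                      x_index = integer(), y_chrom = character(),
                      y_pos = integer(), y_strand = character(),
                      y_index = integer(), stringsAsFactors = FALSE)
  list(contacts = if (length(contacts)) do.call(rbind, c(contacts,
                                                         make.row.names = FALSE))
       else empty,
       all_contacts = if (length(all_contacts))
         do.call(rbind, c(all_contacts, make.row.names = FALSE)) else empty,
       dropped_undigested = dropped_undig,
       qc = as.list(qc))
}

#' Write a tripartite matrix as TSV
#'
#' Tab-delimited `n_bins x n_bins` counts with a header row of bin start
#' coordinates.
#'
#' @param tm a `tripartite_matrix`.
#' @param path output file.
#' @export
write_matrix <- function(tm, path) {
  m <- tm$matrix
  colnames(m) <- tm$bin_starts
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
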