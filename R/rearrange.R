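# Engineered deletion/inversion alleles and wild-type coordinate liftover.
#
# Alleles are single exact half-open edits of the reference: a deletion
# removes [start, end); an inversion replaces it by its reverse
# complement. The coordinate map is the position bijection between the
# mutant and wild-type frames, with an orientation flag inside inverted
# segments.

#' Rearrangement specification
#'
#' @param name allele name (e.g. "del-1", "invTpSB1-Itga6").
#' @param kind `"deletion"` or `"inversion"`.
#' @param chrom chromosome.
#' @param start,end wild-type breakpoints, 0-based half-open.
#' @return a `rearrangement_spec` list.
#' @export
rearrangement_spec <- function(name, kind = c("deletion", "inversion"),
                               chrom, start, end) {
  kind <- match.arg(kind)
  stopifnot(start < end, start >= 0)
  structure(list(name = name, kind = kind, chrom = chrom,
                 start = as.integer(start), end = as.integer(end)),
            class = "rearrangement_spec")
}

#' Read/write a rearrangement spec as JSON
#' @param spec a [rearrangement_spec()].
#' @param path JSON file.
#' @export
write_rearrangement <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rearrangement
#' @export
read_rearrangement <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rearrangement_spec(x$name, x$kind, x$chrom, x$start, x$end)
}

#' Apply a deletion or inversion to a genome
#'
#' @param genome a `DNAStringSet` or named character vector.
#' @param spec a [rearrangement_spec()].
#' @return `list(genome, cmap)`: the mutant genome and the
#'   `coordinate_map` between frames.
#' @export
apply_rearrangement <- function(genome, spec) {
  genome <- as_genome(genome)
  if (!spec$chrom %in% names(genome))
    stop("unknown chromosome: ", spec$chrom, call. = FALSE)
  s <- chrom_string(genome, spec$chrom)
  L <- nchar(s)
  if (spec$end > L) stop("interval out of bounds", call. = FALSE)
  prefix <- substring(s, 1L, spec$start)          # [0, start)
  segment <- substring(s, spec$start + 1L, spec$end)
  suffix <- substring(s, spec$end + 1L, L)
  mut <- if (spec$kind == "deletion") paste0(prefix, suffix) else
    paste0(prefix, revcomp(segment), suffix)
  out <- as.character(genome)
  names(out) <- names(genome)
  out[spec$chrom] <- mut
  mutant <- Biostrings::DNAStringSet(out)
  attr(mutant, "assembly_label") <-
    paste0(attr(genome, "assembly_label"), "+", spec$name)
  cmap <- structure(list(spec = spec, wt_length = L,
                         mut_length = nchar(mut)),
                    class = "coordinate_map")
  list(genome = mutant, cmap = cmap)
}

#' Lift wild-type positions to the mutant frame
#'
#' @param cmap a `coordinate_map` from [apply_rearrangement()].
#' @param pos 0-based wild-type positions (vectorised).
#' @return integer mutant positions; `NA` for deleted positions.
#' @export
lift_forward <- function(cmap, pos) {
  sp <- cmap$spec
  if (any(pos < 0 | pos >= cmap$wt_length))
    stop("position outside wild-type chromosome", call. = FALSE)
  if (sp$kind == "deletion") {
    out <- ifelse(pos < sp$start, pos,
                  ifelse(pos < sp$end, NA_integer_,
                         pos - (sp$end - sp$start)))
  } else {
    out <- ifelse(pos >= sp$start & pos < sp$end,
                  sp$start + sp$end - 1L - pos, pos)
  }
  as.integer(out)
}

#' Lift mutant positions back to the wild-type frame
#'
#' @param cmap a `coordinate_map`.
#' @param pos 0-based mutant positions (vectorised).
#' @return data.frame `(wt_pos, flipped)`; `flipped` is `TRUE` inside an
#'   inverted segment.
#' @export
lift_backward <- function(cmap, pos) {
  sp <- cmap$spec
  if (any(pos < 0 | pos >= cmap$mut_length))
    stop("position outside mutant chromosome", call. = FALSE)
  if (sp$kind == "deletion") {
    wt <- ifelse(pos < sp$start, pos, pos + (sp$end - sp$start))
    flipped <- rep(FALSE, length(pos))
  } else {
    inside <- pos >= sp$start & pos < sp$end
    wt <- ifelse(inside, sp$start + sp$end - 1L - pos, pos)
    flipped <- inside
  }
  data.frame(wt_pos = as.integer(wt), flipped = flipped)
}

#' Project a mutant-frame profile onto the wild-type axis
#'
#' Each mutant fragment interval is mapped through the backward lift;
#' intervals spanning a breakpoint are split at it, inverted pieces appear
#' at reflected coordinates with `flipped = TRUE`, and the deleted
#' wild-type interval (for deletion alleles) is emitted as a no-data row
#' with `NA` score. Scores are carried unchanged.
#'
#' @param mutant_profile a `fragment_profile` computed on the mutant
#'   fragment map.
#' @param cmap the allele's `coordinate_map`.
#' @return data.frame `(chrom, wt_start, wt_end, score, flipped,
#'   mut_index)` sorted by wild-type position; deletion gaps have
#'   `mut_index = NA` and `score = NA`.
#' @export
lift_profile <- function(mutant_profile, cmap) {
  map <- mutant_profile$map
  sp <- cmap$spec
  on_chrom <- map$chrom == sp$chrom
  if (any(map$end[on_chrom] > cmap$mut_length))
    stop("profile map does not match the mutant genome", call. = FALSE)
  rows <- list()
  cutpoints <- if (sp$kind == "deletion") sp$start else c(sp$start, sp$end)
  for (i in which(on_chrom)) {
    s <- map$start[i]; e <- map$end[i]
    edges <- sort(unique(c(s, e, cutpoints[cutpoints > s & cutpoints < e])))
    for (k in seq_len(length(edges) - 1L)) {
      a <- edges[k]; b <- edges[k + 1L]
      lo <- lift_backward(cmap, a)
      hi <- lift_backward(cmap, b - 1L)
      wt_start <- min(lo$wt_pos, hi$wt_pos)
      wt_end <- max(lo$wt_pos, hi$wt_pos) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sp$chrom, wt_start = wt_start, wt_end = wt_end,
        score = mutant_profile$scores[i], flipped = lo$flipped,
        mut_index = map$index[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (sp$kind == "deletion") {
    out <- rbind(out, data.frame(chrom = sp$chrom, wt_start = sp$start,
                                 wt_end = sp$end, score = NA_real_,
                                 flipped = FALSE, mut_index = NA_integer_))
  }
  out <- out[order(out$wt_start, out$wt_end), ]
  rownames(out) <- NULL
  out
}

#' Write a liftover chain-like TSV
#'
#' One row per contiguous block: `wt_start, wt_end, mut_start, mut_end,
#' orientation`.
#'
#' @param cmap a `coordinate_map`.
#' @param path output file.
#' @export
write_chain <- function(cmap, path) {
  sp <- cmap$spec
  if (sp$kind == "deletion") {
    df <- data.frame(
      wt_start = c(0L, sp$end), wt_end = c(sp$start, cmap$wt_length),
      mut_start = c(0L, sp$start),
      mut_end = c(sp$start, cmap$mut_length),
      orientation = c("+", "+"))
  } else {
    df <- data.frame(
      wt_start = c(0L, sp$start, sp$end),
      wt_end = c(sp$start, sp$end, cmap$wt_length),
      mut_start = c(0L, sp$start, sp$end),
      mut_end = c(sp$start, sp$end, cmap$wt_length),
      orientation = c("+", "-", "+"))
  }
  df <- df[df$wt_end > df$wt_start, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
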