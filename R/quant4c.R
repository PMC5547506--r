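# Standard 4C-seq fragment-level quantification.
#
# Processing chain: read -> fragment counts (unique exact mapping),
# viewpoint exclusion (bait +/- 2 kb), normalization to reads per million,
# 11-fragment running-mean smoothing, bait-window (+/- 1 Mb) scaling, and
# an optional power-law distance-decay correction used to emphasise
# long-range signal. Replicates are combined by averaging.

#' Viewpoint (bait) specification
#'
#' @param name viewpoint name.
#' @param chrom chromosome.
#' @param bait_start,bait_end bait interval, 0-based half-open.
#' @param primer_tag the viewpoint primer sequence preceding the retained
#'   CATG at the start of each read.
#' @param exclusion_radius bp around the bait excluded from analysis.
#' @return a `viewpoint_spec` list.
#' @export
viewpoint_spec <- function(name, chrom, bait_start, bait_end, primer_tag,
                           exclusion_radius = 2000L) {
  stopifnot(bait_start < bait_end, exclusion_radius >= 0)
  structure(list(name = name, chrom = chrom,
                 bait_start = as.integer(bait_start),
                 bait_end = as.integer(bait_end),
                 primer_tag = primer_tag,
                 exclusion_radius = as.integer(exclusion_radius)),
            class = "viewpoint_spec")
}

#' Assign 4C reads to restriction fragments
#'
#' Each read's captured sequence (from the first CATG after the viewpoint
#' primer tag onward) is matched exactly against the genome on both
#' strands; a read increments the count of the fragment containing its
#' unique match position. Reads without the primer tag, with no match, or
#' with two or more matches are discarded and tallied.
#'
#' @param reads a reads data.frame `(id, sequence, quality)` (see
#'   [read_fastq()]); sequences may start with a sample barcode.
#' @param map a `fragment_map`.
#' @param vp a [viewpoint_spec()].
#' @param genome the genome (used to build the match index), or a
#'   prebuilt [capture_index()].
#' @return a `fragment_counts` object: per-fragment integer counts,
#'   `total_mapped`, QC tallies, the map and viewpoint.
#' @export
assign_reads <- function(reads, map, vp, genome) {
  idx <- if (inherits(genome, "capture_index")) genome else
    capture_index(genome, map)
  n_frag <- nrow(map)
  counts <- integer(n_frag)
  qc <- c(no_primer = 0L, unmatched = 0L, ambiguous = 0L, assigned = 0L)
  if (nrow(reads) > 0L) {
    tagpos <- regexpr(vp$primer_tag, reads$sequence, fixed = TRUE)
    has_tag <- tagpos > 0L
    qc["no_primer"] <- sum(!has_tag)
    rest <- substring(reads$sequence[has_tag],
                      tagpos[has_tag] + nchar(vp$primer_tag))
    catg <- regexpr("CATG", rest, fixed = TRUE)
    captured <- ifelse(catg > 0L, substring(rest, catg), "")
    qc["no_primer"] <- qc["no_primer"] + sum(catg <= 0L)
    captured <- captured[catg > 0L]
    # resolve unique sequences once; reads sharing a capture share a fate
    uc <- table(captured)
    useq <- names(uc)
    for (i in seq_along(useq)) {
      hit <- map_segment(useq[i], idx, min_len = 20L)
      nreads <- as.integer(uc[[i]])
      if (is.null(hit)) {
        amb <- nrow(index_hits(idx, useq[i]))
        if (!is.null(amb) && length(amb) && !is.na(amb) && amb >= 2L)
          qc["ambiguous"] <- qc["ambiguous"] + nreads
        else qc["unmatched"] <- qc["unmatched"] + nreads
      } else {
        row <- which(map$chrom == hit$chrom & map$index == hit$fragment_index)
        counts[row] <- counts[row] + nreads
        qc["assigned"] <- qc["assigned"] + nreads
      }
    }
  }
  structure(list(viewpoint = vp, counts = counts,
                 total_mapped = sum(counts), qc = as.list(qc),
                 map = map, excluded = logical(n_frag)),
            class = "fragment_counts")
}

#' Zero counts around the viewpoint
#'
#' Every fragment overlapping the bait interval extended by the exclusion
#' radius on each side is zeroed and flagged; `total_mapped` is recomputed
#' over the remaining fragments.
#'
#' @param counts a `fragment_counts`.
#' @param vp a [viewpoint_spec()]; defaults to the one stored in `counts`.
#' @return the updated `fragment_counts`.
#' @export
exclude_viewpoint <- function(counts, vp = counts$viewpoint) {
  map <- counts$map
  lo <- vp$bait_start - vp$exclusion_radius
  hi <- vp$bait_end + vp$exclusion_radius
  excl <- map$chrom == vp$chrom & map$start < hi & map$end > lo
  n_excluded <- sum(counts$counts[excl])
  counts$counts[excl] <- 0L
  counts$excluded <- counts$excluded | excl
  counts$total_mapped <- sum(counts$counts)
  counts$qc$viewpoint_excluded <- n_excluded
  counts
}

new_profile <- function(counts_or_profile, scores, stage, window = NA_integer_) {
  x <- counts_or_profile
  structure(list(viewpoint = x$viewpoint, scores = scores, stage = stage,
                 window = window, excluded = x$excluded, map = x$map),
            class = "fragment_profile")
}

STAGES <- c("normalized", "smoothed", "bait_normalized", "corrected",
            "averaged")

require_stage <- function(profile, allowed) {
  if (!profile$stage %in% allowed)
    stop("operation requires stage ", paste(allowed, collapse = "/"),
         ", got ", profile$stage, call. = FALSE)
  invisible(profile)
}

#' Normalize fragment counts to reads per million
#'
#' @param counts a `fragment_counts` (after [exclude_viewpoint()]).
#' @return a `fragment_profile` at stage `normalized`, in RPM units.
#' @export
normalize_total <- function(counts) {
  if (counts$total_mapped <= 0L)
    stop("no mapped reads to normalize against", call. = FALSE)
  new_profile(counts, counts$counts / counts$total_mapped * 1e6, "normalized")
}

#' Running-mean smoothing over fragments
#'
#' Centred running mean with an 11-fragment window by default, computed
#' independently per chromosome; windows shrink at chromosome edges so
#' every fragment keeps a defined value. Excluded fragments contribute 0
#' and stay flagged.
#'
#' @param profile a `fragment_profile` at stage `normalized`.
#' @param window odd window size in fragments.
#' @return the smoothed `fragment_profile`.
#' @export
smooth_profile <- function(profile, window = 11L) {
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  require_stage(profile, "normalized")
  half <- (window - 1L) %/% 2L
  out <- profile$scores
  for (chrom in unique(profile$map$chrom)) {
    sel <- which(profile$map$chrom == chrom)
    x <- profile$scores[sel]
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    out[sel] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  new_profile(profile, out, "smoothed", window = as.integer(window))
}

#' Scale a profile to its bait window
#'
#' Divides all scores by the mean score of non-excluded fragments whose
#' midpoint lies within the bait interval extended by `half_width` on each
#' side, so that the bait-window mean becomes 1. Used to put profiles from
#' different libraries on a comparable scale.
#'
#' @param profile a smoothed (or corrected) `fragment_profile`.
#' @param vp viewpoint; defaults to the profile's.
#' @param half_width window half-width in bp.
#' @return the scaled `fragment_profile` at stage `bait_normalized`.
#' @export
bait_normalize <- function(profile, vp = profile$viewpoint,
                           half_width = 1e6) {
  require_stage(profile, c("smoothed", "corrected"))
  map <- profile$map
  mid <- (map$start + map$end) / 2
  in_win <- map$chrom == vp$chrom & mid >= vp$bait_start - half_width &
    mid < vp$bait_end + half_width & !profile$excluded
  if (!any(in_win))
    stop("no non-excluded fragment in the bait window", call. = FALSE)
  m <- mean(profile$scores[in_win])
  if (m <= 0) stop("bait-window mean is zero", call. = FALSE)
  new_profile(profile, profile$scores / m, "bait_normalized",
              window = profile$window)
}

#' Power-law distance-decay correction
#'
#' Fits the expected decay `E(d) = exp(c) * d^(-alpha)` with the slope
#' fixed at `-alpha` — a one-parameter least-squares fit of
#' `log(score) + alpha*log(d)` over fragments with positive score and bait
#' distance inside `fit_range` — and divides each positive score by its
#' expectation. Zero scores stay zero. Emphasises long-range signal
#' relative to the genomic-distance background.
#'
#' @param profile a smoothed `fragment_profile`.
#' @param vp viewpoint; defaults to the profile's.
#' @param alpha decay exponent (1 = the standard reciprocal-distance law).
#' @param fit_range distances (bp) used for the fit.
#' @return the corrected `fragment_profile`.
#' @export
profile_correction <- function(profile, vp = profile$viewpoint, alpha = 1,
                               fit_range = c(5e3, 2e6)) {
  require_stage(profile, "smoothed")
  map <- profile$map
  mid <- (map$start + map$end) / 2
  bait_mid <- (vp$bait_start + vp$bait_end) / 2
  d <- ifelse(map$chrom == vp$chrom, abs(mid - bait_mid), NA_real_)
  fit <- !is.na(d) & profile$scores > 0 & d >= fit_range[1] & d <= fit_range[2]
  if (sum(fit) < 2L)
    stop("fewer than 2 fragments eligible for the decay fit", call. = FALSE)
  cc <- mean(log(profile$scores[fit]) + alpha * log(d[fit]))
  out <- profile$scores
  pos <- !is.na(d) & profile$scores > 0
  out[pos] <- profile$scores[pos] * pmax(d[pos], 1)^alpha / exp(cc)
  res <- new_profile(profile, out, "corrected", window = profile$window)
  res$fit_intercept <- cc
  res$fit_alpha <- alpha
  res
}

#' Average replicate profiles
#'
#' Element-wise arithmetic mean of profiles sharing map, viewpoint and
#' processing stage; the exclusion mask is the union of the inputs' masks.
#'
#' @param profiles list of `fragment_profile`s.
#' @return the averaged `fragment_profile` at stage `averaged`.
#' @export
average_replicates <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to average", call. = FALSE)
  stages <- vapply(profiles, `[[`, "", "stage")
  if (length(unique(stages)) != 1L)
    stop("profiles must share a processing stage", call. = FALSE)
  ns <- vapply(profiles, function(p) length(p$scores), integer(1))
  if (length(unique(ns)) != 1L)
    stop("profiles must share a fragment map", call. = FALSE)
  scores <- rowMeans(do.call(cbind, lapply(profiles, `[[`, "scores")))
  excl <- Reduce(`|`, lapply(profiles, `[[`, "excluded"))
  scores[excl] <- 0
  out <- new_profile(profiles[[1L]], scores, "averaged",
                     window = profiles[[1L]]$window)
  out$excluded <- excl
  out$source_stage <- stages[1L]
  out
}

#' Fitted log-log decay slope of a profile
#'
#' Ordinary least-squares slope of `log(score)` on `log(distance)` over
#' non-excluded fragments with positive score and bait distance inside
#' `fit_range`. A well-behaved 4C profile decays with slope close to -1.
#'
#' @inheritParams profile_correction
#' @return the fitted slope (a single number).
#' @export
decay_slope <- function(profile, vp = profile$viewpoint,
                        fit_range = c(5e3, 2e6)) {
  map <- profile$map
  mid <- (map$start + map$end) / 2
  bait_mid <- (vp$bait_start + vp$bait_end) / 2
  d <- ifelse(map$chrom == vp$chrom, abs(mid - bait_mid), NA_real_)
  sel <- !is.na(d) & profile$scores > 0 & !profile$excluded &
    d >= fit_range[1] & d <= fit_range[2]
  if (sum(sel) < 3L) stop("too few fragments for a slope fit", call. = FALSE)
  unname(coef(stats::lm(log(profile$scores[sel]) ~ log(d[sel])))[2L])
}

#' Write a profile stage as bedGraph
#'
#' @param profile a `fragment_profile`.
#' @param path output bedGraph file.
#' @export
write_bedgraph <- function(profile, path) {
  df <- data.frame(chrom = profile$map$chrom, start = profile$map$start,
                   end = profile$map$end, score = profile$scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s_%s",
                     profile$viewpoint$name, profile$stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
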