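# Region-level quantification and rank-based differential statistics.
#
# Fragment scores within named regions (regulatory islands, zones) are the
# unit of observation; groups are compared with two-sided Wilcoxon rank-sum
# tests under Benjamini-Hochberg correction across the tested region
# family, or with Kruskal-Wallis followed by Dunn's pairwise post test for
# three or more groups.

#' Named region set
#'
#' @param regions data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open) — e.g. regulatory islands I-V, GCR, or the X / W /
#'   XW quantification zones.
#' @return a validated `region_set` data.frame.
#' @export
region_set <- function(regions) {
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(regions)),
            !anyDuplicated(regions$name), all(regions$start < regions$end))
  structure(as.data.frame(regions), class = c("region_set", "data.frame"))
}

#' Read a region set from BED
#'
#' @param path BED file with the region name in column 4.
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  region_set(data.frame(name = gr$name,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = BiocGenerics::start(gr) - 1L,
                        end = BiocGenerics::end(gr),
                        stringsAsFactors = FALSE))
}

#' Fragment scores within a region
#'
#' Returns, in genomic order, the scores of all non-excluded fragments
#' whose midpoint lies in the region.
#'
#' @param profile a `fragment_profile` (smoothed, optionally corrected).
#' @param region `list(chrom, start, end)` or a one-row region data.frame.
#' @return numeric score vector.
#' @export
quantify_region <- function(profile, region) {
  map <- profile$map
  mid <- (map$start + map$end) / 2
  sel <- map$chrom == region$chrom & mid >= region$start &
    mid < region$end & !profile$excluded
  if (!any(sel))
    stop("region overlaps no non-excluded fragment", call. = FALSE)
  profile$scores[sel][order(map$start[sel])]
}

#' Per-fragment log2 ratios against a wild-type reference
#'
#' `log2(sample / mean(wild-type))` per fragment; fragments where either
#' the sample score or the wild-type mean is zero (or that are excluded)
#' are masked as `NA` rather than pseudocounted.
#'
#' @param sample a `fragment_profile`.
#' @param wt_profiles list of wild-type `fragment_profile`s on the same
#'   map and viewpoint.
#' @return numeric vector of log2 ratios with `NA` where undefined.
#' @export
log2_ratio <- function(sample, wt_profiles) {
  if (length(wt_profiles) == 0L)
    stop("at least one wild-type profile required", call. = FALSE)
  wt <- rowMeans(do.call(cbind, lapply(wt_profiles, `[[`, "scores")))
  out <- rep(NA_real_, length(sample$scores))
  ok <- sample$scores > 0 & wt > 0 & !sample$excluded
  out[ok] <- log2(sample$scores[ok] / wt[ok])
  out
}

#' Wilcoxon rank-sum tests per region with BH correction
#'
#' For each region, the two groups' score vectors are compared with a
#' two-sided Wilcoxon rank-sum test — exact when both groups have at most
#' `exact_max` tie-free observations, and the tie-corrected normal
#' approximation with continuity correction otherwise. P-values are
#' corrected across the region family by Benjamini-Hochberg, and calls
#' made at `alpha` on the adjusted values.
#'
#' @param groupA,groupB named lists of numeric score vectors (one entry
#'   per region, shared names).
#' @param alpha significance threshold reported in the `call` column.
#' @param exact_max maximum per-group size for the exact test.
#' @return data.frame `(region, n_A, n_B, mean_A, mean_B, log2fc, p, q,
#'   call)`.
#' @export
wilcoxon_bh <- function(groupA, groupB, alpha = 0.05, exact_max = 8L) {
  regions <- names(groupA)
  if (is.null(regions) || !identical(sort(regions), sort(names(groupB))))
    stop("groupA and groupB must cover the same named regions",
         call. = FALSE)
  rows <- lapply(regions, function(rg) {
    a <- groupA[[rg]]; b <- groupB[[rg]]
    if (length(a) == 0L || length(b) == 0L)
      stop("empty group for region ", rg, call. = FALSE)
    exact <- length(a) <= exact_max && length(b) <= exact_max &&
      !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
    if (is.nan(p)) p <- 1   # fully tied data: no rank evidence either way
    data.frame(region = rg, n_A = length(a), n_B = length(b),
               mean_A = mean(a), mean_B = mean(b),
               log2fc = if (mean(a) > 0 && mean(b) > 0)
                 log2(mean(a) / mean(b)) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$call <- ifelse(out$q < alpha,
                     ifelse(out$mean_A > out$mean_B, "increase", "decrease"),
                     "ns")
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis test with Dunn's pairwise post test
#'
#' Global tie-corrected Kruskal-Wallis H across three or more groups,
#' followed by Dunn's z statistics on mean ranks for every pair, with
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param groups named list of at least three numeric vectors.
#' @return list with `H`, `p_kw` (global), and `pairs`: a data.frame
#'   `(group1, group2, z, p, p_adj)`.
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 3L)
    stop("Dunn's post test needs at least 3 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("empty group", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)[names(groups)]
  n <- tapply(rk, g, length)[names(groups)]
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(names(groups), 2L)
  pairs <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (sigma > 0) (mean_rank[[i]] - mean_rank[[j]]) / sigma else 0
    data.frame(group1 = i, group2 = j, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  rownames(pairs) <- NULL
  list(H = unname(kw$statistic), p_kw = kw$p.value, pairs = pairs)
}

#' Write region statistics as TSV
#' @param stats a [wilcoxon_bh()] result.
#' @param path output file.
#' @export
write_region_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
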