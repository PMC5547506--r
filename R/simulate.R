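# Synthetic proximity-ligation library generator.
#
# The generator emulates the data this pipeline consumes: a genome carrying
# first-cutter (CATG) and second-cutter (GATC) motifs at realistic
# densities, a viewpoint-anchored contact model with power-law distance
# decay, enhancer-island enrichment and TAD boundary attenuation, and both
# 100-bp standard and 250-bp multi-way 4C libraries with exhaustive planted
# ground truth (PCR duplicates, undigested ligation products, hub-zone
# correlated three-way contacts).

#' Simulation configuration
#'
#' Collects all generative parameters with defaults chosen to mimic a
#' NlaIII/DpnII 4C library over a 2-Mb locus: motif densities of ~4/kb
#' match the genomic spacing of 4-bp cutters, the decay exponent of 1
#' matches the power law used for profile correction, and the duplicate /
#' undigested / hub rates are the library composition the multiway pipeline
#' is validated against.
#'
#' @param chrom_length chromosome length in bp.
#' @param chrom_name chromosome name used throughout.
#' @param first_density,second_density expected motif occurrences per kb.
#' @param viewpoint_pos bait position in bp.
#' @param islands list of `list(start, end, weight)` contact-enriched
#'   intervals (weight >= 1).
#' @param tads list of `list(start, end)` disjoint TAD intervals; each
#'   interval edge acts as an insulating boundary.
#' @param boundary_attenuation multiplicative contact attenuation per TAD
#'   boundary crossed, in (0, 1].
#' @param decay_exponent power-law distance-decay exponent (> 0).
#' @param hub_zone `list(start, end)` interval of correlated three-way
#'   contacts.
#' @param hub_prob probability that a multiway read draws both partners
#'   from the hub zone.
#' @param n_reads number of reads per simulated library.
#' @param duplicate_rate probability a read is an exact PCR copy of an
#'   earlier read.
#' @param undigested_rate probability a multiway read is an undigested
#'   (collinear adjacent-fragment) product.
#' @param p_third probability a multiway read carries a second ligation
#'   junction (a third segment) at all.
#' @param read_length multiway read length (bp).
#' @param std_read_length standard library read length (bp).
#' @param barcodes character vector of equal-length, distinct sample
#'   barcodes.
#' @param exclusion_radius bp around the bait excluded from the contact
#'   model (matches the analysis-side viewpoint exclusion).
#' @param min_segment,max_segment planted segment length bounds (bp).
#' @param seed integer RNG seed; all outputs are deterministic given the
#'   full configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_length = 2e6L,
                       chrom_name = "chrS",
                       first_density = 4,
                       second_density = 4,
                       viewpoint_pos = 1e6L,
                       islands = list(list(start = 31e4, end = 33e4, weight = 5),
                                      list(start = 36e4, end = 38e4, weight = 4),
                                      list(start = 42e4, end = 44e4, weight = 6),
                                      list(start = 47e4, end = 49e4, weight = 4),
                                      list(start = 50e4, end = 52e4, weight = 3)),
                       tads = list(list(start = 25e4, end = 55e4),
                                   list(start = 55e4, end = 98e4),
                                   list(start = 102e4, end = 175e4)),
                       boundary_attenuation = 0.1,
                       decay_exponent = 1,
                       hub_zone = list(start = 30e4, end = 52e4),
                       hub_prob = 0.5,
                       n_reads = 5000L,
                       duplicate_rate = 0.2,
                       undigested_rate = 0.1,
                       p_third = 1,
                       read_length = 250L,
                       std_read_length = 100L,
                       barcodes = c("ACGTCA", "TGACGT"),
                       exclusion_radius = 2000L,
                       min_segment = 24L,
                       max_segment = 96L,
                       seed = 1L) {
  cfg <- list(chrom_length = as.integer(chrom_length),
              chrom_name = chrom_name,
              first_density = first_density,
              second_density = second_density,
              viewpoint_pos = as.integer(viewpoint_pos),
              islands = islands, tads = tads,
              boundary_attenuation = boundary_attenuation,
              decay_exponent = decay_exponent,
              hub_zone = hub_zone, hub_prob = hub_prob,
              n_reads = as.integer(n_reads),
              duplicate_rate = duplicate_rate,
              undigested_rate = undigested_rate,
              p_third = p_third,
              read_length = as.integer(read_length),
              std_read_length = as.integer(std_read_length),
              barcodes = barcodes,
              exclusion_radius = as.integer(exclusion_radius),
              min_segment = as.integer(min_segment),
              max_segment = as.integer(max_segment),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$chrom_length > 0,
            cfg$first_density >= 0, cfg$second_density >= 0,
            cfg$viewpoint_pos >= 0, cfg$viewpoint_pos < cfg$chrom_length,
            cfg$boundary_attenuation > 0, cfg$boundary_attenuation <= 1,
            cfg$decay_exponent >= 0,
            cfg$hub_prob >= 0, cfg$hub_prob <= 1,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate < 1,
            cfg$undigested_rate >= 0, cfg$undigested_rate < 1,
            cfg$p_third >= 0, cfg$p_third <= 1,
            cfg$n_reads >= 0)
  for (iv in c(cfg$islands, cfg$tads, list(cfg$hub_zone))) {
    if (iv$start >= iv$end || iv$start < 0 || iv$end > cfg$chrom_length)
      stop("interval outside [0, chrom_length)", call. = FALSE)
  }
  for (isl in cfg$islands)
    if (isl$weight < 1) stop("island weights must be >= 1", call. = FALSE)
  bc <- cfg$barcodes
  if (length(unique(nchar(bc))) != 1L || anyDuplicated(bc))
    stop("barcodes must be equal-length and pairwise distinct", call. = FALSE)
  invisible(cfg)
}

#' Read/write a simulation configuration as JSON
#' @param cfg a [sim_config()] object.
#' @param path JSON file path.
#' @export
write_sim_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$islands <- if (is.data.frame(raw$islands))
    lapply(seq_len(nrow(raw$islands)), function(i) as.list(raw$islands[i, ]))
  else raw$islands
  raw$tads <- if (is.data.frame(raw$tads))
    lapply(seq_len(nrow(raw$tads)), function(i) as.list(raw$tads[i, ])) else
    raw$tads
  do.call(sim_config, raw)
}

#' Simulate a genome with controlled motif content
#'
#' Generates a random background sequence scrubbed of accidental cutter
#' motifs, then injects first- and second-cutter motifs at Poisson-spaced
#' positions so that observed motif counts follow the configured densities.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a one-chromosome `DNAStringSet` genome.
#' @export
simulate_genome <- function(config) {
  m1 <- "CATG"; m2 <- "GATC"
  L <- config$chrom_length
  n1_exp <- config$first_density * L / 1000
  n2_exp <- config$second_density * L / 1000
  if ((n1_exp + n2_exp) * 4 > L / 2)
    stop("motif densities exceed injection capacity", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  seq <- with_seed(config$seed, {
    v <- sample(bases, L, replace = TRUE)
    s <- paste(v, collapse = "")
    for (iter in 1:50) {                       # scrub accidental motifs
      occ <- c(motif_starts(s, m1), motif_starts(s, m2))
      if (length(occ) == 0L) break
      v[occ + 2L] <- sample(bases, length(occ), replace = TRUE)
      s <- paste(v, collapse = "")
    }
    n1 <- stats::rpois(1L, n1_exp)
    n2 <- stats::rpois(1L, n2_exp)
    pos <- sort(sample.int(L - 8L, n1 + n2) + 2L) - 1L   # 0-based starts
    if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 4L)]
    which1 <- sort(sample.int(length(pos), min(n1, length(pos))))
    motifs <- rep(m2, length(pos))
    motifs[which1] <- m1
    for (i in seq_along(pos)) {
      p <- pos[i]
      v[(p + 1L):(p + 4L)] <- strsplit(motifs[i], "")[[1L]]
    }
    s <- paste(v, collapse = "")
    injected <- logical(L)
    for (p in pos) injected[(p + 1L):(p + 4L)] <- TRUE
    pos1 <- pos[motifs == m1]; pos2 <- pos[motifs == m2]
    for (iter in 1:50) {                        # repair boundary strays
      stray <- c(setdiff(motif_starts(s, m1), pos1),
                 setdiff(motif_starts(s, m2), pos2))
      if (length(stray) == 0L) break
      for (o in stray) {
        cells <- (o + 1L):(o + 4L)
        free <- cells[!injected[cells]]
        if (length(free) == 0L) next
        v[free[1L]] <- sample(setdiff(bases, v[free[1L]]), 1L)
      }
      s <- paste(v, collapse = "")
    }
    s
  })
  g <- Biostrings::DNAStringSet(stats::setNames(seq, config$chrom_name))
  attr(g, "assembly_label") <- "synthetic"
  g
}

# Per-fragment planting geometry: the longest GATC-free, CATG-anchored
# window on each strand. Forward windows start at the fragment's own CATG;
# reverse windows end 4 bp past the fragment (at the next fragment's CATG,
# read on the minus strand) and must not reach the fragment's own CATG.
fragment_geometry <- function(map, genome, chrom) {
  f <- chrom_fragments(map, chrom)
  s <- chrom_string(genome, chrom)
  n <- nrow(f)
  len <- f$end - f$start
  g2 <- motif_starts(s, attr(map, "second_motif"))
  fwd_run <- len
  rev_run <- pmin(len + 3L, .Machine$integer.max)
  if (length(g2)) {
    frag_of <- findInterval(g2, f$start)
    # forward: first fully-internal GATC caps the run
    internal <- g2 + 4L <= f$end[frag_of]
    if (any(internal)) {
      first_g <- tapply(g2[internal], frag_of[internal], min)
      ix <- as.integer(names(first_g))
      fwd_run[ix] <- pmin(fwd_run[ix], as.integer(first_g) - f$start[ix])
    }
    # reverse: last GATC ending at or before end+4 caps the run
    rel <- g2 <= f$end[frag_of]            # occurrence [g, g+4) within window
    if (any(rel)) {
      last_g <- tapply(g2[rel], frag_of[rel], max)
      ix <- as.integer(names(last_g))
      rev_run[ix] <- pmin(rev_run[ix], f$end[ix] + 3L - as.integer(last_g))
    }
  }
  rev_run <- pmin(rev_run, len + 3L)
  # last fragment has no downstream CATG; first fragment has no own CATG
  list(frags = f, len = len, fwd_run = fwd_run, rev_run = rev_run,
       plus_ok = seq_len(n) > 1L,
       minus_ok = seq_len(n) < n)
}

#' Build a viewpoint contact model
#'
#' Fragment weights combine island enrichment and TAD boundary attenuation;
#' contact probabilities follow a power-law distance decay
#' `P_f ∝ w_f · max(d_f, 1 kb)^(−α)` with `d_f` the midpoint distance to
#' the bait. The bait fragment, fragments within the exclusion radius, and
#' fragments that cannot host a plantable read segment (terminal fragments
#' or GATC-free anchored windows shorter than `min_segment` on either
#' strand) receive probability 0.
#'
#' @param map a `fragment_map`.
#' @param genome the genome the map was digested from.
#' @param config a [sim_config()].
#' @return a `contact_model` with fields `P` (probabilities summing to 1),
#'   `w` (unnormalised weights), `eligible`, `distance`, `viewpoint_index`,
#'   the planting geometry, and the primer tag.
#' @export
build_contact_model <- function(map, genome, config) {
  chrom <- config$chrom_name
  geo <- fragment_geometry(map, genome, chrom)
  f <- geo$frags
  n <- nrow(f)
  mid <- (f$start + f$end) / 2
  vp_idx <- locate(map, chrom, config$viewpoint_pos)
  vp_mid <- mid[vp_idx + 1L]
  d <- abs(mid - vp_mid)

  w <- rep(1, n)
  for (isl in config$islands) {
    inside <- mid >= isl$start & mid < isl$end
    w[inside] <- isl$weight
  }
  boundaries <- sort(unique(unlist(lapply(config$tads,
                                          function(t) c(t$start, t$end)))))
  if (length(boundaries)) {
    nb <- vapply(mid, function(m) {
      sum(boundaries > min(m, vp_mid) & boundaries < max(m, vp_mid))
    }, numeric(1))
    w <- w * config$boundary_attenuation^nb
  }

  excl_lo <- f$start[vp_idx + 1L] - config$exclusion_radius
  excl_hi <- f$end[vp_idx + 1L] + config$exclusion_radius
  in_excl <- f$start < excl_hi & f$end > excl_lo
  eligible <- !in_excl & geo$plus_ok & geo$minus_ok &
    geo$fwd_run >= config$min_segment & geo$rev_run >= config$min_segment

  P <- w * pmax(d, 1000)^(-config$decay_exponent)
  P[!eligible] <- 0
  if (sum(P) <= 0) stop("degenerate contact model: all weights zero",
                        call. = FALSE)
  P <- P / sum(P)

  vp_frag_seq <- substring(chrom_string(genome, chrom),
                           f$start[vp_idx + 1L] + 1L, f$end[vp_idx + 1L])
  if (nchar(vp_frag_seq) < 24L)
    stop("viewpoint fragment too short to derive a primer tag", call. = FALSE)
  primer_tag <- substring(vp_frag_seq, nchar(vp_frag_seq) - 19L,
                          nchar(vp_frag_seq))

  structure(list(P = P, w = w, eligible = eligible, distance = d,
                 viewpoint_index = vp_idx, geometry = geo,
                 chrom = chrom, primer_tag = primer_tag,
                 config = config),
            class = "contact_model")
}

#' Viewpoint specification implied by a simulation
#'
#' @param model a [build_contact_model()] result.
#' @param map the `fragment_map` used to build it.
#' @return a [viewpoint_spec()] whose bait interval is the viewpoint
#'   fragment and whose primer tag matches the generator's.
#' @export
sim_viewpoint <- function(model, map) {
  f <- chrom_fragments(map, model$chrom)
  i <- model$viewpoint_index + 1L
  viewpoint_spec(name = "sim_vp", chrom = model$chrom,
                 bait_start = f$start[i], bait_end = f$end[i],
                 primer_tag = model$primer_tag,
                 exclusion_radius = model$config$exclusion_radius)
}

# Draw one planted segment on fragment `i` (1-based row) and strand,
# returning list(seq, pos). `budget` caps the segment length.
plant_segment <- function(geo, chrom_seq, i, strand, min_len, max_len,
                          budget = Inf) {
  run <- if (strand == "+") geo$fwd_run[i] else geo$rev_run[i]
  hi <- min(run, max_len, budget)
  if (hi < min_len) return(NULL)
  L <- if (hi > min_len) sample(min_len:hi, 1L) else min_len
  repeat {
    if (strand == "+") {
      p <- geo$frags$start[i]
      seg <- substring(chrom_seq, p + 1L, p + L)
    } else {
      p <- geo$frags$end[i] + 4L - L
      seg <- revcomp(substring(chrom_seq, p + 1L, p + L))
    }
    # a segment ending in GAT would form a GATC across the ligation
    # junction with the next segment's CATG and be lost to adapter trimming
    if (!endsWith(seg, "GAT") || L - 1L < min_len) break
    L <- L - 1L
  }
  if (endsWith(seg, "GAT")) return(NULL)
  list(seq = seg, pos = p, len = L)
}

empty_truth <- function() {
  data.frame(read_id = character(), sample = character(),
             x_chrom = character(), x_index = integer(), x_pos = integer(),
             x_strand = character(), y_index = integer(), y_pos = integer(),
             y_strand = character(), duplicate_of = character(),
             undigested = logical(), stringsAsFactors = FALSE)
}

#' Simulate a standard 100-bp 4C library
#'
#' Each read is `barcode + primer_tag + CATG + fragment prefix`, truncated
#' to the standard read length, with the source fragment drawn i.i.d. from
#' the contact model. Qualities are constant high.
#'
#' @param model a `contact_model`.
#' @param map the `fragment_map`.
#' @param genome the genome.
#' @param config a [sim_config()]; `n_reads` reads are produced.
#' @return `list(reads, truth)` where `reads` is a data.frame
#'   `(id, sequence, quality)` and `truth` records each read's planted
#'   fragment.
#' @export
simulate_standard_reads <- function(model, map, genome, config = model$config) {
  geo <- model$geometry
  chrom_seq <- chrom_string(genome, model$chrom)
  n <- config$n_reads
  if (n == 0L)
    return(list(reads = data.frame(id = character(), sequence = character(),
                                   quality = character()),
                truth = empty_truth()))
  with_seed(config$seed + 1L, {
    frag <- sample.int(nrow(geo$frags), n, replace = TRUE, prob = model$P)
    bc_i <- sample.int(length(config$barcodes), n, replace = TRUE)
    bc <- config$barcodes[bc_i]
    cap <- config$std_read_length - nchar(bc) - nchar(model$primer_tag)
    L <- pmin(geo$len[frag], cap)
    captured <- substring(chrom_seq, geo$frags$start[frag] + 1L,
                          geo$frags$start[frag] + L)
    seqs <- paste0(bc, model$primer_tag, captured)
    ids <- sprintf("std%06d", seq_len(n))
    reads <- data.frame(id = ids, sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids,
                        sample = paste0("S", bc_i),
                        x_chrom = model$chrom,
                        x_index = geo$frags$index[frag],
                        x_pos = geo$frags$start[frag],
                        x_strand = "+",
                        y_index = NA_integer_, y_pos = NA_integer_,
                        y_strand = NA_character_,
                        duplicate_of = NA_character_,
                        undigested = FALSE, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a multi-way 250-bp 4C library with planted tripartite contacts
#'
#' Each non-duplicate read carries a mid segment (partner X) and, with
#' probability `p_third`, a third segment (partner Y) joined at CATG
#' ligation junctions: `barcode + primer_tag + CATG..X.. + CATG..Y..`,
#' truncated to `read_length`. With probability `hub_prob` both partners
#' are drawn uniformly from hub-zone fragments (correlated three-way
#' contacts); with probability `undigested_rate` the read is instead an
#' undigested product whose Y is the collinear genomic continuation of X
#' (next fragment on +, previous on −). With probability `duplicate_rate` a
#' read is an exact PCR copy of an earlier read. Segment strands are drawn
#' uniformly and minus-strand segments are reverse-complemented.
#'
#' @inheritParams simulate_standard_reads
#' @return `list(reads, truth)`; `truth` has one row per read with planted
#'   mapping positions/strands of X and Y, `duplicate_of`, and the
#'   `undigested` flag (copies inherit their template's planting).
#' @export
simulate_multiway_reads <- function(model, map, genome, config = model$config) {
  geo <- model$geometry
  chrom_seq <- chrom_string(genome, model$chrom)
  n <- config$n_reads
  if (config$read_length < 3L * 4L + 20L)
    stop("read_length too short for two junctions", call. = FALSE)
  hub_frags <- which(model$eligible &
                       (geo$frags$start + geo$frags$end) / 2 >= config$hub_zone$start &
                       (geo$frags$start + geo$frags$end) / 2 < config$hub_zone$end)
  if (config$hub_prob > 0 && length(hub_frags) == 0L)
    stop("hub_zone contains no eligible fragment", call. = FALSE)
  reads <- vector("list", n)
  truth <- vector("list", n)
  with_seed(config$seed + 2L, {
    for (r in seq_len(n)) {
      id <- sprintf("mw%06d", r)
      if (r > 1L && stats::runif(1) < config$duplicate_rate) {
        tmpl <- sample.int(r - 1L, 1L)
        rec <- truth[[tmpl]]
        rec$read_id <- id
        rec$duplicate_of <- truth[[tmpl]]$read_id
        reads[[r]] <- reads[[tmpl]]
        reads[[r]]$id <- id
        truth[[r]] <- rec
        next
      }
      bc_i <- sample.int(length(config$barcodes), 1L)
      bc <- config$barcodes[bc_i]
      budget <- config$read_length - nchar(bc) - nchar(model$primer_tag)
      undig <- stats::runif(1) < config$undigested_rate
      has_third <- undig || stats::runif(1) < config$p_third
      repeat {
        if (undig) {
          xs <- sample(c("+", "-"), 1L)
          nbr_off <- if (xs == "+") 1L else -1L
          ok <- which(model$P > 0)
          ok <- ok[ok + nbr_off >= 1L & ok + nbr_off <= nrow(geo$frags)]
          nbr <- ok + nbr_off
          sel <- if (xs == "+")
            geo$fwd_run[nbr] >= config$min_segment & geo$plus_ok[nbr]
          else geo$rev_run[nbr] >= config$min_segment & geo$minus_ok[nbr]
          ok <- ok[sel]
          if (length(ok) == 0L) next
          xi <- ok[sample.int(length(ok), 1L, prob = model$P[ok])]
          yi <- xi + nbr_off
          ys <- xs
        } else if (has_third && stats::runif(1) < config$hub_prob) {
          xi <- hub_frags[sample.int(length(hub_frags), 1L)]
          yi <- hub_frags[sample.int(length(hub_frags), 1L)]
          xs <- sample(c("+", "-"), 1L)
          ys <- sample(c("+", "-"), 1L)
        } else {
          xi <- sample.int(nrow(geo$frags), 1L, prob = model$P)
          xs <- sample(c("+", "-"), 1L)
          if (has_third) {
            yi <- sample.int(nrow(geo$frags), 1L, prob = model$P)
            ys <- sample(c("+", "-"), 1L)
          } else yi <- NA_integer_
        }
        # never plant a coincidental collinear-adjacent (undigested-looking)
        # pair outside the undigested branch: the filter could not tell it
        # from a genuine incomplete-digestion product
        if (!undig && !is.na(yi) && ys == xs &&
            yi == xi + (if (xs == "+") 1L else -1L)) next
        segX <- plant_segment(geo, chrom_seq, xi, xs, config$min_segment,
                              config$max_segment)
        if (is.null(segX)) next
        if (!is.na(yi)) {
          segY <- plant_segment(geo, chrom_seq, yi, ys, config$min_segment,
                                config$max_segment,
                                budget = budget - segX$len)
          if (is.null(segY)) next
        } else segY <- NULL
        break
      }
      seq <- paste0(bc, model$primer_tag, segX$seq,
                    if (!is.null(segY)) segY$seq else "")
      seq <- substr(seq, 1L, config$read_length)
      reads[[r]] <- list(id = id, sequence = seq,
                         quality = strrep("I", nchar(seq)))
      truth[[r]] <- data.frame(
        read_id = id, sample = paste0("S", bc_i),
        x_chrom = model$chrom, x_index = geo$frags$index[xi],
        x_pos = segX$pos, x_strand = xs,
        y_index = if (is.null(segY)) NA_integer_ else geo$frags$index[yi],
        y_pos = if (is.null(segY)) NA_integer_ else segY$pos,
        y_strand = if (is.null(segY)) NA_character_ else ys,
        duplicate_of = NA_character_,
        undigested = undig, stringsAsFactors = FALSE)
    }
  })
  reads_df <- data.frame(
    id = vapply(reads, `[[`, "", "id"),
    sequence = vapply(reads, `[[`, "", "sequence"),
    quality = vapply(reads, `[[`, "", "quality"),
    stringsAsFactors = FALSE)
  truth_df <- do.call(rbind, truth)
  if (is.null(truth_df)) truth_df <- empty_truth()
  list(reads = reads_df, truth = truth_df)
}

#' Planted unique tripartite pairs per sample
#'
#' The ground-truth counterpart of the multiway pipeline's deduplicated
#' contact list: distinct `(X pos/strand, Y pos/strand)` tuples over
#' non-duplicate, non-undigested reads that carry a third segment.
#'
#' @param truth a truth data.frame from [simulate_multiway_reads()].
#' @return data.frame of unique planted pairs with a `sample` column.
#' @export
planted_unique_pairs <- function(truth) {
  t <- truth[is.na(truth$duplicate_of) & !truth$undigested &
               !is.na(truth$y_pos), , drop = FALSE]
  key <- paste(t$sample, t$x_chrom, t$x_pos, t$x_strand,
               t$x_chrom, t$y_pos, t$y_strand)
  t <- t[!duplicated(key), c("sample", "x_chrom", "x_pos", "x_strand",
                             "y_pos", "y_strand")]
  rownames(t) <- NULL
  t
}

#' FASTQ and truth-table I/O for simulated libraries
#'
#' Reads are written in Sanger (Phred+33) FASTQ; the truth table as TSV.
#'
#' @param reads a reads data.frame `(id, sequence, quality)`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(out, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  S4Vectors::mcols(x) <- NULL
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = quals,
             stringsAsFactors = FALSE)
}

#' @param truth a truth data.frame.
#' @rdname write_fastq
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
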