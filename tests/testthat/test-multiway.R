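test_that("demultiplexing is exact-prefix with conservation", {
  bc <- c(A = "AAAAAA", B = "CCCCCC")
  mk_reads <- function(seqs) data.frame(
    id = paste0("r", seq_along(seqs)), sequence = seqs,
    quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
  reads <- mk_reads(c(paste0("AAAAAA", strrep("G", 30)),
                      paste0("CCCCCC", strrep("G", 30)),
                      paste0("AAAAAC", strrep("G", 30))))  # 1 mismatch
  bins <- demultiplex(reads, bc)
  expect_equal(nrow(bins$A), 1L)
  expect_equal(nrow(bins$B), 1L)
  expect_equal(nrow(bins$unassigned), 1L)
  expect_equal(bins$A$sequence, strrep("G", 30))  # barcode removed
  expect_equal(sum(vapply(bins, nrow, integer(1))), nrow(reads))
  expect_error(demultiplex(reads, c("AAAAAA", "AAAAAA")), "duplicate")

  set.seed(21)
  seqs <- paste0(sample(c(bc, "GGGGGG"), 60, replace = TRUE),
                 replicate(60, random_dna(40)))
  bins2 <- demultiplex(mk_reads(seqs), bc)
  expect_equal(sum(vapply(bins2, nrow, integer(1))), 60L)
})

test_that("viewpoint stripping keeps the first CATG after the tag", {
  vp <- viewpoint_spec("vp", "chr", 0L, 10L, "TTTTAAAACC")
  reads <- data.frame(
    id = c("a", "b", "c"),
    sequence = c(paste0("TTTTAAAACC", "CATG", strrep("A", 20)),
                 strrep("G", 34),                         # no tag
                 paste0("TTTTAAAACC", "GG", "CATG", strrep("A", 18))),
    quality = strrep("I", 34), stringsAsFactors = FALSE)
  out <- strip_viewpoint(reads, vp)
  expect_equal(out$n_discarded, 1L)
  expect_true(all(startsWith(out$reads$sequence, "CATG")))
  expect_equal(out$reads$sequence[1], paste0("CATG", strrep("A", 20)))
  # intervening bases before the CATG are dropped too
  expect_equal(out$reads$sequence[2], paste0("CATG", strrep("A", 18)))
})

test_that("trimming cuts at the first GATC and by the quality rule", {
  mk <- function(seq, qual = strrep("I", nchar(seq)))
    data.frame(id = "r", sequence = seq, quality = qual,
               stringsAsFactors = FALSE)
  # high quality, no GATC: unchanged
  s <- paste0("CATG", strrep("A", 30))
  expect_equal(trim_reads(mk(s))$reads$sequence, s)
  # cut at the first GATC occurrence
  long <- paste0("CATGAAA", strrep("C", 20), "GATC", "TTT")
  expect_equal(trim_reads(mk(long))$reads$sequence,
               paste0("CATGAAA", strrep("C", 20)))
  expect_equal(trim_reads(mk("CATGAAAGATCTTT"), min_len = 1L)$reads$sequence,
               "CATGAAA")
  # reads shorter than min_len after trimming are discarded
  out <- trim_reads(mk("CATGAAAGATCTTT"), min_len = 24L)
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$n_discarded, 1L)

  # planted low-quality tail: compare with an independent running-sum rule
  set.seed(31)
  for (rep in 1:20) {
    n <- 40L
    q <- c(sample(25:40, 30, replace = TRUE), sample(0:15, 10, replace = TRUE))
    qual <- intToUtf8(q + 33L)
    seq <- paste0("CATG", strrep("AC", 18))   # motif-free body
    ref_keep <- {
      s <- 0; cut <- n + 1L
      for (j in n:1) {
        s <- s + (10L - q[j])
        if (s > 0) cut <- j else break
      }
      cut - 1L
    }
    got <- trim_reads(mk(seq, qual), min_len = 1L)$reads$sequence
    expect_equal(nchar(got), ref_keep)
  }
})

test_that("reads split at the first internal ligation junction", {
  expect_equal(split_read("CATGAAAA"),
               data.frame(mid = "CATGAAAA", third = NA_character_))
  expect_equal(split_read("CATGAAACATGTTT"),
               data.frame(mid = "CATGAAA", third = "CATGTTT"))
  # tie-break at the earliest occurrence
  expect_equal(split_read("CATGCATGCATG"),
               data.frame(mid = "CATG", third = "CATGCATG"))
})

test_that("segments map by unique exact match on either strand", {
  set.seed(51)
  s <- paste0(random_dna(500), "CATG", random_dna(500))
  g <- c(chrM = s)
  map <- digest(g)
  idx <- capture_index(g, map)
  seg <- substr(s, 101, 130)                       # unique 30-mer
  hit <- map_segment(seg, idx)
  expect_equal(hit$pos, 100L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$fragment_index, 0L)
  rc_hit <- map_segment(revcomp(seg), idx)
  expect_equal(rc_hit$pos, 100L)
  expect_equal(rc_hit$strand, "-")
  # a repeated segment is unmapped
  s2 <- paste0(seg, random_dna(50), seg)
  expect_null(map_segment(seg, c(chrM = s2)))
  # too-short segments are unmapped
  expect_null(map_segment(substr(seg, 1, 10), idx))
  # anchored-index route agrees with a full matchPattern scan
  catg_seg <- paste0("CATG", substr(s, 505, 534))
  expect_equal(map_segment(catg_seg, idx),
               map_segment(catg_seg, structure(g, map = map)))
})

test_that("a failed third is rescued by re-splitting at CATG", {
  set.seed(52)
  uniqueA <- paste0("CATG", random_dna(40))
  s <- paste0(random_dna(300), uniqueA, random_dna(300))
  g <- c(chrM = s)
  map <- digest(g)
  idx <- capture_index(g, map)
  junk <- random_dna(30)
  third <- paste0(uniqueA, "CATG", junk)
  expect_null(map_segment(third, idx))             # junk breaks the match
  hit <- rescue_third(third, idx)
  expect_equal(hit$pos, 300L)
  # no internal CATG: no rescue
  expect_null(rescue_third(uniqueA, idx))
  # still-ambiguous 5' part: unmapped
  dup <- paste0("CATG", random_dna(30))
  g2 <- c(chrM = paste0(dup, random_dna(40), dup, random_dna(40)))
  m2 <- digest(g2)
  expect_null(rescue_third(paste0(dup, "CATG", junk),
                           capture_index(g2, m2)))
})

test_that("undigested filtering drops collinear continuations only", {
  hit <- function(frag, strand) data.frame(chrom = "c", pos = 0L,
                                           strand = strand,
                                           fragment_index = frag)
  expect_true(is_undigested(hit(5L, "+"), hit(6L, "+")))
  expect_false(is_undigested(hit(5L, "+"), hit(6L, "-")))
  expect_false(is_undigested(hit(5L, "+"), hit(4L, "+")))
  expect_true(is_undigested(hit(5L, "-"), hit(4L, "-")))
  expect_false(is_undigested(hit(5L, "+"), hit(7L, "+")))
  # strand-agnostic variant drops any |delta index| = 1 pair
  expect_true(is_undigested(hit(5L, "+"), hit(6L, "-"),
                            strand_aware = FALSE))
  expect_true(is_undigested(hit(5L, "+"), hit(4L, "+"),
                            strand_aware = FALSE))
})

test_that("deduplication keys on the exact position-strand 6-tuple", {
  ct <- data.frame(x_chrom = "c", x_pos = 10L, x_strand = "+",
                   y_chrom = "c", y_pos = 50L, y_strand = "+")
  five <- ct[rep(1, 5), ]
  expect_equal(nrow(deduplicate(five)), 1L)
  # contacts differing only in Y strand are both kept
  two <- rbind(ct, transform(ct, y_strand = "-"))
  expect_equal(nrow(deduplicate(two)), 2L)
  # idempotence
  set.seed(61)
  many <- data.frame(x_chrom = "c", x_pos = sample(1:20, 50, TRUE),
                     x_strand = sample(c("+", "-"), 50, TRUE),
                     y_chrom = "c", y_pos = sample(1:20, 50, TRUE),
                     y_strand = sample(c("+", "-"), 50, TRUE))
  once <- deduplicate(many)
  expect_identical(deduplicate(once), once)
})

test_that("matrix binning is symmetric and conserving", {
  region <- list(chrom = "c", start = 1000L, end = 101000L)
  ct <- data.frame(x_chrom = "c", x_pos = 1000L + 15000L, x_strand = "+",
                   y_chrom = "c", y_pos = 1000L + 20000L, y_strand = "+")
  tm <- build_matrix(ct, region, binsize = 20000L)
  expect_equal(tm$matrix[1, 2], 1L)
  expect_equal(tm$matrix[2, 1], 1L)
  expect_equal(sum(tm$matrix), 2L)
  # same-bin contact hits the diagonal once
  ct2 <- data.frame(x_chrom = "c", x_pos = 2000L, x_strand = "+",
                    y_chrom = "c", y_pos = 3000L, y_strand = "+")
  tm2 <- build_matrix(ct2, region, binsize = 20000L)
  expect_equal(tm2$matrix[1, 1], 1L)
  # conservation: upper triangle incl. diagonal sums to the contact count
  set.seed(62)
  n <- 200L
  rnd <- data.frame(x_chrom = "c",
                    x_pos = sample(1000:100999, n, TRUE), x_strand = "+",
                    y_chrom = "c",
                    y_pos = sample(1000:100999, n, TRUE), y_strand = "+")
  tm3 <- build_matrix(rnd, region, binsize = 20000L)
  expect_equal(sum(tm3$matrix[upper.tri(tm3$matrix, diag = TRUE)]), n)
  expect_identical(tm3$matrix, t(tm3$matrix))
  # out-of-region contacts are excluded
  out <- transform(rnd, y_pos = 200000L)
  expect_equal(sum(build_matrix(out, region, 20000L)$matrix), 0L)
  expect_error(build_matrix(rnd, list(chrom = "c", start = 10L, end = 10L)),
               "empty region")
})

test_that("zone occupancy counts bins with any tripartite contact", {
  region <- list(chrom = "c", start = 0L, end = 100000L)
  none <- data.frame(x_chrom = character(), x_pos = integer(),
                     x_strand = character(), y_chrom = character(),
                     y_pos = integer(), y_strand = character())
  tm0 <- build_matrix(none, region, 20000L)
  expect_equal(zone_fraction(tm0, list(start = 0, end = 100000)), 0)
  full <- data.frame(x_chrom = "c", x_pos = seq(0L, 80000L, 20000L) + 1L,
                     x_strand = "+", y_chrom = "c", y_pos = 50L,
                     y_strand = "+")
  tmf <- build_matrix(full, region, 20000L)
  expect_equal(zone_fraction(tmf, list(start = 0, end = 100000)), 100)
  expect_error(zone_fraction(tmf, list(start = 100000, end = 100001)),
               "no bin")
})

test_that("the end-to-end pipeline recovers the planted truth exactly", {
  fx <- small_locus()
  cfg <- small_sim_config(n_reads = 500L, seed = 71)
  mw <- simulate_multiway_reads(fx$model, fx$map, fx$genome, cfg)
  res <- run_multiway(mw$reads, fx$map, fx$idx, fx$vp, cfg$barcodes)
  # read conservation across QC classes
  expect_equal(sum(unlist(res$qc)), nrow(mw$reads))
  # unique contacts equal planted unique pairs (100% precision and recall)
  expect_identical(contact_key(res$contacts),
                   contact_key(planted_unique_pairs(mw$truth)))
  # dropped undigested reads are exactly the planted ones (plus copies)
  expect_setequal(res$dropped_undigested,
                  mw$truth$read_id[mw$truth$undigested])
  # removed duplicates equal the redundancy of the planted contact list
  expect_equal(res$qc$duplicate,
               nrow(res$all_contacts) - nrow(res$contacts))
})
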