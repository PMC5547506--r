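make_counts <- function(map, counts, vp) {
  structure(list(viewpoint = vp, counts = as.integer(counts),
                 total_mapped = sum(counts), qc = list(),
                 map = map, excluded = logical(nrow(map))),
            class = "fragment_counts")
}

toy_map <- function(n = 10L, frag_len = 100L) {
  starts <- (seq_len(n) - 1L) * frag_len
  tricontact:::new_fragment_map(
    data.frame(chrom = "chrT", start = starts, end = starts + frag_len,
               index = seq_len(n) - 1L, has_second_cutter = FALSE),
    "CATG", "GATC", c(chrT = n * frag_len))
}

toy_vp <- function(bait_start = 400L, bait_end = 500L, excl = 0L) {
  viewpoint_spec("vp", "chrT", bait_start, bait_end, "ACGT",
                 exclusion_radius = excl)
}

test_that("reads are assigned to the fragments they were drawn from", {
  fx <- small_locus()
  cfg <- small_sim_config(n_reads = 1000L, seed = 41)
  std <- simulate_standard_reads(fx$model, fx$map, fx$genome, cfg)
  fc <- assign_reads(std$reads, fx$map, fx$vp, fx$idx)
  planted <- table(factor(std$truth$x_index, levels = fx$map$index))
  expect_equal(fc$counts, as.integer(planted))
  expect_equal(fc$total_mapped, 1000L)
  expect_equal(fc$qc$assigned, 1000L)
})

test_that("ambiguous and empty inputs are handled by QC, not errors", {
  # a captured sequence occurring twice in the genome is discarded
  core <- random_dna(40, seed = 77)
  s <- paste0(random_dna(30), "CATG", core, random_dna(25),
              "CATG", core, random_dna(30))
  g <- c(chrA = s)
  map <- digest(g)
  vp <- viewpoint_spec("vp", "chrA", 0L, 10L, substr(s, 1, 8),
                       exclusion_radius = 0L)
  amb_read <- data.frame(id = "r1",
                         sequence = paste0(substr(s, 1, 8), "CATG",
                                           substr(core, 1, 30)),
                         quality = strrep("I", 42))
  fc <- assign_reads(amb_read, map, vp, g)
  expect_equal(fc$total_mapped, 0L)
  expect_equal(fc$qc$ambiguous, 1L)

  empty <- data.frame(id = character(), sequence = character(),
                      quality = character())
  fc0 <- assign_reads(empty, map, vp, g)
  expect_equal(sum(fc0$counts), 0L)
  expect_equal(fc0$total_mapped, 0L)

  # a read without the primer tag is tallied, not assigned
  no_tag <- data.frame(id = "r2", sequence = strrep("T", 50),
                       quality = strrep("I", 50))
  fct <- assign_reads(no_tag, map, vp, g)
  expect_equal(fct$qc$no_primer, 1L)
})

test_that("viewpoint exclusion zeroes overlapping fragments only", {
  map <- toy_map()
  counts <- make_counts(map, rep(10L, 10L), toy_vp(bait_start = 450L,
                                                   bait_end = 460L,
                                                   excl = 0L))
  # exclusion radius 0, bait inside fragment 4 -> exactly that fragment
  out <- exclude_viewpoint(counts)
  expect_equal(which(out$excluded) - 1L, 4L)
  expect_equal(out$counts[5L], 0L)
  expect_equal(out$total_mapped, 90L)

  # a 1-bp overlap with the extended window still zeroes the fragment
  counts2 <- make_counts(map, rep(10L, 10L),
                         toy_vp(bait_start = 450L, bait_end = 460L,
                                excl = 51L))
  out2 <- exclude_viewpoint(counts2)
  expect_equal(which(out2$excluded) - 1L, c(3L, 4L, 5L))
})

test_that("RPM normalization preserves ratios and totals", {
  map <- toy_map(3L)
  fc <- make_counts(map, c(2L, 0L, 2L), toy_vp())
  pr <- normalize_total(fc)
  expect_equal(pr$scores, c(5e5, 0, 5e5))
  expect_equal(sum(pr$scores), 1e6)
  expect_equal(pr$stage, "normalized")

  set.seed(4)
  counts <- rpois(50, 20)
  fc2 <- make_counts(toy_map(50L), counts, toy_vp())
  fc2$total_mapped <- sum(counts) + 25L   # some reads outside the map
  pr2 <- normalize_total(fc2)
  expect_equal(sum(pr2$scores) / 1e6, sum(counts) / fc2$total_mapped)
  # ratio conservation between any two fragments
  nz <- which(counts > 0)
  expect_equal(pr2$scores[nz[1]] / pr2$scores[nz[2]],
               counts[nz[1]] / counts[nz[2]])
  fc0 <- make_counts(toy_map(3L), c(0L, 0L, 0L), toy_vp())
  expect_error(normalize_total(fc0), "no mapped reads")
})

test_that("running-mean smoothing equals the brute-force windowed mean", {
  map <- toy_map(500L)
  set.seed(11)
  scores <- runif(500) * 100
  pr <- tricontact:::new_profile(make_counts(map, rep(0L, 500), toy_vp()),
                                 scores, "normalized")
  sm <- smooth_profile(pr, window = 11L)
  brute <- vapply(seq_len(500), function(i) {
    w <- max(1, i - 5):min(500, i + 5)
    mean(scores[w])
  }, numeric(1))
  expect_equal(sm$scores, brute, tolerance = 1e-12)

  # window 1 is the identity; a constant profile is unchanged
  expect_equal(smooth_profile(pr, window = 1L)$scores, scores)
  prc <- tricontact:::new_profile(make_counts(map, rep(0L, 500), toy_vp()),
                                  rep(3.5, 500), "normalized")
  expect_equal(smooth_profile(prc)$scores, rep(3.5, 500))
  expect_error(smooth_profile(pr, window = 4L), "odd")
})

test_that("smoothing is a linear operator", {
  map <- toy_map(80L)
  set.seed(12)
  x <- runif(80); y <- runif(80)
  mk <- function(v) tricontact:::new_profile(
    make_counts(map, rep(0L, 80), toy_vp()), v, "normalized")
  lhs <- smooth_profile(mk(2 * x + 5 * y))$scores
  rhs <- 2 * smooth_profile(mk(x))$scores + 5 * smooth_profile(mk(y))$scores
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("bait-window scaling fixes the window mean at 1", {
  map <- toy_map(200L, frag_len = 1000L)
  vp <- viewpoint_spec("vp", "chrT", 1e5, 1e5 + 1000, "ACGT")
  set.seed(13)
  scores <- runif(200) + 0.1
  mk <- function(v, stage = "smoothed") tricontact:::new_profile(
    make_counts(map, rep(0L, 200), vp), v, stage, window = 11L)
  out <- bait_normalize(mk(scores), half_width = 5e4)
  mid <- (map$start + map$end) / 2
  in_win <- mid >= vp$bait_start - 5e4 & mid < vp$bait_end + 5e4
  expect_equal(mean(out$scores[in_win]), 1, tolerance = 1e-12)
  # scale invariance: a 7x-scaled input gives the identical output
  out7 <- bait_normalize(mk(7 * scores), half_width = 5e4)
  expect_equal(out7$scores, out$scores, tolerance = 1e-12)
  # idempotence at the fixed point
  again <- bait_normalize(tricontact:::new_profile(
    make_counts(map, rep(0L, 200), vp), out$scores, "smoothed"),
    half_width = 5e4)
  expect_equal(again$scores, out$scores, tolerance = 1e-12)
})

test_that("decay correction flattens an exact power-law profile", {
  map <- toy_map(400L, frag_len = 1000L)
  vp <- viewpoint_spec("vp", "chrT", 2e5, 2e5 + 1000, "ACGT")
  mid <- (map$start + map$end) / 2
  d <- abs(mid - (vp$bait_start + vp$bait_end) / 2)
  scores <- ifelse(d > 0, 3 / d, 0)
  mk <- function(v) tricontact:::new_profile(
    make_counts(map, rep(0L, 400), vp), v, "smoothed", window = 11L)
  out <- profile_correction(mk(scores), alpha = 1,
                            fit_range = c(5e3, 2e6))
  in_range <- d >= 5e3 & d <= 2e6
  expect_true(all(abs(log(out$scores[in_range])) < 1e-9))

  # alpha = 0 divides by the geometric mean only: shape unchanged
  out0 <- profile_correction(mk(scores), alpha = 0)
  ratio <- out0$scores[in_range] / scores[in_range]
  expect_equal(max(ratio), min(ratio), tolerance = 1e-9)

  # scale equivariance: 10x input, same corrected output, 10x intercept
  out10 <- profile_correction(mk(10 * scores), alpha = 1)
  expect_equal(out10$scores, out$scores, tolerance = 1e-12)
  expect_equal(exp(out10$fit_intercept), 10 * exp(out$fit_intercept),
               tolerance = 1e-9)
})

test_that("replicate averaging is the element-wise mean", {
  map <- toy_map(30L)
  set.seed(14)
  mk <- function(v, excl = logical(30)) {
    p <- tricontact:::new_profile(make_counts(map, rep(0L, 30), toy_vp()),
                                  v, "smoothed", window = 11L)
    p$excluded <- excl
    p
  }
  a <- runif(30); b <- runif(30); c3 <- runif(30)
  avg <- average_replicates(list(mk(a), mk(b), mk(c3)))
  expect_equal(avg$scores, (a + b + c3) / 3)
  expect_equal(avg$stage, "averaged")
  # averaging one profile, or a profile with itself, is the identity
  expect_equal(average_replicates(list(mk(a)))$scores, a)
  expect_equal(average_replicates(list(mk(a), mk(a)))$scores, a)
  # the exclusion mask is the union and forces zeros
  e1 <- c(TRUE, rep(FALSE, 29)); e2 <- c(FALSE, TRUE, rep(FALSE, 28))
  avg2 <- average_replicates(list(mk(a, e1), mk(b, e2)))
  expect_true(all(avg2$excluded[1:2]))
  expect_equal(avg2$scores[1:2], c(0, 0))
  # mixed stages are rejected
  bad <- mk(b); bad$stage <- "normalized"
  expect_error(average_replicates(list(mk(a), bad)), "stage")
  expect_error(average_replicates(list()), "no profiles")
})

test_that("stage transitions are enforced in order", {
  map <- toy_map(30L)
  pr <- tricontact:::new_profile(make_counts(map, rep(1L, 30), toy_vp()),
                                 runif(30), "normalized")
  expect_error(bait_normalize(pr), "stage")
  expect_error(profile_correction(pr), "stage")
  sm <- smooth_profile(pr)
  expect_error(smooth_profile(sm), "stage")
})
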