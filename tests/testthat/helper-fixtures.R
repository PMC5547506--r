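# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# random motif-free DNA of length n (for hand-built genomes)
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (!is.null(seed)) set.seed(seed)
  s <- draw()
  for (i in 1:20) {
    occ <- c(gregexpr("CATG", s, fixed = TRUE)[[1L]],
             gregexpr("GATC", s, fixed = TRUE)[[1L]])
    occ <- occ[occ > 0L]
    if (length(occ) == 0L) break
    v <- strsplit(s, "")[[1L]]
    v[occ + 1L] <- sample(c("A", "C", "G", "T"), length(occ), replace = TRUE)
    s <- paste(v, collapse = "")
  }
  s
}

# a small but complete simulated locus shared by several test files:
# 300-kb chromosome, viewpoint mid-chromosome, one island-rich hub TAD
small_sim_config <- function(n_reads = 600L, seed = 101L, ...) {
  sim_config(chrom_length = 3e5, viewpoint_pos = 15e4,
             islands = list(list(start = 4e4, end = 5e4, weight = 5),
                            list(start = 6e4, end = 7e4, weight = 4)),
             tads = list(list(start = 2e4, end = 9e4),
                         list(start = 9e4, end = 14e4),
                         list(start = 16e4, end = 28e4)),
             hub_zone = list(start = 4e4, end = 8e4),
             n_reads = n_reads, seed = seed, ...)
}

small_locus <- function() {
  fixture("small_locus", function() {
    cfg <- small_sim_config()
    g <- simulate_genome(cfg)
    map <- digest(g)
    model <- build_contact_model(map, g, cfg)
    list(cfg = cfg, genome = g, map = map, model = model,
         vp = sim_viewpoint(model, map),
         idx = capture_index(g, map))
  })
}

# independent brute-force digestion: slide a window over the sequence
brute_force_cuts <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (L < k) return(integer(0))
  windows <- substring(seq, 1:(L - k + 1L), k:L)
  which(windows == motif) - 1L
}

# independent exact Wilcoxon rank-sum p-value by full enumeration of the
# choose(n_a + n_b, n_a) rank assignments
enumerate_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(length(pooled), n_a)
  w_all <- apply(combs, 2L, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  w_mean <- n_a * (length(b)) / 2
  mean(abs(w_all - w_mean) >= abs(w_obs - w_mean) - 1e-12)
}

# independent Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

contact_key <- function(df) {
  sort(paste(df$sample, df$x_pos, df$x_strand, df$y_pos, df$y_strand))
}
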