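# Shared fixture builders. Everything is generated in code; no binary
# or downloaded data.

# a deterministic PWM whose consensus is `seq`
consensus_pwm <- function(seq, id = seq) {
  idx <- match(strsplit(seq, "")[[1L]], c("A", "C", "G", "T"))
  m <- vapply(idx, function(i) { v <- numeric(4L); v[i] <- 1; v },
              numeric(4L))
  rownames(m) <- c("A", "C", "G", "T")
  new_pwm(m, id = id)
}

# hand-written 2-promoter, 3-species MAF text
write_toy_maf <- function(path, texts = NULL) {
  if (is.null(texts))
    texts <- list(gene1 = c("ACGTACGTAC", "ACGTACGTAC", "ACCTACGTAC"),
                  gene2 = c("TTTTGGGGCC", "TTTTGGGGCC", "TTTTGGCGCC"))
  species <- c("hg", "sp1", "sp2")[seq_along(texts[[1L]])]
  lines <- "##maf version=1"
  for (g in names(texts)) {
    lines <- c(lines, "a score=0")
    for (i in seq_along(texts[[g]])) {
      txt <- texts[[g]][i]
      size <- nchar(gsub("-", "", txt))
      lines <- c(lines, sprintf("s %s.%s 0 %d + %d %s",
                                species[i], g, size, size, txt))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}

# a motif cluster with simulated per-species conservation, built the way
# the dictionary stage would observe it: each member sequence is copied
# to (n_species - 1) aligned species rows and mutated i.i.d. at `rate`.
simulated_cluster <- function(seqs, n_species = 8, rate = 0.02,
                              id = "cluster", pseudocount = 0.01) {
  n <- nchar(seqs[1L])
  bases <- c("A", "C", "G", "T")
  k <- length(seqs)
  profile <- matrix(0, nrow = k, ncol = n)
  conserved <- integer(k)
  for (i in seq_len(k)) {
    enc <- match(strsplit(seqs[i], "")[[1L]], bases)
    matches <- rep(1, n)          # the reference row matches itself
    full <- 1L
    for (s in seq_len(n_species - 1L)) {
      mut <- runif(n) < rate
      matches <- matches + !mut
      if (!any(mut)) full <- full + 1L
    }
    profile[i, ] <- matches
    conserved[i] <- full
  }
  loci <- data.frame(member = seq_len(k),
                     promoter = sprintf("p%03d", seq_len(k)),
                     start = 100L + 20L * seq_len(k),
                     conserved_species = conserved)
  new_motif_cluster(seqs, a = rep(1, k), c = conserved, profile = profile,
                    loci = loci, n_species = n_species,
                    pseudocount = pseudocount, id = id)
}

random_pwm_seeded <- function(seed, length, dominant = 0.85) {
  set.seed(seed)
  random_pwm(length, dominant)
}

random_word <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent positional-scan oracle for the run decomposition
runs_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  l <- integer()
  run <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) {
      run <- run + 1L
    } else if (run > 0L) {
      l <- c(l, run)
      run <- 0L
    }
  }
  if (run > 0L) l <- c(l, run)
  l
}

# independent plain-R Smith-Waterman score (match +1, mismatch -5,
# gaps 0), written as a straightforward cellwise DP
sw_score_oracle <- function(t1, t2, match = 1, mismatch = -5, gap = 0) {
  n <- length(t1); m <- length(t2)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (t1[i] == t2[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
    }
  }
  max(H)
}

# exact upper-tail hypergeometric probability by explicit combinatorics
hyper_upper_oracle <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

small_sim <- function(seed, n_promoters = 12, promoter_length = 400,
                      n_species = 6, background_rate = 0.3,
                      site_rate = 0.02, motifs = NULL, n_motifs = 2,
                      motif_length = 8, ...) {
  set.seed(seed)
  if (is.null(motifs))
    motifs <- lapply(seq_len(n_motifs), function(i)
      random_pwm(motif_length, 0.85, id = sprintf("m%02d", i)))
  cfg <- simulation_config(n_promoters = n_promoters,
                           promoter_length = promoter_length,
                           n_species = n_species,
                           background_rate = background_rate,
                           site_rate = site_rate, motifs = motifs,
                           seed = seed, ...)
  simulate_promoters(cfg)
}
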