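mk_sites <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    site_records(r[[1L]], as.integer(r[[2L]]), as.integer(r[[3L]]),
                 r[[4L]], r[[5L]])))
}

test_that("build_groups splits occurrence runs at the 1000 bp boundary", {
  sites <- mk_sites(list("g1", 0, 8, "+", "m1"),
                    list("g1", 108, 116, "+", "m2"),
                    list("g1", 2116, 2124, "+", "m3"))
  groups <- build_groups(sites)
  expect_length(groups, 2L)
  expect_equal(length(groups[[1L]]$tokens), 2L)
  expect_equal(length(groups[[2L]]$tokens), 1L)
  # gap of exactly 1000 stays in one group ("not more than 1000")
  sites <- mk_sites(list("g1", 0, 8, "+", "m1"),
                    list("g1", 1008, 1016, "+", "m2"))
  expect_length(build_groups(sites), 1L)
  sites <- mk_sites(list("g1", 0, 8, "+", "m1"),
                    list("g1", 1009, 1017, "+", "m2"))
  expect_length(build_groups(sites), 2L)
  # a single occurrence forms a singleton group; strand enters the token
  sites <- mk_sites(list("g1", 0, 8, "-", "m1"))
  g <- build_groups(sites)
  expect_length(g, 1L)
  expect_equal(g[[1L]]$tokens, "m1/-")
  # partition property: no occurrence lost or duplicated
  set.seed(23)
  sites <- do.call(rbind, lapply(1:5, function(i) {
    starts <- sort(sample.int(6000, 12))
    site_records(paste0("g", i), starts, starts + 8L, "+",
                 sample(paste0("m", 1:4), 12, replace = TRUE))
  }))
  groups <- build_groups(sites)
  expect_equal(sum(vapply(groups, function(g) nrow(g$occ), integer(1L))),
               nrow(sites))
})

test_that("symbol alignment matches the DP oracle and the stated examples", {
  al <- sw_align_symbols(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  expect_equal(al$score, 4)
  expect_equal(nrow(al$alignment), 4L)
  # disjoint alphabets: empty local alignment, score 0
  al <- sw_align_symbols(c("A", "B"), c("X", "Y"))
  expect_equal(al$score, 0)
  # one free gap is preferred over a -5 mismatch
  al <- sw_align_symbols(c("A", "B", "C", "D"),
                         c("A", "B", "X", "C", "D"))
  expect_equal(al$score, 4)
  expect_true(any(al$alignment[, "a"] == 0L)) # the gap opposite X
  # empty input
  expect_equal(sw_align_symbols(character(), c("A"))$score, 0)
})

test_that("symbol alignment equals the oracle on random token strings", {
  set.seed(24)
  for (i in 1:300) {
    t1 <- sample(c("A", "B", "C"), sample(1:6, 1), replace = TRUE)
    t2 <- sample(c("A", "B", "C"), sample(1:6, 1), replace = TRUE)
    expect_equal(sw_align_symbols(t1, t2)$score, sw_score_oracle(t1, t2),
                 info = paste(paste(t1, collapse = ""),
                              paste(t2, collapse = "")))
  }
})

test_that("find_candidates orders by shared distinct motifs", {
  sites <- mk_sites(
    list("g1", 0, 8, "+", "m1"), list("g1", 20, 28, "+", "m2"),
    list("g1", 40, 48, "+", "m3"), list("g1", 60, 68, "+", "m4"),
    list("g1", 80, 88, "+", "m5"),
    # shares 5
    list("g2", 0, 8, "+", "m1"), list("g2", 20, 28, "+", "m2"),
    list("g2", 40, 48, "+", "m3"), list("g2", 60, 68, "+", "m4"),
    list("g2", 80, 88, "+", "m5"),
    # shares 3
    list("g3", 0, 8, "+", "m1"), list("g3", 20, 28, "+", "m2"),
    list("g3", 40, 48, "+", "m3"),
    # shares 2 (excluded)
    list("g4", 0, 8, "+", "m1"), list("g4", 20, 28, "+", "m2"))
  groups <- build_groups(sites)
  seed <- groups[[1L]]
  cands <- find_candidates(seed, groups, min_shared = 3)
  expect_equal(vapply(cands, `[[`, character(1L), "promoter"),
               c("g2", "g3"))
  # brute-force check of the shared counts on random groups
  set.seed(25)
  sites <- do.call(rbind, lapply(1:12, function(i) {
    motifs <- sample(paste0("m", 1:8), 5)
    starts <- seq(0, by = 50, length.out = 5)
    site_records(paste0("g", i), starts, starts + 8L, "+", motifs)
  }))
  groups <- build_groups(sites)
  seed <- groups[[1L]]
  cands <- find_candidates(seed, groups, 3)
  for (cand in cands) {
    shared <- length(intersect(unique(seed$occ$motif),
                               unique(cand$occ$motif)))
    expect_gte(shared, 3L)
  }
  # none shares enough -> empty
  expect_length(find_candidates(seed, groups[1L], 3), 0L)
})

test_that("center-star alignment of identical strings is gapless", {
  sites <- mk_sites(
    list("g1", 0, 8, "+", "m1"), list("g1", 20, 28, "+", "m2"),
    list("g1", 40, 48, "+", "m3"), list("g1", 60, 68, "+", "m4"),
    list("g2", 0, 8, "+", "m1"), list("g2", 20, 28, "+", "m2"),
    list("g2", 40, 48, "+", "m3"), list("g2", 60, 68, "+", "m4"),
    list("g3", 0, 8, "+", "m1"), list("g3", 20, 28, "+", "m2"),
    list("g3", 40, 48, "+", "m3"), list("g3", 60, 68, "+", "m4"))
  groups <- build_groups(sites)
  aln <- center_star_align(groups)
  expect_equal(ncol(aln$tokens), 4L)
  expect_false(anyNA(aln$tokens))
  expect_equal(aln$AL, 3 * 4) # 3 pairs x 4 matched columns
  # two groups reduce to the pairwise alignment
  aln2 <- center_star_align(groups[1:2])
  expect_equal(aln2$AL, 4)
})

test_that("center-star beats random gap placements in sum-of-pairs", {
  set.seed(26)
  mk_group <- function(i, motifs) {
    starts <- seq(0, by = 40, length.out = length(motifs))
    build_groups(site_records(paste0("g", i), starts, starts + 8L, "+",
                              motifs))[[1L]]
  }
  for (rep in 1:5) {
    gs <- lapply(1:4, function(i)
      mk_group(i, sample(paste0("m", 1:4), sample(3:5, 1),
                         replace = TRUE)))
    aln <- center_star_align(gs)
    width <- ncol(aln$tokens)
    toks <- lapply(gs, `[[`, "tokens")
    rand_sp <- replicate(100, {
      m <- matrix(NA_character_, nrow = 4, ncol = width)
      for (r in 1:4) {
        pos <- sort(sample.int(width, length(toks[[r]])))
        m[r, pos] <- toks[[r]]
      }
      motifforge:::sum_of_pairs(m)
    })
    expect_gte(aln$AL, max(rand_sp))
  }
})

test_that("a planted pattern is assembled with full generality", {
  # the same 3-motif arrangement in 5 promoters plus unrelated noise
  planted <- lapply(1:5, function(i) {
    starts <- c(0, 100, 220)
    site_records(paste0("g", i), starts, starts + 8L, "+",
                 c("m1", "m2", "m3"))
  })
  noise <- lapply(6:9, function(i) {
    starts <- c(0, 90)
    site_records(paste0("g", i), starts, starts + 8L, "+",
                 c(paste0("x", i), paste0("y", i)))
  })
  sites <- do.call(rbind, c(planted, noise))
  groups <- build_groups(sites)
  cbp <- assemble_cbp(groups[[1L]], groups)
  expect_false(is.null(cbp))
  expect_equal(cbp$GEN, 5)
  expect_setequal(cbp$motifs, c("m1", "m2", "m3"))
  expect_equal(cbp$ROB, 1)
  expect_equal(cbp$COV, 24)
  expect_equal(unname(cbp$D), c(92, 112))
  # a seed with no candidates yields nothing
  expect_null(assemble_cbp(groups[[6L]], groups))
})

test_that("columns below the support threshold are dropped", {
  # only 2 promoters share the 3 motifs: support 2 < 3 kills every column
  sites <- do.call(rbind, lapply(1:2, function(i) {
    starts <- c(0, 100, 220)
    site_records(paste0("g", i), starts, starts + 8L, "+",
                 c("m1", "m2", "m3"))
  }))
  groups <- build_groups(sites)
  expect_null(assemble_cbp(groups[[1L]], groups, min_support = 3))
  # with min_support 2 the same pattern is emitted
  cbp <- assemble_cbp(groups[[1L]], groups, min_support = 2)
  expect_false(is.null(cbp))
  expect_equal(cbp$GEN, 2)
})

test_that("cbp metrics follow their definitions on a worked example", {
  # m1 twice per group, m2 once -> ROB = 1.5
  sites <- do.call(rbind, lapply(1:3, function(i) {
    site_records(paste0("g", i), c(0, 50, 120), c(8, 58, 128), "+",
                 c("m1", "m1", "m2"))
  }))
  groups <- build_groups(sites)
  cbp <- assemble_cbp(groups[[1L]], groups, min_shared = 2,
                      min_support = 3)
  expect_false(is.null(cbp))
  expect_equal(cbp$GEN, 3)
  expect_equal(cbp$ROB, 1.5)
  expect_equal(cbp$COV, 24)
})

test_that("significance is near zero under a vacuous null and high for real patterns", {
  # vacuous: the pattern's motifs are the only labels in the universe
  # and every group carries several copies of each, so relabelling
  # (almost) never breaks the co-occurrence and null GEN ~ observed
  sites <- do.call(rbind, lapply(1:4, function(i) {
    starts <- seq(0, by = 60, length.out = 9)
    site_records(paste0("g", i), starts, starts + 8L, "+",
                 rep(c("m1", "m2", "m3"), 3))
  }))
  groups <- build_groups(sites)
  cbp <- assemble_cbp(groups[[1L]], groups)
  sig <- cbp_significance(cbp, sites, n_perm = 50, seed = 31)
  expect_true(sig$degenerate || abs(sig$SIG) < 2)

  # planted in 8 of 40 promoters among diverse background labels
  planted <- lapply(1:8, function(i)
    site_records(paste0("g", i), c(0, 100, 220), c(8, 108, 228), "+",
                 c("m1", "m2", "m3")))
  set.seed(32)
  noise <- lapply(9:40, function(i) {
    starts <- c(0, 100, 220)
    site_records(paste0("g", i), starts, starts + 8L, "+",
                 sample(paste0("n", 1:12), 3))
  })
  sites <- do.call(rbind, c(planted, noise))
  groups <- build_groups(sites)
  cbp <- assemble_cbp(groups[[1L]], groups)
  sig <- cbp_significance(cbp, sites, n_perm = 100, seed = 33)
  expect_gt(sig$SIG, 3)
  expect_error(cbp_significance(cbp, sites, n_perm = 1), "n_perm")
})

test_that("mining deduplicates patterns and extracts the STFBM tally", {
  planted <- lapply(1:5, function(i)
    site_records(paste0("g", i), c(0, 100, 220), c(8, 108, 228), "+",
                 c("m1", "m2", "m3")))
  sites <- do.call(rbind, planted)
  cbps <- mine_cbps(sites)
  expect_length(cbps, 1L) # one pattern, not one copy per seed
  expect_equal(cbps[[1L]]$id, "c-1")
  expect_equal(cbps[[1L]]$GEN, 5)
  stfbm <- extract_stfbm(cbps)
  expect_setequal(stfbm$motifs, c("m1", "m2", "m3"))
  expect_equal(unname(stfbm$counts["m1"]), 1L)
  expect_equal(extract_stfbm(list())$motifs, character())
  # counts match a brute-force tally over CBP membership lists
  tal <- table(unlist(lapply(cbps, `[[`, "motifs")))
  expect_equal(as.integer(stfbm$counts[names(tal)]),
               as.integer(tal))
})

test_that("the DOT topology export encodes adjacency weights", {
  planted <- lapply(1:4, function(i)
    site_records(paste0("g", i), c(0, 100, 220), c(8, 108, 228), "+",
                 c("m1", "m2", "m3")))
  cbps <- mine_cbps(do.call(rbind, planted))
  path <- withr::local_tempfile(fileext = ".dot")
  write_cbp_dot(cbps[[1L]], path)
  dot <- readLines(path)
  expect_true(any(grepl("digraph", dot)))
  expect_true(any(grepl("\"m1/\\+\" -> \"m2/\\+\"", dot)))
  expect_true(any(grepl("weight=1.000", dot)))
})
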