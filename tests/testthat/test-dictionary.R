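toy_blocks <- function(texts) {
  path <- withr::local_tempfile(fileext = ".maf",
                                .local_envir = parent.frame())
  write_toy_maf(path, texts)
  read_maf(path)
}

test_that("extract_words slides one window per reference position", {
  blocks <- toy_blocks(list(g1 = c("ACGTAC", "ACGTAC", "ACGTAC")))
  dict <- extract_words(blocks, 4)
  expect_equal(sort(dict$words), c("ACGT", "CGTA", "GTAC"))
  expect_equal(dict$a, rep(1L, 3L))
  # all species identical: c = a * n_species at every word
  expect_equal(dict$c, dict$a * 3)
  expect_equal(unname(dict$profile[1L, ]), rep(3, 4))
})

test_that("identical words at multiple loci collapse into one entry", {
  blocks <- toy_blocks(list(g1 = c("ACGTACGT", "ACGTACGT", "ACGTACGT"),
                            g2 = c("TTACGTTT", "TTACGTTT", "TTACGTTT")))
  dict <- extract_words(blocks, 4)
  i <- match("ACGT", dict$words)
  expect_equal(dict$a[i], 3L)  # twice in g1 (offsets 0, 4), once in g2
  expect_equal(nrow(dict$loci[dict$loci$word == i, ]), 3L)
})

test_that("windows containing N or gaps in the reference are skipped", {
  blocks <- toy_blocks(list(g1 = c("ACNTACGT", "ACGTACGT", "ACGTACGT")))
  dict <- extract_words(blocks, 4)
  expect_equal(sort(dict$words), c("ACGT", "TACG"))
  blocks <- toy_blocks(list(g1 = c("AC-TACGT", "ACGTACGT", "ACGTACGT")))
  dict <- extract_words(blocks, 4)
  # reference-gap columns are skipped; coordinates follow ungapped ref
  expect_false(any(grepl("-", dict$words)))
  i <- match("TACG", dict$words)
  expect_equal(dict$loci$start[dict$loci$word == i], 2L)
})

test_that("word length beyond the blocks yields an empty dictionary", {
  blocks <- toy_blocks(list(g1 = c("ACGT", "ACGT", "ACGT")))
  dict <- extract_words(blocks, 10)
  expect_length(dict, 0L)
})

test_that("zero site mutation makes planted words fully conserved", {
  motifs <- list(consensus_pwm("ACGTTGCA", id = "m1"))
  cfg <- simulation_config(n_promoters = 6, promoter_length = 150,
                           n_species = 5, background_rate = 0.4,
                           site_rate = 0, motifs = motifs, seed = 3)
  sim <- simulate_promoters(cfg)
  site_dict <- extract_site_words(sim$blocks, sim$truth$sites, 8)
  expect_gt(length(site_dict), 0L)
  expect_equal(site_dict$c, site_dict$a * 5)
})

test_that("species_permutation sorts by Hamming distance with canonical ties", {
  # sp1 distance 2, sp2 distance 1 -> (sp2, sp1)
  blocks <- toy_blocks(list(g1 = c("ACGT", "AGTT", "ACGA")))
  dict <- extract_words(blocks, 4)
  expect_equal(species_permutation(dict, 1L), c("sp2", "sp1"))
  # all identical -> canonical order
  blocks <- toy_blocks(list(g1 = c("ACGT", "ACGT", "ACGT")))
  dict <- extract_words(blocks, 4)
  expect_equal(species_permutation(dict, 1L), c("sp1", "sp2"))
  # gaps count as mismatches
  blocks <- toy_blocks(list(g1 = c("ACGT", "AC-T", "ACGT")))
  dict <- extract_words(blocks, 4)
  expect_equal(species_permutation(dict, 1L), c("sp2", "sp1"))
})

test_that("species similarity ordering follows per-species rates", {
  motifs <- list(random_pwm(8, 0.9, id = "m1"))
  sim <- small_sim(41, n_promoters = 30, promoter_length = 200,
                   n_species = 4, background_rate = c(0.1, 0.3, 0.5),
                   site_rate = c(0.01, 0.02, 0.03), motifs = motifs)
  dict <- extract_words(sim$blocks, 8)
  perms <- species_permutation(dict)
  # the least-mutated species should lead the permutation most often
  lead <- table(perms[, 1L])
  expect_equal(names(which.max(lead)), "sp01")
  expect_gt(mean(perms[, 1L] == "sp01"), mean(perms[, 1L] == "sp03"))
})

test_that("prefix filter keeps learned prefixes and is a contraction", {
  sim <- small_sim(51, n_promoters = 15, promoter_length = 250,
                   n_species = 8, background_rate = 0.35,
                   site_rate = 0.02)
  dict <- extract_words(sim$blocks, 8)
  site_dict <- extract_site_words(sim$blocks, sim$truth$sites, 8)
  out <- prefix_filter(dict, site_dict, k = 5)
  expect_lte(length(out), length(dict))
  expect_true(all(out$words %in% dict$words))
  # every site word itself passes (its prefix is learned)
  self <- prefix_filter(site_dict, site_dict, k = 5)
  expect_equal(length(self), length(site_dict))
  expect_error(prefix_filter(dict, site_dict, k = 100), "exceeds")
  # planted sites pass at a higher rate than background words
  kept_site <- sum(out$words %in% site_dict$words) /
    sum(dict$words %in% site_dict$words)
  kept_bg <- sum(!out$words %in% site_dict$words) /
    sum(!dict$words %in% site_dict$words)
  expect_gt(kept_site, kept_bg)
})

test_that("conservation curve filter matches profiles within tolerance", {
  sim <- small_sim(61, n_promoters = 15, promoter_length = 250,
                   n_species = 8, background_rate = 0.35,
                   site_rate = 0.02)
  dict <- extract_words(sim$blocks, 8)
  site_dict <- extract_site_words(sim$blocks, sim$truth$sites, 8)
  # tolerance 0 keeps words whose profile equals a learned one
  self <- conservation_curve_filter(site_dict, site_dict, 0)
  expect_equal(length(self), length(site_dict))
  tol <- calibrate_curve_tolerance(site_dict, 0.95)
  out <- conservation_curve_filter(dict, site_dict, tol)
  expect_lte(length(out), length(dict))
  kept_site <- sum(out$words %in% site_dict$words) /
    sum(dict$words %in% site_dict$words)
  kept_bg <- sum(!out$words %in% site_dict$words) /
    sum(!dict$words %in% site_dict$words)
  expect_gt(kept_site, kept_bg)
})

test_that("a flat-zero profile is rejected against flat-one references", {
  # distance between all-0 and all-1 profiles of length 8 is sqrt(8)
  mk <- function(match_all) {
    texts <- if (match_all) c("ACGTACGT", "ACGTACGT", "ACGTACGT")
    else c("ACGTACGT", "CATGCATG", "CATGCATG")
    toy_blocks(list(g1 = texts))
  }
  learned <- extract_words(mk(TRUE), 8)   # profile 3/3 everywhere
  query <- extract_words(mk(FALSE), 8)    # profile 1/3 everywhere
  out <- conservation_curve_filter(query, learned, 0.1)
  expect_length(out, 0L)
  out <- conservation_curve_filter(query, learned,
                                   sqrt(8) * (2 / 3) + 0.01)
  expect_length(out, 1L)
})

test_that("merge_dictionaries is the brute-force set intersection", {
  sim <- small_sim(71, n_promoters = 8, promoter_length = 150,
                   n_species = 4)
  dict <- extract_words(sim$blocks, 6)
  set.seed(72)
  i1 <- sample(length(dict), min(100, length(dict)))
  i2 <- sample(length(dict), min(100, length(dict)))
  d1 <- dict_subset(dict, sort(i1))
  d2 <- dict_subset(dict, sort(i2))
  merged <- merge_dictionaries(d1, d2)
  expect_setequal(merged$words, intersect(d1$words, d2$words))
  # identical sets -> same set; disjoint -> empty
  expect_equal(merge_dictionaries(d1, d1)$words, d1$words)
  only1 <- dict_subset(dict, setdiff(seq_along(dict$words), i2))
  expect_length(merge_dictionaries(only1, d2), 0L)
  # bookkeeping preserved
  i <- match(merged$words[1L], dict$words)
  expect_equal(merged$a[1L], dict$a[i])
  expect_equal(merged$c[1L], dict$c[i])
})

test_that("filters are deterministic and permutation order is stable", {
  sim <- small_sim(81, n_promoters = 10, promoter_length = 200,
                   n_species = 6)
  dict <- extract_words(sim$blocks, 8)
  site_dict <- extract_site_words(sim$blocks, sim$truth$sites, 8)
  a <- prefix_filter(dict, site_dict, 3)
  b <- prefix_filter(dict, site_dict, 3)
  expect_identical(a$words, b$words)
})
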