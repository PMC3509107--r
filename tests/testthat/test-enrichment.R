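test_that("consensus windows score zero and mismatches score the closed form", {
  pwm <- consensus_pwm("ACGTACGT", id = "det")
  proms <- c(gA = paste0("TTTT", "ACGTACGT", "TTTT"))
  res <- scan_targets(pwm, proms, theta = 1, eps = 0.01)
  expect_equal(res$genes, "gA")
  expect_equal(res$sites$start, 4L)
  expect_equal(res$sites$seq, "ACGTACGT")
  # a single mismatch against a deterministic PWM scores ln(0.01/1.01)
  # below the consensus; with theta = 1 it fails, lower theta passes
  proms <- c(gB = paste0("TTTT", "ACGTACGA", "TTTT"))
  expect_length(scan_targets(pwm, proms, theta = 1)$genes, 0L)
  w_pen <- log(0.01 / 1.01)
  w_min <- 8 * w_pen
  theta_needed <- 1 - w_pen / w_min # fraction of range at one mismatch
  res <- scan_targets(pwm, proms, theta = theta_needed - 0.01)
  expect_equal(res$genes, "gB")
})

test_that("scanning finds planted consensus sites on the reverse strand", {
  pwm <- consensus_pwm("AAAACCGT", id = "det") # not its own palindrome
  rc <- paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit("AAAACCGT", "")[[1L]]]), collapse = "")
  proms <- c(gC = paste0("TTTT", rc, "TTTT"))
  res <- scan_targets(pwm, proms, theta = 1)
  expect_equal(res$genes, "gC")
  expect_equal(res$sites$strand, "-")
})

test_that("strict scanning recovers exactly the promoters with planted sites", {
  set.seed(41)
  pwm <- consensus_pwm("ACGTTGCA", id = "m")
  proms <- vapply(1:40, function(i) random_word(300), character(1L))
  names(proms) <- paste0("g", 1:40)
  with_site <- paste0("g", sample(40, 10))
  for (g in with_site) {
    proms[g] <- paste0(substr(proms[g], 1, 100), "ACGTTGCA",
                       substr(proms[g], 109, 300))
  }
  res <- scan_targets(pwm, proms, theta = 1)
  # every planted promoter is found; chance 8-mers are possible but
  # none occurred under this seed
  expect_setequal(res$genes, with_site)
})

test_that("annotation propagation computes the ancestor closure", {
  ann <- annotation_set(
    gene2term = list(g1 = "c", g2 = "a"),
    parents = list(c = "b", b = "a"))
  out <- propagate_annotations(ann)
  expect_setequal(out$gene2term$g1, c("a", "b", "c"))
  expect_equal(out$gene2term$g2, "a")
  # idempotent
  again <- propagate_annotations(out)
  expect_equal(again$gene2term, out$gene2term)
  # diamond DAG equals brute-force reachability
  ann <- annotation_set(
    gene2term = list(g = "d"),
    parents = list(d = c("b", "c"), b = "a", c = "a"))
  out <- propagate_annotations(ann)
  expect_setequal(out$gene2term$g, c("a", "b", "c", "d"))
  # cycles are an error
  ann <- annotation_set(gene2term = list(g = "x"),
                        parents = list(x = "y", y = "x"))
  expect_error(propagate_annotations(ann), "cycle")
})

test_that("hypergeometric p equals exact combinatorics for all small universes", {
  for (N in c(5L, 8L, 12L, 16L, 20L)) {
    genes <- paste0("g", seq_len(N))
    for (K in c(2L, N %/% 2, N - 1L)) {
      for (n in c(2L, N %/% 2)) {
        term_genes <- genes[seq_len(K)]
        targets <- genes[seq_len(n)]
        ann <- annotation_set(
          gene2term = setNames(rep(list("t1"), K), term_genes),
          universe = genes)
        df <- hypergeom_enrich(targets, ann)
        k <- length(intersect(term_genes, targets))
        if (k == 0L) {
          expect_equal(nrow(df), 0L)
        } else {
          expect_equal(df$p, hyper_upper_oracle(k, K, N, n),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d", N, K, n))
          expect_equal(df$q, df$p) # single test: BH leaves p unchanged
        }
      }
    }
  }
})

test_that("a term exclusive to the whole target set is maximally significant", {
  N <- 12L; n <- 4L
  genes <- paste0("g", seq_len(N))
  targets <- genes[1:n]
  ann <- annotation_set(
    gene2term = setNames(rep(list("t1"), n), targets),
    universe = genes)
  df <- hypergeom_enrich(targets, ann)
  expect_equal(df$p, 1 / choose(N, n), tolerance = 1e-12)
})

test_that("BH q-values match the closed-form step-up on a toy p-list", {
  # direct check of the multiple-testing behaviour hypergeom_enrich uses
  p <- c(0.01, 0.02, 0.03, 0.04, 0.9)
  expect_equal(p.adjust(p, "BH"), c(0.05, 0.05, 0.05, 0.05, 0.9))
  genes <- paste0("g", 1:20)
  g2t <- lapply(setNames(genes, genes), function(g) character())
  # five terms with varying overlap into a fixed target set
  for (i in 1:5) {
    members <- genes[seq_len(4 * i)]
    for (g in members) g2t[[g]] <- c(g2t[[g]], paste0("t", i))
  }
  ann <- annotation_set(g2t, universe = genes)
  df <- hypergeom_enrich(genes[1:6], ann)
  expect_true(all(df$q >= df$p))
  expect_true(all(diff(df$q[order(df$p)]) >= -1e-12)) # monotone in p
})

test_that("null simulation attains its analytic type-I error", {
  # fixed design: N = 1000, K = 500, n = 200; the discrete attained
  # level at alpha = 0.05 is P(X >= 111) = 0.0484
  N <- 1000L; K <- 500L; n <- 200L
  genes <- paste0("g", seq_len(N))
  ann <- annotation_set(
    gene2term = setNames(rep(list("t1"), K), genes[seq_len(K)]),
    universe = genes)
  set.seed(42)
  rejections <- replicate(1000, {
    targets <- sample(genes, n)
    df <- hypergeom_enrich(targets, ann)
    nrow(df) == 1L && df$p <= 0.05
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rejections) - 0.05), 3 * se)
})

test_that("ontology distance is the Jaccard distance and a metric", {
  expect_equal(ontology_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(ontology_distance(c("a"), c("b")), 1)
  expect_equal(ontology_distance(c("a", "b"), c("a", "b", "c", "d",
                                                "e", "f", "g", "h"))
               , 0.75)
  expect_warning(d <- ontology_distance(character(), character()),
                 "empty")
  expect_equal(d, 1)
  # triangle inequality on random sets
  set.seed(43)
  for (i in 1:100) {
    s <- function() sample(letters[1:8], sample(1:6, 1))
    A <- s(); B <- s(); C <- s()
    expect_lte(ontology_distance(A, C),
               ontology_distance(A, B) + ontology_distance(B, C) + 1e-12)
  }
})

test_that("the ontology map links nearest neighbours and significant terms", {
  term_sets <- list(o1 = c("a", "b"), o2 = c("a", "b"), o3 = c("x"))
  edges <- ontology_map_graph(term_sets, top_n = 1)
  nb <- edges[edges$type == "neighbour", ]
  expect_equal(nb$to[nb$from == "o1"], "o2")
  expect_equal(nb$weight[nb$from == "o1"], 1)
  # brute-force check of neighbour lists on random objects
  set.seed(44)
  sets <- lapply(1:15, function(i) sample(letters[1:10], sample(2:6, 1)))
  names(sets) <- paste0("o", 1:15)
  edges <- ontology_map_graph(sets, top_n = 3)
  for (id in names(sets)) {
    d <- vapply(setdiff(names(sets), id), function(j)
      ontology_distance(sets[[id]], sets[[j]]), numeric(1L))
    expected <- names(sort(d))[1:3]
    got <- edges$to[edges$from == id & edges$type == "neighbour"]
    expect_equal(sort(unname(vapply(got, function(g) d[[g]],
                                    numeric(1L)))),
                 sort(unname(d[expected])), tolerance = 1e-12)
  }
  # alpha = 0 suppresses object-term edges
  enr <- list(o1 = data.frame(term = "a", k = 1, K = 1, n = 1, N = 2,
                              p = 0.001, q = 0.001))
  edges <- ontology_map_graph(term_sets, enr, top_n = 1, alpha = 0)
  expect_length(edges$to[edges$type == "term"], 0L)
  edges <- ontology_map_graph(term_sets, enr, top_n = 1, alpha = 0.05)
  expect_equal(edges$to[edges$type == "term"], "a")
  # DOT export
  path <- withr::local_tempfile(fileext = ".dot")
  write_graph_dot(edges, path)
  expect_true(any(grepl("o1.*--.*a|o1.*--.*o2", readLines(path))))
})
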