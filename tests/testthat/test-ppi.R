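# Brute-force O(n^2) edge-count oracle.
count_edges_oracle <- function(set, edges, cutoff) {
  n <- 0L
  seen <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    if (key %in% seen) next
    if (a %in% set && b %in% set &&
        !is.na(edges$score[i]) && edges$score[i] > cutoff) {
      n <- n + 1L
      seen <- c(seen, key)
    }
  }
  n
}

test_that("edge counting matches a brute-force oracle and its basics", {
  expect_equal(count_edges(character(), data.frame(protein_a = "a",
                                                   protein_b = "b",
                                                   score = 1)), 0L)
  # complete 4-node graph, all scores 1, cutoff 0.7 -> C(4,2)
  pairs <- t(combn(letters[1:4], 2))
  e4 <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2], score = 1)
  expect_equal(count_edges(letters[1:4], e4, 0.7), 6L)
  set.seed(31)
  prot <- sprintf("p%02d", 1:30)
  e <- data.frame(protein_a = sample(prot, 220, TRUE),
                  protein_b = sample(prot, 220, TRUE),
                  score = runif(220))
  set <- sample(prot, 14)
  for (cut in c(0.2, 0.5, 0.8))
    expect_equal(count_edges(set, e, cut), count_edges_oracle(set, e, cut))
})

test_that("edge counts are monotone non-increasing in the score cutoff", {
  net <- generate_ppi_network(net_sim_config(n_proteins = 60, seed = 3))
  set <- sample(unique(c(net$edges$protein_a, net$edges$protein_b)), 25)
  cnt <- sapply(seq(0, 1, 0.1), function(ct) count_edges(set, net$edges, ct))
  expect_true(all(diff(cnt) <= 0))
})

test_that("unscored sources are counted only on request", {
  e <- data.frame(protein_a = c("a", "a"), protein_b = c("b", "c"),
                  score = c(0.9, NA))
  expect_equal(count_edges(c("a", "b", "c"), e, 0.7), 1L)
  expect_equal(count_edges(c("a", "b", "c"), e, 0.7,
                           include_unscored = TRUE), 2L)
})

test_that("null sampling hits its closed-form extremes deterministically", {
  prot <- sprintf("p%02d", 1:12)
  edgeless <- data.frame(protein_a = character(), protein_b = character(),
                         score = numeric())
  expect_true(all(sample_null(prot, 5, edgeless, 0.7, 20, 1)$counts == 0))
  pairs <- t(combn(prot, 2))
  full <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                     score = 1)
  expect_true(all(sample_null(prot, 6, full, 0.5, 25, 2)$counts == choose(6, 2)))
  expect_true(all(sample_null(prot, 12, full, 0.5, 5, 3)$counts ==
                    count_edges(prot, full, 0.5)))
  n1 <- sample_null(prot, 6, full, 0.5, 10, 4)
  expect_identical(n1$counts, sample_null(prot, 6, full, 0.5, 10, 4)$counts)
  expect_error(sample_null(prot, 13, full, 0.5), "exceeds")
})

# Independent 2^n enumeration oracle for the one-sample signed-rank test.
signed_rank_oracle <- function(x, mu) {
  d <- (x - mu)[x != mu]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

test_that("exact signed-rank p matches full sign enumeration for n <= 12", {
  set.seed(5)
  cases <- list(
    rpois(8, 10),
    c(3, 3, 5, 7, 7, 7, 9),          # heavy ties
    rnorm(12),
    c(1, 2, 4, 8, 16, 32),
    rep(c(2, 5), 6))                  # maximal ties
  for (x in cases) {
    for (mu in c(0, median(x), max(x) + 1)) {
      got <- signed_rank_test(x, mu)
      expect_equal(got$p, signed_rank_oracle(x, mu), tolerance = 1e-12)
    }
  }
})

test_that("exact signed-rank p agrees with wilcox.test when tie-free", {
  set.seed(6)
  x <- rnorm(10)
  ref <- wilcox.test(x, mu = 0.2, exact = TRUE)
  got <- signed_rank_test(x, 0.2)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("the normal approximation matches wilcox.test without continuity", {
  set.seed(9)
  x <- round(rnorm(60, 10, 3))
  ref <- wilcox.test(x, mu = 9, exact = FALSE, correct = FALSE)
  got <- signed_rank_test(x, 9)
  expect_equal(got$method, "normal")
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("enrichment folds and flags behave at the reference points", {
  null <- structure(list(counts = c(2, 3, 4, 4, 4, 5, 6, 4, 3, 5, 4, 4, 6, 2),
                         set_size = 5, n_samples = 14, cutoff = 0.7,
                         seed = 1), class = "null_distribution")
  res <- enrichment_test(4, null)     # observed at the null median
  expect_equal(res$fold, 1)
  expect_gt(res$p, 0.5)
  far <- enrichment_test(50, null)    # far above every null count
  # saturates at the minimum attainable p (all signs negative)
  expect_equal(far$p, enrichment_test(60, null)$p, tolerance = 1e-12)
  expect_lt(far$p, 0.005)
  zero <- structure(list(counts = rep(0L, 10), set_size = 3, n_samples = 10,
                         cutoff = 0.7, seed = 1),
                    class = "null_distribution")
  res0 <- enrichment_test(3, zero)
  expect_false(res0$fold_defined)
  expect_true(is.na(res0$fold))
})

test_that("combined networks merge sources and compute degrees correctly", {
  empty <- build_combined_network(letters[1:3],
                                  list(s1 = data.frame(protein_a = character(),
                                                       protein_b = character(),
                                                       score = numeric())))
  expect_equal(nrow(empty$nodes), 0L)

  string_like <- data.frame(protein_a = c("a", "b", "c"),
                            protein_b = c("b", "c", "d"),
                            score = c(0.9, 0.5, 0.95), source = "string-like")
  rna_ppi <- data.frame(protein_a = c("a", "a"), protein_b = c("b", "d"),
                        score = NA_real_, source = "rna-ppi")
  net <- build_combined_network(c("a", "b", "c", "d"),
                                list(string = string_like, rna = rna_ppi),
                                cutoffs = c(string = 0.7))
  # a-b supported twice -> one node pair, two tagged links
  ab <- net$edges[net$edges$protein_a == "a" & net$edges$protein_b == "b", ]
  expect_equal(nrow(ab), 2L)
  expect_setequal(ab$source, c("string-like", "rna-ppi"))
  # b-c fails the cutoff; c only connects via c-d
  expect_false(any(net$edges$protein_a == "b" & net$edges$protein_b == "c"))
  # degree = distinct partners on the union
  deg_oracle <- sapply(net$nodes$protein, function(p) {
    pairs <- unique(net$edges[, 1:2])
    sum(pairs$protein_a == p | pairs$protein_b == p)
  })
  expect_equal(net$nodes$degree, unname(deg_oracle))
  # isolated proteins are dropped from the view
  net2 <- build_combined_network(c("a", "b", "z"),
                                 list(string = string_like),
                                 cutoffs = c(string = 0.7))
  expect_false("z" %in% net2$nodes$protein)
})

test_that("graphml export round-trips through igraph", {
  e <- data.frame(protein_a = c("a", "b"), protein_b = c("b", "c"),
                  score = c(0.9, 0.8), source = "string-like")
  net <- build_combined_network(c("a", "b", "c"), list(s = e),
                                cutoffs = c(s = 0.7))
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  unlink(path)
})
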