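test_that("marginal entropy matches closed forms", {
  expect_equal(marginal_entropy(rep(1, 10)), 0)
  expect_equal(marginal_entropy(c(1, 1, 0, 0), base = 2), 1)
  # p = 0.25: -(1/4) ln(1/4) - (3/4) ln(3/4)
  expect_equal(marginal_entropy(c(1, 0, 0, 0)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-12)
  expect_error(marginal_entropy(numeric(0)), "empty")
  expect_error(marginal_entropy(c(0, 2)), "binary")
})

test_that("joint entropy degenerates correctly", {
  x <- c(1, 1, 0, 0, 1)
  expect_equal(joint_entropy(x, x), marginal_entropy(x))
  y <- c(1, 0, 1, 0, 1)
  expect_equal(joint_entropy(rep(1, 5), y), marginal_entropy(y))
  expect_error(joint_entropy(x, y[1:3]), "length mismatch")
  # near-independent planted columns: joint ~ sum of marginals
  set.seed(1)
  a <- rbinom(5000, 1, 0.3); b <- rbinom(5000, 1, 0.6)
  expect_equal(joint_entropy(a, b), marginal_entropy(a) + marginal_entropy(b),
               tolerance = 0.01)
})

test_that("mutual information matches the brute-force cell sum", {
  expect_equal(mutual_information(c(1, 0, 1, 0), c(1, 0, 1, 0), base = 2), 1)
  expect_equal(mutual_information(rep(1, 6), c(1, 0, 1, 0, 1, 0)), 0)
  v <- vectors_from_counts(40, 10, 10, 40)
  expect_equal(mutual_information(v$a, v$b), mi_bruteforce(40, 10, 10, 40),
               tolerance = 1e-12)
})

test_that("MI is symmetric, bounded, base-consistent and row-duplication invariant", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    a <- rbinom(n, 1, runif(1)); b <- rbinom(n, 1, runif(1))
    mi <- mutual_information(a, b)
    expect_identical(mi, mutual_information(b, a))
    expect_gte(mi, 0)
    expect_lte(mi, min(marginal_entropy(a), marginal_entropy(b)) + 1e-12)
    expect_equal(mutual_information(a, b, base = 2), mi / log(2),
                 tolerance = 1e-12)
    expect_equal(mutual_information(rep(a, 2), rep(b, 2)), mi,
                 tolerance = 1e-12)
  }
})

test_that("plug-in MI equals brute force on all 2x2 tables up to n = 8", {
  for (n in 1:8) {
    for (n11 in 0:n) for (n10 in 0:(n - n11)) for (n01 in 0:(n - n11 - n10)) {
      n00 <- n - n11 - n10 - n01
      v <- vectors_from_counts(n11, n10, n01, n00)
      expect_equal(mutual_information(v$a, v$b),
                   max(mi_bruteforce(n11, n10, n01, n00), 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("pairwise_mi enumerates all unordered pairs consistently", {
  set.seed(3)
  m <- matrix(rbinom(60, 1, 0.5), nrow = 10,
              dimnames = list(NULL, c("c", "a", "b", "f", "e", "d")))
  edges <- pairwise_mi(m)
  expect_equal(nrow(edges), choose(6, 2))
  expect_true(all(edges$gene_a < edges$gene_b))
  # cross-check the vectorized path against the scalar implementation
  for (i in sample(nrow(edges), 8)) {
    expect_equal(edges$mi[i],
                 mutual_information(m[, edges$gene_a[i]],
                                    m[, edges$gene_b[i]]),
                 tolerance = 1e-12)
  }
  expect_error(pairwise_mi(m[, 1, drop = FALSE]), "at least 2 genes")

  dup <- cbind(x = c(1, 1, 0, 0), y = c(1, 1, 0, 0))
  expect_equal(pairwise_mi(dup)$mi, marginal_entropy(dup[, 1]))
  const <- cbind(x = c(1, 1, 1, 1), y = c(1, 0, 1, 0))
  e2 <- pairwise_mi(const)
  expect_equal(e2$mi, 0)
  expect_equal(attr(e2, "constant_genes"), "x")
})

test_that("pairwise_mi defaults to the CPR genomes of a pa_matrix", {
  m <- rbind(g1 = c(1, 1), g2 = c(0, 0), g3 = c(1, 0), g4 = c(0, 1))
  colnames(m) <- c("a", "b")
  pa <- make_pa(m, group = c("CPR", "CPR", "nonCPR", "nonCPR"))
  e <- pairwise_mi(pa)
  expect_equal(attr(e, "n_genomes"), 2L)
  expect_equal(e$mi, marginal_entropy(c(1, 0)))       # perfectly coupled in CPR
  expect_equal(attr(pairwise_mi(pa, group = NULL), "n_genomes"), 4L)
})

test_that("thresholding is closed at the bound and sweep counts are monotone", {
  edges <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                      mi = c(0.336, 0.09, 0.1))
  net <- threshold_network(edges, tau = 0.1)
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$mi >= 0.1))
  expect_equal(nrow(threshold_network(edges, tau = 0)$edges), 3)

  sw <- threshold_sweep(edges, c(0, 0.05, 0.1, 0.2, 1))
  expect_equal(sw$n_edges, c(3L, 3L, 2L, 1L, 0L))
  expect_true(all(diff(sw$n_edges) <= 0))
  expect_error(threshold_sweep(edges, c(0.2, 0.1)), "ascending")
})

test_that("node statistics report degree, weight and explicit tie sets", {
  star <- threshold_network(
    data.frame(gene_a = c("hub", "hub", "b"), gene_b = c("a", "b", "hub"),
               mi = c(0.2, 0.2, 0.2)), tau = 0.1)
  st <- node_stats(star)
  expect_equal(st$degree[st$gene_id == "hub"], 3L)
  expect_equal(st$weight[st$gene_id == "hub"], 0.6)
  expect_equal(attr(st, "argmax")$by_weight, "hub")

  two <- threshold_network(data.frame(gene_a = "a", gene_b = "b", mi = 0.3),
                           tau = 0.1)
  st2 <- node_stats(two)
  expect_equal(st2$degree, c(1L, 1L))
  expect_setequal(attr(st2, "argmax")$by_degree, c("a", "b"))
  empty <- threshold_network(data.frame(gene_a = "a", gene_b = "b", mi = 0.01),
                             tau = 0.1)
  expect_error(node_stats(empty), "no edges")
})

test_that("isolated catalogue genes are retained and flagged", {
  cat3 <- default_catalog()[1:3, ]
  edges <- data.frame(gene_a = cat3$gene_id[1], gene_b = cat3$gene_id[2],
                      mi = 0.5)
  net <- threshold_network(edges, tau = 0.1, catalog = cat3)
  expect_equal(sum(net$nodes$isolated), 1L)
  expect_equal(net$nodes$gene_id[net$nodes$isolated], cat3$gene_id[3])
})

test_that("graphml export round-trips through igraph", {
  f <- withr::local_tempfile(fileext = ".graphml")
  net <- threshold_network(
    data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"), mi = c(0.3, 0.2)),
    tau = 0.1)
  write_network_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
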