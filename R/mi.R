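# Entropy / mutual-information machinery on binary occurrence profiles.
# Plug-in (empirical) estimators with no pseudocounts, matching the
# H(A) = -sum p(a) log p(a), H(A,B) = -sum sum p(a,b) log p(a,b),
# MI(A,B) = H(A) + H(B) - H(A,B) definitions. The log base is configurable
# ("nat" for natural log, or a numeric base such as 2) and is recorded on
# every result.

log_div <- function(base) {
  if (identical(base, "nat")) return(1)
  if (is.numeric(base) && length(base) == 1L && base > 0 && base != 1)
    return(log(base))
  stop("base must be \"nat\" or a positive numeric != 1", call. = FALSE)
}

check_binary <- function(x, what = "column") {
  if (length(x) == 0L) stop(what, " is empty", call. = FALSE)
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop(what, " must be binary 0/1 with no NA", call. = FALSE)
  invisible(x)
}

entropy_from_counts <- function(counts, base = "nat") {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p)) / log_div(base)
}

#' Entropy and mutual information of binary gene profiles
#'
#' `marginal_entropy()` is the entropy of the empirical Bernoulli distribution
#' of one presence/absence column; `joint_entropy()` the entropy of the
#' empirical joint distribution over the four (present/absent x
#' present/absent) cells; `mutual_information()` is
#' `H(A) + H(B) - H(A,B)`, clipped to 0 when round-off makes it negative by
#' less than 1e-12. `0 * log 0` is treated as 0 throughout.
#'
#' @param x,y Binary (0/1) vectors of equal length.
#' @param base Logarithm base: `"nat"` (natural log, the default) or a
#'   number such as `2`.
#' @return A non-negative scalar.
#' @examples
#' marginal_entropy(c(1, 1, 0, 0), base = 2) # fair coin: 1 bit
#' mutual_information(c(1, 0, 1, 0), c(1, 0, 1, 0), base = 2)
#' @export
marginal_entropy <- function(x, base = "nat") {
  check_binary(x)
  entropy_from_counts(c(sum(x == 0), sum(x == 1)), base)
}

#' @rdname marginal_entropy
#' @export
joint_entropy <- function(x, y, base = "nat") {
  check_binary(x, "first column")
  check_binary(y, "second column")
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  entropy_from_counts(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                        sum(x == 0 & y == 1), sum(x == 0 & y == 0)), base)
}

#' @rdname marginal_entropy
#' @export
mutual_information <- function(x, y, base = "nat") {
  mi <- marginal_entropy(x, base) + marginal_entropy(y, base) -
    joint_entropy(x, y, base)
  if (mi < 0) {
    if (mi < -1e-9)
      stop("negative mutual information beyond numerical tolerance")
    mi <- 0
  }
  mi
}

#' Pairwise mutual information over all gene pairs
#'
#' Computes the plug-in MI for every unordered pair of genes (columns) over
#' the selected genomes: `n * (n - 1) / 2` edges for `n` genes, e.g. 11781
#' pairs for the default 154-gene catalogue. By default the computation is
#' restricted to CPR genomes when the matrix metadata contains that group,
#' since the dependency network of interest is within the reduced-genome
#' lineage; pass `group = NULL` to use all genomes.
#'
#' Genes that are constant (present or absent in every selected genome) have
#' zero entropy and hence MI 0 with every partner; they are retained and
#' flagged in the `constant_genes` attribute rather than dropped.
#'
#' @param pa A `pa_matrix`, or a plain binary matrix (genomes x genes).
#' @param genes Optional subset of gene ids (>= 2).
#' @param group Group of genomes to use: `"auto"` (the default) selects the
#'   CPR genomes when the metadata has that group and all genomes otherwise;
#'   `NULL` forces all genomes; any other value is a metadata group label.
#' @param base Log base, see [marginal_entropy()].
#' @return A data.frame of class `mi_edges` with columns `gene_a`, `gene_b`
#'   (canonical order `gene_a < gene_b`), `mi`; attributes `base`,
#'   `n_genomes`, `group`, `constant_genes`.
#' @export
pairwise_mi <- function(pa, genes = NULL, group = "auto", base = "nat") {
  if (inherits(pa, "pa_matrix")) {
    if (identical(group, "auto"))
      group <- if (any(pa$metadata$group == "CPR")) "CPR" else NULL
    m <- subset_pa(pa, group = group, genes = genes)$mat
  } else {
    m <- as.matrix(pa)
    if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (nrow(m) < 1L) stop("no genomes selected", call. = FALSE)
  check_binary(as.vector(m), "matrix")
  storage.mode(m) <- "double"
  n <- nrow(m)
  plogp <- function(cnt) {                 # cnt/n * log(cnt/n), 0 at cnt = 0
    out <- matrix(0, nrow(cnt), ncol(cnt))
    pos <- cnt > 0
    out[pos] <- (cnt[pos] / n) * log(cnt[pos] / n)
    out
  }
  n11 <- crossprod(m)
  c1 <- colSums(m)
  n10 <- outer(c1, rep(1, length(c1))) - n11   # a present, b absent
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  h_joint <- -(plogp(n11) + plogp(n10) + plogp(n01) + plogp(n00))
  h1 <- vapply(seq_along(c1),
               function(i) entropy_from_counts(c(c1[i], n - c1[i])), 0)
  mi <- outer(h1, h1, "+") - h_joint
  mi[mi < 0] <- 0                               # round-off only
  mi <- mi / log_div(base)

  idx <- which(upper.tri(mi), arr.ind = TRUE)
  ga <- colnames(m)[idx[, 1]]
  gb <- colnames(m)[idx[, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga, gene_b = gb, mi = mi[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL
  structure(edges, base = base, n_genomes = n, group = group,
            constant_genes = colnames(m)[c1 == 0 | c1 == n],
            class = c("mi_edges", "data.frame"))
}

#' Threshold an MI edge list into a dependency network
#'
#' Retains edges with `mi >= tau` (closed bound: a pair at exactly the
#' threshold is kept).
#'
#' @param edges `mi_edges` from [pairwise_mi()].
#' @param tau Non-negative MI threshold (default 0.1).
#' @param catalog Optional catalogue used to attach role labels and to list
#'   isolated catalogue genes.
#' @return Object of class `dependency_network`: list with `edges`, `nodes`
#'   (with `isolated` flag), `threshold`, `base`.
#' @export
threshold_network <- function(edges, tau = 0.1, catalog = NULL) {
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  keep <- edges[edges$mi >= tau, , drop = FALSE]
  rownames(keep) <- NULL
  connected <- unique(c(keep$gene_a, keep$gene_b))
  all_genes <- if (!is.null(catalog)) catalog$gene_id else
    unique(c(edges$gene_a, edges$gene_b))
  nodes <- data.frame(gene_id = union(connected, all_genes),
                      stringsAsFactors = FALSE)
  nodes$isolated <- !(nodes$gene_id %in% connected)
  if (!is.null(catalog))
    nodes$role <- catalog$role[match(nodes$gene_id, catalog$gene_id)]
  structure(list(edges = keep, nodes = nodes, threshold = tau,
                 base = attr(edges, "base") %||% "nat"),
            class = "dependency_network")
}

#' @export
print.dependency_network <- function(x, ...) {
  cat(sprintf("dependency network: %d edges with MI >= %g (%d connected, %d isolated nodes)\n",
              nrow(x$edges), x$threshold, sum(!x$nodes$isolated),
              sum(x$nodes$isolated)))
  invisible(x)
}

#' Node degree and cumulative edge weight
#'
#' Per-node statistics of a thresholded dependency network: the degree
#' (number of incident edges) and the cumulative weight (sum of incident MI
#' values). The nodes attaining the maxima are reported as sets in the
#' `argmax` attribute, so ties are explicit.
#'
#' @param network A `dependency_network`.
#' @return Data.frame (gene_id, degree, weight) sorted by decreasing weight;
#'   attribute `argmax` is `list(by_degree = ..., by_weight = ...)`.
#' @export
node_stats <- function(network) {
  e <- network$edges
  if (nrow(e) == 0L) stop("network has no edges", call. = FALSE)
  genes <- sort(unique(c(e$gene_a, e$gene_b)))
  deg <- table(factor(c(e$gene_a, e$gene_b), levels = genes))
  wt <- tapply(c(e$mi, e$mi), factor(c(e$gene_a, e$gene_b), levels = genes),
               sum)
  out <- data.frame(gene_id = genes, degree = as.integer(deg),
                    weight = as.numeric(wt), stringsAsFactors = FALSE)
  out <- out[order(-out$weight, -out$degree, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "argmax") <- list(
    by_degree = out$gene_id[out$degree == max(out$degree)],
    by_weight = out$gene_id[out$weight >= max(out$weight) - 1e-12])
  out
}

#' Sweep the MI threshold
#'
#' Applies [threshold_network()] at each threshold and records the edge count
#' (monotone non-increasing) and the argmax nodes by degree and by weight, to
#' check that hub identity is stable as the dependency definition varies.
#'
#' @param edges `mi_edges`.
#' @param taus Ascending numeric thresholds.
#' @return Data.frame (tau, n_edges) with list columns `argmax_degree`,
#'   `argmax_weight` (empty when no edges survive).
#' @export
threshold_sweep <- function(edges, taus) {
  if (is.unsorted(taus)) stop("taus must be sorted ascending", call. = FALSE)
  rows <- lapply(taus, function(tau) {
    net <- threshold_network(edges, tau)
    if (nrow(net$edges) == 0L)
      return(list(tau = tau, n_edges = 0L, argmax_degree = character(0),
                  argmax_weight = character(0)))
    st <- node_stats(net)
    am <- attr(st, "argmax")
    list(tau = tau, n_edges = nrow(net$edges),
         argmax_degree = am$by_degree, argmax_weight = am$by_weight)
  })
  data.frame(tau = vapply(rows, `[[`, 0, "tau"),
             n_edges = vapply(rows, `[[`, 0L, "n_edges"),
             argmax_degree = I(lapply(rows, `[[`, "argmax_degree")),
             argmax_weight = I(lapply(rows, `[[`, "argmax_weight")))
}

#' Export a dependency network
#'
#' `write_edges_tsv()` writes the edge list; `write_network_graphml()` writes
#' GraphML for external graph viewers.
#'
#' @param network A `dependency_network`.
#' @param path Output file.
#' @export
write_edges_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
write_network_graphml <- function(network, path) {
  vertices <- network$nodes[!network$nodes$isolated, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    network$edges[c("gene_a", "gene_b", "mi")],
    directed = FALSE, vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
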