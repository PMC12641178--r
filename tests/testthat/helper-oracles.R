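# Independent oracles and fixture builders used across the suite.

# Binary vectors realizing a 2x2 contingency table (n11, n10, n01, n00).
vectors_from_counts <- function(n11, n10, n01, n00) {
  list(a = rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
       b = rep(c(1, 0, 1, 0), c(n11, n10, n01, n00)))
}

# Brute-force mutual information: direct sum of p * log(p / (pa * pb)) over
# the four joint cells -- deliberately a different formula from the
# entropy-difference implementation under test.
mi_bruteforce <- function(n11, n10, n01, n00, base = exp(1)) {
  n <- n11 + n10 + n01 + n00
  p <- c(n11, n10, n01, n00) / n
  pa <- c(p[1] + p[2], p[1] + p[2], p[3] + p[4], p[3] + p[4])
  pb <- c(p[1] + p[3], p[2] + p[4], p[1] + p[3], p[2] + p[4])
  keep <- p > 0
  sum(p[keep] * log(p[keep] / (pa[keep] * pb[keep]), base = base))
}

# Brute-force small parsimony: minimum number of state changes over an
# exhaustive enumeration of all internal-node labelings.
parsimony_bruteforce <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- integer(ntip + nint)
  states[seq_len(ntip)] <- tip_states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    states[(ntip + 1):(ntip + nint)] <-
      bitwAnd(bitwShiftR(mask, 0:(nint - 1)), 1L)
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# Minimal pa_matrix built directly from a binary matrix.
make_pa <- function(mat, group = "CPR", taxon_class = "ABY1",
                    roles = NULL, categories = NULL) {
  genomes <- rownames(mat) %||% sprintf("g%02d", seq_len(nrow(mat)))
  genes <- colnames(mat) %||% sprintf("gene%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genomes, genes)
  storage.mode(mat) <- "integer"
  meta <- data.frame(genome_id = genomes,
                     group = rep_len(group, nrow(mat)),
                     taxon_class = rep_len(taxon_class, nrow(mat)),
                     stringsAsFactors = FALSE)
  cat <- data.frame(gene_id = genes,
                    role = rep_len(roles %||% "RBF", ncol(mat)),
                    category = rep_len(categories %||% "other", ncol(mat)),
                    ko_ids = "", stringsAsFactors = FALSE)
  class(cat) <- c("rbf_catalog", "data.frame")
  rbfcoevo:::new_pa_matrix(mat, meta, cat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_catalog <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("gene_id\trole\tcategory\tko_ids", rows), f)
  f
}
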