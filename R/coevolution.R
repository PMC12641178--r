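# Triplet co-evolution of der / rplA / H78 and class-resolved summaries.

TRIPLET_BITS <- c("der", "rplA", "h78")  # fixed bit order, der = high bit

#' Class-resolved conservation table
#'
#' Conservation ratio of each gene within each taxonomic class (heatmap-ready,
#' the clade-resolved analogue of the group-level [conservation_ratio()]).
#'
#' @param pa A `pa_matrix`.
#' @param genes Optional gene subset.
#' @param classes Optional subset of taxon classes; classes with no genomes
#'   are skipped with a warning.
#' @return Data.frame (taxon_class, gene_id, ratio, n).
#' @export
per_class_conservation <- function(pa, genes = NULL, classes = NULL) {
  sub <- if (is.null(genes)) pa else subset_pa(pa, genes = genes)
  cls <- classes %||% sort(unique(sub$metadata$taxon_class))
  empty <- cls[!cls %in% sub$metadata$taxon_class]
  if (length(empty)) {
    warning("skipping empty class(es): ", paste(empty, collapse = ", "))
    cls <- setdiff(cls, empty)
  }
  do.call(rbind, lapply(cls, function(cl) {
    rows <- sub$metadata$taxon_class == cl
    data.frame(taxon_class = cl, gene_id = colnames(sub$mat),
               ratio = colMeans(sub$mat[rows, , drop = FALSE]),
               n = sum(rows), row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Encode der/rplA/H78 triplet states
#'
#' Packs, per genome, the ordered presence bits of the GTPase gene `der`, the
#' uL1 gene `rplA`, and 23S rRNA helix 78 into a state in 0..7. The bit order
#' is fixed as (der, rplA, H78) with der as the most significant bit, so
#' e.g. (der = 0, rplA = 1, H78 = 1) encodes as 3. Genomes with no H78 call
#' are excluded and counted in the `n_excluded` attribute.
#'
#' @param pa A `pa_matrix` containing `der` and `rplA` columns.
#' @param h78_calls Named 0/1 vector of helix-78 presence per genome (from
#'   [h78_presence_calls()] or a generator).
#' @return Data.frame of class `triplet_states` (genome_id, taxon_class, der,
#'   rplA, h78, state).
#' @export
encode_triplets <- function(pa, h78_calls) {
  need <- setdiff(c("der", "rplA"), colnames(pa$mat))
  if (length(need))
    stop("matrix lacks gene(s): ", paste(need, collapse = ", "), call. = FALSE)
  ids <- rownames(pa$mat)
  have <- ids %in% names(h78_calls) & !is.na(h78_calls[ids])
  out <- data.frame(genome_id = ids[have],
                    taxon_class = pa$metadata$taxon_class[have],
                    der = as.integer(pa$mat[have, "der"]),
                    rplA = as.integer(pa$mat[have, "rplA"]),
                    h78 = as.integer(h78_calls[ids[have]]),
                    stringsAsFactors = FALSE)
  out$state <- encode_triplet_state(out$der, out$rplA, out$h78)
  attr(out, "n_excluded") <- sum(!have)
  class(out) <- c("triplet_states", "data.frame")
  out
}

#' @rdname encode_triplets
#' @param der,rplA,h78 Bit vectors.
#' @export
encode_triplet_state <- function(der, rplA, h78) {
  stopifnot(all(c(der, rplA, h78) %in% 0:1))
  as.integer(der * 4L + rplA * 2L + h78)
}

#' @rdname encode_triplets
#' @param state Integer state(s) in 0..7.
#' @export
decode_triplet_state <- function(state) {
  stopifnot(all(state %in% 0:7))
  cbind(der = state %/% 4L, rplA = (state %/% 2L) %% 2L, h78 = state %% 2L)
}

#' Per-class triplet state proportions
#'
#' For each taxon class, the proportion of genomes in each observed triplet
#' state (the dot-plot summary of presence/absence combinations per class).
#' Proportions sum to 1 within each class.
#'
#' @param states A `triplet_states` data.frame.
#' @return Data.frame (taxon_class, state, count, proportion); attribute
#'   `modal_state` is the named per-class modal state.
#' @export
class_state_proportions <- function(states) {
  out <- do.call(rbind, lapply(split(states, states$taxon_class), function(d) {
    tab <- table(d$state)
    data.frame(taxon_class = d$taxon_class[1],
               state = as.integer(names(tab)),
               count = as.integer(tab),
               proportion = as.numeric(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  modal <- vapply(split(out, out$taxon_class),
                  function(d) d$state[which.max(d$count)], 0L)
  attr(out, "modal_state") <- modal
  out
}

#' Ancestral triplet states on a phylogeny
#'
#' Reconstructs the der, rplA and H78 bits independently by Fitch parsimony
#' ([fitch_reconstruct()]) and combines them into a triplet state per node.
#'
#' @param tree Rooted binary `phylo` whose tips are genome ids.
#' @param states A `triplet_states` data.frame covering the tree's tips.
#' @inheritParams fitch_reconstruct
#' @return List with `node_states` (0..7 per node), `histories` (per-bit
#'   `character_history`), `tip_class` (named classes for tips).
#' @export
triplet_history <- function(tree, states, root_resolve = "present") {
  m <- as.matrix(states[c("der", "rplA", "h78")])
  rownames(m) <- states$genome_id
  keep <- rownames(m) %in% tree$tip.label
  if (!all(keep))
    message(sum(!keep), " genome(s) absent from the tree dropped")
  m <- m[keep, , drop = FALSE]
  hist <- lapply(colnames(m), function(b)
    fitch_reconstruct(tree, stats::setNames(m[, b], rownames(m)),
                      root_resolve = root_resolve))
  names(hist) <- colnames(m)
  node_states <- encode_triplet_state(hist$der$states, hist$rplA$states,
                                      hist$h78$states)
  names(node_states) <- names(hist$der$states)
  list(node_states = node_states, histories = hist,
       tip_class = stats::setNames(states$taxon_class, states$genome_id))
}

#' Trajectory graph of triplet state transitions
#'
#' Builds the directed graph of ancestral-to-descendant triplet state changes
#' along the tree: nodes are the observed states, each transition edge is a
#' parent-to-child branch whose state changed, annotated with the taxon class
#' of the subtending clade (`"mixed"` when the descendants span classes).
#'
#' @param tree Rooted binary `phylo`.
#' @param node_states Integer 0..7 state per node (tips first, as returned in
#'   `triplet_history()$node_states`), or the list returned by
#'   [triplet_history()].
#' @param tip_class Optional named class per tip (taken from the
#'   `triplet_history` result when that is supplied).
#' @return Object of class `trajectory_graph`: list with `nodes` (observed
#'   states), `edges` (from_state, to_state, n, classes) and the tree.
#' @export
trajectory_graph <- function(tree, node_states, tip_class = NULL) {
  if (is.list(node_states) && !is.null(node_states$node_states)) {
    tip_class <- tip_class %||% node_states$tip_class
    node_states <- node_states$node_states
  }
  ntip <- length(tree$tip.label)
  if (length(node_states) != ntip + tree$Nnode)
    stop("need a state for every node of the tree", call. = FALSE)
  if (anyNA(node_states)) stop("missing ancestral states", call. = FALSE)
  edge <- tree$edge
  changed <- which(node_states[edge[, 1]] != node_states[edge[, 2]])
  pp <- ape::prop.part(tree)   # tip sets per internal node (root first)
  clade_class <- function(node) {
    tips <- if (node <= ntip) node else pp[[node - ntip]]
    cls <- unique(tip_class[tree$tip.label[tips]])
    if (is.null(tip_class)) NA_character_
    else if (length(cls) == 1L) cls else "mixed"
  }
  edges <- data.frame(
    from_state = as.integer(node_states[edge[changed, 1]]),
    to_state = as.integer(node_states[edge[changed, 2]]),
    child = edge[changed, 2],
    clade_class = vapply(edge[changed, 2], clade_class, ""),
    stringsAsFactors = FALSE)
  agg <- if (nrow(edges)) {
    a <- stats::aggregate(child ~ from_state + to_state + clade_class,
                          data = edges, FUN = length)
    names(a)[names(a) == "child"] <- "n"
    a[order(a$from_state, a$to_state), ]
  } else data.frame(from_state = integer(0), to_state = integer(0),
                    clade_class = character(0), n = integer(0))
  rownames(agg) <- NULL
  structure(list(nodes = sort(unique(as.integer(node_states))),
                 edges = agg, tree = tree),
            class = "trajectory_graph")
}

#' @export
print.trajectory_graph <- function(x, ...) {
  cat(sprintf("trajectory graph: %d state(s), %d transition type(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    print(within(x$edges, path <- paste0(from_state, " -> ", to_state)))
  invisible(x)
}

#' Extract the transition path seen in a set of classes
#'
#' @param traj A `trajectory_graph`.
#' @param classes Character vector of taxon classes.
#' @return The subset of transition edges whose clade annotation is one of
#'   `classes` (or `"mixed"` clades containing only them are not included).
#' @export
trajectory_path <- function(traj, classes) {
  traj$edges[traj$edges$clade_class %in% classes, , drop = FALSE]
}

#' Pairwise mutual information of the triplet bits
#'
#' MI between the der, rplA and H78 presence profiles across genomes,
#' computed with the same plug-in estimator as the gene network.
#'
#' @param states A `triplet_states` data.frame.
#' @param base Log base, see [marginal_entropy()].
#' @return Data.frame (pair, mi) for der-rplA, rplA-H78, der-H78.
#' @export
triplet_mi <- function(states, base = "nat") {
  if (nrow(states) < 2L) stop("need >= 2 genomes", call. = FALSE)
  pairs <- list(c("der", "rplA"), c("rplA", "h78"), c("der", "h78"))
  data.frame(
    pair = vapply(pairs, paste, "", collapse = "-"),
    mi = vapply(pairs, function(p)
      mutual_information(states[[p[1]]], states[[p[2]]], base = base), 0),
    stringsAsFactors = FALSE)
}
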