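# Fitch small parsimony for a binary character on a rooted binary tree,
# with an explicit most-parsimonious node assignment and the implied
# gain/loss event list.

#' Fitch parsimony reconstruction of a binary character
#'
#' Bottom-up Fitch pass (state sets by intersection, union on conflict; the
#' number of unions is the parsimony score) followed by a top-down resolution
#' into one most-parsimonious assignment: a node whose state set contains its
#' parent's resolved state takes that state (the classical no-extra-change
#' rule); an ambiguous root is resolved toward presence by default, since the
#' focal biogenesis genes are argued to predate the radiation being studied
#' (a Dollo-leaning prior). All nodes whose Fitch set was ambiguous are
#' flagged.
#'
#' @param tree A rooted binary `phylo` tree (see [ape::read.tree()]).
#' @param states Named 0/1 vector with one state per tip label.
#' @param root_resolve State used when the root set is ambiguous:
#'   `"present"` (default) or `"absent"`.
#' @return Object of class `character_history`: list with `score` (parsimony
#'   score = number of events), `states` (0/1 per node, tips then internals,
#'   named by tip label / node number), `events` (data.frame parent, child,
#'   child_label, event in gain/loss), `ambiguous_nodes` (integer node ids).
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' h <- fitch_reconstruct(tr, c(a = 1, b = 1, c = 0, d = 0))
#' h$score # one transition
#' @export
fitch_reconstruct <- function(tree, states,
                              root_resolve = c("present", "absent")) {
  root_resolve <- match.arg(root_resolve)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree))
    stop("tree must be binary (fully resolved)", call. = FALSE)
  ntip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("unlabeled leaf state(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lv <- states[tree$tip.label]
  if (anyNA(lv) || !all(lv %in% c(0, 1)))
    stop("leaf states must be 0/1 with no NA", call. = FALSE)

  nnode <- ntip + tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  set <- integer(nnode)
  set[seq_len(ntip)] <- ifelse(lv == 1, 2L, 1L)
  edge <- tree$edge
  post <- ape::reorder.phylo(tree, "postorder")$edge
  score <- 0L
  # children pairs arrive consecutively in postorder for binary trees
  for (i in seq(1L, nrow(post), by = 2L)) {
    parent <- post[i, 1]
    s1 <- set[post[i, 2]]; s2 <- set[post[i + 1, 2]]
    inter <- bitwAnd(s1, s2)
    if (inter == 0L) {
      set[parent] <- bitwOr(s1, s2)
      score <- score + 1L
    } else set[parent] <- inter
  }

  root <- ntip + 1L
  state <- integer(nnode)
  resolve <- function(s, prefer) {
    if (s == 3L) prefer else if (s == 2L) 1L else 0L
  }
  state[root] <- resolve(set[root], if (root_resolve == "present") 1L else 0L)
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    s <- set[ch]
    parent_bit <- if (state[p] == 1L) 2L else 1L
    state[ch] <- if (bitwAnd(s, parent_bit) != 0L) state[p]
                 else resolve(s, state[p])
  }

  changed <- state[edge[, 1]] != state[edge[, 2]]
  events <- data.frame(parent = edge[changed, 1], child = edge[changed, 2],
                       child_label = ifelse(edge[changed, 2] <= ntip,
                                            tree$tip.label[edge[changed, 2]],
                                            as.character(edge[changed, 2])),
                       event = ifelse(state[edge[changed, 2]] == 1L,
                                      "gain", "loss"),
                       stringsAsFactors = FALSE)
  stopifnot(nrow(events) == score)  # resolution is most parsimonious
  names(state) <- c(tree$tip.label, as.character(root:nnode))
  structure(list(score = score, states = state, events = events,
                 ambiguous_nodes = which(set == 3L), tree = tree,
                 root_resolve = root_resolve),
            class = "character_history")
}

#' @export
print.character_history <- function(x, ...) {
  cat(sprintf("character history: parsimony score %d (%d gains, %d losses), %d ambiguous node(s)\n",
              x$score, sum(x$events$event == "gain"),
              sum(x$events$event == "loss"), length(x$ambiguous_nodes)))
  invisible(x)
}

#' Reconstruct several genes on one tree
#'
#' Runs [fitch_reconstruct()] independently per gene column and collects the
#' per-gene histories and a combined event table.
#'
#' @param tree Rooted binary `phylo`.
#' @param state_matrix Binary matrix, rows = tip labels, columns = genes; a
#'   `pa_matrix` is accepted (genomes absent from the tree are dropped with a
#'   message, tree tips without data are an error).
#' @param genes Optional gene subset.
#' @inheritParams fitch_reconstruct
#' @return Named list of `character_history`; attribute `events` binds all
#'   event tables with a `gene` column.
#' @export
fitch_multi <- function(tree, state_matrix, genes = NULL,
                        root_resolve = "present") {
  m <- if (inherits(state_matrix, "pa_matrix")) state_matrix$mat else
    as.matrix(state_matrix)
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  extra <- setdiff(rownames(m), tree$tip.label)
  if (length(extra)) {
    message(length(extra), " genome(s) absent from the tree dropped")
    m <- m[rownames(m) %in% tree$tip.label, , drop = FALSE]
  }
  absent <- setdiff(tree$tip.label, rownames(m))
  if (length(absent))
    stop("tree tips without states: ", paste(utils::head(absent, 5),
                                             collapse = ", "), call. = FALSE)
  out <- lapply(colnames(m), function(g)
    fitch_reconstruct(tree, stats::setNames(m[, g], rownames(m)),
                      root_resolve = root_resolve))
  names(out) <- colnames(m)
  ev <- do.call(rbind, lapply(names(out), function(g) {
    e <- out[[g]]$events
    if (nrow(e)) cbind(gene = g, e) else NULL
  }))
  attr(out, "events") <- ev %||%
    data.frame(gene = character(0), parent = integer(0), child = integer(0),
               child_label = character(0), event = character(0))
  out
}

#' Export gain/loss events
#'
#' Writes the combined event table of a [fitch_multi()] result as TSV
#' (gene, branch parent->child, event).
#'
#' @param histories Result of [fitch_multi()].
#' @param path Output TSV.
#' @export
write_history_tsv <- function(histories, path) {
  ev <- attr(histories, "events")
  ev$branch <- paste0(ev$parent, "->", ev$child)
  utils::write.table(ev[c("gene", "branch", "child_label", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
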