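# Deterministic synthetic-data generators. These emulate the statistical
# structure the analysis assumes -- class-structured binary gene content with
# planted co-occurrence, class-specific losses, gain/loss histories along
# trees, and structure alignments with planted helix deletions -- so that
# every pipeline stage is testable without downloads. All generators take an
# integer seed and are byte-deterministic given it.

#' Synthetic-data presets
#'
#' Presets are versioned YAML configuration files shipped under
#' `inst/extdata/presets/`. `list_presets()` names them;
#' `preset_config(name)` loads one; [gen_preset()] materializes all of a
#' preset's artifacts.
#'
#' Available presets: `paper_like_cpr` (505 genomes over 8 classes with a
#' conserved RBF core, background retention calibrated so the median
#' per-genome RBF count is 25, class knockouts of der/obgE/era/rbfA and
#' rplA/rplI, five planted co-occurrence pairs, and class-level H78 loss),
#' `mi_planted_pairs` (independent baseline with 5 planted pairs),
#' `der_hub` (der co-varying with six partners), `fig4_triplet`
#' (triplet-analysis preset with an H78-variant alignment), and
#' `helix_fig4b` (small cohort with class-specific H12/H58/H78 shortening).
#'
#' @param name Preset name.
#' @return `preset_config()` returns the parsed configuration list.
#' @export
preset_config <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "rbfcoevo")
  if (!nzchar(path))
    stop("unknown preset: ", name, " (see list_presets())", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$classes <- unlist(cfg$classes)
  cfg
}

#' @rdname preset_config
#' @export
list_presets <- function() {
  sub("\\.yaml$", "",
      dir(system.file("extdata", "presets", package = "rbfcoevo"),
          pattern = "\\.yaml$"))
}

# retention probability matrix genes x classes from a preset's retention block
retention_matrix <- function(cfg, catalog) {
  r <- cfg$retention
  classes <- names(cfg$classes)
  base <- ifelse(catalog$role == "RP", r$rp_p, r$rbf_background_p)
  base[catalog$gene_id %in% unlist(r$rbf_core)] <- r$rbf_core_p
  for (g in names(r$gene_overrides))
    base[catalog$gene_id == g] <- r$gene_overrides[[g]]
  R <- matrix(base, nrow = nrow(catalog), ncol = length(classes),
              dimnames = list(catalog$gene_id, classes))
  for (g in names(r$class_knockouts))
    R[g, unlist(r$class_knockouts[[g]])] <- r$knockout_p
  if (any(R < 0 | R > 1)) stop("retention probabilities must be in [0, 1]",
                               call. = FALSE)
  R
}

#' Generate a class-structured presence/absence matrix
#'
#' Genomes are drawn per taxon class; each gene is an independent
#' Bernoulli(retention) baseline, except planted partner genes, which copy
#' their driver's value with probability `strength` and otherwise fall back
#' to their own independent baseline (a copy/independent mixture, so planted
#' co-variation strength maps monotonically to mutual information). Class
#' knockouts are retention-probability overrides (default 0.02 rather than
#' exactly 0, mimicking annotation noise).
#'
#' @param config A preset configuration from [preset_config()] (or a list
#'   with the same shape).
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @param catalog Gene catalogue defining the columns.
#' @return List with `pa` (a `pa_matrix`), `truth` (generation labels:
#'   retention matrix, planted pairs, knockouts, and -- when the preset has
#'   an `h78` block -- per-class expected triplet states), and `h78_calls`
#'   (named 0/1 vector, or NULL).
#' @export
gen_matrix <- function(config, seed, catalog = default_catalog()) {
  classes <- config$classes
  stopifnot(length(classes) >= 1L, all(classes >= 1L))
  R <- retention_matrix(config, catalog)
  pairs <- planted_pairs_df(config)
  if (nrow(pairs)) {
    if (anyDuplicated(pairs$partner) ||
        any(pairs$partner %in% pairs$driver))
      stop("planted partners must be unique and not drivers", call. = FALSE)
    missing <- setdiff(c(pairs$driver, pairs$partner), catalog$gene_id)
    if (length(missing))
      stop("planted genes not in catalogue: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(pairs$strength < 0 | pairs$strength > 1))
      stop("strength must be in [0, 1]", call. = FALSE)
  }

  n <- sum(classes)
  cls <- rep(names(classes), classes)
  ids <- sprintf("G%04d", seq_len(n))
  meta <- data.frame(genome_id = ids, group = config$group %||% "CPR",
                     taxon_class = cls, stringsAsFactors = FALSE)
  out <- with_seed(seed, {
    mat <- matrix(0L, nrow = n, ncol = nrow(catalog),
                  dimnames = list(ids, catalog$gene_id))
    for (cl in names(classes)) {
      rows <- which(cls == cl)
      p <- R[, cl]
      mat[rows, ] <- (matrix(stats::runif(length(rows) * nrow(catalog)),
                             nrow = length(rows)) <
                        matrix(p, nrow = length(rows), ncol = length(p),
                               byrow = TRUE)) * 1L
    }
    for (i in seq_len(nrow(pairs))) {
      copy <- stats::runif(n) < pairs$strength[i]
      mat[copy, pairs$partner[i]] <- mat[copy, pairs$driver[i]]
    }
    h78_calls <- NULL
    if (!is.null(config$h78)) {
      ph <- rep(config$h78$retention_p, n)
      ph[cls %in% unlist(config$h78$knockout_classes)] <- config$h78$knockout_p
      h78_calls <- stats::setNames(as.integer(stats::runif(n) < ph), ids)
    }
    list(mat = mat, h78_calls = h78_calls)
  })

  truth <- list(retention = R, planted_pairs = pairs,
                class_knockouts = config$retention$class_knockouts,
                seed = seed)
  if (!is.null(config$h78)) {
    ph <- stats::setNames(rep(config$h78$retention_p, length(classes)),
                          names(classes))
    ph[unlist(config$h78$knockout_classes)] <- config$h78$knockout_p
    truth$h78_retention <- ph
    truth$modal_state <- stats::setNames(encode_triplet_state(
      as.integer(R["der", ] > 0.5), as.integer(R["rplA", ] > 0.5),
      as.integer(ph > 0.5)), names(classes))
  }
  list(pa = new_pa_matrix(out$mat, meta, catalog), truth = truth,
       h78_calls = out$h78_calls)
}

planted_pairs_df <- function(config) {
  pp <- config$planted_pairs
  if (is.null(pp) || length(pp) == 0L)
    return(data.frame(driver = character(0), partner = character(0),
                      strength = numeric(0)))
  data.frame(driver = vapply(pp, `[[`, "", "driver"),
             partner = vapply(pp, `[[`, "", "partner"),
             strength = vapply(pp, function(p) as.numeric(p$strength), 0),
             stringsAsFactors = FALSE)
}

#' Generate a random class-monophyletic phylogeny
#'
#' Random birth-process (Yule-like, via [ape::rtree()]) tree whose leaves are
#' genome ids and whose taxon classes form contiguous monophyletic clades:
#' a class backbone tree is drawn first and each class tip is replaced by a
#' random subtree over that class's genomes.
#'
#' @param classes Either a single integer (number of leaves, one class) or a
#'   named integer vector of genomes per class.
#' @param seed Integer RNG seed.
#' @param ids Optional leaf labels (default `G0001`...); must follow class
#'   order.
#' @return List with `tree` (rooted binary `phylo`) and `class_map` (named
#'   class per leaf).
#' @export
gen_tree <- function(classes, seed, ids = NULL) {
  if (is.null(names(classes)) && length(classes) == 1L)
    classes <- c(clade = as.integer(classes))
  if (sum(classes) < 2L) stop("need at least 2 leaves", call. = FALSE)
  ids <- ids %||% sprintf("G%04d", seq_len(sum(classes)))
  cls <- rep(names(classes), classes)
  with_seed(seed, {
    id_split <- split(ids, factor(cls, levels = names(classes)))
    sub_nwk <- vapply(names(classes), function(cl) {
      tips <- id_split[[cl]]
      if (length(tips) == 1L) return(tips)
      t <- ape::rtree(length(tips), tip.label = tips)
      sub(";$", "", ape::write.tree(t))
    }, "")
    if (length(classes) == 1L) {
      nwk <- paste0(sub_nwk[[1]], ";")
    } else {
      backbone <- ape::rtree(length(classes),
                             tip.label = paste0("@", names(classes), "@"))
      nwk <- ape::write.tree(backbone)
      for (cl in names(classes))
        nwk <- sub(paste0("@", cl, "@"), sub_nwk[[cl]], nwk, fixed = TRUE)
    }
    tree <- ape::read.tree(text = nwk)
    list(tree = tree, class_map = stats::setNames(cls, ids))
  })
}

#' Simulate a binary gain/loss history along a tree
#'
#' Two-state Markov process (gain rate 0->1, loss rate 1->0) simulated along
#' every branch with exponential waiting times; the true event list is
#' returned so parsimony reconstructions can be scored against it.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param gain,loss Non-negative rates per unit branch length.
#' @param root_state Character state at the root (0 or 1).
#' @param seed Integer RNG seed.
#' @return List with `tip_states` (named 0/1), `node_states` (all nodes),
#'   `events` (data.frame parent, child, event, time) and `n_events`.
#' @export
simulate_history <- function(tree, gain, loss, root_state = 1L, seed) {
  stopifnot(gain >= 0, loss >= 0, root_state %in% 0:1)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    state <- integer(ntip + tree$Nnode)
    state[ntip + 1L] <- as.integer(root_state)
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
    lens <- tree$edge.length[match(paste(pre[, 1], pre[, 2]),
                                   paste(tree$edge[, 1], tree$edge[, 2]))]
    ev <- list()
    for (i in seq_len(nrow(pre))) {
      s <- state[pre[i, 1]]
      t_left <- lens[i]
      repeat {
        rate <- if (s == 1L) loss else gain
        if (rate == 0) break
        w <- stats::rexp(1, rate)
        if (w > t_left) break
        t_left <- t_left - w
        s <- 1L - s
        ev[[length(ev) + 1L]] <- data.frame(
          parent = pre[i, 1], child = pre[i, 2],
          event = if (s == 1L) "gain" else "loss",
          time = lens[i] - t_left, stringsAsFactors = FALSE)
      }
      state[pre[i, 2]] <- s
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(parent = integer(0), child = integer(0),
                 event = character(0), time = numeric(0))
    list(tip_states = stats::setNames(state[seq_len(ntip)], tree$tip.label),
         node_states = state, events = events, n_events = nrow(events))
  })
}

#' Generate a structure alignment with planted helix deletions
#'
#' The reference row is an ungapped random canonical sequence; rows carry
#' class-planted stem truncations (kept stem bases at the paired ends of each
#' strand segment, the rest gapped) and optional insert columns (lowercase
#' residues, gapped in the reference). Truth labels record per-row expected
#' helix lengths, stems and H78 class labels.
#'
#' @param genomes Data.frame (genome_id, taxon_class) naming the rows.
#' @param helix_table A `helix_table` (defaults to the packaged synthetic
#'   table).
#' @param helix_plan Data.frame (class, helix_id, keep_stem): number of
#'   paired bases kept per strand segment for that class (0 deletes the
#'   helix; classes/helices not listed stay full length).
#' @param inserts Optional data.frame (class, helix_id, len): lowercase
#'   insert of `len` residues planted inside the 5' strand segment for that
#'   class.
#' @param ref_length Ungapped reference length (must cover the helix table).
#' @param seed Integer RNG seed.
#' @return List with `aln` (a `structure_alignment`, reference row
#'   `"reference"`), `truth` (per row x helix: length, stem, label for H78)
#'   and `seed_lengths`/`seed_stems` (named per helix).
#' @export
gen_alignment <- function(genomes, helix_plan = NULL, inserts = NULL,
                          helix_table = synthetic_helix_table(),
                          ref_length = 240L, seed = 1L) {
  ht <- validate_helix_table(as.data.frame(helix_table))
  if (max(ht$tp_end) > ref_length)
    stop("helix table exceeds reference length", call. = FALSE)
  helix_plan <- helix_plan %||%
    data.frame(class = character(0), helix_id = character(0),
               keep_stem = integer(0))
  inserts <- inserts %||%
    data.frame(class = character(0), helix_id = character(0),
               len = integer(0))
  seg_len <- stats::setNames(ht$fp_end - ht$fp_start + 1L, ht$helix_id)
  bad <- helix_plan$keep_stem > seg_len[helix_plan$helix_id] |
    helix_plan$keep_stem < 0
  if (any(bad))
    stop("deletion plan outside helix: ",
         paste(helix_plan$helix_id[bad], collapse = ", "), call. = FALSE)
  if (nrow(inserts) && !all(inserts$helix_id %in% ht$helix_id))
    stop("insert plan names unknown helix", call. = FALSE)

  with_seed(seed, {
    ref <- sample(c("A", "C", "G", "U"), ref_length, replace = TRUE)
    # global column layout: insert blocks placed after the 3rd reference
    # position of the named helix's 5' segment
    ins_pos <- if (nrow(inserts))
      ht$fp_start[match(inserts$helix_id, ht$helix_id)] + 2L else integer(0)
    layout_extra <- stats::setNames(rep(0L, ref_length),
                                    as.character(seq_len(ref_length)))
    for (p in unique(ins_pos))
      layout_extra[p] <- max(inserts$len[ins_pos == p])

    build_row <- function(cl) {
      chars <- ref
      plan <- helix_plan[helix_plan$class == cl, , drop = FALSE]
      for (j in seq_len(nrow(plan))) {
        h <- ht[ht$helix_id == plan$helix_id[j], ]
        keep <- plan$keep_stem[j]
        fp <- h$fp_start:h$fp_end; tp <- h$tp_start:h$tp_end
        # keep the paired ends: start of 5' segment, end of 3' segment
        drop_fp <- if (keep < length(fp)) fp[(keep + 1L):length(fp)] else
          integer(0)
        drop_tp <- if (keep < length(tp))
          tp[seq_len(length(tp) - keep)] else integer(0)
        chars[c(drop_fp, drop_tp)] <- "-"
      }
      out <- character(0)
      for (p in seq_len(ref_length)) {
        out <- c(out, chars[p])
        if (layout_extra[p] > 0L) {
          myins <- inserts[inserts$class == cl &
                             ins_pos == p, , drop = FALSE]
          len <- if (nrow(myins)) myins$len[1] else 0L
          out <- c(out, rep("a", len), rep(".", layout_extra[p] - len))
        }
      }
      paste(out, collapse = "")
    }

    ref_row <- {
      chars <- ref
      out <- character(0)
      for (p in seq_len(ref_length)) {
        out <- c(out, chars[p])
        if (layout_extra[p] > 0L) out <- c(out, rep(".", layout_extra[p]))
      }
      paste(out, collapse = "")
    }
    class_rows <- vapply(unique(genomes$taxon_class), build_row, "")
    seqs <- c(reference = ref_row,
              stats::setNames(class_rows[genomes$taxon_class],
                              genomes$genome_id))
    aln <- structure_alignment(seqs, ref = "reference")

    truth <- do.call(rbind, lapply(seq_len(nrow(genomes)), function(i) {
      cl <- genomes$taxon_class[i]
      do.call(rbind, lapply(ht$helix_id, function(h) {
        plan <- helix_plan[helix_plan$class == cl &
                             helix_plan$helix_id == h, , drop = FALSE]
        keep <- if (nrow(plan)) plan$keep_stem[1] else seg_len[[h]]
        ilen <- {
          mi <- inserts[inserts$class == cl & inserts$helix_id == h, ,
                        drop = FALSE]
          if (nrow(mi)) mi$len[1] else 0L
        }
        data.frame(seq_id = genomes$genome_id[i], taxon_class = cl,
                   helix_id = h, length = 2L * keep + ilen, stem = keep,
                   label = if (h == "H78") stem_label(keep, seg_len[[h]])
                           else NA_character_,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(truth) <- NULL
    list(aln = aln, truth = truth,
         seed_lengths = stats::setNames(2L * seg_len, names(seg_len)),
         seed_stems = seg_len)
  })
}

# planted-stem label under the H78 classification convention
stem_label <- function(stem, seed_stem, presence_min = 2L) {
  if (stem < presence_min) "absent"
  else if (stem >= 2 && stem <= 3) "short_stem"
  else if (stem >= 6 && stem <= 8) "mid_stem"
  else if (stem >= seed_stem - 1L) "full"
  else NA_character_
}

#' @rdname read_helix_table
#' @export
synthetic_helix_table <- function() {
  read_helix_table(system.file("extdata", "synthetic_helix_table.tsv",
                               package = "rbfcoevo", mustWork = TRUE))
}

#' Materialize every artifact of a preset
#'
#' Runs the generators a preset configures: always the presence/absence
#' matrix (with truth labels and, when configured, H78 presence calls), plus
#' a class-monophyletic tree, and the planted structure alignment for presets
#' with an `alignment` block.
#'
#' @param name Preset name (see [list_presets()]).
#' @param seed Integer RNG seed; sub-generators use fixed offsets of it.
#' @param tree Whether to generate the phylogeny.
#' @return List: `config`, `pa`, `truth`, `h78_calls`, and optionally
#'   `tree`, `class_map`, `alignment` (the [gen_alignment()] result).
#' @export
gen_preset <- function(name, seed, tree = TRUE) {
  cfg <- preset_config(name)
  gm <- gen_matrix(cfg, seed = seed)
  out <- list(config = cfg, pa = gm$pa, truth = gm$truth,
              h78_calls = gm$h78_calls)
  if (tree) {
    tr <- gen_tree(cfg$classes, seed = seed + 1L)
    out$tree <- tr$tree
    out$class_map <- tr$class_map
  }
  if (!is.null(cfg$alignment)) {
    plan <- do.call(rbind, lapply(cfg$alignment$helix_plan, as.data.frame))
    ins <- if (length(cfg$alignment$inserts))
      do.call(rbind, lapply(cfg$alignment$inserts, as.data.frame)) else NULL
    out$alignment <- gen_alignment(
      genomes = gm$pa$metadata[c("genome_id", "taxon_class")],
      helix_plan = plan, inserts = ins,
      ref_length = cfg$alignment$ref_length %||% 240L, seed = seed + 2L)
  }
  out
}

#' Write synthetic artifacts in the pipeline's input formats
#'
#' `write_annotations_tsv()` emits one (genome_id, identifier) row per
#' present gene, using the first KO id where the catalogue has one and the
#' gene symbol otherwise; `write_metadata_tsv()` emits the genome metadata;
#' `write_truth_json()` serializes generation truth labels.
#'
#' @param pa A `pa_matrix`.
#' @param path Output file.
#' @export
write_annotations_tsv <- function(pa, path) {
  kos <- vapply(strsplit(pa$catalog$ko_ids, ";", fixed = TRUE),
                function(k) if (length(k) && nzchar(k[1])) k[1] else "", "")
  ident <- ifelse(nzchar(kos), kos, pa$catalog$gene_id)
  idx <- which(pa$mat == 1L, arr.ind = TRUE)
  out <- data.frame(genome_id = rownames(pa$mat)[idx[, 1]],
                    identifier = ident[idx[, 2]], stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$identifier), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_tsv
#' @export
write_metadata_tsv <- function(pa, path) {
  utils::write.table(pa$metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_tsv
#' @param truth Truth-label list from a generator.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
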