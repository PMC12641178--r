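# End-to-end orchestration: matrix -> conservation -> MI network ->
# gain/loss -> triplet (-> helix) with a machine-readable report.

#' Run the full comparative pipeline
#'
#' Executes the configured stages over synthetic (preset) or real-mode
#' inputs, writing every stage's outputs plus a JSON report with key
#' statistics and MD5 checksums of all files. Re-running with the same
#' configuration and seed reproduces all outputs byte-identically. Any stage
#' failure aborts with the stage name; partial outputs are retained next to
#' a `FAILED` marker file.
#'
#' @param config Either a YAML file path or a list. Recognized fields:
#'   `preset` (synthetic mode; a preset name) or `annotations`/`metadata`
#'   (real-mode TSV paths) and optionally `tree` (newick) and `catalog`
#'   (TSV); `seed` (integer, default 1); `group` (network group, default
#'   CPR); `mi_base` ("nat" or a number); `tau` (MI threshold, default 0.1);
#'   `conservation_low`/`conservation_high`; `gainloss_genes` (default der,
#'   obgE, era, rbfA).
#' @param out_dir Output directory (created; must be empty or absent).
#' @return The report, invisibly. Key statistics echoed: per-group median
#'   RBF/RP counts, evaluated pair count, edges at the threshold, hub gene,
#'   gain/loss event counts, triplet summary when H78 calls exist.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  if (dir.exists(out_dir) && length(dir(out_dir)))
    stop("output directory is not empty: ", out_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config, stages = list(), files = character(0))
  fail <- function(stage, e) {
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  emit <- function(file) {
    report$files <<- c(report$files, file)
    file
  }

  # --- matrix stage -------------------------------------------------------
  dat <- stage("matrix", {
    if (!is.null(config$preset)) {
      gp <- gen_preset(config$preset, seed = seed)
      write_annotations_tsv(gp$pa, emit(file.path(out_dir, "annotations.tsv")))
      write_metadata_tsv(gp$pa, emit(file.path(out_dir, "metadata.tsv")))
      gp
    } else {
      catalog <- if (!is.null(config$catalog)) load_catalog(config$catalog)
                 else default_catalog()
      pa <- build_matrix(config$annotations, config$metadata, catalog)
      tree <- if (!is.null(config$tree)) {
        tr <- ape::read.tree(config$tree)
        if (!ape::is.rooted(tr))
          stop("input tree is unrooted; supply a rooted newick")
        tr
      }
      list(pa = pa, tree = tree, h78_calls = config_h78_calls(config))
    }
  })
  pa <- dat$pa
  write_matrix_tsv(pa, emit(file.path(out_dir, "matrix.tsv")))

  # --- conservation stage -------------------------------------------------
  low <- config$conservation_low %||% 0.10
  high <- config$conservation_high %||% 0.90
  groups <- unique(pa$metadata$group)
  cons <- stage("conservation", {
    prof <- do.call(rbind, lapply(groups, function(g)
      classify_conservation(conservation_ratio(pa, g), low, high)))
    utils::write.table(prof, emit(file.path(out_dir, "conservation.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    byclass <- per_class_conservation(pa)
    utils::write.table(byclass,
                       emit(file.path(out_dir, "class_conservation.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof
  })

  # --- MI network stage ---------------------------------------------------
  tau <- config$tau %||% 0.1
  base <- config$mi_base %||% "nat"
  group <- config$group %||% (if ("CPR" %in% groups) "CPR" else groups[1])
  net <- stage("mi_network", {
    edges <- pairwise_mi(pa, group = group, base = base)
    net <- threshold_network(edges, tau = tau, catalog = pa$catalog)
    write_edges_tsv(net, emit(file.path(out_dir, "edges.tsv")))
    write_network_graphml(net, emit(file.path(out_dir, "network.graphml")))
    list(edges = edges, net = net)
  })
  hub <- if (nrow(net$net$edges)) {
    st <- node_stats(net$net)
    attr(st, "argmax")$by_weight[1]
  } else NA_character_

  # --- gain/loss stage ----------------------------------------------------
  genes <- unlist(config$gainloss_genes %||%
                    list("der", "obgE", "era", "rbfA"))
  gl <- if (!is.null(dat$tree)) stage("gainloss", {
    hist <- fitch_multi(dat$tree, pa, genes = genes)
    write_history_tsv(hist, emit(file.path(out_dir, "gainloss.tsv")))
    hist
  })

  # --- triplet stage ------------------------------------------------------
  trip <- if (!is.null(dat$h78_calls)) stage("triplet", {
    states <- encode_triplets(pa, dat$h78_calls)
    utils::write.table(states, emit(file.path(out_dir, "triplet_states.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    props <- class_state_proportions(states)
    utils::write.table(props,
                       emit(file.path(out_dir, "triplet_proportions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(states = states, props = props, mi = triplet_mi(states, base = base))
  })

  # --- helix stage (alignment presets / real alignments) ------------------
  helix <- if (!is.null(dat$alignment)) stage("helix", {
    al <- dat$alignment
    map <- map_reference_coordinates(al$aln, synthetic_helix_table())
    lens <- helix_lengths(al$aln, map)
    write_helix_lengths_tsv(lens, emit(file.path(out_dir,
                                                 "helix_lengths.tsv")))
    classes <- stats::setNames(pa$metadata$taxon_class, pa$metadata$genome_id)
    cmp <- compare_to_seed(lens[lens$seq_id != al$aln$ref, ],
                           al$seed_lengths, classes)
    utils::write.table(cmp, emit(file.path(out_dir, "helix_shortening.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(lengths = lens, shortening = cmp)
  })

  # --- report -------------------------------------------------------------
  counts <- gene_counts(pa, role = "RBF")
  rp_counts <- gene_counts(pa, role = "RP")
  report$summary <- list(
    n_genomes = nrow(pa$mat), n_genes = ncol(pa$mat),
    median_rbf_by_group = as.list(counts$group_median),
    median_rp_by_group = as.list(rp_counts$group_median),
    n_pairs_evaluated = nrow(net$edges),
    n_edges_at_tau = nrow(net$net$edges), tau = tau, mi_base = base,
    network_group = group, hub_gene = hub,
    n_gainloss_events = if (!is.null(gl)) nrow(attr(gl, "events")),
    triplet_mi = if (!is.null(trip)) as.list(stats::setNames(
      trip$mi$mi, trip$mi$pair)),
    n_shortened_class_helix = if (!is.null(helix))
      sum(helix$shortening$shortened))
  report$checksums <- as.list(tools::md5sum(report$files))
  names(report$checksums) <- basename(report$files)
  jsonlite::write_json(report[c("summary", "checksums")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("genomes: %d  genes: %d", nrow(pa$mat), ncol(pa$mat)),
    sprintf("median RBF count by group: %s",
            paste(names(counts$group_median), counts$group_median,
                  sep = "=", collapse = ", ")),
    sprintf("pairs evaluated: %d; edges with MI >= %g: %d; hub: %s",
            nrow(net$edges), tau, nrow(net$net$edges), hub)),
    file.path(out_dir, "summary.txt"))
  invisible(report)
}

# real-mode per-genome H78 calls from a TSV (genome_id, h78)
config_h78_calls <- function(config) {
  if (is.null(config$h78_calls)) return(NULL)
  d <- utils::read.delim(config$h78_calls, stringsAsFactors = FALSE)
  stop_if_missing_cols(d, c("genome_id", "h78"), "h78 calls")
  stats::setNames(as.integer(d$h78), d$genome_id)
}
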