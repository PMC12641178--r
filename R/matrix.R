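#' Build a binary gene presence/absence matrix
#'
#' Materializes the central object of the pipeline: a genomes-by-genes binary
#' matrix. A cell is 1 iff any identifier for the gene (its symbol or any of
#' its KO ids in the catalogue) occurs in that genome's annotation set, which
#' maximizes recall for KO-based annotations.
#'
#' @param annotations data.frame with columns `genome_id`, `identifier`
#'   (one pair per line), or a path to such a TSV.
#' @param metadata data.frame with columns `genome_id`, `group` (e.g. `CPR`,
#'   `nonCPR`, `symbiotic`), `taxon_class`, or a path to such a TSV. Defines
#'   the genome set; genomes without annotations get all-zero rows.
#' @param catalog An `rbf_catalog` (see [load_catalog()]); defaults to the
#'   packaged catalogue.
#' @return An object of class `pa_matrix`: a list with `mat` (integer 0/1
#'   matrix, rownames = genome ids, colnames = catalogue gene order),
#'   `metadata` (per-genome group and taxon_class) and `catalog`.
#' @examples
#' md <- data.frame(genome_id = c("g1", "g2"), group = "CPR",
#'                  taxon_class = "ABY1")
#' ann <- data.frame(genome_id = "g1", identifier = "K03977") # der
#' pa <- build_matrix(ann, md)
#' pa$mat[, "der"]
#' @export
build_matrix <- function(annotations, metadata, catalog = default_catalog()) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  stop_if_missing_cols(annotations, c("genome_id", "identifier"), "annotations")
  stop_if_missing_cols(metadata, c("genome_id", "group", "taxon_class"),
                       "metadata")
  if (nrow(catalog) == 0L) stop("catalogue is empty", call. = FALSE)
  dup <- metadata$genome_id[duplicated(metadata$genome_id)]
  if (length(dup))
    stop("duplicate genome_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (nrow(annotations) == 0L)
    stop("annotation table is empty", call. = FALSE)
  if (any(!nzchar(metadata$group)) || any(!nzchar(metadata$taxon_class)))
    stop("metadata group and taxon_class must be non-empty", call. = FALSE)
  unknown <- setdiff(annotations$genome_id, metadata$genome_id)
  if (length(unknown))
    warning(length(unknown), " annotated genome(s) absent from metadata; ",
            "dropped: ", paste(utils::head(unknown, 5), collapse = ", "))

  mat <- matrix(0L, nrow = nrow(metadata), ncol = nrow(catalog),
                dimnames = list(metadata$genome_id, catalog$gene_id))
  map <- catalog_identifier_map(catalog)
  hit <- merge(annotations, map, by = "identifier")
  hit <- hit[hit$genome_id %in% metadata$genome_id, , drop = FALSE]
  if (nrow(hit))
    mat[cbind(match(hit$genome_id, rownames(mat)),
              match(hit$gene_id, colnames(mat)))] <- 1L
  new_pa_matrix(mat, metadata, catalog)
}

new_pa_matrix <- function(mat, metadata, catalog) {
  stopifnot(all(mat %in% c(0L, 1L)),
            identical(rownames(mat), metadata$genome_id),
            identical(colnames(mat), catalog$gene_id))
  structure(list(mat = mat,
                 metadata = metadata[c("genome_id", "group", "taxon_class")],
                 catalog = catalog),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("pa_matrix: %d genomes x %d genes; groups: %s\n",
              nrow(x$mat), ncol(x$mat),
              paste(sprintf("%s (%d)", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = ", ")))
  invisible(x)
}

#' @rdname build_matrix
#' @param path Path to a TSV file.
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname build_matrix
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname build_matrix
#' @param pa A `pa_matrix`.
#' @export
write_matrix_tsv <- function(pa, path) {
  out <- data.frame(genome_id = rownames(pa$mat), pa$mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Subset helper: genomes by group and/or genes by role
subset_pa <- function(pa, group = NULL, role = NULL, genes = NULL) {
  keep_g <- rep(TRUE, nrow(pa$mat))
  if (!is.null(group)) {
    if (!any(pa$metadata$group == group))
      stop("unknown group label: ", group, call. = FALSE)
    keep_g <- pa$metadata$group == group
  }
  keep_c <- rep(TRUE, ncol(pa$mat))
  if (!is.null(role)) keep_c <- keep_c & pa$catalog$role %in% role
  if (!is.null(genes)) {
    missing <- setdiff(genes, pa$catalog$gene_id)
    if (length(missing))
      stop("genes not in catalogue: ", paste(missing, collapse = ", "),
           call. = FALSE)
    keep_c <- keep_c & pa$catalog$gene_id %in% genes
  }
  new_pa_matrix(pa$mat[keep_g, keep_c, drop = FALSE],
                pa$metadata[keep_g, , drop = FALSE],
                pa$catalog[keep_c, , drop = FALSE])
}

#' Per-genome gene counts and group summaries
#'
#' Counts how many catalogue genes of a given role each genome carries, the
#' group-wise medians, and the count histogram (the analogue of the published
#' RBF-count histograms).
#'
#' @param pa A `pa_matrix` from [build_matrix()] or [gen_matrix()].
#' @param role Catalogue role to count, `"RBF"` (default) or `"RP"`.
#' @return A list with `counts` (data.frame genome_id, group, taxon_class,
#'   count), `group_median` (named numeric) and `histogram` (table).
#' @export
gene_counts <- function(pa, role = "RBF") {
  sub <- subset_pa(pa, role = role)
  counts <- data.frame(genome_id = rownames(sub$mat),
                       group = sub$metadata$group,
                       taxon_class = sub$metadata$taxon_class,
                       count = as.integer(rowSums(sub$mat)),
                       stringsAsFactors = FALSE)
  list(counts = counts,
       group_median = tapply(counts$count, counts$group, stats::median),
       histogram = table(counts$count))
}

#' Per-group gene conservation ratios
#'
#' The conservation ratio of a gene within a group is the fraction of the
#' group's genomes carrying the gene: an exact rational count, always in
#' `[0, 1]`.
#'
#' @param pa A `pa_matrix`.
#' @param group Group label present in the metadata (e.g. `"CPR"`).
#' @return Data.frame of class `conservation_profile` with columns `gene_id`,
#'   `ratio`, `n_present`, `n_genomes`, `group`.
#' @export
conservation_ratio <- function(pa, group) {
  sub <- subset_pa(pa, group = group)
  n <- nrow(sub$mat)
  pres <- colSums(sub$mat)
  out <- data.frame(gene_id = colnames(sub$mat),
                    ratio = as.numeric(pres) / n,
                    n_present = as.integer(pres),
                    n_genomes = n, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Classify conservation ratios
#'
#' Partitions ratios into `nearly_absent` (ratio < `low`), `less_conserved`
#' (`low` <= ratio <= `high`; the interval is closed on both sides, matching
#' the "ranging from 10% to 90%" convention) and `highly_conserved`
#' (ratio > `high`).
#'
#' @param ratio Numeric vector of ratios in `[0, 1]`, or a
#'   `conservation_profile`.
#' @param low,high Category boundaries, `0 <= low < high <= 1`.
#' @return Factor with levels `nearly_absent`, `less_conserved`,
#'   `highly_conserved` (a `category` column is appended when a profile is
#'   given).
#' @export
classify_conservation <- function(ratio, low = 0.10, high = 0.90) {
  if (!(is.numeric(low) && is.numeric(high) && low >= 0 && low < high &&
        high <= 1))
    stop("invalid thresholds: need 0 <= low < high <= 1", call. = FALSE)
  if (inherits(ratio, "conservation_profile")) {
    ratio$category <- classify_conservation(ratio$ratio, low, high)
    return(ratio)
  }
  if (any(ratio < 0 | ratio > 1)) stop("ratios must be in [0, 1]", call. = FALSE)
  cut(ratio, breaks = c(-Inf, low, high, Inf), right = FALSE,
      labels = c("nearly_absent", "less_conserved", "highly_conserved")) ->
    cats
  # cut(right = FALSE) puts `high` itself into the top bin; the convention
  # here is closed on the less_conserved side at both boundaries.
  cats[ratio == high] <- "less_conserved"
  cats
}

#' Compare conservation profiles of two groups
#'
#' Produces a scatter-ready gene table of the two groups' ratios and the
#' derived list of genes that are highly conserved in group A but only
#' less conserved in group B (the published "lost in the reduced lineage"
#' contrast).
#'
#' @param profile_a,profile_b `conservation_profile`s over the same catalogue.
#' @param low,high Passed to [classify_conservation()].
#' @return Data.frame with per-gene ratios, categories and `transition`
#'   strings; attribute `shifted` holds the gene ids highly conserved in A
#'   and less conserved in B.
#' @export
compare_groups <- function(profile_a, profile_b, low = 0.10, high = 0.90) {
  if (!setequal(profile_a$gene_id, profile_b$gene_id) ||
      nrow(profile_a) != nrow(profile_b))
    stop("profiles are over different gene sets", call. = FALSE)
  b <- profile_b[match(profile_a$gene_id, profile_b$gene_id), ]
  cat_a <- classify_conservation(profile_a$ratio, low, high)
  cat_b <- classify_conservation(b$ratio, low, high)
  out <- data.frame(gene_id = profile_a$gene_id,
                    ratio_a = profile_a$ratio, ratio_b = b$ratio,
                    category_a = cat_a, category_b = cat_b,
                    transition = ifelse(as.character(cat_a) ==
                                          as.character(cat_b), "",
                                        paste0(cat_a, "->", cat_b)),
                    stringsAsFactors = FALSE)
  attr(out, "shifted") <- out$gene_id[cat_a == "highly_conserved" &
                                        cat_b == "less_conserved"]
  out
}

#' Principal-component ordination of a presence/absence matrix
#'
#' Thin wrapper around [stats::prcomp()] on the centered (not scaled) binary
#' matrix, returning per-genome scores, per-gene loadings, explained-variance
#' fractions and the top-loading genes for the leading components.
#'
#' @param pa A `pa_matrix`.
#' @param genes Optional gene subset.
#' @param n_top How many top-loading genes to report per component.
#' @return List with `scores`, `loadings`, `var_explained`, `top_loadings`.
#' @export
ordinate <- function(pa, genes = NULL, n_top = 4L) {
  sub <- if (is.null(genes)) pa else subset_pa(pa, genes = genes)
  m <- sub$mat
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 genomes and 2 genes", call. = FALSE)
  if (all(apply(m, 2L, function(col) length(unique(col)) == 1L)))
    stop("no variance: matrix is constant", call. = FALSE)
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- min(2L, ncol(p$rotation))
  top <- lapply(seq_len(k), function(i) {
    l <- p$rotation[, i]
    names(sort(abs(l), decreasing = TRUE))[seq_len(min(n_top, length(l)))]
  })
  names(top) <- colnames(p$rotation)[seq_len(k)]
  list(scores = p$x, loadings = p$rotation, var_explained = ve,
       top_loadings = top)
}

#' Two-sample t test on per-genome gene counts
#'
#' Plain independent two-sample t test between two groups' per-genome counts
#' (no multiple-testing correction is applied).
#'
#' @param counts `counts` data.frame from [gene_counts()].
#' @param group_a,group_b Group labels.
#' @return An object of class `htest` from [stats::t.test()].
#' @export
compare_group_counts <- function(counts, group_a, group_b) {
  stats::t.test(counts$count[counts$group == group_a],
                counts$count[counts$group == group_b])
}
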