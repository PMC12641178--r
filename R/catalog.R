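CATALOG_ROLES <- c("RBF", "RP")
CATALOG_CATEGORIES <- c("GTPase", "maturation", "ribonuclease", "helicase",
                        "modification", "other", "chaperone")

#' Load an RBF/RP gene catalogue
#'
#' Reads a tab-separated catalogue of ribosome biogenesis factor (RBF) and
#' ribosomal protein (RP) genes. The catalogue defines the columns of every
#' presence/absence matrix built by [build_matrix()]: one entry per gene, with
#' a functional role (`RBF` or `RP`), a category (GTPase, maturation factor,
#' ribonuclease, helicase, modification enzyme, chaperone, or other) and an
#' optional set of orthology (KO) identifiers used for presence calling.
#'
#' The packaged default catalogue ([default_catalog()]) holds 100 RBF genes in
#' six functional categories plus the two folding chaperone systems, and the
#' 54 standard bacterial ribosomal protein genes (23 `rpl`, 10 `rpm`,
#' 21 `rps`). Gene symbols follow E. coli usage. It is a reconstruction of a
#' published curated list assembled from KEGG's prokaryotic ribosome
#' biogenesis factors plus manually curated additions (`lepA`, `bipA`,
#' `engB`, `rhlE`, `pnp`, `rnb`, `rnj`, `rnr`, `rnt`, `rph`, `rnmV`, `groEL`,
#' `groES`, `dnaK`, `dnaJ`, `grpE`, `yheS`); KO identifiers are filled in only
#' where unambiguous, and presence calling falls back to the gene symbol where
#' they are blank.
#'
#' @param path Path to a TSV file with header columns `gene_id`, `role`,
#'   `category`, `ko_ids` (semicolon-separated, may be blank).
#' @return A data.frame of class `rbf_catalog` with those four columns.
#' @examples
#' cat154 <- default_catalog()
#' table(cat154$role)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  stop_if_missing_cols(df, c("gene_id", "role", "category", "ko_ids"),
                       "catalogue")
  if (nrow(df) == 0L) stop("catalogue has no entries", call. = FALSE)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in catalogue: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(df$role), CATALOG_ROLES)
  if (length(bad_role))
    stop("unknown role in catalogue: ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  bad_cat <- setdiff(unique(df$category), CATALOG_CATEGORIES)
  if (length(bad_cat))
    stop("unknown category in catalogue: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  df$ko_ids[is.na(df$ko_ids)] <- ""
  class(df) <- c("rbf_catalog", "data.frame")
  df
}

#' @rdname load_catalog
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "rbf_rp_catalog.tsv",
                           package = "rbfcoevo", mustWork = TRUE))
}

# identifier -> gene_id lookup table; a gene matches its symbol or any KO id
catalog_identifier_map <- function(catalog) {
  kos <- strsplit(catalog$ko_ids, ";", fixed = TRUE)
  ids <- mapply(function(g, k) unique(c(g, k[nzchar(k)])), catalog$gene_id, kos,
                SIMPLIFY = FALSE)
  data.frame(identifier = unlist(ids, use.names = FALSE),
             gene_id = rep(catalog$gene_id, lengths(ids)),
             stringsAsFactors = FALSE)
}

#' @export
print.rbf_catalog <- function(x, ...) {
  cat(sprintf("RBF/RP gene catalogue: %d entries (%d RBF, %d RP)\n",
              nrow(x), sum(x$role == "RBF"), sum(x$role == "RP")))
  print(table(role = x$role, category = x$category))
  invisible(x)
}
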