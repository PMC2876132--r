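#' Read a genes-by-samples expression TSV
#'
#' Expected layout: a header row of sample identifiers, one row per gene
#' with the gene identifier in the first column and real-valued expression in
#' the remaining columns.  Duplicated identifiers, missing values and
#' non-numeric cells are rejected with the offending row/column named.
#'
#' @param path Path to a tab-separated text file.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(df) < 3L || nrow(df) < 2L)
    stop("expression file needs >= 2 genes and >= 2 samples: ", path)
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in ", path)
  vals <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (jj in seq_along(sample_ids)) {
    cell <- df[[jj + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad)) {
      if (any(is.na(cell[bad]) | cell[bad] %in% c("NA", "", "NaN")))
        stop("missing value at gene '", gene_ids[bad[1L]], "', sample '",
             sample_ids[jj], "' in ", path,
             "; impute or filter before analysis")
      stop("non-numeric value '", cell[bad[1L]], "' at gene '",
           gene_ids[bad[1L]], "', sample '", sample_ids[jj], "' in ", path)
    }
    vals[, jj] <- num
  }
  expression_matrix(vals, gene_ids, sample_ids)
}

#' Write an expression matrix as TSV
#'
#' @param X An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(X, path) {
  X <- as_expression_matrix(X)
  df <- data.frame(gene_id = rownames(X), unclass(X), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths so the tree can be reread by any
#' standard phylogenetics parser.
#'
#' @param tree An `hclust`/`merge_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write all pipeline artifacts plus a reproducibility manifest
#'
#' Writes the gene/sample PPP matrices (TSV), their dendrograms (Newick),
#' the context assignment (TSV), the differential co-expression table (TSV)
#' and a JSON manifest recording the seed, configuration, package version and
#' an MD5 checksum of every written file.
#'
#' @param outdir Output directory (created if needed).
#' @param summary A `"chain_summary"` from [run_chain()] (optional).
#' @param ppps Named list of `"ppp_matrix"` objects to write (optional).
#' @param trees Named list of `merge_tree`s (optional).
#' @param contexts Named integer vector of context labels (optional).
#' @param dcs A `"dcs_result"` (optional).
#' @param extra Extra metadata to embed in the manifest.
#' @return The manifest, invisibly; written as `manifest.json` in `outdir`.
#' @export
write_outputs <- function(outdir, summary = NULL, ppps = NULL, trees = NULL,
                          contexts = NULL, dcs = NULL, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character(0)
  for (nm in names(ppps)) {
    f <- file.path(outdir, paste0("ppp_", nm, ".tsv"))
    m <- ppps[[nm]]$values
    dimnames(m) <- list(ppps[[nm]]$item_ids, ppps[[nm]]$item_ids)
    write_matrix_tsv(m, f)
    files <- c(files, f)
  }
  for (nm in names(trees)) {
    f <- file.path(outdir, paste0("tree_", nm, ".nwk"))
    write_newick(trees[[nm]], f)
    files <- c(files, f)
  }
  if (!is.null(contexts)) {
    f <- file.path(outdir, "contexts.tsv")
    write.table(data.frame(sample_id = names(contexts) %||%
                             seq_along(contexts),
                           context = as.integer(contexts)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(dcs)) {
    f <- file.path(outdir, "dcs.tsv")
    write.table(dcs[, c("gene_id", "score", "context", "cluster_size",
                        "rank")],
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "dcim",
    version = as.character(packageVersion("dcim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(summary)) summary$config$seed else extra$seed,
    config = if (!is.null(summary))
      summary$config[c("n_burnin", "n_keep", "thin", "seed",
                       "resample_concentrations", "track_local", "n_aux")]
    else NULL,
    n_kept = summary$n_kept,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    extra = extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
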