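pkg_version <- function() {
  as.character(utils::packageVersion("dctopo"))
}

# deterministic provenance header lines for TSV outputs (no timestamps)
provenance_header <- function(what, extra = NULL) {
  fields <- c(package = paste0("dctopo ", pkg_version()), content = what,
              extra)
  paste0("# ", names(fields), ": ", unname(fields))
}

write_tsv_with_header <- function(df, path, what, extra = NULL,
                                  sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(what, extra), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  writeLines(paste(names(df), collapse = sep), con)
  writeLines(do.call(paste, c(df, sep = sep)), con)
  invisible(path)
}

#' Write a score table as TSV
#'
#' Writes a [dcglob_scores()] or [dcloc_scores()] table with a
#' deterministic provenance header ('#'-prefixed lines: package version,
#' method, grid). Two runs with identical inputs produce byte-identical
#' files.
#'
#' @param scores Score table.
#' @param path Output path.
#' @param extra Optional named character vector of extra header fields.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, path, extra = NULL) {
  grid <- attr(scores, "grid")
  write_tsv_with_header(
    as.data.frame(scores), path,
    what = paste0(attr(scores, "method"), " scores"),
    extra = c(grid = if (!is.null(grid))
      sprintf("k=%d z_max=%.17g", grid$k, grid$z_max), extra)
  )
}

#' Write an expression matrix as delimited text
#'
#' First column `gene_id`, header row of sample ids, body = expression
#' values at full precision (round-trips bitwise through
#' [read_expression()]).
#'
#' @param m Genes x samples matrix.
#' @param path Output path.
#' @param sep Field separator (`"\t"` or `","`).
#' @return The path, invisibly.
#' @export
write_expression <- function(m, path, sep = "\t") {
  validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, what = "expression matrix", sep = sep)
}

#' Write a sample-to-group label table
#'
#' @param groups Named character vector: `groups[sample_id] = group`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_labels <- function(groups, path) {
  write_tsv_with_header(
    data.frame(sample_id = names(groups), group = unname(groups),
               stringsAsFactors = FALSE),
    path, what = "sample labels")
}

#' Read expression data and sample labels into a condition pair
#'
#' The expression file is delimited text (TSV by default) with gene ids in
#' the first column, a header row of sample ids and log2 expression values
#' in the body; '#'-prefixed lines are ignored. The label file maps every
#' sample id to one of exactly two group names; the alphabetically first
#' group becomes condition A.
#'
#' @param path Expression file.
#' @param label_path Two-column label file (sample_id, group).
#' @param sep Field separator of the expression file (`"\t"` or `","`).
#' @param allow_unequal Passed to [condition_pair()].
#' @return A [condition_pair()]; the group names are attached as attribute
#'   `groups` (named `A`, `B`).
#' @export
read_expression <- function(path, label_path, sep = "\t",
                            allow_unequal = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(raw[[1]]))
    stop("duplicated gene identifier(s): ",
         paste(unique(raw[[1]][duplicated(raw[[1]])]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(raw[-1], is.numeric, TRUE)]
    stop("non-numeric expression values in column(s): ",
         paste(bad, collapse = ", "))
  }
  rownames(m) <- raw[[1]]
  lab <- utils::read.table(label_path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  groups <- as.character(lab[[2]])
  names(groups) <- as.character(lab[[1]])
  missing_lab <- setdiff(colnames(m), names(groups))
  if (length(missing_lab))
    stop("sample(s) without a group label: ",
         paste(missing_lab, collapse = ", "))
  groups <- groups[colnames(m)]
  lev <- sort(unique(groups))
  if (length(lev) != 2)
    stop("need exactly two groups, found: ", paste(lev, collapse = ", "))
  pair <- condition_pair(m[, groups == lev[1], drop = FALSE],
                         m[, groups == lev[2], drop = FALSE],
                         allow_unequal = allow_unequal)
  attr(pair, "groups") <- c(A = lev[1], B = lev[2])
  pair
}

#' Collapse probe-level rows to one row per gene
#'
#' When a gene is measured by several probes, the probe with the highest
#' mean expression across all samples is kept (ties broken by the
#' lexicographically smallest probe id).
#'
#' @param m Probes x samples matrix (probe ids as row names).
#' @param map `data.frame` with columns `probe_id`, `gene_id` covering all
#'   probes of `m`.
#' @return Genes x samples matrix keyed by gene id.
#' @export
collapse_probes <- function(m, map) {
  validate_expression_matrix(m, "probe matrix")
  stopifnot(is.data.frame(map),
            all(c("probe_id", "gene_id") %in% names(map)))
  unmapped <- setdiff(rownames(m), map$probe_id)
  if (length(unmapped))
    stop("probe(s) without a gene mapping: ",
         paste(unmapped, collapse = ", "))
  map <- map[map$probe_id %in% rownames(m), , drop = FALSE]
  mu <- rowMeans(m)[map$probe_id]
  ord <- order(map$gene_id, -mu, map$probe_id)
  pick <- map[ord, ][!duplicated(map$gene_id[ord]), , drop = FALSE]
  out <- m[pick$probe_id, , drop = FALSE]
  rownames(out) <- pick$gene_id
  out[order(rownames(out)), , drop = FALSE]
}

#' Export a thresholded correlation network for Cytoscape
#'
#' Thresholds the Fisher-z matrix at a cutoff given on the Pearson
#' correlation scale (converted internally via `atanh`) and writes the
#' resulting graph as a SIF edge list (edge type `cc`; isolated genes as
#' single-token lines) or as GraphML with a per-node `degree` attribute.
#'
#' @param fz A `fisher_z_matrix`.
#' @param pearson_threshold Edge rule c > threshold, 0 < threshold < 1.
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @return The path, invisibly.
#' @export
export_network <- function(fz, pearson_threshold, path,
                           format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (pearson_threshold <= 0 || pearson_threshold >= 1)
    stop("pearson_threshold must lie in (0, 1)")
  net <- network_at(fz, fisher_transform(pearson_threshold))
  g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$name <- fz$gene_ids
  igraph::V(g)$degree <- igraph::degree(g)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el)) paste(el[, 1], "cc", el[, 2], sep = "\t")
      else character(0)
    isolated <- fz$gene_ids[igraph::degree(g) == 0]
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}
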