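#' Read a samples-by-taxa abundance table
#'
#' Reads a tab-separated count matrix whose first column holds sample
#' identifiers and whose header names the taxa. Orientation is never
#' guessed: tables are samples in rows, taxa in columns; pass
#' `transpose = TRUE` if a file is stored the other way around.
#'
#' @param path Path to a TSV file.
#' @param transpose Transpose the matrix after reading (for taxa-in-rows
#'   files).
#' @return A tibble with a character `sample` column followed by one numeric
#'   column per taxon.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_abundance_table(
#'   tibble::tibble(sample = c("s1", "s2"), t1 = c(3, 1), t2 = c(0, 2)), tf
#' )
#' read_abundance_table(tf)
#' @export
read_abundance_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    dups <- unique(header[-1][duplicated(header[-1])])
    abort(paste0(
      "duplicated taxon column(s) in ", path, ": ",
      paste(dups, collapse = ", ")
    ))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  names(tab)[1] <- "sample"
  tab$sample <- as.character(tab$sample)
  if (isTRUE(transpose)) {
    m <- t(abundance_matrix(tab))
    tab <- tibble::as_tibble(m, rownames = "sample")
  }
  validate_abundance_table(tab, path = path)
  tab
}

#' Write a samples-by-taxa abundance table
#'
#' @param table Abundance tibble (`sample` column first).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  validate_abundance_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

validate_abundance_table <- function(tab, path = NULL) {
  where <- if (is.null(path)) "" else paste0(" in ", path)
  if (ncol(tab) < 2L) abort(paste0("no taxon columns", where))
  if (anyDuplicated(tab$sample)) {
    abort(paste0(
      "duplicated sample identifier(s)", where, ": ",
      paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", ")
    ))
  }
  counts <- tab[-1]
  bad_type <- names(counts)[!vapply(counts, is.numeric, logical(1))]
  if (length(bad_type)) {
    abort(paste0(
      "non-numeric count column(s)", where, ": ",
      paste(head(bad_type, 5L), collapse = ", ")
    ))
  }
  m <- as.matrix(counts)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    abort(paste0(
      "missing cells", where, " in sample(s): ",
      paste(head(tab$sample[bad], 5L), collapse = ", ")
    ))
  }
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)
    abort(paste0(
      "negative count(s)", where, " in sample(s): ",
      paste(head(tab$sample[bad], 5L), collapse = ", ")
    ))
  }
  invisible(tab)
}

# samples-by-taxa numeric matrix with sample rownames
abundance_matrix <- function(tab) {
  m <- as.matrix(tab[-1])
  rownames(m) <- tab$sample
  storage.mode(m) <- "double"
  m
}

#' Read or write per-sample study metadata
#'
#' Metadata tables carry one row per composite sample: site, forest type
#' (`PF`, `QPF`, `QBF`), neighboring plant richness, and soil/litter
#' covariates.
#'
#' @param path TSV path.
#' @return `read_study_metadata()`: a tibble with a character `sample`
#'   column. `write_study_metadata()`: `path`, invisibly.
#' @export
read_study_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample" %in% names(meta)) names(meta)[1] <- "sample"
  meta$sample <- as.character(meta$sample)
  if (anyDuplicated(meta$sample)) abort("duplicated sample identifiers in metadata")
  meta
}

#' @rdname read_study_metadata
#' @param meta Metadata tibble.
#' @export
write_study_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Export / import a co-occurrence network as GraphML
#'
#' Writes node attributes (taxon id, genus, kingdom) and edge attributes
#' (rho, p, sign) so the file opens directly in Gephi or Cytoscape.
#' Reading the file back reproduces the signed edge set exactly.
#'
#' @param net An `emnet_network` (see [build_network()]).
#' @param path Output `.graphml` path.
#' @return `path` invisibly for the writer; an `emnet_network` for the
#'   reader.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "emnet_network"))
  g <- net$graph
  for (nm in names(net$params)) {
    g <- igraph::set_graph_attr(g, paste0("param_", nm), net$params[[nm]])
  }
  g <- igraph::set_graph_attr(g, "provenance", net$provenance %||% "")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ga <- igraph::graph_attr(g)
  params <- ga[startsWith(names(ga), "param_")]
  names(params) <- sub("^param_", "", names(params))
  for (nm in names(ga)) g <- igraph::delete_graph_attr(g, nm)
  new_emnet_network(g, params = params, provenance = ga$provenance %||% "")
}

new_emnet_network <- function(graph, params = list(), provenance = "") {
  structure(
    list(graph = graph, params = params, provenance = provenance),
    class = "emnet_network"
  )
}

#' @export
print.emnet_network <- function(x, ...) {
  s <- if (igraph::ecount(x$graph)) igraph::E(x$graph)$sign else integer()
  cat(sprintf(
    "<emnet_network> %d nodes, %d edges (%d positive, %d negative)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    sum(s > 0), sum(s < 0)
  ))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = "=", collapse = ", "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
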