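# Plain-text readers and writers for the pipeline's interchange formats:
# expression TSV, rank-matrix TSV, GMT gene sets, signed edge lists and
# two-section tag files.

#' Write / read a genes x samples matrix as TSV
#'
#' First column `gene_id`, remaining columns the sample labels.
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv`: the numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param collection A `gene_set_collection`.
#' @param path File path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], "na", collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param universe Background gene list for the read collection (default:
#'   union of all members).
#' @return `read_gmt`: a `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe)
}

#' Write / read a signed pathway edge list as TSV
#'
#' Columns `from`, `to`, `sign` (+1 / -1).
#'
#' @param graph A `pathway_graph`.
#' @param path File path.
#' @export
write_edge_tsv <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @param genes Member genes (default: all endpoints in the file).
#' @return `read_edge_tsv`: a `pathway_graph`.
#' @export
read_edge_tsv <- function(path, genes = NULL) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- sort(unique(c(edges$from, edges$to)))
  pathway_graph(genes, edges)
}

#' Write / read a two-section tag file for a signature
#'
#' Plain text with `>UP` and `>DOWN` section headers followed by one gene
#' id per line.
#'
#' @param sig A [tag_signature()].
#' @param path File path.
#' @export
write_tagfile <- function(sig, path) {
  writeLines(c(">UP", sig$up_tags, ">DOWN", sig$down_tags), path)
  invisible(path)
}

#' @rdname write_tagfile
#' @return `read_tagfile`: a [tag_signature()].
#' @export
read_tagfile <- function(path) {
  lines <- readLines(path)
  up_at <- which(lines == ">UP")
  down_at <- which(lines == ">DOWN")
  if (length(up_at) != 1 || length(down_at) != 1 || down_at < up_at) {
    stop("malformed tag file: expected >UP then >DOWN sections",
         call. = FALSE)
  }
  tag_signature(lines[seq(up_at + 1, down_at - 1)],
            lines[seq(down_at + 1, length(lines))])
}

#' Write a compendium rank matrix and metadata as TSV
#'
#' The rank matrix is written genes x instances (first column `gene_id`),
#' metadata as a separate four-column table.
#'
#' @param compendium A `reference_compendium`.
#' @param rank_path,meta_path Output paths.
#' @export
write_compendium_tsv <- function(compendium, rank_path, meta_path) {
  write_expression_tsv(compendium$rank_matrix, rank_path)
  write.table(compendium$instances, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(rank_path)
}

#' @rdname write_compendium_tsv
#' @return `read_compendium_tsv`: a `reference_compendium` (planted-truth
#'   annotations, if any, are not round-tripped).
#' @export
read_compendium_tsv <- function(rank_path, meta_path) {
  rm_ <- read_expression_tsv(rank_path)
  storage.mode(rm_) <- "integer"
  instances <- read.delim(meta_path, stringsAsFactors = FALSE)
  structure(list(rank_matrix = rm_, instances = instances,
                 universe = rownames(rm_),
                 mimic_instances = character(0),
                 anti_instances = character(0)),
            class = "reference_compendium")
}
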