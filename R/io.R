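#' Sample x trait table with environment/saponin partition
#'
#' @param values Numeric matrix, samples in rows, traits in columns.
#' @param env_factors Column names flagged as environmental factors.
#' @param saponins Column names flagged as saponin contents.
#'
#' @return Object of class \code{trait_table}: the value matrix plus the
#'   partition of its columns.
#' @export
trait_table <- function(values, env_factors, saponins) {
  assert_that(is.matrix(values) && is.numeric(values),
              "trait values must be a numeric matrix")
  assert_that(!is.null(colnames(values)) && !is.null(rownames(values)),
              "trait matrix needs sample and trait names")
  assert_that(!anyDuplicated(colnames(values)) && !anyDuplicated(rownames(values)),
              "duplicate sample or trait IDs")
  unknown <- setdiff(colnames(values), c(env_factors, saponins))
  if (length(unknown) > 0) {
    stop("trait(s) in neither the environment nor the saponin list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  overlap <- intersect(env_factors, saponins)
  assert_that(length(overlap) == 0, "a trait cannot be both environment and saponin")
  structure(list(values = values,
                 env_factors = intersect(colnames(values), env_factors),
                 saponins = intersect(colnames(values), saponins)),
            class = "trait_table")
}

#' Environmental columns of a trait table
#' @param traits A \code{trait_table}.
#' @return Numeric matrix, samples x environmental factors.
#' @export
env_values <- function(traits) {
  traits$values[, traits$env_factors, drop = FALSE]
}

#' Saponin columns of a trait table
#' @param traits A \code{trait_table}.
#' @return Numeric matrix, samples x saponins.
#' @export
saponin_values <- function(traits) {
  traits$values[, traits$saponins, drop = FALSE]
}

# full-precision TSV writer: "%.17g" survives a write/read round trip
#' @noRd
write_numeric_tsv <- function(mat, path) {
  chr <- matrix(sprintf("%.17g", mat), nrow(mat),
                dimnames = dimnames(mat))
  chr[is.na(mat)] <- ""
  df <- data.frame(id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @noRd
read_numeric_tsv <- function(path, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated row IDs in ", path, call. = FALSE)
  }
  if (anyDuplicated(colnames(raw)[-1])) {
    stop("duplicated column IDs in ", path, call. = FALSE)
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  body[body == ""] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell(s) in ", path, ", e.g. row ", ids[bad[1, 1]],
         " column ", colnames(body)[bad[1, 2]], call. = FALSE)
  }
  num
}

#' Read a sample x transcript expression table (TSV)
#'
#' Expects a header row and an ID column.  Orientation is auto-detected
#' with the samples < transcripts heuristic (a table with more rows than
#' columns is assumed to be transcript-major and is transposed), which can
#' be overridden with \code{samples_as_rows}.  Empty cells become
#' \code{NA}; non-numeric cells and duplicated IDs are errors.
#'
#' @param path File path.
#' @param samples_as_rows \code{NULL} (auto), \code{TRUE} or \code{FALSE}.
#' @param sep Field separator; tab by default, "," for CSV input.
#'
#' @return Numeric matrix with samples in rows and transcripts in columns.
#' @export
read_expression <- function(path, samples_as_rows = NULL, sep = "\t") {
  mat <- read_numeric_tsv(path, sep = sep)
  if (is.null(samples_as_rows)) {
    samples_as_rows <- nrow(mat) <= ncol(mat)
  }
  if (!samples_as_rows) mat <- t(mat)
  log_stage("io", "read expression ", nrow(mat), " samples x ", ncol(mat),
            " transcripts from ", path)
  mat
}

#' Write an expression matrix as TSV
#' @param expr Samples x transcripts matrix.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path) {
  write_numeric_tsv(expr, path)
}

#' Read a sample x trait table (TSV)
#'
#' Columns must appear in exactly one of the two provided name lists;
#' unlisted columns are a configuration error.
#'
#' @param path File path (samples in rows, traits in columns).
#' @param env_names Names of environmental factor columns.
#' @param saponin_names Names of saponin columns.
#' @param sep Field separator.
#'
#' @return A \code{\link{trait_table}}.
#' @export
read_traits <- function(path, env_names = default_env_factors(),
                        saponin_names = default_saponins(), sep = "\t") {
  mat <- read_numeric_tsv(path, sep = sep)
  trait_table(mat, env_factors = env_names, saponins = saponin_names)
}

#' Write a trait table as TSV
#' @param traits A \code{trait_table}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_traits <- function(traits, path) {
  write_numeric_tsv(traits$values, path)
}

#' Align a trait table to an expression matrix's sample order
#'
#' @param expr Samples x transcripts matrix.
#' @param traits A \code{trait_table} whose sample set must equal the
#'   expression matrix's (any order on disk).
#'
#' @return The trait table reordered to the expression sample order.
#' @export
align_samples <- function(expr, traits) {
  es <- rownames(expr)
  ts <- rownames(traits$values)
  if (!setequal(es, ts)) {
    stop("sample mismatch between expression and trait tables: ",
         paste(union(setdiff(es, ts), setdiff(ts, es)), collapse = ", "),
         call. = FALSE)
  }
  traits$values <- traits$values[es, , drop = FALSE]
  traits
}

#' @noRd
graph_to_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("source", "target")],
    directed = TRUE,
    vertices = graph$nodes[, c("id", "node_kind", "layer")])
  igraph::E(g)$weight <- graph$edges$r
  igraph::E(g)$criterion <- graph$edges$criterion
  g
}

#' Export a directed association graph
#'
#' GraphML keeps node attributes \code{node_kind} and \code{layer} and the
#' signed correlation as edge attribute \code{weight}; the edge TSV has
#' columns source, target, weight and criterion (corr | variance | both).
#'
#' @param graph A directed association graph from
#'   \code{\link{build_directed_graph}}.
#' @param path Output file path.
#' @param format "graphml" or "edge_tsv".
#' @return The path, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  validate_graph(graph)
  if (format == "graphml") {
    igraph::write_graph(graph_to_igraph(graph), path, format = "graphml")
  } else {
    df <- data.frame(source = graph$edges$source, target = graph$edges$target,
                     weight = sprintf("%.17g", graph$edges$r),
                     criterion = graph$edges$criterion,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a GraphML association graph
#'
#' Inverse of \code{\link{export_graph}} for the GraphML format.
#'
#' @param path GraphML file written by \code{export_graph}.
#' @return A directed association graph object.
#' @export
import_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      node_kind = igraph::V(g)$node_kind,
                      layer = as.integer(igraph::V(g)$layer),
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(source = el$from, target = el$to,
                      r = if (nrow(el)) el$weight else numeric(0),
                      p = rep(NA_real_, nrow(el)),
                      variance_contribution = rep(NA_real_, nrow(el)),
                      criterion = if (nrow(el)) el$criterion else character(0),
                      stringsAsFactors = FALSE)
  new_assoc_graph(nodes, edges, r_threshold = NA_real_,
                  variance_threshold = NA_real_)
}
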