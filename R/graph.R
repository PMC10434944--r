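#' Correlate two layers of node signals
#'
#' All pairwise Pearson correlations and two-sided p-values between
#' upstream and downstream node signals, as candidate directed edges.
#' Zero-variance nodes yield no candidates (with a warning).
#'
#' @param upstream_signals Samples x nodes matrix (edge sources).
#' @param downstream_signals Samples x nodes matrix (edge targets).
#'
#' @return Data frame of edge candidates: source, target, r, p,
#'   variance_contribution (NA until the variance filter runs) and
#'   criterion (NA until filtering).
#' @export
correlate_layers <- function(upstream_signals, downstream_signals) {
  assert_that(identical(rownames(upstream_signals), rownames(downstream_signals)),
              "layer sample orders must match")
  assert_that(nrow(upstream_signals) >= 3, "need at least 3 samples")
  up_sd <- apply(upstream_signals, 2, stats::sd)
  dn_sd <- apply(downstream_signals, 2, stats::sd)
  dead <- c(colnames(upstream_signals)[up_sd == 0],
            colnames(downstream_signals)[dn_sd == 0])
  if (length(dead) > 0) {
    warning("zero-variance node(s) excluded from candidates: ",
            paste(dead, collapse = ", "), call. = FALSE)
  }
  up <- upstream_signals[, up_sd > 0, drop = FALSE]
  dn <- downstream_signals[, dn_sd > 0, drop = FALSE]
  r <- stats::cor(up, dn)
  p <- cor_pvalue(r, nrow(up))
  data.frame(source = rep(colnames(up), times = ncol(dn)),
             target = rep(colnames(dn), each = ncol(up)),
             r = as.vector(r), p = as.vector(p),
             variance_contribution = NA_real_,
             criterion = NA_character_,
             stringsAsFactors = FALSE)
}

#' Cumulative variance-contribution filter for one target node
#'
#' Each candidate precursor's contribution is its squared correlation with
#' the target, normalized to sum to one over the candidates.  Candidates
#' are sorted in descending contribution order and the smallest prefix
#' whose cumulative contribution reaches \code{threshold} is selected
#' (the boundary is inclusive: a prefix summing exactly to the threshold
#' suffices).
#'
#' @param candidates Data frame of edge candidates for a single target
#'   (as produced by \code{\link{correlate_layers}}).
#' @param threshold Cumulative contribution threshold in (0, 1],
#'   default 0.8.
#'
#' @return The selected candidates with \code{variance_contribution}
#'   filled in and \code{criterion} set to "variance"; empty (with a
#'   warning) when all contributions are zero.
#' @export
variance_contribution_filter <- function(candidates, threshold = 0.8) {
  assert_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  assert_that(length(unique(candidates$target)) <= 1,
              "candidates must concern a single target node")
  contrib <- candidates$r^2
  total <- sum(contrib)
  if (nrow(candidates) == 0 || total == 0) {
    warning("all variance contributions are zero; nothing selected",
            call. = FALSE)
    return(candidates[0, ])
  }
  contrib <- contrib / total
  ord <- order(contrib, decreasing = TRUE)
  cum <- cumsum(contrib[ord])
  n_keep <- min(which(cum >= threshold - 1e-12))
  keep <- ord[seq_len(n_keep)]
  out <- candidates[keep, , drop = FALSE]
  out$variance_contribution <- contrib[keep]
  out$criterion <- "variance"
  out
}

#' @noRd
new_assoc_graph <- function(nodes, edges, r_threshold, variance_threshold) {
  structure(list(nodes = nodes, edges = edges,
                 r_threshold = r_threshold,
                 variance_threshold = variance_threshold),
            class = "assoc_graph")
}

#' Construct a directed association graph from node and edge tables
#'
#' Lets a layered graph be assembled directly (e.g. for compiling a
#' hand-designed white-box network).  The result is validated: acyclic,
#' layer-monotone, environment nodes source-only, saponin nodes sink-only.
#'
#' @param nodes Data frame with columns id, node_kind (environment /
#'   module / saponin) and layer (integer; environment lowest).
#' @param edges Data frame with columns source, target and r (signed
#'   weight); p, variance_contribution and criterion are optional.
#'
#' @return A validated \code{assoc_graph}.
#' @export
assoc_graph <- function(nodes, edges) {
  for (col in c("p", "variance_contribution")) {
    if (is.null(edges[[col]])) edges[[col]] <- rep(NA_real_, nrow(edges))
  }
  if (is.null(edges$criterion)) {
    edges$criterion <- rep(NA_character_, nrow(edges))
  }
  graph <- new_assoc_graph(
    nodes[, c("id", "node_kind", "layer")],
    edges[, c("source", "target", "r", "p", "variance_contribution",
              "criterion")],
    r_threshold = NA_real_, variance_threshold = NA_real_)
  validate_graph(graph)
  graph
}

#' Validate a directed association graph
#'
#' Asserts acyclicity, strict layer monotonicity of every edge, absence of
#' incoming edges on environment nodes and of outgoing edges on saponin
#' nodes.
#'
#' @param graph An \code{assoc_graph}.
#' @return The graph, invisibly; errors on violation.
#' @export
validate_graph <- function(graph) {
  assert_that(inherits(graph, "assoc_graph"), "not an association graph")
  nodes <- graph$nodes
  edges <- graph$edges
  assert_that(!anyDuplicated(nodes$id), "duplicate node IDs")
  if (nrow(edges) > 0) {
    layer <- stats::setNames(nodes$layer, nodes$id)
    kind <- stats::setNames(nodes$node_kind, nodes$id)
    assert_that(all(c(edges$source, edges$target) %in% nodes$id),
                "edge endpoint missing from node set")
    assert_that(all(layer[edges$source] < layer[edges$target]),
                "edge violates layer monotonicity")
    assert_that(all(kind[edges$target] != "environment"),
                "environment node with incoming edge")
    assert_that(all(kind[edges$source] != "saponin"),
                "saponin node with outgoing edge")
    assert_that(igraph::is_dag(graph_to_igraph(graph)), "graph contains a cycle")
  }
  invisible(graph)
}

# accept edges for one target given gated candidates: correlation rule,
# variance rule, or their union/intersection
#' @noRd
accept_edges_for_target <- function(cands, r_threshold, variance_threshold,
                                    combine) {
  if (nrow(cands) == 0) return(cands[0, ])
  by_corr <- abs(cands$r) > r_threshold
  selected_var <- suppressWarnings(
    variance_contribution_filter(cands, variance_threshold))
  by_var <- cands$source %in% selected_var$source
  keep <- if (combine == "or") by_corr | by_var else by_corr & by_var
  out <- cands[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  out$criterion <- ifelse(by_corr[keep] & by_var[keep], "both",
                          ifelse(by_corr[keep], "corr", "variance"))
  vc <- stats::setNames(selected_var$variance_contribution, selected_var$source)
  out$variance_contribution <- unname(vc[out$source])
  out
}

#' Build the layered environment-module-saponin directed graph
#'
#' Layer 0 holds environmental factors, layers 1..L co-expression module
#' eigengenes and the final layer saponin contents.  Working layer by
#' layer, candidate edges into each target node are first gated at the
#' significance level \code{alpha}, then accepted when they satisfy the
#' absolute-correlation criterion (|r| > \code{r_threshold}) or fall into
#' the smallest precursor prefix whose cumulative normalized
#' squared-correlation contribution reaches \code{variance_threshold}
#' (union by default; \code{combine = "and"} requires both).  Modules with
#' no accepted environment edge may attach behind an already-placed module
#' when \code{max_module_layers > 1}.  Modules without a path onward to
#' any saponin are pruned.
#'
#' @param env Samples x environmental-factor matrix.
#' @param eigengenes An \code{eigengene_matrix} (samples x modules).
#' @param saponins Samples x saponin matrix.
#' @param r_threshold Absolute correlation threshold, default 0.4.
#' @param variance_threshold Cumulative contribution threshold, default 0.8.
#' @param max_module_layers Maximum number of module layers, default 2.
#' @param alpha Significance gate on candidate correlations, default 0.05.
#' @param combine "or" (default) or "and" combination of the two criteria.
#'
#' @return A validated \code{assoc_graph}; edge weights are the signed
#'   correlations.  When no saponin node is reachable the graph has zero
#'   edges and a warning is emitted.
#' @export
build_directed_graph <- function(env, eigengenes, saponins,
                                 r_threshold = 0.4, variance_threshold = 0.8,
                                 max_module_layers = 2, alpha = 0.05,
                                 combine = c("or", "and")) {
  combine <- match.arg(combine)
  eig <- unclass(eigengenes)
  assert_that(identical(rownames(env), rownames(eig)) &&
                identical(rownames(env), rownames(saponins)),
              "env, eigengene and saponin samples must be aligned")
  module_layer <- integer(0)
  edges <- list()
  remaining <- colnames(eig)
  upstream <- env
  for (l in seq_len(max_module_layers)) {
    if (length(remaining) == 0 || ncol(upstream) == 0) break
    cands <- correlate_layers(upstream, eig[, remaining, drop = FALSE])
    cands <- cands[cands$p < alpha, , drop = FALSE]
    placed_now <- character(0)
    for (m in unique(cands$target)) {
      acc <- accept_edges_for_target(cands[cands$target == m, , drop = FALSE],
                                     r_threshold, variance_threshold, combine)
      if (nrow(acc) > 0) {
        edges[[length(edges) + 1]] <- acc
        placed_now <- c(placed_now, m)
      }
    }
    if (length(placed_now) == 0) break
    module_layer[placed_now] <- l
    remaining <- setdiff(remaining, placed_now)
    upstream <- eig[, placed_now, drop = FALSE]
  }

  placed <- names(module_layer)
  sap_edges <- list()
  if (length(placed) > 0) {
    cands <- correlate_layers(eig[, placed, drop = FALSE], saponins)
    cands <- cands[cands$p < alpha, , drop = FALSE]
    for (s in unique(cands$target)) {
      acc <- accept_edges_for_target(cands[cands$target == s, , drop = FALSE],
                                     r_threshold, variance_threshold, combine)
      if (nrow(acc) > 0) sap_edges[[length(sap_edges) + 1]] <- acc
    }
  }
  edges_df <- do.call(rbind, c(edges, sap_edges))
  if (is.null(edges_df)) {
    edges_df <- data.frame(source = character(0), target = character(0),
                           r = numeric(0), p = numeric(0),
                           variance_contribution = numeric(0),
                           criterion = character(0), stringsAsFactors = FALSE)
  }

  # prune modules with no onward path to a saponin (deepest layer first)
  repeat {
    has_out <- unique(edges_df$source)
    dead <- setdiff(names(module_layer), has_out)
    if (length(dead) == 0) break
    module_layer <- module_layer[setdiff(names(module_layer), dead)]
    edges_df <- edges_df[!(edges_df$target %in% dead) &
                           !(edges_df$source %in% dead), , drop = FALSE]
  }

  sap_in <- intersect(colnames(saponins), unique(edges_df$target))
  if (length(sap_in) == 0) {
    warning("no saponin node reachable; graph is empty", call. = FALSE)
    nodes <- data.frame(id = character(0), node_kind = character(0),
                        layer = integer(0), stringsAsFactors = FALSE)
    return(new_assoc_graph(nodes, edges_df[0, ], r_threshold, variance_threshold))
  }
  env_in <- intersect(colnames(env), unique(edges_df$source))
  n_mod_layers <- if (length(module_layer)) max(module_layer) else 0L
  nodes <- rbind(
    data.frame(id = env_in, node_kind = "environment", layer = 0L,
               stringsAsFactors = FALSE),
    data.frame(id = names(module_layer), node_kind = "module",
               layer = as.integer(module_layer), stringsAsFactors = FALSE),
    data.frame(id = sap_in, node_kind = "saponin",
               layer = n_mod_layers + 1L, stringsAsFactors = FALSE))
  graph <- new_assoc_graph(nodes, edges_df, r_threshold, variance_threshold)
  log_stage("graph", "nodes: env=", length(env_in), " modules=",
            length(module_layer), " saponins=", length(sap_in),
            "; edges=", nrow(edges_df))
  validate_graph(graph)
  graph
}

#' Map detected modules to planted ground-truth modules
#'
#' Each detected module is matched to the planted module contributing the
#' majority of its transcripts (background counts as its own class).
#'
#' @param partition A \code{module_partition} from detection.
#' @param truth_assignment Named character vector of planted labels
#'   (\code{ground_truth$module_assignment}).
#'
#' @return Named character vector: detected module label -> planted label.
#' @export
match_modules <- function(partition, truth_assignment) {
  detected <- setdiff(unique(partition$assignment), "grey")
  out <- stats::setNames(character(length(detected)), detected)
  for (m in detected) {
    ids <- names(partition$assignment)[partition$assignment == m]
    out[m] <- names(which.max(table(truth_assignment[ids])))
  }
  out
}

#' Precision and recall of recovered graph edges against ground truth
#'
#' Detected module labels are translated to planted labels via
#' \code{module_map}; module-module edges and edges onto saponins that
#' have no generating coefficients (the aggregate TS) are excluded from
#' scoring, since the truth sets define no status for them.
#'
#' @param graph An \code{assoc_graph} built from detected modules.
#' @param ground_truth The \code{ground_truth} component of
#'   \code{\link{generate_dataset}}'s output.
#' @param module_map Mapping from \code{\link{match_modules}}.
#'
#' @return List with \code{precision}, \code{recall}, \code{n_true},
#'   \code{n_recovered} and the translated edge data frame.
#' @export
edge_recovery_scores <- function(graph, ground_truth, module_map) {
  truth <- rbind(
    ground_truth$true_env_module_edges[, c("source", "target")],
    ground_truth$true_module_saponin_edges[, c("source", "target")])
  truth_keys <- paste(truth$source, truth$target)
  scored_saponins <- unique(ground_truth$true_module_saponin_edges$target)
  kind <- stats::setNames(graph$nodes$node_kind, graph$nodes$id)
  ed <- graph$edges
  src <- ifelse(kind[ed$source] == "module", module_map[ed$source], ed$source)
  tgt <- ifelse(kind[ed$target] == "module", module_map[ed$target], ed$target)
  scored <- !(kind[ed$source] == "module" & kind[ed$target] == "module") &
    !(kind[ed$target] == "saponin" & !(tgt %in% scored_saponins))
  keys <- unique(paste(src[scored], tgt[scored]))
  tp <- sum(keys %in% truth_keys)
  list(precision = if (length(keys)) tp / length(keys) else NA_real_,
       recall = tp / length(truth_keys),
       n_true = length(truth_keys), n_recovered = length(keys),
       edges = data.frame(source = src, target = tgt, scored = scored,
                          stringsAsFactors = FALSE))
}
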