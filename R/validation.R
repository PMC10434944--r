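#' Contingency-table degrees of freedom
#'
#' DF = (a - 1)(b - 1) for a x b category counts.  A degenerate table
#' with a single category on either margin yields DF = 0 with a warning.
#'
#' @param a Number of categories of the first condition (>= 1).
#' @param b Number of categories of the second condition (>= 1).
#'
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(a, b) {
  assert_that(is_count(a) && is_count(b),
              "a and b must be positive counts")
  df <- (a - 1L) * (b - 1L)
  if (df == 0) {
    warning("degenerate table: zero degrees of freedom", call. = FALSE)
  }
  as.integer(df)
}

#' Construct a validated 2x2 contingency table
#'
#' Rows are the associated / non-associated module-combination categories
#' (NAMC, nNAMC), columns the effective / invalid frequencies.
#' Non-integer frequencies are accepted as weights without rounding.
#'
#' @param observed 2x2 nonnegative numeric matrix.
#'
#' @return Object of class \code{contingency_table} with the observed
#'   cells and the row, column and grand totals.
#' @export
contingency_table <- function(observed) {
  observed <- as.matrix(observed)
  assert_that(identical(dim(observed), c(2L, 2L)),
              "observed must be a 2x2 matrix")
  assert_that(is.numeric(observed) && all(is.finite(observed)) &&
                all(observed >= 0),
              "observed frequencies must be nonnegative numbers")
  if (is.null(rownames(observed))) rownames(observed) <- c("NAMC", "nNAMC")
  if (is.null(colnames(observed))) colnames(observed) <- c("effective", "invalid")
  structure(list(observed = observed,
                 row_totals = rowSums(observed),
                 col_totals = colSums(observed),
                 grand_total = sum(observed)),
            class = "contingency_table")
}

#' Chi-square independence test on a 2x2 contingency table
#'
#' Expected frequencies E_ij = row_i x col_j / N; the statistic is
#' sum((|O - E| - c)^2 / E) with c = 0.5 under the Yates continuity
#' correction (default; |O - E| - c is floored at zero) and c = 0
#' uncorrected.  Degrees of freedom come from
#' \code{\link{degrees_of_freedom}}.
#'
#' @param table A \code{contingency_table} or a 2x2 matrix.
#' @param correction "yates" (default) or "none".
#' @param alpha Significance level, default 0.05.
#'
#' @return Object of class \code{chi_square_result}: statistic, df,
#'   p-value, expected frequencies, correction used and the rejection
#'   flag at \code{alpha}.
#' @export
chi_square_validity <- function(table, correction = c("yates", "none"),
                                alpha = 0.05) {
  correction <- match.arg(correction)
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  O <- table$observed
  N <- table$grand_total
  E <- outer(table$row_totals, table$col_totals) / N
  if (any(E == 0)) {
    stop("degenerate table: an expected frequency is zero", call. = FALSE)
  }
  cc <- if (correction == "yates") 0.5 else 0
  dev <- pmax(abs(O - E) - cc, 0)
  statistic <- sum(dev^2 / E)
  df <- degrees_of_freedom(nrow(O), ncol(O))
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df, p_value = p,
                 correction = correction, expected = E,
                 alpha = alpha, reject = p < alpha),
            class = "chi_square_result")
}

#' NAMC / nNAMC frequencies from a module partition and graph
#'
#' A helper construction (the source study does not specify its
#' combinatorial recipe): the associated frequency is the transcript count
#' of modules with a directed path to the target saponin, the
#' non-associated frequency that of the remaining non-grey modules, both
#' multiplied by \code{scale_factor}.  Arranged as a perfect-association
#' 2x2 table (associated modules effective, others invalid).
#'
#' @param partition A \code{module_partition}.
#' @param graph An \code{assoc_graph}.
#' @param target_saponin Saponin node ID.
#' @param scale_factor Positive multiplier on the raw transcript counts.
#'
#' @return A \code{contingency_table}.
#' @export
namc_table <- function(partition, graph, target_saponin, scale_factor = 1) {
  assert_that(scale_factor > 0, "scale_factor must be > 0")
  assert_that(target_saponin %in% graph$nodes$id,
              "target saponin is not a graph node")
  g <- graph_to_igraph(graph)
  modules <- graph$nodes$id[graph$nodes$node_kind == "module"]
  reach <- igraph::distances(g, v = modules, to = target_saponin,
                             mode = "out", weights = NA)
  connected <- modules[is.finite(reach[, 1])]
  counts <- table(partition$assignment)
  all_mod <- setdiff(names(counts), "grey")
  namc <- sum(counts[intersect(all_mod, connected)]) * scale_factor
  nnamc <- sum(counts[setdiff(all_mod, connected)]) * scale_factor
  contingency_table(matrix(c(namc, 0, 0, nnamc), 2, 2, byrow = TRUE,
                           dimnames = list(c("NAMC", "nNAMC"),
                                           c("effective", "invalid"))))
}

#' Positive validity test: known transcripts map into connected modules
#'
#' Locates the modules containing transcripts known to act in the target
#' saponin's biosynthesis, checks whether those modules have a directed
#' path to the target saponin node within \code{max_path} steps, and
#' summarizes GS-MM concordance (correlation of |MM| with |GS| over each
#' implicated module's members).  The test passes when at least one
#' implicated module is connected.
#'
#' @param known_ids Nonempty character vector of transcript IDs present in
#'   the partition.
#' @param partition A \code{module_partition}.
#' @param gsmm A \code{gsmm_table}.
#' @param graph An \code{assoc_graph}.
#' @param target_saponin Saponin node the known transcripts act on.
#' @param max_path Maximum accepted path length (default 3).
#'
#' @return Object of class \code{positive_test_report}: per-transcript and
#'   per-module tables and the overall \code{pass} flag.
#' @export
positive_test <- function(known_ids, partition, gsmm, graph, target_saponin,
                          max_path = 3) {
  assert_that(length(known_ids) > 0, "known_ids must be nonempty")
  missing_ids <- setdiff(known_ids, names(partition$assignment))
  if (length(missing_ids) > 0) {
    stop("unknown transcript ID(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  modules <- unname(partition$assignment[known_ids])
  implicated <- setdiff(unique(modules), "grey")
  sap_in_graph <- target_saponin %in% graph$nodes$id
  path_len <- stats::setNames(rep(Inf, length(implicated)), implicated)
  if (sap_in_graph && length(implicated) > 0) {
    g <- graph_to_igraph(graph)
    in_graph <- intersect(implicated, graph$nodes$id)
    if (length(in_graph) > 0) {
      d <- igraph::distances(g, v = in_graph, to = target_saponin,
                             mode = "out", weights = NA)
      path_len[in_graph] <- d[, 1]
    }
  }
  concordance <- stats::setNames(rep(NA_real_, length(implicated)), implicated)
  gs_col <- if (target_saponin %in% colnames(gsmm$gs)) target_saponin else NA
  for (m in implicated) {
    members <- names(partition$assignment)[partition$assignment == m]
    if (!is.na(gs_col) && m %in% colnames(gsmm$mm) && length(members) >= 3) {
      concordance[m] <- stats::cor(abs(gsmm$mm[members, m]),
                                   abs(gsmm$gs[members, gs_col]))
    }
  }
  per_transcript <- data.frame(
    transcript = known_ids, module = modules,
    mm = vapply(seq_along(known_ids), function(i) {
      if (modules[i] %in% colnames(gsmm$mm)) {
        gsmm$mm[known_ids[i], modules[i]]
      } else NA_real_
    }, numeric(1)),
    gs = if (!is.na(gs_col)) gsmm$gs[known_ids, gs_col] else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  per_module <- data.frame(
    module = implicated,
    n_known = vapply(implicated, function(m) sum(modules == m), integer(1)),
    path_length = unname(path_len),
    connected = unname(is.finite(path_len) & path_len <= max_path),
    gs_mm_concordance = unname(concordance),
    stringsAsFactors = FALSE, row.names = NULL)
  pass <- nrow(per_module) > 0 && any(per_module$connected)
  if (!pass) {
    log_stage("validate", "positive test FAILED: no implicated module is ",
              "connected to ", target_saponin,
              if (length(implicated) == 0) " (all known transcripts in grey)")
  }
  structure(list(per_transcript = per_transcript, per_module = per_module,
                 target_saponin = target_saponin, pass = pass),
            class = "positive_test_report")
}
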