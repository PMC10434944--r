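#' Filter unusable transcripts
#'
#' Removes transcript columns whose missing fraction exceeds
#' \code{max_missing_fraction} or whose variance (computed over non-missing
#' values) is at most \code{min_variance}.  The defaults implement the
#' strict reading "missing data or zero variance": any missingness and any
#' exactly-constant column disqualify a transcript.
#'
#' @param expr Samples x transcripts matrix, possibly with \code{NA}s.
#' @param max_missing_fraction Maximum tolerated missing fraction (default 0).
#' @param min_variance Variance at or below which a transcript is removed
#'   (default 0).
#'
#' @return List with \code{expression} (the retained columns) and
#'   \code{report}, a \code{filter_report} accounting for every input
#'   transcript (removed + retained = input).
#' @export
filter_transcripts <- function(expr, max_missing_fraction = 0,
                               min_variance = 0) {
  assert_that(is.matrix(expr) && ncol(expr) > 0 && nrow(expr) > 0,
              "expr must be a nonempty matrix")
  assert_that(max_missing_fraction >= 0 && max_missing_fraction <= 1,
              "max_missing_fraction must lie in [0, 1]")
  assert_that(min_variance >= 0, "min_variance must be nonnegative")

  missing_frac <- colMeans(is.na(expr))
  vars <- apply(expr, 2, stats::var, na.rm = TRUE)
  too_missing <- missing_frac > max_missing_fraction
  # all-NA columns have undefined variance; they fall under missingness
  low_var <- !too_missing & (!is.finite(vars) | vars <= min_variance)

  removed <- too_missing | low_var
  reasons <- ifelse(too_missing, "missing_excess", "zero_variance")[removed]
  names(reasons) <- colnames(expr)[removed]

  if (all(removed)) {
    stop("all transcripts removed by filtering; nothing left to analyse",
         call. = FALSE)
  }
  report <- structure(list(
    n_input_transcripts = ncol(expr),
    n_removed = sum(removed),
    n_retained = sum(!removed),
    removed_ids = colnames(expr)[removed],
    reasons = reasons), class = "filter_report")
  log_stage("preprocess", "filtered transcripts: input=", ncol(expr),
            " removed=", report$n_removed, " retained=", report$n_retained)
  list(expression = expr[, !removed, drop = FALSE], report = report)
}

#' Detect outlier samples by hierarchical clustering
#'
#' Samples are clustered on their Euclidean expression distance; cutting
#' the dendrogram at \code{cut_height} partitions them, and every sample
#' outside the largest cluster is flagged.  On an exact tie for largest
#' cluster nothing is flagged and a warning is emitted (conservative).
#'
#' @param expr Samples x transcripts matrix (>= 3 samples).
#' @param cut_height Positive height at which the sample dendrogram is cut.
#' @param linkage Agglomeration method, "average" (default) or "complete".
#'
#' @return An \code{outlier_report}: dendrogram merge heights, the cut
#'   height and the flagged sample IDs.
#' @export
detect_outlier_samples <- function(expr, cut_height,
                                   linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  assert_that(is.matrix(expr) && nrow(expr) >= 3,
              "need at least 3 samples for outlier detection")
  assert_that(is.numeric(cut_height) && length(cut_height) == 1 && cut_height > 0,
              "cut_height must be > 0")
  hc <- stats::hclust(stats::dist(expr), method = linkage)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  biggest <- sizes[sizes == max(sizes)]
  if (length(biggest) > 1) {
    warning("tie for largest sample cluster at cut height ", cut_height,
            "; no samples flagged", call. = FALSE)
    flagged <- character(0)
  } else {
    flagged <- rownames(expr)[cl != as.integer(names(biggest))]
  }
  log_stage("preprocess", "outlier scan: samples=", nrow(expr),
            " cut_height=", cut_height, " flagged=", length(flagged))
  structure(list(dendrogram_heights = hc$height,
                 cut_height = cut_height,
                 flagged_samples = flagged,
                 cluster_sizes = as.integer(sizes)),
            class = "outlier_report")
}
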