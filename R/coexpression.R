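#' Pairwise Pearson correlation with p-values
#'
#' Computes the full symmetric Pearson correlation matrix S over
#' transcripts together with two-sided p-values from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param expr Samples x transcripts matrix without missing values
#'   (run \code{\link{filter_transcripts}} first).
#'
#' @return Object of class \code{cor_matrix} with components \code{ids},
#'   \code{r}, \code{p} and \code{n}.
#' @export
correlation_matrix <- function(expr) {
  assert_that(is.matrix(expr) && nrow(expr) >= 3,
              "need at least 3 samples")
  assert_that(!anyNA(expr), "missing values present; filter first")
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance transcript(s) should have been filtered: ",
         paste(colnames(expr)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(expr)
  p <- cor_pvalue(r, nrow(expr))
  diag(p) <- 0
  structure(list(ids = colnames(expr), r = r, p = p, n = nrow(expr)),
            class = "cor_matrix")
}

# Scale-free topology fit: bin log10(k) into nbins equal-width bins,
# regress log10 of the bin frequency on log10 of the bin's mean
# connectivity.  R^2 is signed negative when the slope is positive.
#' @noRd
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = nbins + 1)
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- log10(meank[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Soft-threshold scan for approximate scale-free topology
#'
#' For each candidate exponent beta the power adjacency |S|^beta is formed,
#' node connectivities k are computed, and the scale-free fit index R^2 of
#' the degree distribution is evaluated (10 logarithmic bins; R^2 is
#' negated when the log-log slope is positive).  The chosen beta is the
#' smallest one reaching \code{target_r2}, falling back with a warning to
#' the beta maximizing R^2 when none does.
#'
#' @param corr A \code{cor_matrix}.
#' @param beta_grid Candidate positive integer exponents.
#' @param target_r2 Scale-free fit target, default 0.9.
#'
#' @return Object of class \code{soft_threshold_scan} with the per-beta
#'   fit indices, mean connectivities and \code{chosen_beta}.
#' @export
pick_soft_threshold <- function(corr, beta_grid = 1:20, target_r2 = 0.9) {
  assert_that(inherits(corr, "cor_matrix"), "corr must be a cor_matrix")
  assert_that(length(beta_grid) > 0 && all(beta_grid >= 1),
              "beta_grid must be nonempty, entries >= 1")
  assert_that(target_r2 > 0 && target_r2 <= 1, "target_r2 must be in (0, 1]")
  absr <- abs(corr$r)
  diag(absr) <- 0
  r2s <- meank <- numeric(length(beta_grid))
  for (i in seq_along(beta_grid)) {
    k <- colSums(absr^beta_grid[i])
    meank[i] <- mean(k)
    r2s[i] <- scale_free_fit(k)
  }
  if (all(is.na(r2s))) {
    warning("degenerate connectivity distribution; using the largest beta",
            call. = FALSE)
    chosen <- max(beta_grid)
  } else if (any(r2s >= target_r2, na.rm = TRUE)) {
    chosen <- beta_grid[min(which(r2s >= target_r2))]
  } else {
    chosen <- beta_grid[which.max(r2s)]
    warning("no beta reached the scale-free target R^2 of ", target_r2,
            "; using the best fit (beta = ", chosen, ")", call. = FALSE)
  }
  log_stage("modules", "soft-threshold scan over ", length(beta_grid),
            " values; chosen beta=", chosen)
  structure(list(beta_grid = beta_grid, scale_free_r2 = r2s,
                 mean_connectivity = meank, chosen_beta = chosen,
                 target_r2 = target_r2),
            class = "soft_threshold_scan")
}

#' Power adjacency a_ij = |S_ij|^beta
#'
#' @param corr A \code{cor_matrix}.
#' @param beta Integer exponent >= 1.
#'
#' @return Object of class \code{adjacency_matrix}; the diagonal is set to
#'   zero by convention and excluded from connectivity.
#' @export
power_adjacency <- function(corr, beta) {
  assert_that(inherits(corr, "cor_matrix"), "corr must be a cor_matrix")
  assert_that(is.numeric(beta) && length(beta) == 1 && beta >= 1,
              "beta must be >= 1")
  a <- abs(corr$r)^beta
  diag(a) <- 0
  structure(list(ids = corr$ids, a = a, beta = beta),
            class = "adjacency_matrix")
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, where k_i = sum_j a_ij is the node connectivity; TOM_ii = 1.
#' Because the adjacency diagonal is zero the matrix product already
#' restricts u to nodes other than i and j.
#'
#' @param adj An \code{adjacency_matrix}.
#'
#' @return Object of class \code{tom_matrix} with the overlap matrix,
#'   connectivities and the dissimilarity 1 - TOM used for clustering.
#' @export
topological_overlap <- function(adj) {
  assert_that(inherits(adj, "adjacency_matrix"), "adj must be an adjacency_matrix")
  a <- adj$a
  k <- colSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  if (any(denom <= 0)) {
    stop("nonpositive TOM denominator; adjacency is not in [0, 1]",
         call. = FALSE)
  }
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  structure(list(ids = adj$ids, tom = tom, connectivity = k),
            class = "tom_matrix")
}

# relabel modules by decreasing size: ME1 is the largest; grey unchanged
#' @noRd
relabel_by_size <- function(assignment) {
  non_grey <- assignment[assignment != "grey"]
  if (length(non_grey) == 0) return(assignment)
  sizes <- sort(table(non_grey), decreasing = TRUE)
  map <- stats::setNames(paste0("ME", seq_along(sizes)), names(sizes))
  out <- assignment
  out[assignment != "grey"] <- map[non_grey]
  out
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut at a fixed height; clusters smaller than \code{min_size} are
#' relegated to the unassigned "grey" module.  Modules are labelled
#' "ME1", "ME2", ... in decreasing size order.
#'
#' @param tom A \code{tom_matrix}.
#' @param min_size Minimum module size (default 30).
#' @param cut_height Dendrogram cut height in (0, 1), default 0.9: under
#'   the power adjacency, unrelated transcripts attach near dissimilarity
#'   1 while co-regulated ones attach well below, so the cut sits above
#'   the in-module regime and below the background attachment regime.
#'
#' @return Object of class \code{module_partition} with the
#'   transcript -> module assignment.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.9) {
  assert_that(inherits(tom, "tom_matrix"), "tom must be a tom_matrix")
  assert_that(is_count(min_size) && min_size >= 2, "min_size must be >= 2")
  assert_that(cut_height > 0 && cut_height < 1, "cut_height must be in (0, 1)")
  dmat <- pmin(pmax(1 - tom$tom, 0), 1)  # clamp rounding spill outside [0, 1]
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  hc$height <- round(hc$height, 10)  # UPGMA is monotone; drop fp jitter
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  assignment <- ifelse(sizes[as.character(cl)] >= min_size,
                       paste0("C", cl), "grey")
  names(assignment) <- tom$ids
  assignment <- relabel_by_size(assignment)
  log_stage("modules", "detected ", length(setdiff(unique(assignment), "grey")),
            " modules (min_size=", min_size, ", cut_height=", cut_height,
            "); grey=", sum(assignment == "grey"))
  structure(list(assignment = assignment, min_size = as.integer(min_size),
                 cut_height = cut_height),
            class = "module_partition")
}

#' Module eigengenes (first principal components)
#'
#' Each module's transcripts are standardized (zero mean, unit variance per
#' transcript) and the first principal component of the standardized
#' profiles is taken as the module eigengene, rescaled to unit variance and
#' sign-oriented so that its correlation with the module's mean
#' standardized profile is nonnegative.  The grey module is excluded.
#'
#' @param expr Samples x transcripts matrix.
#' @param partition A \code{module_partition}.
#'
#' @return Samples x modules numeric matrix of class \code{eigengene_matrix}
#'   with attribute \code{explained_variance} (fraction of standardized
#'   module variance captured by the first component).
#' @export
module_eigengenes <- function(expr, partition) {
  assert_that(inherits(partition, "module_partition"),
              "partition must be a module_partition")
  modules <- setdiff(unique(partition$assignment), "grey")
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", modules)))
  modules <- modules[order(num, modules, na.last = TRUE)]
  assert_that(length(modules) > 0, "no non-grey modules to summarize")
  eig <- matrix(0, nrow(expr), length(modules),
                dimnames = list(rownames(expr), modules))
  expl <- stats::setNames(numeric(length(modules)), modules)
  for (m in modules) {
    members <- names(partition$assignment)[partition$assignment == m]
    z <- standardize_columns(expr[, members, drop = FALSE], "transcript")
    if (length(members) == 1) {
      warning("module ", m, " has a single transcript; eigengene equals ",
              "its standardized profile", call. = FALSE)
      scores <- z[, 1]
      expl[m] <- 1
    } else {
      sv <- svd(z, nu = 1, nv = 0)
      scores <- sv$u[, 1] * sv$d[1]
      expl[m] <- sv$d[1]^2 / sum(sv$d^2)
    }
    scores <- scores / stats::sd(scores)
    avg <- rowMeans(z)
    # mean profile can vanish (e.g. mirror-image members); fall back to the
    # first member so the orientation stays deterministic
    ref <- if (stats::sd(avg) > 0) avg else z[, 1]
    if (stats::cor(scores, ref) < 0) scores <- -scores
    eig[, m] <- scores
  }
  structure(eig, explained_variance = expl, class = c("eigengene_matrix", "matrix"))
}

#' Demote weak module members to grey by module membership
#'
#' Transcripts can attach to a module through chance correlation with its
#' latent signal (topological overlap normalizes by the smaller
#' connectivity, which flatters nodes whose few connections all point into
#' one module).  This step recomputes each module's eigengene and demotes
#' members whose absolute module membership |cor(transcript, eigengene)|
#' falls below \code{min_kme}; modules dropping under \code{min_size}
#' afterwards go entirely to grey.  The default 0.65 sits between the
#' largest chance correlation expected at a few dozen samples (~0.55) and
#' the weakest genuine membership under the generative model (~0.71).
#'
#' @param partition A \code{module_partition}.
#' @param expr Samples x transcripts matrix.
#' @param min_kme Minimum absolute module membership (default 0.65).
#'
#' @return A \code{module_partition} with weak members demoted to grey and
#'   labels reassigned by decreasing size.
#' @export
prune_module_membership <- function(partition, expr, min_kme = 0.65) {
  assert_that(inherits(partition, "module_partition"),
              "partition must be a module_partition")
  assert_that(min_kme >= 0 && min_kme <= 1, "min_kme must be in [0, 1]")
  assignment <- partition$assignment
  modules <- setdiff(unique(assignment), "grey")
  if (length(modules) > 0) {
    eig <- module_eigengenes(expr, partition)
    for (m in modules) {
      members <- names(assignment)[assignment == m]
      kme <- abs(stats::cor(expr[, members, drop = FALSE], unclass(eig)[, m]))
      assignment[members[kme < min_kme]] <- "grey"
    }
    sizes <- table(assignment[assignment != "grey"])
    too_small <- names(sizes)[sizes < partition$min_size]
    assignment[assignment %in% too_small] <- "grey"
  }
  assignment <- relabel_by_size(assignment)
  log_stage("modules", "membership pruning at |kME| >= ", min_kme, ": ",
            sum(assignment == "grey") - sum(partition$assignment == "grey"),
            " transcripts demoted to grey")
  structure(list(assignment = assignment, min_size = partition$min_size,
                 cut_height = partition$cut_height),
            class = "module_partition")
}

#' Merge modules with similar eigengenes
#'
#' Modules are clustered on the dissimilarity 1 - cor(eigengene_i,
#' eigengene_j) (average linkage); groups joined below \code{merge_height}
#' are merged, eigengenes recomputed, and the process repeated until
#' stable.  Labels are reassigned by decreasing size.
#'
#' @param partition A \code{module_partition}.
#' @param expr Samples x transcripts matrix.
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#'
#' @return A \code{module_partition} with merged assignments.
#' @export
merge_modules <- function(partition, expr, merge_height = 0.25) {
  assert_that(inherits(partition, "module_partition"),
              "partition must be a module_partition")
  assert_that(merge_height > 0 && merge_height < 1,
              "merge_height must be in (0, 1)")
  assignment <- partition$assignment
  repeat {
    modules <- setdiff(unique(assignment), "grey")
    if (length(modules) <= 1) break
    part <- structure(list(assignment = assignment,
                           min_size = partition$min_size,
                           cut_height = partition$cut_height),
                      class = "module_partition")
    eig <- module_eigengenes(expr, part)
    d <- stats::as.dist(pmin(pmax(1 - stats::cor(unclass(eig)), 0), 2))
    hc <- stats::hclust(d, method = "average")
    hc$height <- round(hc$height, 10)
    groups <- stats::cutree(hc, h = merge_height)
    if (max(groups) == length(groups)) break
    for (g in unique(groups)) {
      members <- names(groups)[groups == g]
      if (length(members) > 1) {
        assignment[assignment %in% members] <- members[1]
      }
    }
  }
  assignment <- relabel_by_size(assignment)
  log_stage("modules", "after merging at height ", merge_height, ": ",
            length(setdiff(unique(assignment), "grey")), " modules")
  structure(list(assignment = assignment, min_size = partition$min_size,
                 cut_height = partition$cut_height),
            class = "module_partition")
}

#' Gene significance and module membership
#'
#' MM (module membership) is the correlation of each transcript with each
#' module eigengene.  GS (gene significance) for each trait is the signed
#' -log10 p-value of the transcript-trait correlation: the sign carries
#' the direction of the association, the magnitude its strength; p-values
#' are floored at 1e-300 to keep GS finite.
#'
#' @param expr Samples x transcripts matrix.
#' @param eigengenes An \code{eigengene_matrix}.
#' @param traits A \code{trait_table} aligned to the expression samples.
#'
#' @return Object of class \code{gsmm_table}: matrices \code{mm}
#'   (transcripts x modules), \code{gs} (transcripts x traits, signed
#'   -log10 p) and \code{gs_r} (the underlying correlations), plus the
#'   sample count \code{n}.
#' @export
gs_mm <- function(expr, eigengenes, traits) {
  assert_that(identical(rownames(expr), rownames(traits$values)),
              "expression and trait samples must be aligned")
  assert_that(identical(rownames(expr), rownames(unclass(eigengenes))),
              "expression and eigengene samples must be aligned")
  n <- nrow(expr)
  mm <- stats::cor(expr, unclass(eigengenes))
  tvals <- traits$values
  tsd <- apply(tvals, 2, stats::sd)
  gs_r <- matrix(NA_real_, ncol(expr), ncol(tvals),
                 dimnames = list(colnames(expr), colnames(tvals)))
  ok <- tsd > 0
  if (any(!ok)) {
    warning("zero-variance trait(s); GS undefined for: ",
            paste(colnames(tvals)[!ok], collapse = ", "), call. = FALSE)
  }
  gs_r[, ok] <- stats::cor(expr, tvals[, ok, drop = FALSE])
  p <- cor_pvalue(gs_r, n)
  gs <- sign(gs_r) * (-log10(pmax(p, 1e-300)))
  structure(list(mm = mm, gs = gs, gs_r = gs_r, n = n), class = "gsmm_table")
}
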