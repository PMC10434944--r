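# Shared fixtures, built in code.  The heavyweight default synthetic runs
# are computed lazily once and cached for the whole suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full module-detection chain on one dataset
run_module_chain <- function(sim, beta = 5) {
  filt <- filter_transcripts(sim$expression)
  corr <- correlation_matrix(filt$expression)
  tom <- topological_overlap(power_adjacency(corr, beta))
  part <- detect_modules(tom)
  part <- prune_module_membership(part, filt$expression)
  part <- merge_modules(part, filt$expression)
  eig <- module_eigengenes(filt$expression, part)
  list(sim = sim, expression = filt$expression, corr = corr, tom = tom,
       partition = part, eigengenes = eig)
}

default_run <- function() {
  cached("default_run", function() {
    suppressMessages(run_module_chain(
      generate_dataset(synthetic_config(seed = 1))))
  })
}

noise_free_run <- function() {
  cached("noise_free_run", function() {
    suppressMessages(run_module_chain(
      generate_dataset(synthetic_config(seed = 1, transcript_noise_sd = 0))))
  })
}

# adjusted Rand index between a detected partition and planted labels
partition_ari <- function(partition, truth) {
  ids <- names(partition$assignment)
  mclust::adjustedRandIndex(partition$assignment[ids], truth[ids])
}

# brute-force topological overlap: the triple loop straight from the
# definition, independent of the matrix-product implementation
tom_brute_force <- function(a) {
  n <- nrow(a)
  k <- colSums(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      }
      out[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# correlation matrix carrying an (approximately) scale-free power
# adjacency at the generating exponent: a deterministic power-law degree
# sequence realized as a simple graph, strong correlations on its edges
# over a moderate background
scale_free_corr <- function(n = 400, s = 0.9, c = 0.45, gamma = 2.5,
                            seed = 42) {
  set.seed(seed)
  d <- pmin(round(2 * (n / seq_len(n))^(1 / (gamma - 1))), n - 1)
  if (sum(d) %% 2 == 1) d[n] <- d[n] + 1
  g <- igraph::sample_degseq(d, method = "vl")
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  S <- ifelse(adj > 0, s, c)
  diag(S) <- 1
  dimnames(S) <- list(paste0("T", seq_len(n)), paste0("T", seq_len(n)))
  structure(list(ids = rownames(S), r = S,
                 p = matrix(0, n, n, dimnames = dimnames(S)), n = 40),
            class = "cor_matrix")
}

# vector with an exact sample correlation r to a given standardized x
exact_correlation_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- as.vector(scale(stats::rnorm(n)))
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- as.vector(scale(z))
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}

# hand-built layered graph: env -> module -> saponin tree with the given
# edge weights (used for white-box compile/train fixtures)
toy_graph <- function() {
  nodes <- data.frame(
    id = c("E1", "E2", "E3", "M1", "M2", "Rb1", "Re"),
    node_kind = c(rep("environment", 3), rep("module", 2), rep("saponin", 2)),
    layer = c(0L, 0L, 0L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("E1", "E2", "E3", "M1", "M2"),
    target = c("M1", "M1", "M2", "Rb1", "Re"),
    r = c(0.6, 0.8, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE)
  assoc_graph(nodes, edges)
}

# data drawn from the toy graph's own linear standardized model; the
# environment columns are made exactly orthonormal (unit sample variance,
# zero sample correlation) so the generating standardized coefficients
# are the exact edge weights 0.6 / 0.8 / 1.0
toy_graph_data <- function(n = 60, noise_sd = 0.1, seed = 3) {
  set.seed(seed)
  env <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 3), n, 3))))[, -1]
  env <- env * sqrt(n - 1)
  dimnames(env) <- list(paste0("S", seq_len(n)), c("E1", "E2", "E3"))
  m1 <- 0.6 * env[, "E1"] + 0.8 * env[, "E2"]
  m2 <- env[, "E3"]
  sap <- cbind(Rb1 = m1 + stats::rnorm(n, sd = noise_sd),
               Re = m2 + stats::rnorm(n, sd = noise_sd))
  rownames(sap) <- rownames(env)
  list(env = env, saponins = sap)
}

table2_matrix <- function() {
  tab <- utils::read.table(
    system.file("extdata", "rb1_contingency.tsv", package = "panaxnet"),
    sep = "\t", header = TRUE, row.names = 1)
  as.matrix(tab)
}
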