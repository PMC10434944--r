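small_expr <- function(cols) {
  mat <- do.call(cbind, cols)
  rownames(mat) <- paste0("S", seq_len(nrow(mat)))
  mat
}

test_that("correlation matrix reproduces hand-computed coefficients and p-values", {
  expr <- small_expr(list(T1 = c(1, 2, 3, 4), T2 = c(2, 4, 6, 8),
                          T3 = c(4, 3, 2, 1), T4 = c(1, 3, 2, 4)))
  cm <- correlation_matrix(expr)
  expect_equal(cm$r["T1", "T2"], 1)
  expect_equal(cm$r["T1", "T3"], -1)
  expect_equal(cm$r["T1", "T4"], 0.8)  # cov 4 over sd sqrt(5)*sqrt(5) * (3/3)
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  # p-values agree with the t-transform oracle in cor.test
  oracle <- cor.test(expr[, "T1"], expr[, "T4"])$p.value
  expect_equal(cm$p["T1", "T4"], oracle, tolerance = 1e-12)
  expect_error(correlation_matrix(small_expr(list(T1 = c(1, 1, 1),
                                                  T2 = c(1, 2, 3)))),
               "zero-variance")
})

test_that("power adjacency is the exact elementwise |r|^beta with zero diagonal", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0.25, -0.5, 0.25, 1), 3, 3,
              dimnames = list(paste0("T", 1:3), paste0("T", 1:3)))
  cm <- structure(list(ids = rownames(r), r = r, p = r * 0, n = 10),
                  class = "cor_matrix")
  a5 <- power_adjacency(cm, 5)
  expect_equal(a5$a["T1", "T2"], 0.03125)
  expect_equal(a5$a["T1", "T3"], 0.03125)  # sign discarded
  expect_equal(unname(diag(a5$a)), rep(0, 3))
  a1 <- power_adjacency(cm, 1)
  expect_equal(a1$a, abs(r) - diag(3))
  expect_error(power_adjacency(cm, 0.5), ">= 1")
})

test_that("raising beta weakly decreases every off-diagonal adjacency entry", {
  cm <- correlation_matrix(default_run()$expression[, 1:50])
  prev <- power_adjacency(cm, 1)$a
  for (beta in 2:6) {
    cur <- power_adjacency(cm, beta)$a
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
})

test_that("topological overlap matches its closed forms", {
  # two isolated nodes: TOM = a / (a + 1 - a) = a
  for (a_val in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(0, a_val, a_val, 0), 2, 2,
                dimnames = list(c("T1", "T2"), c("T1", "T2")))
    adj <- structure(list(ids = rownames(a), a = a, beta = 5),
                     class = "adjacency_matrix")
    tom <- topological_overlap(adj)
    expect_equal(tom$tom["T1", "T2"], a_val, tolerance = 1e-12)
  }
  # complete graph with uniform adjacency: ((n-2)a^2 + a)/((n-1)a + 1 - a) = a
  for (n in 2:10) {
    a <- matrix(0.4, n, n, dimnames = list(paste0("T", 1:n), paste0("T", 1:n)))
    diag(a) <- 0
    adj <- structure(list(ids = rownames(a), a = a, beta = 5),
                     class = "adjacency_matrix")
    tom <- topological_overlap(adj)
    off <- tom$tom[upper.tri(tom$tom)]
    expect_equal(off, rep(0.4, length(off)), tolerance = 1e-12)
  }
  # disconnected pair with no shared neighbours
  a <- matrix(0, 4, 4, dimnames = list(paste0("T", 1:4), paste0("T", 1:4)))
  a["T1", "T2"] <- a["T2", "T1"] <- 0.7
  a["T3", "T4"] <- a["T4", "T3"] <- 0.7
  adj <- structure(list(ids = rownames(a), a = a, beta = 5),
                   class = "adjacency_matrix")
  expect_equal(topological_overlap(adj)$tom["T1", "T3"], 0)
})

test_that("topological overlap equals the brute-force triple loop on random adjacencies", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 20
    a <- matrix(runif(n * n, 0, 0.9), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(paste0("T", 1:n), paste0("T", 1:n))
    adj <- structure(list(ids = rownames(a), a = a, beta = 5),
                     class = "adjacency_matrix")
    fast <- topological_overlap(adj)$tom
    slow <- tom_brute_force(a)
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
})

test_that("the soft-threshold scan picks the generating exponent on a scale-free fixture", {
  corr <- scale_free_corr()
  scan <- pick_soft_threshold(corr, 1:10, target_r2 = 0.9)
  expect_identical(scan$chosen_beta, 6L)
  expect_lt(scan$scale_free_r2[5], 0.9)
  expect_gte(scan$scale_free_r2[6], 0.9)
  # a one-point grid is returned as-is
  one <- suppressWarnings(pick_soft_threshold(corr, 4L, target_r2 = 0.9))
  expect_identical(one$chosen_beta, 4L)
})

test_that("a degenerate connectivity distribution falls back with a warning", {
  r <- matrix(0.5, 4, 4, dimnames = list(paste0("T", 1:4), paste0("T", 1:4)))
  diag(r) <- 1
  cm <- structure(list(ids = rownames(r), r = r, p = r * 0, n = 10),
                  class = "cor_matrix")
  expect_warning(scan <- pick_soft_threshold(cm, 1:4), "degenerate")
  expect_identical(scan$chosen_beta, 4L)
})

test_that("noise-free planted modules are recovered exactly; small groups go grey", {
  cfg <- synthetic_config(seed = 8, n_samples = 30, n_transcripts = 510,
                          module_sizes = c(rep(100L, 5), 10L),
                          transcript_noise_sd = 0)
  sim <- suppressMessages(generate_dataset(cfg))
  run <- suppressMessages(run_module_chain(sim))
  truth <- sim$ground_truth$module_assignment
  detected <- setdiff(unique(run$partition$assignment), "grey")
  expect_length(detected, 5)
  # the size-10 planted group cannot reach min_size and lands in grey
  small <- names(truth)[truth == "M6"]
  expect_identical(unname(run$partition$assignment[small]), rep("grey", 10))
  big <- names(truth)[truth %in% paste0("M", 1:5)]
  expect_equal(mclust::adjustedRandIndex(run$partition$assignment[big],
                                         truth[big]), 1)
})

test_that("eigengenes summarize their module and orient deterministically", {
  set.seed(12)
  z <- as.vector(scale(rnorm(20)))
  # module of identical profiles: eigengene is that standardized profile
  expr <- small_expr(list(T1 = 3 * z + 5, T2 = 3 * z + 5, T3 = 3 * z + 5))
  part <- structure(list(assignment = c(T1 = "ME1", T2 = "ME1", T3 = "ME1"),
                         min_size = 2L, cut_height = 0.9),
                    class = "module_partition")
  eig <- module_eigengenes(expr, part)
  expect_equal(unname(unclass(eig)[, "ME1"]), z, tolerance = 1e-10)
  expect_equal(unname(attr(eig, "explained_variance")["ME1"]), 1)
  # mirror-image module: first PC carries all variance, orientation fixed
  expr2 <- small_expr(list(T1 = z, T2 = -z))
  part2 <- structure(list(assignment = c(T1 = "ME1", T2 = "ME1"),
                          min_size = 2L, cut_height = 0.9),
                     class = "module_partition")
  eig2 <- module_eigengenes(expr2, part2)
  expect_equal(unname(attr(eig2, "explained_variance")["ME1"]), 1)
  expect_equal(unname(unclass(eig2)[, "ME1"]), z, tolerance = 1e-10)
})

test_that("noise-free eigengenes recover the latent signal; explained variance is optimal", {
  run <- noise_free_run()
  truth <- run$sim$ground_truth
  map <- match_modules(run$partition, truth$module_assignment)
  for (m in colnames(unclass(run$eigengenes))) {
    expect_equal(abs(cor(unclass(run$eigengenes)[, m],
                         truth$latent_module_signals[, map[m]])), 1,
                 tolerance = 1e-9)
  }
  # first-PC optimality: the eigengene explains at least an equal share
  expl <- attr(run$eigengenes, "explained_variance")
  sizes <- table(run$partition$assignment)
  for (m in names(expl)) {
    expect_gte(expl[[m]], 1 / sizes[[m]])
  }
})

test_that("modules from a duplicated driver merge; orthogonal modules never do", {
  e2m <- matrix(0, 13, 2, dimnames = list(default_env_factors(), c("M1", "M2")))
  e2m[1, 1] <- 1
  e2m[1, 2] <- 1  # same latent driver twice
  m2s <- matrix(1.2, 2, 9, dimnames = list(c("M1", "M2"),
                                           head(default_saponins(), 9)))
  cfg <- synthetic_config(seed = 13, n_transcripts = 120,
                          module_sizes = c(50L, 50L),
                          env_to_module_coefficients = e2m,
                          module_to_saponin_coefficients = m2s,
                          transcript_noise_sd = 0.3)
  sim <- suppressMessages(generate_dataset(cfg))
  part <- structure(list(assignment = ifelse(
    sim$ground_truth$module_assignment == "background", "grey",
    sim$ground_truth$module_assignment),
    min_size = 30L, cut_height = 0.9), class = "module_partition")
  merged <- suppressMessages(merge_modules(part, sim$expression))
  expect_length(setdiff(unique(merged$assignment), "grey"), 1)

  run <- default_run()  # independent drivers: eigengene dissimilarity ~ 1
  n_before <- length(setdiff(unique(run$partition$assignment), "grey"))
  expect_identical(n_before, 8L)
})

test_that("membership pruning demotes chance hangers-on but keeps true members", {
  run <- noise_free_run()
  truth <- run$sim$ground_truth$module_assignment
  map <- match_modules(run$partition, truth)
  for (m in names(map)) {
    members <- names(run$partition$assignment)[run$partition$assignment == m]
    expect_true(all(truth[members] == map[m]))
  }
})

test_that("GS and MM carry the documented conventions", {
  run <- default_run()
  sim <- run$sim
  gsmm <- gs_mm(run$expression, run$eigengenes,
                align_samples(run$expression, sim$traits))
  # a transcript is perfectly membered in the module it equals
  m <- colnames(unclass(run$eigengenes))[1]
  expr2 <- cbind(run$expression[, 1:5], PROBE = unclass(run$eigengenes)[, m])
  gsmm2 <- gs_mm(expr2, run$eigengenes, align_samples(expr2, sim$traits))
  expect_equal(gsmm2$mm["PROBE", m], 1, tolerance = 1e-12)
  # uncorrelated transcript-trait pair: r = 0 gives GS = 0
  expect_true(all(abs(gsmm$mm) <= 1 + 1e-12))
  expect_true(all(is.finite(gsmm$gs)))
  # GS magnitude is the -log10 p of the underlying correlation
  idx <- which.max(abs(gsmm$gs[, "Rb1"]))
  oracle <- cor.test(run$expression[, idx],
                     saponin_values(sim$traits)[, "Rb1"])$p.value
  expect_equal(abs(gsmm$gs[idx, "Rb1"]), -log10(oracle), tolerance = 1e-9)
  expect_equal(sign(gsmm$gs[idx, "Rb1"]), sign(gsmm$gs_r[idx, "Rb1"]))
})

test_that("a zero-variance trait yields an undefined GS column with a warning", {
  run <- default_run()
  traits <- align_samples(run$expression, run$sim$traits)
  traits$values[, "soil_type"] <- 1
  expect_warning(gsmm <- gs_mm(run$expression, run$eigengenes, traits),
                 "soil_type")
  expect_true(all(is.na(gsmm$gs[, "soil_type"])))
})
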