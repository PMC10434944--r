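test_that("compilation counts units, weights and biases from the graph", {
  g <- toy_graph()
  net <- compile_network(g)
  expect_length(net$node_order, 7)
  expect_identical(nrow(net$edges), 5L)
  expect_length(net$biases, 4)  # modules + saponins
  expect_equal(net$edges$weight,
               g$edges$r[match(paste(net$edges$source, net$edges$target),
                               paste(g$edges$source, g$edges$target))])
  expect_error(compile_network(assoc_graph(
    data.frame(id = character(0), node_kind = character(0), layer = integer(0)),
    data.frame(source = character(0), target = character(0), r = numeric(0)))),
    "empty")
})

test_that("an unreachable saponin node is a compilation error naming it", {
  nodes <- data.frame(id = c("E1", "M1", "Rb1", "Rg1"),
                      node_kind = c("environment", "module", "saponin",
                                    "saponin"),
                      layer = c(0L, 1L, 2L, 2L))
  edges <- data.frame(source = c("E1", "M1"), target = c("M1", "Rb1"),
                      r = c(0.8, 0.9))
  expect_error(compile_network(assoc_graph(nodes, edges)), "Rg1")
})

test_that("training is deterministic, masked and loss-decreasing", {
  dat <- toy_graph_data()
  net <- compile_network(toy_graph())
  fit1 <- suppressMessages(train_network(net, dat$env, dat$saponins,
                                         epochs = 200, seed = 5))
  fit2 <- suppressMessages(train_network(net, dat$env, dat$saponins,
                                         epochs = 200, seed = 5))
  expect_identical(fit1$network$edges$weight, fit2$network$edges$weight)
  expect_identical(fit1$loss, fit2$loss)
  # the mask never grows: trained connections = graph edges exactly
  expect_identical(paste(fit1$network$edges$source, fit1$network$edges$target),
                   paste(net$edges$source, net$edges$target))
  expect_lte(fit1$loss[length(fit1$loss)], fit1$loss[1])
  expect_error(train_network(net, dat$env, dat$saponins, epochs = 0),
               "positive count")
})

test_that("loss is non-increasing at a small learning rate", {
  dat <- toy_graph_data()
  net <- compile_network(toy_graph())
  fit <- suppressMessages(train_network(net, dat$env, dat$saponins,
                                        learning_rate = 1e-3, epochs = 300,
                                        seed = 1))
  expect_true(all(diff(fit$loss) <= 1e-12))
})

test_that("a linear network fits held-out graph-consistent data", {
  dat <- toy_graph_data(n = 60, noise_sd = 0.1, seed = 3)
  train_idx <- 1:42
  test_idx <- 43:60
  net <- compile_network(toy_graph())
  fit <- suppressMessages(train_network(
    net, dat$env[train_idx, ], dat$saponins[train_idx, ],
    learning_rate = 0.01, epochs = 2000, seed = 2))
  pred <- predict(fit$network, dat$env[test_idx, ])
  ref <- dat$saponins[test_idx, colnames(pred), drop = FALSE]
  ev <- evaluate_predictions(pred, ref)
  expect_gte(ev$r2, 0.9)
})

test_that("standardized weights are recovered on noise-free data", {
  dat <- toy_graph_data(n = 60, noise_sd = 0, seed = 4)
  net <- compile_network(toy_graph())
  fit <- suppressMessages(train_network(net, dat$env, dat$saponins,
                                        learning_rate = 0.05, epochs = 3000,
                                        seed = 6))
  got <- setNames(fit$network$edges$weight,
                  paste(fit$network$edges$source, fit$network$edges$target))
  truth <- c("E1 M1" = 0.6, "E2 M1" = 0.8, "E3 M2" = 1,
             "M1 Rb1" = 1, "M2 Re" = 1)
  expect_lt(max(abs(got[names(truth)] - truth)), 0.05)
})

test_that("prediction reproduces the training forward pass and respects input checks", {
  dat <- toy_graph_data()
  net <- compile_network(toy_graph())
  fit <- suppressMessages(train_network(net, dat$env, dat$saponins,
                                        epochs = 100, seed = 1))
  pred1 <- predict(fit$network, dat$env)
  pred2 <- predict(fit$network, dat$env)
  expect_identical(pred1, pred2)
  # row-wise operation: sample order does not matter
  perm <- c(10:1, 11:60)
  expect_equal(predict(fit$network, dat$env[perm, ]), pred1[perm, ],
               tolerance = 1e-12)
  expect_error(predict(fit$network, dat$env[, c("E1", "E2")]), "E3")
  expect_error(predict(net, dat$env), "trained")
})

test_that("a linear network with zero biases is homogeneous in standardized space", {
  net <- compile_network(toy_graph())
  net$input_scaler <- list(mean = setNames(rep(0, 3), c("E1", "E2", "E3")),
                           sd = setNames(rep(1, 3), c("E1", "E2", "E3")))
  net$output_scaler <- list(mean = setNames(rep(0, 2), c("Rb1", "Re")),
                            sd = setNames(rep(1, 2), c("Rb1", "Re")))
  x <- matrix(rnorm(30), 10, 3,
              dimnames = list(paste0("S", 1:10), c("E1", "E2", "E3")))
  expect_equal(predict(net, 3 * x), 3 * predict(net, x), tolerance = 1e-12)
  expect_equal(unname(predict(net, x * 0)), matrix(0, 10, 2),
               tolerance = 1e-12)
})

test_that("evaluation reproduces its closed-form example", {
  pred <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("S", 1:3), "Rb1"))
  ref <- matrix(c(1, 2, 4), 3, 1, dimnames = list(paste0("S", 1:3), "Rb1"))
  ev <- evaluate_predictions(pred, ref)
  expect_equal(ev$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ev$cv, sqrt(1 / 3) / (7 / 3), tolerance = 1e-12)
  expect_equal(ev$r2, 1 - 1 / (42 / 9), tolerance = 1e-12)
  perfect <- evaluate_predictions(ref, ref)
  expect_identical(perfect$rmse, 0)
  expect_identical(perfect$r2, 1)
  zero_ref <- matrix(c(-1, 0, 1), 3, 1,
                     dimnames = list(paste0("S", 1:3), "Rb1"))
  expect_warning(ev0 <- evaluate_predictions(pred, zero_ref), "CV undefined")
  expect_true(is.na(ev0$cv))
})

test_that("edge perturbation scales one path and leaves the rest untouched", {
  dat <- toy_graph_data(noise_sd = 0)
  net <- compile_network(toy_graph())
  fit <- suppressMessages(train_network(net, dat$env, dat$saponins,
                                        epochs = 500, seed = 1))
  # shift inputs so baseline means are away from zero
  env_shift <- dat$env + 1
  rep1 <- perturb_edge(fit$network, c("M1", "Rb1"), scale = 1, env_shift)
  expect_equal(rep1$percent_change, 0, tolerance = 1e-9)
  rep2 <- perturb_edge(fit$network, c("M1", "Rb1"), scale = 2, env_shift)
  base_rb1 <- mean(predict(fit$network, env_shift)[, "Rb1"])
  expect_equal(rep2$baseline, base_rb1, tolerance = 1e-12)
  # positive path, positive mean module activity: upscaling raises Rb1
  expect_gt(rep2$percent_change, 0)
  # Re has no path through the perturbed edge
  re_row <- rep2$per_saponin[rep2$per_saponin$saponin == "Re", ]
  expect_equal(re_row$percent_change, 0, tolerance = 1e-12)
  # the original network is untouched
  w_before <- fit$network$edges$weight
  invisible(perturb_edge(fit$network, c("M1", "Rb1"), 3, env_shift))
  expect_identical(fit$network$edges$weight, w_before)
  expect_error(perturb_edge(fit$network, c("E1", "Rb1"), 2, env_shift),
               "mask")
  expect_error(perturb_edge(fit$network, c("M1", "Rb1"), 0, env_shift),
               "> 0")
})

test_that("percent change matches its closed form and rejects a zero baseline", {
  expect_equal(signif(percent_change(0.02407, 0.02498), 3), 3.78)
  expect_equal(signif(percent_change(0.02407, 0.02707), 3), 12.5)
  expect_identical(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero baseline")
})
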