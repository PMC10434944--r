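#' Compile a directed association graph into a white-box network
#'
#' One network unit per graph node; connections exist exactly where the
#' graph has edges (the connectivity mask), so the model stays readable as
#' the biological graph it came from.  Edge weights are initialized to the
#' graph's signed correlations, biases to zero.  The activation applies to
#' module (hidden) units; environment units are inputs and saponin units
#' are linear outputs.  Input and output scalers are fitted at training
#' time.
#'
#' @param graph A nonempty \code{assoc_graph} in which every saponin node
#'   is reachable from at least one environment node.
#' @param activation "linear" (default) or "tanh".
#'
#' @return Object of class \code{whitebox_network}.
#' @export
compile_network <- function(graph, activation = c("linear", "tanh")) {
  activation <- match.arg(activation)
  validate_graph(graph)
  assert_that(nrow(graph$nodes) > 0 && nrow(graph$edges) > 0,
              "cannot compile an empty graph")
  g <- graph_to_igraph(graph)
  kind <- stats::setNames(graph$nodes$node_kind, graph$nodes$id)
  env_ids <- graph$nodes$id[kind == "environment"]
  sap_ids <- graph$nodes$id[kind == "saponin"]
  reach <- igraph::distances(g, v = env_ids, to = sap_ids, mode = "out",
                             weights = NA)
  unreachable <- sap_ids[apply(reach, 2, function(d) all(!is.finite(d)))]
  if (length(unreachable) > 0) {
    stop("saponin node(s) unreachable from any environment node: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  topo <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]
  non_input <- setdiff(topo, env_ids)
  structure(list(
    node_order = topo,
    node_kind = kind[topo],
    edges = data.frame(source = graph$edges$source,
                       target = graph$edges$target,
                       weight = graph$edges$r, stringsAsFactors = FALSE),
    biases = stats::setNames(numeric(length(non_input)), non_input),
    activation = activation,
    input_nodes = env_ids,
    output_nodes = sap_ids,
    input_scaler = NULL,
    output_scaler = NULL), class = "whitebox_network")
}

#' @noRd
wb_activate <- function(z, activation) {
  if (activation == "tanh") tanh(z) else z
}

#' @noRd
wb_activate_grad <- function(val, activation) {
  if (activation == "tanh") 1 - val^2 else 1
}

# forward pass in standardized space; returns samples x nodes value matrix
#' @noRd
wb_forward <- function(network, x_std) {
  vals <- matrix(0, nrow(x_std), length(network$node_order),
                 dimnames = list(rownames(x_std), network$node_order))
  vals[, network$input_nodes] <- x_std[, network$input_nodes]
  for (node in setdiff(network$node_order, network$input_nodes)) {
    inc <- network$edges[network$edges$target == node, , drop = FALSE]
    z <- network$biases[node] +
      vals[, inc$source, drop = FALSE] %*% inc$weight
    vals[, node] <- if (network$node_kind[node] == "module") {
      wb_activate(z, network$activation)
    } else {
      z
    }
  }
  vals
}

#' @noRd
fit_scaler <- function(x) {
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
}

#' @noRd
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean[colnames(x)], "-"), 2,
        scaler$sd[colnames(x)], "/")
}

#' @noRd
invert_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$sd[colnames(x)], "*"), 2,
        scaler$mean[colnames(x)], "+")
}

#' Train a white-box network by masked gradient descent
#'
#' Inputs and outputs are standardized by scalers fitted on the training
#' data; full-batch gradient descent minimizes the mean squared error over
#' all output cells, with gradients restricted to the masked weights and
#' the biases.  Initialization adds seed-controlled uniform jitter of
#' +/- 0.01 around the correlation-based edge weights.
#'
#' @param network A \code{whitebox_network}.
#' @param env_data Samples x environment matrix (training inputs).
#' @param saponin_data Samples x saponin matrix (training targets).
#' @param learning_rate Step size, default 0.01.
#' @param epochs Number of full-batch epochs, >= 1 (default 2000).
#' @param seed Integer seed for the initialization jitter.
#'
#' @return Object of class \code{training_result}: the trained network
#'   (with fitted scalers), the per-epoch MSE trajectory, the
#'   hyperparameters and a convergence flag.
#' @export
train_network <- function(network, env_data, saponin_data,
                          learning_rate = 0.01, epochs = 2000, seed = 1L) {
  assert_that(inherits(network, "whitebox_network"), "not a whitebox_network")
  assert_that(is_count(epochs), "epochs must be a positive count")
  assert_that(identical(rownames(env_data), rownames(saponin_data)),
              "input and target samples must be aligned")
  assert_that(all(network$input_nodes %in% colnames(env_data)),
              "env_data lacks required environment columns")
  assert_that(all(network$output_nodes %in% colnames(saponin_data)),
              "saponin_data lacks required saponin columns")
  set.seed(seed)
  net <- network
  net$input_scaler <- fit_scaler(env_data[, net$input_nodes, drop = FALSE])
  net$output_scaler <- fit_scaler(saponin_data[, net$output_nodes, drop = FALSE])
  x <- apply_scaler(env_data[, net$input_nodes, drop = FALSE], net$input_scaler)
  y <- apply_scaler(saponin_data[, net$output_nodes, drop = FALSE],
                    net$output_scaler)
  net$edges$weight <- net$edges$weight +
    stats::runif(nrow(net$edges), -0.01, 0.01)

  n <- nrow(x)
  n_out <- length(net$output_nodes)
  losses <- numeric(epochs)
  non_input <- setdiff(net$node_order, net$input_nodes)
  for (epoch in seq_len(epochs)) {
    vals <- wb_forward(net, x)
    pred <- vals[, net$output_nodes, drop = FALSE]
    resid <- pred - y
    losses[epoch] <- mean(resid^2)
    if (!is.finite(losses[epoch])) {
      stop("training diverged (non-finite loss); lower the learning rate",
           call. = FALSE)
    }
    # backpropagate deltas in reverse topological order
    delta <- matrix(0, n, length(net$node_order),
                    dimnames = list(NULL, net$node_order))
    delta[, net$output_nodes] <- 2 * resid / (n * n_out)
    for (node in rev(net$node_order)) {
      if (net$node_kind[node] == "module") {
        out <- net$edges[net$edges$source == node, , drop = FALSE]
        upstream_err <- delta[, out$target, drop = FALSE] %*% out$weight
        delta[, node] <- upstream_err *
          wb_activate_grad(vals[, node], net$activation)
      }
    }
    gw <- colSums(vals[, net$edges$source, drop = FALSE] *
                    delta[, net$edges$target, drop = FALSE])
    gb <- colSums(delta[, non_input, drop = FALSE])
    net$edges$weight <- net$edges$weight - learning_rate * gw
    net$biases[non_input] <- net$biases[non_input] - learning_rate * gb
  }
  converged <- epochs < 2 ||
    abs(losses[epochs] - losses[epochs - 1]) < 1e-8 * max(1, losses[1])
  log_stage("train", "epochs=", epochs, " lr=", learning_rate,
            " initial MSE=", signif(losses[1], 4),
            " final MSE=", signif(losses[epochs], 4))
  structure(list(network = net, loss = losses,
                 hyperparameters = list(learning_rate = learning_rate,
                                        epochs = epochs, seed = seed),
                 converged = converged), class = "training_result")
}

#' Predict saponin contents from environmental factors
#'
#' Forward pass through the network topology; inputs are standardized with
#' the training scalers and outputs de-standardized to native units.
#'
#' @param object A trained \code{whitebox_network}.
#' @param env_data Samples x environment matrix containing every
#'   compile-time environment node.
#' @param ... Unused.
#'
#' @return Samples x saponin matrix of predictions.
#' @export
predict.whitebox_network <- function(object, env_data, ...) {
  assert_that(!is.null(object$input_scaler),
              "network has not been trained (no fitted scalers)")
  missing_cols <- setdiff(object$input_nodes, colnames(env_data))
  if (length(missing_cols) > 0) {
    stop("missing environment column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- apply_scaler(env_data[, object$input_nodes, drop = FALSE],
                    object$input_scaler)
  vals <- wb_forward(object, x)
  invert_scaler(vals[, object$output_nodes, drop = FALSE],
                object$output_scaler)
}

#' Evaluate predictions against reference values
#'
#' RMSE over all cells, coefficient of variation CV = RMSE / mean of the
#' reference values, and goodness of fit R^2 = 1 - SS_res / SS_tot with
#' SS_tot about the reference grand mean; residuals and a per-saponin
#' breakdown are included.
#'
#' @param predicted Samples x saponin matrix.
#' @param reference Matrix of the same shape, aligned samples.
#'
#' @return Object of class \code{evaluation_report}.
#' @export
evaluate_predictions <- function(predicted, reference) {
  assert_that(identical(dim(predicted), dim(reference)),
              "predicted and reference must have the same shape")
  assert_that(identical(rownames(predicted), rownames(reference)),
              "samples must be aligned")
  resid <- predicted - reference
  rmse <- sqrt(mean(resid^2))
  ref_mean <- mean(reference)
  cv <- if (ref_mean == 0) {
    warning("reference mean is zero; CV undefined", call. = FALSE)
    NA_real_
  } else {
    rmse / ref_mean
  }
  ss_res <- sum(resid^2)
  ss_tot <- sum((reference - ref_mean)^2)
  r2 <- 1 - ss_res / ss_tot
  per_sap <- data.frame(
    saponin = colnames(reference),
    rmse = sqrt(colMeans(resid^2)),
    mean_reference = colMeans(reference),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(rmse = rmse, cv = cv, r2 = r2,
                 residuals = resid, residual_mean = mean(resid),
                 per_saponin = per_sap), class = "evaluation_report")
}

#' Perturb one edge weight and measure the prediction response
#'
#' Multiplies a single masked weight by \code{scale}, recomputes the
#' predictions on \code{env_data} and reports the percent change of the
#' mean predicted value of the targeted saponin; the original network is
#' left unmodified.  When the perturbed edge ends on a module, the target
#' saponin must be named explicitly.
#'
#' @param network A trained \code{whitebox_network}.
#' @param edge Length-2 character vector (source, target); must be a
#'   masked connection.
#' @param scale Positive multiplier on the edge weight.
#' @param env_data Samples x environment matrix.
#' @param target_saponin Saponin whose mean prediction is tracked;
#'   defaults to the edge target when that is a saponin node.
#'
#' @return Object of class \code{perturbation_report} with the baseline
#'   and perturbed mean predictions, the percent change for the target
#'   saponin and the per-saponin breakdown.
#' @export
perturb_edge <- function(network, edge, scale, env_data,
                         target_saponin = NULL) {
  assert_that(is.numeric(scale) && length(scale) == 1 && scale > 0,
              "scale must be > 0")
  assert_that(length(edge) == 2, "edge must be c(source, target)")
  hit <- which(network$edges$source == edge[1] &
                 network$edges$target == edge[2])
  if (length(hit) != 1) {
    stop("edge ", edge[1], " -> ", edge[2], " is not in the network mask",
         call. = FALSE)
  }
  if (is.null(target_saponin)) {
    assert_that(edge[2] %in% network$output_nodes,
                "name target_saponin when the edge does not end on a saponin")
    target_saponin <- edge[2]
  }
  assert_that(target_saponin %in% network$output_nodes,
              "unknown target saponin")
  baseline <- predict(network, env_data)
  perturbed_net <- network
  perturbed_net$edges$weight[hit] <- perturbed_net$edges$weight[hit] * scale
  perturbed <- predict(perturbed_net, env_data)
  base_means <- colMeans(baseline)
  pert_means <- colMeans(perturbed)
  pc <- unname(percent_change(base_means[target_saponin],
                              pert_means[target_saponin]))
  per_sap <- data.frame(
    saponin = names(base_means),
    baseline_mean = unname(base_means),
    perturbed_mean = unname(pert_means),
    percent_change = unname(ifelse(
      base_means == 0, NA_real_,
      (pert_means - base_means) / base_means * 100)),
    stringsAsFactors = FALSE)
  structure(list(edge = edge, scale = scale,
                 target_saponin = target_saponin,
                 baseline = unname(base_means[target_saponin]),
                 perturbed = unname(pert_means[target_saponin]),
                 percent_change = pc,
                 per_saponin = per_sap), class = "perturbation_report")
}

#' Percent change of a perturbed value relative to a baseline
#'
#' (perturbed - baseline) / baseline * 100; reports quote it at 3
#' significant figures.
#'
#' @param baseline Nonzero reference value.
#' @param perturbed New value.
#'
#' @return Percent change (full precision).
#' @export
percent_change <- function(baseline, perturbed) {
  assert_that(is.numeric(baseline) && is.numeric(perturbed),
              "baseline and perturbed must be numeric")
  if (any(baseline == 0)) {
    stop("percent change undefined for a zero baseline", call. = FALSE)
  }
  (perturbed - baseline) / baseline * 100
}
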