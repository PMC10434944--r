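#' Default pipeline configuration
#'
#' Every threshold of the analysis chain as a config key: the soft
#' threshold grid and scale-free target (0.9), the module cut height,
#' minimum module size (30), eigengene merge height (0.25), the edge
#' criteria (|r| > 0.4, cumulative variance 0.8), the significance level
#' (0.05), the sample-outlier cut height and the training
#' hyperparameters.  Values can be overridden individually via
#' \code{overrides} or a YAML file.
#'
#' @param overrides Named list (or YAML file path) of keys to replace.
#'
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    beta = 5L,
    beta_grid = 1:20,
    scale_free_target_r2 = 0.9,
    module_cut_height = 0.9,
    min_module_size = 30L,
    min_kme = 0.65,
    merge_height = 0.25,
    r_threshold = 0.4,
    variance_threshold = 0.8,
    max_module_layers = 2L,
    alpha = 0.05,
    combine = "or",
    max_missing_fraction = 0,
    min_variance = 0,
    outlier_cut_height = 43000,
    learning_rate = 0.01,
    epochs = 2000L,
    activation = "linear",
    perturb_scale = 2,
    target_saponin = "Rb1",
    max_path = 3L)
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  for (key in names(overrides)) cfg[[key]] <- overrides[[key]]
  cfg
}

#' @noRd
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Serialize a white-box network (topology, weights, scalers) as JSON
#' @param network A \code{whitebox_network}.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path) {
  scaler_payload <- function(s) {
    if (is.null(s)) NULL else list(mean = as.list(s$mean), sd = as.list(s$sd))
  }
  payload <- list(
    node_order = network$node_order,
    node_kind = as.list(network$node_kind),
    edges = network$edges,
    biases = as.list(network$biases),
    activation = network$activation,
    input_nodes = network$input_nodes,
    output_nodes = network$output_nodes,
    input_scaler = scaler_payload(network$input_scaler),
    output_scaler = scaler_payload(network$output_scaler))
  write_json_report(payload, path)
}

#' Load a white-box network serialized by \code{\link{write_network}}
#' @param path JSON path.
#' @return A \code{whitebox_network}.
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unscale <- function(s) {
    if (is.null(s)) return(NULL)
    list(mean = unlist(s$mean), sd = unlist(s$sd))
  }
  structure(list(
    node_order = raw$node_order,
    node_kind = unlist(raw$node_kind),
    edges = as.data.frame(raw$edges, stringsAsFactors = FALSE),
    biases = unlist(raw$biases) %||% stats::setNames(numeric(0), character(0)),
    activation = raw$activation,
    input_nodes = raw$input_nodes,
    output_nodes = raw$output_nodes,
    input_scaler = unscale(raw$input_scaler),
    output_scaler = unscale(raw$output_scaler)), class = "whitebox_network")
}

#' Run the full analysis chain on one dataset
#'
#' Executes simulate (optional), filter, outlier detection, module
#' detection with merging, the layered directed graph, white-box network
#' training and evaluation, the positive and negative validity tests and
#' one edge perturbation, writing every intermediate artifact into
#' \code{out_dir} so stages can be replayed from files.
#'
#' @param config List from \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if needed).
#' @param expression Optional samples x transcripts matrix; simulated from
#'   \code{config$seed} when omitted.
#' @param traits Optional \code{trait_table}; simulated when omitted.
#' @param known_ids Optional transcript IDs for the positive test; when
#'   simulating, defaults to members of the module that drives the target
#'   saponin.
#'
#' @return Invisible list with every stage's result objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("panaxnet"),
                         expression = NULL, traits = NULL, known_ids = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ground_truth <- NULL
  if (is.null(expression) || is.null(traits)) {
    sim <- generate_dataset(synthetic_config(seed = config$seed))
    expression <- sim$expression
    traits <- sim$traits
    ground_truth <- sim$ground_truth
    write_expression(expression, file.path(out_dir, "expression.tsv"))
    write_traits(traits, file.path(out_dir, "traits.tsv"))
    write_json_report(list(
      module_assignment = as.list(sim$ground_truth$module_assignment),
      true_env_module_edges = sim$ground_truth$true_env_module_edges,
      true_module_saponin_edges = sim$ground_truth$true_module_saponin_edges),
      file.path(out_dir, "ground_truth.json"))
  }
  traits <- align_samples(expression, traits)

  filt <- filter_transcripts(expression, config$max_missing_fraction,
                             config$min_variance)
  outliers <- detect_outlier_samples(filt$expression,
                                     cut_height = config$outlier_cut_height)
  keep <- setdiff(rownames(filt$expression), outliers$flagged_samples)
  expr <- filt$expression[keep, , drop = FALSE]
  traits$values <- traits$values[keep, , drop = FALSE]
  write_json_report(list(filter = unclass(filt$report),
                         outliers = unclass(outliers)),
                    file.path(out_dir, "preprocess_report.json"))

  corr <- correlation_matrix(expr)
  scan <- suppressWarnings(
    pick_soft_threshold(corr, config$beta_grid, config$scale_free_target_r2))
  # beta = NULL defers to the scan; the fixed default keeps runs comparable
  beta <- config$beta %||% scan$chosen_beta
  adj <- power_adjacency(corr, beta)
  tom <- topological_overlap(adj)
  partition <- detect_modules(tom, config$min_module_size,
                              config$module_cut_height)
  partition <- prune_module_membership(partition, expr, config$min_kme)
  partition <- merge_modules(partition, expr, config$merge_height)
  eig <- module_eigengenes(expr, partition)
  gsmm <- gs_mm(expr, eig, traits)
  utils::write.table(
    data.frame(transcript = names(partition$assignment),
               module = unname(partition$assignment)),
    file.path(out_dir, "module_partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_numeric_tsv(unclass(eig), file.path(out_dir, "eigengenes.tsv"))
  write_numeric_tsv(gsmm$mm, file.path(out_dir, "module_membership.tsv"))
  write_numeric_tsv(gsmm$gs, file.path(out_dir, "gene_significance.tsv"))
  utils::write.table(
    data.frame(beta = scan$beta_grid, scale_free_r2 = scan$scale_free_r2,
               mean_connectivity = scan$mean_connectivity),
    file.path(out_dir, "soft_threshold_scan.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  graph <- build_directed_graph(env_values(traits), eig, saponin_values(traits),
                                r_threshold = config$r_threshold,
                                variance_threshold = config$variance_threshold,
                                max_module_layers = config$max_module_layers,
                                alpha = config$alpha, combine = config$combine)
  export_graph(graph, file.path(out_dir, "graph.graphml"), "graphml")
  export_graph(graph, file.path(out_dir, "graph_edges.tsv"), "edge_tsv")

  network <- compile_network(graph, activation = config$activation)
  fit <- train_network(network, env_values(traits), saponin_values(traits),
                       learning_rate = config$learning_rate,
                       epochs = config$epochs, seed = config$seed)
  predictions <- predict(fit$network, env_values(traits))
  evaluation <- evaluate_predictions(
    predictions, saponin_values(traits)[, colnames(predictions), drop = FALSE])
  write_network(fit$network, file.path(out_dir, "network.json"))
  write_numeric_tsv(predictions, file.path(out_dir, "predictions.tsv"))
  write_numeric_tsv(evaluation$residuals, file.path(out_dir, "residuals.tsv"))
  write_json_report(list(rmse = evaluation$rmse, cv = evaluation$cv,
                         r2 = evaluation$r2,
                         residual_mean = evaluation$residual_mean),
                    file.path(out_dir, "evaluation.json"))

  target <- config$target_saponin
  if (is.null(known_ids) && !is.null(ground_truth)) {
    driver <- ground_truth$true_module_saponin_edges
    driver <- driver$source[driver$target == target]
    if (length(driver) > 0) {
      members <- names(ground_truth$module_assignment)[
        ground_truth$module_assignment == driver[1]]
      known_ids <- utils::head(members, 5)
    }
  }
  validation <- NULL
  if (!is.null(known_ids)) {
    pos <- positive_test(known_ids, partition, gsmm, graph, target,
                         max_path = config$max_path)
    neg_tab <- namc_table(partition, graph, target)
    neg <- chi_square_validity(neg_tab, correction = "yates",
                               alpha = config$alpha)
    validation <- list(positive = pos, negative = neg)
    write_json_report(list(
      positive = list(pass = pos$pass, per_module = pos$per_module),
      negative = list(statistic = neg$statistic, df = neg$df,
                      p_value = neg$p_value, reject = neg$reject)),
      file.path(out_dir, "validation.json"))
  }

  perturbation <- NULL
  into_target <- graph$edges[graph$edges$target == target, , drop = FALSE]
  if (nrow(into_target) > 0) {
    edge <- c(into_target$source[1], target)
    perturbation <- perturb_edge(fit$network, edge, config$perturb_scale,
                                 env_values(traits))
    write_json_report(list(edge = edge, scale = config$perturb_scale,
                           baseline = perturbation$baseline,
                           perturbed = perturbation$perturbed,
                           percent_change = signif(perturbation$percent_change, 3)),
                      file.path(out_dir, "perturbation.json"))
  }

  write_json_report(list(
    seed = config$seed,
    n_samples = nrow(expr), n_transcripts = ncol(expr),
    scan_chosen_beta = scan$chosen_beta,
    beta_used = beta,
    n_modules = length(setdiff(unique(partition$assignment), "grey")),
    n_graph_edges = nrow(graph$edges),
    evaluation = list(rmse = evaluation$rmse, cv = evaluation$cv,
                      r2 = evaluation$r2)),
    file.path(out_dir, "report.json"))

  invisible(list(expression = expr, traits = traits,
                 ground_truth = ground_truth,
                 filter_report = filt$report, outlier_report = outliers,
                 soft_threshold = scan, partition = partition,
                 eigengenes = eig, gsmm = gsmm, graph = graph,
                 training = fit, predictions = predictions,
                 evaluation = evaluation, validation = validation,
                 perturbation = perturbation, out_dir = out_dir))
}
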