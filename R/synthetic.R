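#' Default environmental factor names
#'
#' The 13 essential ecological factors used throughout: temperatures,
#' radiation, water-related variables, elevation and soil descriptors.
#'
#' @return Character vector of length 13.
#' @export
default_env_factors <- function() {
  c("air_temperature", "air_bottom_temperature", "surface_mean_temperature",
    "soil_temperature", "surface_shortwave_radiation", "soil_moisture",
    "soil_water_content", "rainfall", "total_precipitation", "elevation",
    "soil_type", "soil_pH", "soil_water_potential")
}

#' Default saponin trait names
#'
#' Nine individual ginsenosides plus total saponins (TS).
#'
#' @return Character vector of length 10.
#' @export
default_saponins <- function() {
  c("Rb1", "Rb2", "Rb3", "Rc", "Rd", "Re", "Rf", "Rg1", "Rg2", "TS")
}

#' Configuration for the synthetic data generator
#'
#' Builds a validated configuration describing a planted-module study:
#' latent environmental drivers feed transcript co-expression modules,
#' modules feed saponin contents.  Defaults emulate the scale of the real
#' study: 42 samples, 2000 transcripts of which 8 modules of 100 are
#' structured (the rest background), 13 environmental factors and 10
#' saponin traits.
#'
#' The default coefficient matrices are sparse: module m is driven by the
#' m-th environmental factor (coefficient 1), saponins Rb1..Rg1 are each
#' driven by one module (coefficient 1.2) and Rg2 by two modules
#' (coefficient 0.8 each).  TS is always generated as the sum of the nine
#' individual saponin columns and therefore carries no generating
#' coefficients of its own.
#'
#' @param n_samples Number of samples (default 42).
#' @param n_transcripts Number of transcripts (default 2000).
#' @param module_sizes Integer vector of planted module sizes, each >= 30
#'   unless deliberately testing the unassigned ("grey") path.
#' @param env_factor_names Names of environmental factors.
#' @param saponin_names Names of saponin traits; must end with "TS".
#' @param env_to_module_coefficients Matrix (env x module) of driver
#'   coefficients, many zeros.
#' @param module_to_saponin_coefficients Matrix (module x individual
#'   saponin) of coefficients, many zeros.  Excludes the TS column.
#' @param transcript_noise_sd Gaussian noise SD on in-module transcripts
#'   (default 0.5).
#' @param trait_noise_sd Gaussian noise SD on individual saponins
#'   (default 0.3).
#' @param env_noise_sd Observation noise SD on environmental factors.
#'   Default 0: factors are the latent drivers observed without error.
#' @param seed Integer seed controlling all randomness.
#'
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_samples = 42,
                             n_transcripts = 2000,
                             module_sizes = rep(100L, 8),
                             env_factor_names = default_env_factors(),
                             saponin_names = default_saponins(),
                             env_to_module_coefficients = NULL,
                             module_to_saponin_coefficients = NULL,
                             transcript_noise_sd = 0.5,
                             trait_noise_sd = 0.3,
                             env_noise_sd = 0,
                             seed = 1L) {
  assert_that(is_count(n_samples), "n_samples must be a positive count")
  assert_that(is_count(n_transcripts), "n_transcripts must be a positive count")
  assert_that(all(vapply(module_sizes, is_count, logical(1))),
              "module_sizes must be positive counts")
  assert_that(sum(module_sizes) <= n_transcripts,
              "sum(module_sizes) exceeds n_transcripts")
  assert_that(transcript_noise_sd >= 0 && trait_noise_sd >= 0 && env_noise_sd >= 0,
              "noise SDs must be nonnegative")
  assert_that(saponin_names[length(saponin_names)] == "TS",
              "last saponin must be the aggregate TS")
  n_modules <- length(module_sizes)
  module_names <- paste0("M", seq_len(n_modules))
  individual <- saponin_names[-length(saponin_names)]

  if (is.null(env_to_module_coefficients)) {
    env_to_module_coefficients <- matrix(
      0, length(env_factor_names), n_modules,
      dimnames = list(env_factor_names, module_names))
    for (m in seq_len(min(n_modules, length(env_factor_names)))) {
      env_to_module_coefficients[m, m] <- 1
    }
  }
  if (is.null(module_to_saponin_coefficients)) {
    module_to_saponin_coefficients <- matrix(
      0, n_modules, length(individual),
      dimnames = list(module_names, individual))
    for (j in seq_len(min(length(individual), n_modules))) {
      module_to_saponin_coefficients[j, j] <- 1.2
    }
    if (length(individual) > n_modules && n_modules >= 5) {
      extra <- setdiff(individual, colnames(module_to_saponin_coefficients)[
        seq_len(n_modules)])
      for (j in extra) {
        module_to_saponin_coefficients[c(1, 5), j] <- 0.8
      }
    }
  }
  assert_that(identical(dim(env_to_module_coefficients),
                        c(length(env_factor_names), n_modules)),
              "env_to_module_coefficients must be env x module")
  assert_that(identical(dim(module_to_saponin_coefficients),
                        c(n_modules, length(individual))),
              "module_to_saponin_coefficients must be module x individual saponin")

  structure(list(
    n_samples = as.integer(n_samples),
    n_transcripts = as.integer(n_transcripts),
    n_modules = n_modules,
    module_sizes = as.integer(module_sizes),
    env_factor_names = env_factor_names,
    saponin_names = saponin_names,
    env_to_module_coefficients = env_to_module_coefficients,
    module_to_saponin_coefficients = module_to_saponin_coefficients,
    transcript_noise_sd = transcript_noise_sd,
    trait_noise_sd = trait_noise_sd,
    env_noise_sd = env_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic expression/trait dataset with known ground truth
#'
#' Environmental factors are drawn as independent standard normal latent
#' drivers; each module's latent signal is the configured linear
#' combination of drivers, standardized to zero mean and unit variance.
#' In-module transcripts are affine functions of their module signal
#' (loading uniform in [0.5, 1.5] with random sign, baseline uniform in
#' [5, 50]) plus Gaussian noise; background transcripts are i.i.d.
#' unit-variance noise.  Individual saponins are linear combinations of
#' module signals plus noise and a positive baseline; TS is the exact sum
#' of the nine individual saponin columns.
#'
#' @param config A \code{\link{synthetic_config}}.
#'
#' @return List with components \code{expression} (samples x transcripts
#'   matrix), \code{traits} (a \code{\link{trait_table}}) and
#'   \code{ground_truth} (module assignment, latent signals and true edge
#'   sets).
#' @export
generate_dataset <- function(config) {
  assert_that(inherits(config, "synthetic_config"),
              "config must come from synthetic_config()")
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_transcripts
  M <- config$n_modules
  module_names <- rownames(config$module_to_saponin_coefficients)

  sample_ids <- paste0("S", seq_len(n))
  transcript_ids <- sprintf("T%05d", seq_len(p))

  # latent environmental drivers, one per configured factor
  env <- matrix(stats::rnorm(n * length(config$env_factor_names)), n,
                dimnames = list(sample_ids, config$env_factor_names))
  env <- scale(env)

  # module latent signals: linear combinations of drivers, standardized
  latent_raw <- env %*% config$env_to_module_coefficients
  latent <- standardize_columns(latent_raw, "latent module signal")
  attr(latent, "scaled:center") <- NULL
  attr(latent, "scaled:scale") <- NULL
  colnames(latent) <- module_names

  assignment <- rep("background", p)
  idx <- 1L
  for (m in seq_len(M)) {
    assignment[seq(idx, length.out = config$module_sizes[m])] <- module_names[m]
    idx <- idx + config$module_sizes[m]
  }
  names(assignment) <- transcript_ids

  loadings <- stats::runif(p, 0.5, 1.5) * sample(c(-1, 1), p, replace = TRUE)
  baselines <- stats::runif(p, 5, 50)
  expr <- matrix(0, n, p, dimnames = list(sample_ids, transcript_ids))
  for (t in seq_len(p)) {
    if (assignment[t] == "background") {
      expr[, t] <- baselines[t] + stats::rnorm(n)
    } else {
      expr[, t] <- baselines[t] + loadings[t] * latent[, assignment[t]] +
        stats::rnorm(n, sd = config$transcript_noise_sd)
    }
  }

  individual <- config$saponin_names[-length(config$saponin_names)]
  sap_base <- stats::runif(length(individual), 2, 6)
  sap <- latent %*% config$module_to_saponin_coefficients +
    matrix(stats::rnorm(n * length(individual), sd = config$trait_noise_sd),
           n, length(individual))
  sap <- sweep(sap, 2, sap_base, "+")
  colnames(sap) <- individual
  sap <- cbind(sap, TS = rowSums(sap))

  env_obs <- env
  if (config$env_noise_sd > 0) {
    env_obs <- env + matrix(stats::rnorm(n * ncol(env), sd = config$env_noise_sd),
                            n, ncol(env))
  }

  traits <- trait_table(cbind(env_obs, sap),
                        env_factors = config$env_factor_names,
                        saponins = config$saponin_names)

  e2m <- which(config$env_to_module_coefficients != 0, arr.ind = TRUE)
  true_env_module_edges <- data.frame(
    source = rownames(config$env_to_module_coefficients)[e2m[, 1]],
    target = module_names[e2m[, 2]],
    coefficient = config$env_to_module_coefficients[e2m],
    stringsAsFactors = FALSE)
  m2s <- which(config$module_to_saponin_coefficients != 0, arr.ind = TRUE)
  true_module_saponin_edges <- data.frame(
    source = module_names[m2s[, 1]],
    target = colnames(config$module_to_saponin_coefficients)[m2s[, 2]],
    coefficient = config$module_to_saponin_coefficients[m2s],
    stringsAsFactors = FALSE)

  log_stage("simulate", "samples=", n, " transcripts=", p, " modules=", M,
            " seed=", config$seed)
  list(expression = expr,
       traits = traits,
       ground_truth = list(
         module_assignment = assignment,
         latent_module_signals = latent,
         true_env_module_edges = true_env_module_edges,
         true_module_saponin_edges = true_module_saponin_edges))
}

#' Shift one sample's expression profile to create an outlier
#'
#' Adds \code{magnitude} times the global expression standard deviation to
#' every transcript of one randomly chosen sample, emulating an aberrant
#' sample that hierarchical clustering should flag.
#'
#' @param expr Samples x transcripts expression matrix.
#' @param magnitude Positive shift in units of the global SD.
#' @param seed Integer seed selecting the sample.
#'
#' @return The perturbed matrix; the chosen sample ID is stored in
#'   \code{attr(, "outlier_sample")}.
#' @export
inject_outlier_sample <- function(expr, magnitude, seed = 1L) {
  assert_that(is.matrix(expr) && nrow(expr) > 0 && ncol(expr) > 0,
              "expr must be a nonempty matrix")
  assert_that(is.numeric(magnitude) && length(magnitude) == 1 && magnitude > 0,
              "magnitude must be > 0")
  set.seed(seed)
  victim <- sample(nrow(expr), 1)
  out <- expr
  out[victim, ] <- out[victim, ] + magnitude * stats::sd(expr)
  attr(out, "outlier_sample") <- rownames(expr)[victim]
  out
}
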