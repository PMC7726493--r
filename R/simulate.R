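#' Configuration for the synthetic expression-study generator
#'
#' Describes a replicated multi-compound microarray design: one control group
#' plus several compound groups measured on a common probe universe. A core of
#' `shared_de_count` probes responds to every compound with correlated log2
#' effect sizes (one concordant sign per probe), each compound additionally
#' perturbs `private_de_count` probes of its own, and the remaining probes are
#' null. Defaults mirror a two-cell-line bisphenol exposure design: a
#' ~20,000-probe array, four replicates per condition, and three compounds
#' against one control.
#'
#' @param n_probes probe universe size N.
#' @param n_replicates replicates per condition.
#' @param conditions character vector of condition labels; the FIRST element
#'   is the control group.
#' @param shared_de_count probes perturbed by all compounds.
#' @param private_de_count probes perturbed by exactly one compound (per
#'   compound).
#' @param effect_mean,effect_sd mean and sd of the log2 effect magnitude.
#' @param effect_correlation target Pearson correlation, in \[0, 1\], between
#'   compounds' effect sizes on shared probes (exchangeable across compounds).
#'   Attained exactly when `effect_mean = 0`; with a nonzero mean the shared
#'   concordant sign raises the unconditional correlation above this value
#'   (see the methods vignette).
#' @param noise_sd sd of the i.i.d. Gaussian measurement noise, log2 units.
#' @param baseline_mean,baseline_sd per-probe baseline log2 intensity
#'   distribution.
#' @param seed RNG seed; identical (config, seed) gives identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20000L,
                       n_replicates = 4L,
                       conditions = c("control", "BPA", "BPF", "BPS"),
                       shared_de_count = 200L,
                       private_de_count = 100L,
                       effect_mean = 1.5,
                       effect_sd = 0.5,
                       effect_correlation = 0.5,
                       noise_sd = 0.25,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_replicates = as.integer(n_replicates),
              conditions = as.character(conditions),
              shared_de_count = as.integer(shared_de_count),
              private_de_count = as.integer(private_de_count),
              effect_mean = effect_mean, effect_sd = effect_sd,
              effect_correlation = effect_correlation,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  stop_field <- function(field, msg)
    stop(sprintf("invalid sim_config: `%s` %s", field, msg), call. = FALSE)
  if (cfg$n_probes < 1L) stop_field("n_probes", "must be positive")
  if (cfg$n_replicates < 1L) stop_field("n_replicates", "must be positive")
  if (length(cfg$conditions) < 2L || anyDuplicated(cfg$conditions))
    stop_field("conditions", "needs >= 2 unique labels (control first)")
  if (cfg$shared_de_count < 0L) stop_field("shared_de_count", "must be >= 0")
  if (cfg$private_de_count < 0L) stop_field("private_de_count", "must be >= 0")
  n_compounds <- length(cfg$conditions) - 1L
  if (cfg$shared_de_count + n_compounds * cfg$private_de_count > cfg$n_probes)
    stop_field("shared_de_count",
               "+ conditions * private_de_count exceeds n_probes")
  if (cfg$effect_sd < 0) stop_field("effect_sd", "must be >= 0")
  if (cfg$effect_correlation < 0 || cfg$effect_correlation > 1)
    stop_field("effect_correlation", "must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop_field("noise_sd", "must be > 0")
  if (cfg$baseline_sd < 0) stop_field("baseline_sd", "must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic expression study with ground truth
#'
#' Draws baseline log2 intensities per probe, injects the configured shared
#' and private effects into the compound groups, adds i.i.d. Gaussian noise to
#' every measurement, and returns both the expression matrix and the exact
#' truth used to generate it. Shared-probe effects are jointly Gaussian with
#' an exchangeable correlation matrix (single-factor construction), and each
#' shared probe draws one fair-coin sign applied to all compounds, so shared
#' probes move concordantly up or down.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{matrix}{an [expression_matrix()]; control samples are baseline +
#'       noise, treated samples additionally carry the true effect.}
#'     \item{truth}{a data.frame with `probe_id`, `membership` (`"shared"`,
#'       `"private_<compound>"` or `"null"`) and one `effect_<compound>`
#'       column per compound holding the true log2 effect (0 for unaffected
#'       probes).}
#'   }
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  compounds <- cfg$conditions[-1L]
  k <- length(compounds)
  with_seed(cfg$seed, {
    probe_ids <- sprintf("probe_%05d", seq_len(cfg$n_probes))
    baseline <- rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)

    n_de <- cfg$shared_de_count + k * cfg$private_de_count
    de_idx <- if (n_de > 0L) sample.int(cfg$n_probes, n_de) else integer(0)
    shared_idx <- de_idx[seq_len(cfg$shared_de_count)]
    private_idx <- split(
      de_idx[cfg$shared_de_count + seq_len(k * cfg$private_de_count)],
      rep(seq_len(k), each = cfg$private_de_count))

    effects <- matrix(0, cfg$n_probes, k,
                      dimnames = list(probe_ids, compounds))
    membership <- rep("null", cfg$n_probes)
    if (cfg$shared_de_count > 0L) {
      rho <- cfg$effect_correlation
      z0 <- rnorm(cfg$shared_de_count)
      z <- matrix(rnorm(cfg$shared_de_count * k), ncol = k)
      # exchangeable correlation rho via a shared latent factor
      corr <- sqrt(rho) * z0 + sqrt(1 - rho) * z
      sign_shared <- sample(c(-1, 1), cfg$shared_de_count, replace = TRUE)
      effects[shared_idx, ] <-
        sign_shared * (cfg$effect_mean + cfg$effect_sd * corr)
      membership[shared_idx] <- "shared"
    }
    if (cfg$private_de_count > 0L) {
      for (j in seq_len(k)) {
        idx <- private_idx[[j]]
        sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
        effects[idx, j] <-
          sgn * rnorm(length(idx), cfg$effect_mean, cfg$effect_sd)
        membership[idx] <- paste0("private_", compounds[j])
      }
    }

    n_samples <- cfg$n_replicates * length(cfg$conditions)
    treatment <- rep(cfg$conditions, each = cfg$n_replicates)
    replicate <- rep(seq_len(cfg$n_replicates), times = length(cfg$conditions))
    sample_ids <- sprintf("%s_r%d", treatment, replicate)
    values <- matrix(baseline, cfg$n_probes, n_samples) +
      matrix(rnorm(cfg$n_probes * n_samples, 0, cfg$noise_sd),
             cfg$n_probes, n_samples)
    for (j in seq_len(k))
      values[, treatment == compounds[j]] <-
        values[, treatment == compounds[j]] + effects[, j]
    dimnames(values) <- list(probe_ids, sample_ids)

    samples <- data.frame(sample_id = sample_ids,
                          cell_line = "synthetic",
                          treatment = treatment,
                          replicate = replicate,
                          stringsAsFactors = FALSE)
    truth <- data.frame(probe_id = probe_ids, membership = membership,
                        stringsAsFactors = FALSE)
    for (j in seq_len(k)) truth[[paste0("effect_", compounds[j])]] <- effects[, j]

    list(matrix = expression_matrix(values, samples), truth = truth)
  })
}

#' Configuration for synthetic concentration-response curves
#'
#' @param concentrations strictly increasing concentrations in uM, first
#'   element 0 (vehicle). Default: a 6-point range spanning 0-500 uM.
#' @param true_ic50 concentration at which the mean response crosses 50% of
#'   vehicle control, uM; `NA` for a compound whose response never falls to
#'   50% within the tested range.
#' @param hill_slope Hill coefficient of the logistic decay (dimensionless).
#' @param response_floor asymptotic response at high concentration, percent of
#'   control; the logistic crosses 50% at `true_ic50` exactly when the floor
#'   is 0.
#' @param noise_sd per-replicate Gaussian noise, percent-of-control units.
#' @param n_replicates wells per concentration.
#' @param seed RNG seed.
#' @return A validated list of class `dose_config`.
#' @export
dose_config <- function(concentrations = c(0, 10, 50, 100, 250, 500),
                        true_ic50 = 50,
                        hill_slope = 1,
                        response_floor = 0,
                        noise_sd = 5,
                        n_replicates = 5L,
                        seed = 1L) {
  if (length(concentrations) < 2L || any(diff(concentrations) <= 0))
    stop("`concentrations` must be strictly increasing")
  if (concentrations[1] != 0)
    stop("first concentration must be 0 (vehicle)")
  if (!is.na(true_ic50) && true_ic50 <= 0)
    stop("`true_ic50` must be positive (or NA for not-reached)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (response_floor < 0 || response_floor >= 50)
    stop("`response_floor` must lie in [0, 50)")
  structure(list(concentrations = as.numeric(concentrations),
                 true_ic50 = true_ic50, hill_slope = hill_slope,
                 response_floor = response_floor, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "dose_config")
}

#' Generate a synthetic concentration-response curve
#'
#' Mean structure is a monotone-decreasing logistic in concentration,
#' expressed as percent of the vehicle control (100 at concentration 0,
#' before noise): `floor + (100 - floor) / (1 + (c / ic50)^h)`. When
#' `true_ic50` is `NA` the mean declines linearly to 60% of control at the
#' highest tested concentration, so it never reaches 50% — the behaviour of a
#' low-toxicity compound within the tested range.
#'
#' @param config a [dose_config()].
#' @return An object of class `dose_curve`: list with `concentration` (uM),
#'   `response` (mean percent of control across replicates), `replicates`
#'   (points x replicates matrix), `n_replicates`, `response_sd`, and the
#'   generating `config`.
#' @export
generate_dose_response <- function(config) {
  if (!inherits(config, "dose_config")) config <- do.call(dose_config, config)
  cfg <- config
  conc <- cfg$concentrations
  mean_resp <- if (is.na(cfg$true_ic50)) {
    100 - 40 * conc / max(conc)
  } else {
    cfg$response_floor + (100 - cfg$response_floor) /
      (1 + (conc / cfg$true_ic50)^cfg$hill_slope)
  }
  with_seed(cfg$seed, {
    reps <- matrix(rnorm(length(conc) * cfg$n_replicates, mean_resp,
                         cfg$noise_sd),
                   nrow = length(conc))
    structure(list(concentration = conc,
                   response = rowMeans(reps),
                   replicates = reps,
                   n_replicates = cfg$n_replicates,
                   response_sd = apply(reps, 1, sd),
                   config = cfg),
              class = "dose_curve")
  })
}

#' @export
print.dose_curve <- function(x, ...) {
  cat(sprintf("dose_curve: %d concentrations (%g-%g uM), %d replicates/point\n",
              length(x$concentration), min(x$concentration),
              max(x$concentration), x$n_replicates))
  print(data.frame(concentration_uM = x$concentration,
                   response_pct = round(x$response, 2)))
  invisible(x)
}
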