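#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles input locations, analysis thresholds and output directory. The
#' defaults are the study's stated settings: 1.5-fold change, 5% FDR, and
#' PCA on the 1000 highest-variance probes.
#'
#' @param matrix_path,samples_path expression matrix (TSV) and sample sheet
#'   (CSV) paths; alternatively pass an in-memory matrix via `em`.
#' @param em optional [expression_matrix()]; overrides the file inputs.
#' @param dose_paths optional named character vector of dose-response CSV
#'   paths (one per compound).
#' @param control control treatment label.
#' @param fc_threshold linear fold-change threshold (> 1).
#' @param alpha FDR level.
#' @param pca_top_k number of top-variance probes entering PCA.
#' @param universe `"all"` (N = all probes on the matrix) or `"expressed"`
#'   (N = probes whose mean log2 intensity exceeds `expressed_cutoff`).
#' @param expressed_cutoff mean log2 intensity cutoff for the expressed
#'   universe.
#' @param pca_samples optional character vector of treatment labels to keep
#'   in the PCA stage (default: all samples).
#' @param seed seed for the Monte-Carlo overlap null run in the report.
#' @param mc_reps Monte-Carlo replicates for the overlap null (0 disables).
#' @param out_dir output directory; created if needed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, samples_path = NULL,
                            em = NULL, dose_paths = NULL,
                            control = "control",
                            fc_threshold = 1.5, alpha = 0.05,
                            pca_top_k = 1000L,
                            universe = c("all", "expressed"),
                            expressed_cutoff = 5,
                            pca_samples = NULL,
                            seed = 1L, mc_reps = 2000L,
                            out_dir = "txconcord_out") {
  universe <- match.arg(universe)
  if (is.null(em) && (is.null(matrix_path) || is.null(samples_path)))
    stop("supply either `em` or both `matrix_path` and `samples_path`")
  if (fc_threshold <= 1) stop("`fc_threshold` must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  structure(list(matrix_path = matrix_path, samples_path = samples_path,
                 em = em, dose_paths = dose_paths, control = control,
                 fc_threshold = fc_threshold, alpha = alpha,
                 pca_top_k = as.integer(pca_top_k), universe = universe,
                 expressed_cutoff = expressed_cutoff,
                 pca_samples = pca_samples,
                 seed = as.integer(seed), mc_reps = as.integer(mc_reps),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full multi-compound concordance analysis
#'
#' Orchestrates every stage over one expression study: per-compound
#' differential expression tables and up/down gene lists, the three-set Venn
#' partitions of the up- and down-sets, all pairwise and three-way
#' overlap-ratio summaries (with a seeded Monte-Carlo exceedance probability
#' for the three-way overlaps), the genome-wide Spearman concordance matrix
#' of log2 fold-change profiles, top-variance PCA of the samples, IC50
#' estimates for any supplied dose-response curves, and a machine-readable
#' run manifest with configuration and output checksums. Identical inputs,
#' configuration and seed give checksum-identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`de`, `overlap`,
#'   `venn`, `concordance`, `pca`, `ic50`, `manifest`); all tables are also
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "pipeline_config")) stop("`config` must be a pipeline_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)

  em <- stage("input", {
    if (!is.null(cfg$em)) cfg$em
    else read_expression_matrix(cfg$matrix_path, cfg$samples_path)
  })
  compounds <- setdiff(unique(em$samples$treatment), cfg$control)
  if (!length(compounds)) stop("pipeline stage 'input' failed: no treated groups")

  universe_ids <- stage("universe", {
    if (cfg$universe == "all") rownames(em$values)
    else rownames(em$values)[rowMeans(em$values) > cfg$expressed_cutoff]
  })
  N <- length(universe_ids)

  de <- stage("diffexpr", {
    tabs <- lapply(compounds, function(cmp)
      de_table(em, cmp, cfg$control, cfg$fc_threshold, cfg$alpha))
    names(tabs) <- compounds
    for (cmp in compounds) {
      write_de_table(tabs[[cmp]], out(sprintf("de_%s.tsv", cmp)))
      write_gene_list(de_probes(tabs[[cmp]], "up"),
                      out(sprintf("up_%s.txt", cmp)))
      write_gene_list(de_probes(tabs[[cmp]], "down"),
                      out(sprintf("down_%s.txt", cmp)))
    }
    tabs
  })

  up_sets <- lapply(de, de_probes, direction = "up")
  down_sets <- lapply(de, de_probes, direction = "down")
  dereg_sets <- lapply(de, de_probes, direction = "deregulated")

  venn <- stage("venn", {
    v <- NULL
    if (length(compounds) == 3L) {
      v <- list(up = venn_partition(up_sets, universe_ids),
                down = venn_partition(down_sets, universe_ids))
      vdf <- data.frame(region = names(v$up), up = as.integer(v$up),
                        down = as.integer(v$down))
      utils::write.table(vdf, out("venn_regions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    v
  })

  ovl <- stage("overlap", {
    tab <- rbind(cbind(direction = "up", overlap_table(up_sets, N)),
                 cbind(direction = "down", overlap_table(down_sets, N)),
                 cbind(direction = "deregulated",
                       overlap_table(dereg_sets, N)))
    if (cfg$mc_reps > 0L && length(compounds) >= 3L) {
      tab$p_exceed_mc <- NA_real_
      three <- which(tab$k == 3 & tab$defined)
      for (r in three) {
        sizes <- as.integer(strsplit(tab$n_sets[r], ",")[[1]])
        mc <- monte_carlo_null(sizes[1], sizes[2], sizes[3], N = N,
                               reps = cfg$mc_reps,
                               seed = cfg$seed + r,
                               observed = tab$observed[r])
        tab$p_exceed_mc[r] <- mc$p_exceed
      }
    }
    utils::write.table(tab, out("overlap_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })

  conc <- stage("concordance", {
    profiles <- lapply(de, function(d) d$log2fc)
    cm <- pairwise_concordance(profiles)
    utils::write.table(data.frame(condition = rownames(cm$R), cm$R,
                                  check.names = FALSE),
                       out("concordance_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cm
  })

  pca <- stage("pca", {
    em_pca <- em
    if (!is.null(cfg$pca_samples)) {
      keep <- em$samples$treatment %in% cfg$pca_samples
      em_pca <- expression_matrix(em$values[, keep, drop = FALSE],
                                  em$samples[keep, , drop = FALSE])
    }
    top <- select_top_variance(em_pca, min(cfg$pca_top_k, nrow(em_pca$values)))
    res <- pca_samples(em_pca, top)
    scores <- data.frame(sample_id = rownames(res$scores),
                         treatment = res$samples$treatment,
                         res$scores[, seq_len(min(4, ncol(res$scores))),
                                    drop = FALSE],
                         check.names = FALSE)
    utils::write.table(scores, out("pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(component = seq_along(res$percent_var),
                                  percent_var = res$percent_var),
                       out("pca_variance.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res
  })

  ic50 <- stage("ic50", {
    res <- NULL
    if (!is.null(cfg$dose_paths)) {
      res <- lapply(cfg$dose_paths, function(p) estimate_ic50(read_dose_curve(p)))
      df <- data.frame(compound = names(res),
                       status = vapply(res, `[[`, "", "status"),
                       ic50_uM = vapply(res, `[[`, 1, "ic50"),
                       a = vapply(res, `[[`, 1, "a"),
                       b = vapply(res, `[[`, 1, "b"))
      utils::write.table(df, out("ic50.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    res
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
    m <- list(
      package_version = as.character(utils::packageVersion("txconcord")),
      config = list(control = cfg$control, fc_threshold = cfg$fc_threshold,
                    alpha = cfg$alpha, pca_top_k = cfg$pca_top_k,
                    universe = cfg$universe, seed = cfg$seed,
                    mc_reps = cfg$mc_reps),
      universe_size = N,
      n_de = lapply(de, function(d) as.list(as.integer(table(d$call))) |>
               setNames(levels(d$call))),
      checksums = as.list(tools::md5sum(file.path(cfg$out_dir, files))))
    names(m$checksums) <- files
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    m
  })

  invisible(list(de = de, overlap = ovl, venn = venn, concordance = conc,
                 pca = pca, ic50 = ic50, manifest = manifest,
                 universe_size = N))
}
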