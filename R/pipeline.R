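#' Configuration for a multi-construct experiment
#'
#' @param profiles Named list of [localization_profile()] objects (e.g. from
#'   [load_construct_catalogue()]).
#' @param n_cells Cells per construct cohort (>= 1; published cohorts used
#'   8-14).
#' @param geometry Shared [cell_geometry()].
#' @param noise Shared [noise_model()].
#' @param reference_construct Name of the construct every other cohort is
#'   tested against (pairwise Wilcoxon and Fisher), typically the full-length
#'   wild-type fusion.
#' @param cer_threshold Positivity threshold for the qualitative call.
#' @param prob_ill_defined Per-cell probability of an ill-defined plate.
#' @param seed Master RNG seed; everything downstream derives from it.
#' @param output_dir Directory for the report bundle.
#' @param holm Also report Holm-adjusted p-values (default off: published
#'   pairwise p-values are raw).
#' @param make_figure Write the box-and-whisker figure (PNG).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(profiles, n_cells = 10,
                              geometry = cell_geometry(),
                              noise = noise_model(),
                              reference_construct = names(profiles)[1],
                              cer_threshold = 1.6,
                              prob_ill_defined = 0.18,
                              seed = 1L, output_dir = tempfile("cer_run_"),
                              holm = FALSE, make_figure = TRUE) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "localization_profile")))
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  }
  if (!reference_construct %in% names(profiles)) {
    stop("reference_construct must name one of the profiles")
  }
  stopifnot(n_cells >= 1)
  structure(list(profiles = profiles, n_cells = as.integer(n_cells),
                 geometry = geometry, noise = noise,
                 reference_construct = reference_construct,
                 cer_threshold = cer_threshold,
                 prob_ill_defined = prob_ill_defined,
                 seed = as.integer(seed), output_dir = output_dir,
                 holm = holm, make_figure = make_figure),
            class = "experiment_config")
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Run a full multi-construct experiment
#'
#' Generation -> quantification -> scoring -> statistics -> reporting from
#' one configuration, emulating a complete construct-panel experiment. For
#' every profile a cohort is generated and quantified (hand-ROI emulation,
#' 12-SD segmentation, QC window), scored, and summarized; each non-reference
#' cohort is compared to the reference with the exact Wilcoxon rank-sum test
#' on eligible CERs and Fisher's exact test on positive-vs-rest call counts;
#' each cohort's CER distribution gets an Anderson-Darling normality flag.
#'
#' The report bundle written to `config$output_dir`:
#' \itemize{
#'   \item `cells.csv` - one row per cell (truth, measurement, QC, call);
#'   \item `cohorts.csv` - per-construct counts, box statistics, normality;
#'   \item `comparisons.csv` - pairwise tests vs the reference with
#'     significance stars (* / ** / *** for p < 0.05 / 0.01 / 0.001);
#'   \item `config.json`, `run_log.json` - full parameter record, seed and
#'     config MD5 hash, so every number traces to a logged seed + config;
#'   \item `cer_boxplot.png` (optional) - box = Tukey hinges, whiskers =
#'     range, diamond = mean, dashed line at the positivity threshold.
#' }
#' Outputs are byte-reproducible for a fixed config and seed.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list with `cells` (data frame), `summaries`,
#'   `comparisons` (data frame), and `paths` of the files written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(config$seed)
  cohort_seeds <- sample.int(.Machine$integer.max, length(config$profiles))
  names(cohort_seeds) <- names(config$profiles)

  summaries <- list()
  cell_rows <- list()
  for (nm in names(config$profiles)) {
    prof <- config$profiles[[nm]]
    cohort <- generate_cohort(prof, config$n_cells, config$geometry,
                              config$noise, seed = cohort_seeds[[nm]],
                              prob_ill_defined = config$prob_ill_defined)
    ms <- vector("list", length(cohort))
    for (i in seq_along(cohort)) {
      ms[[i]] <- tryCatch(
        quantify_cell(cohort[[i]], cell_id = sprintf("%s_%02d", nm, i)),
        error = function(e) {
          stop(sprintf("construct '%s', cell %s_%02d: %s",
                       nm, nm, i, conditionMessage(e)), call. = FALSE)
        })
    }
    plate_flags <- vapply(cohort, `[[`, logical(1), "plate_defined")
    sm <- withCallingHandlers(
      summarize_cohort(ms, plate_flags, construct = nm,
                       cer_threshold = config$cer_threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    summaries[[nm]] <- sm
    cell_rows[[nm]] <- data.frame(
      construct = nm,
      cell_id = vapply(ms, `[[`, character(1), "cell_id"),
      seed = vapply(cohort, `[[`, integer(1), "seed"),
      expression = vapply(cohort, `[[`, numeric(1), "expression"),
      true_cer = vapply(cohort, `[[`, numeric(1), "true_cer"),
      chrom_mean = vapply(ms, `[[`, numeric(1), "chrom_mean"),
      cell_mean = vapply(ms, `[[`, numeric(1), "cell_mean"),
      bg_mean = vapply(ms, function(m) m$background$mean, numeric(1)),
      bg_sd = vapply(ms, function(m) m$background$sd, numeric(1)),
      cer = vapply(ms, `[[`, numeric(1), "cer"),
      qc_pass = vapply(ms, `[[`, logical(1), "qc_pass"),
      plate_defined = plate_flags,
      call = sm$calls,
      reason = sm$reasons)
  }
  cells <- do.call(rbind, c(cell_rows, make.row.names = FALSE))

  cohorts <- do.call(rbind, lapply(summaries, function(sm) {
    ad <- if (length(sm$cer_values) >= 8 && sd(sm$cer_values) > 0) {
      anderson_darling_normal(sm$cer_values)
    } else NULL
    data.frame(
      construct = sm$construct, n_total = sm$n_total,
      n_positive = sm$n_positive, n_absent = sm$n_absent,
      n_cannot_call = sm$n_cannot_call, n_quant = length(sm$cer_values),
      mean_cer = if (is.null(sm$box)) NA_real_ else sm$box$mean,
      sd_cer = if (length(sm$cer_values) > 1) sd(sm$cer_values) else NA_real_,
      median = if (is.null(sm$box)) NA_real_ else sm$box$median,
      q1 = if (is.null(sm$box)) NA_real_ else sm$box$q1,
      q3 = if (is.null(sm$box)) NA_real_ else sm$box$q3,
      min = if (is.null(sm$box)) NA_real_ else sm$box$min,
      max = if (is.null(sm$box)) NA_real_ else sm$box$max,
      ad_statistic = if (is.null(ad)) NA_real_ else ad$statistic,
      ad_p = if (is.null(ad)) NA_real_ else ad$p_value,
      normal_at_0.05 = if (is.null(ad)) NA else !ad$reject_normal)
  }))

  ref <- config$reference_construct
  ref_sm <- summaries[[ref]]
  others <- setdiff(names(summaries), ref)
  comparisons <- do.call(rbind, lapply(others, function(nm) {
    sm <- summaries[[nm]]
    wt <- if (length(sm$cer_values) >= 1 && length(ref_sm$cer_values) >= 1) {
      suppressWarnings(wilcoxon_exact(sm$cer_values, ref_sm$cer_values))
    } else NULL
    tab <- matrix(c(sm$n_positive, sm$n_total - sm$n_positive,
                    ref_sm$n_positive, ref_sm$n_total - ref_sm$n_positive),
                  2, 2, byrow = TRUE)
    ft <- suppressWarnings(fisher_exact(tab))
    data.frame(
      construct = nm, reference = ref,
      wilcoxon_W = if (is.null(wt)) NA_real_ else wt$statistic,
      wilcoxon_p = if (is.null(wt)) NA_real_ else wt$p_value,
      wilcoxon_stars = if (is.null(wt)) "" else significance_stars(wt$p_value),
      pos_a = tab[1, 1], rest_a = tab[1, 2],
      pos_ref = tab[2, 1], rest_ref = tab[2, 2],
      fisher_p = ft$p_value,
      fisher_stars = significance_stars(ft$p_value))
  }))
  if (isTRUE(config$holm) && !is.null(comparisons) && nrow(comparisons)) {
    comparisons$wilcoxon_p_holm <- p.adjust(comparisons$wilcoxon_p, "holm")
    comparisons$fisher_p_holm <- p.adjust(comparisons$fisher_p, "holm")
  }

  paths <- c(cells = file.path(config$output_dir, "cells.csv"),
             cohorts = file.path(config$output_dir, "cohorts.csv"),
             comparisons = file.path(config$output_dir, "comparisons.csv"),
             config = file.path(config$output_dir, "config.json"),
             log = file.path(config$output_dir, "run_log.json"))
  write.csv(cells, paths[["cells"]], row.names = FALSE)
  write.csv(cohorts, paths[["cohorts"]], row.names = FALSE)
  if (!is.null(comparisons)) {
    write.csv(comparisons, paths[["comparisons"]], row.names = FALSE)
  }

  config_json <- list(
    constructs = lapply(config$profiles, unclass),
    n_cells = config$n_cells,
    geometry = unclass(config$geometry),
    noise = unclass(config$noise),
    reference_construct = ref,
    cer_threshold = config$cer_threshold,
    prob_ill_defined = config$prob_ill_defined,
    seed = config$seed,
    conventions = list(
      qc_window = c(50, 500), qc_endpoints = "inclusive",
      segmentation = "background mean + 12 SD, largest connected component",
      quartiles = "Tukey hinges (median of halves)",
      positivity = "CER strictly above threshold",
      two_sided_fisher = "sum of table probabilities <= observed",
      two_sided_wilcoxon = "doubled smaller tail, capped at 1"))
  jsonlite::write_json(config_json, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = config$seed,
         cohort_seeds = as.list(cohort_seeds),
         config_md5 = unname(tools::md5sum(paths[["config"]])),
         package_version = as.character(utils::packageVersion("cerquant"))),
    paths[["log"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(config$make_figure)) {
    fig <- file.path(config$output_dir, "cer_boxplot.png")
    plot_cer_boxes(cohorts, config$cer_threshold, fig)
    paths <- c(paths, figure = fig)
  }

  invisible(list(cells = cells, summaries = summaries, cohorts = cohorts,
                 comparisons = comparisons, paths = paths))
}

# Box-and-whisker figure from precomputed cohort statistics: box = Tukey
# hinges, whiskers = range, diamond = mean, dashed positivity threshold.
#' @importFrom rlang .data
plot_cer_boxes <- function(cohorts, cer_threshold, path) {
  df <- cohorts[!is.na(cohorts$median), , drop = FALSE]
  df$construct <- factor(df$construct, levels = df$construct)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$construct)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", width = 0.55, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_cer),
                        shape = 18, size = 3) +
    ggplot2::geom_hline(yintercept = cer_threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "Chromosome enrichment ratio (CER)") +
    ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  grDevices::png(path, width = 170 + 90 * nrow(df), height = 480, res = 110)
  print(p)
  grDevices::dev.off()
  invisible(path)
}
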