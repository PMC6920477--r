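#' Build a pipeline configuration
#'
#' Validates paths and thresholds for [run_pipeline()]. Either give
#' \code{expr}/\code{meta} paths to analyze existing data, or a
#' [sim_config()] under \code{simulate} to generate a cohort first.
#'
#' @param expr,meta paths to expression and metadata TSVs (or
#'   \code{NULL} when \code{simulate} is given).
#' @param gmt path to a GMT gene-set file.
#' @param panel path to a one-symbol-per-line panel file, or \code{NULL}
#'   for the packaged circadian panel.
#' @param outdir output directory.
#' @param simulate optional [sim_config()].
#' @param fdr_alpha,alpha_unc significance thresholds in (0, 1).
#' @param n_perm,b_draws enrichment permutations and Monte-Carlo draws.
#' @param tcgsa_ref reference distribution for the time-course test.
#' @param exclude_sets gene-set names dropped after reading the GMT.
#' @param cohorts cohorts for the time-course stage.
#' @param normalize whether to quantile-normalize before modelling.
#' @param seed integer seed governing every stochastic stage.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expr = NULL, meta = NULL, gmt = NULL,
                            panel = NULL, outdir = "sdexpr_out",
                            simulate = NULL,
                            fdr_alpha = 0.05, alpha_unc = 0.05,
                            n_perm = 1000, b_draws = 10000,
                            tcgsa_ref = "chisq",
                            exclude_sets = character(),
                            cohorts = c("patients", "controls",
                                        "responders", "non_responders"),
                            normalize = TRUE, seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(expr) || is.null(meta))
      stop("either `simulate` or both `expr` and `meta` must be given")
    for (p in c(expr, meta)) if (!file.exists(p)) stop("missing input: ", p)
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  if (!is.null(gmt) && !file.exists(gmt)) stop("missing GMT file: ", gmt)
  if (!is.null(panel) && !file.exists(panel)) stop("missing panel file: ", panel)
  if (fdr_alpha <= 0 || fdr_alpha >= 1 || alpha_unc <= 0 || alpha_unc >= 1)
    stop("alpha thresholds must lie in (0, 1)")
  structure(
    list(expr = expr, meta = meta, gmt = gmt, panel = panel,
         outdir = outdir, simulate = simulate, fdr_alpha = fdr_alpha,
         alpha_unc = alpha_unc, n_perm = n_perm, b_draws = b_draws,
         tcgsa_ref = tcgsa_ref, exclude_sets = exclude_sets,
         cohorts = cohorts, normalize = normalize, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()] (the \code{simulate} block, if present, holds
#'   [sim_config()] arguments).
#' @return A validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_config, raw$simulate)
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Summarize significant genes per contrast
#'
#' @param results named list of \code{deg_results} (one per contrast).
#' @param alpha q-value threshold.
#' @return data.frame with columns \code{contrast}, \code{n_sig},
#'   \code{n_up}, \code{n_down}; \code{n_up + n_down = n_sig} always.
#' @export
summarize_counts <- function(results, alpha = 0.05) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    sig <- !is.na(r$q) & r$q < alpha & r$converged & r$direction != 0
    data.frame(contrast = nm, n_sig = sum(sig),
               n_up = sum(sig & r$direction > 0),
               n_down = sum(sig & r$direction < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contrast = character(0), n_sig = integer(0),
                      n_up = integer(0), n_down = integer(0))
  stopifnot(all(out$n_up + out$n_down == out$n_sig))
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> quantile normalization -> per-gene
#' LRT contrasts M1-M3 -> baseline models -> circadian-panel screen and
#' Monte-Carlo test -> preranked enrichment per contrast -> time-course
#' gene-set analysis per cohort -> summary report. Every stage writes a
#' TSV under \code{outdir}; a JSON manifest records the seed, package
#' version, configuration and stage row counts, and two runs with the
#' same config and seed produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "sdexpr",
    version = as.character(utils::packageVersion("sdexpr")),
    seed = config$seed,
    config = config_fingerprint(config),
    stages = list()
  )

  # -- input stage ----------------------------------------------------
  if (!is.null(config$simulate)) {
    stage_log("simulate", "generating synthetic cohort (seed %d)",
              config$simulate$seed)
    study <- simulate_cohort(config$simulate)
    write_expression(study, file.path(outdir, "expression.tsv"),
                     file.path(outdir, "samples.tsv"))
    write_tsv(truth_table(config$simulate), file.path(outdir, "truth.tsv"))
  } else {
    stage_log("read", "reading %s", config$expr)
    study <- read_expression(config$expr, config$meta)
  }
  manifest$stages$input <- list(genes = length(study$genes),
                                samples = nrow(study$samples))

  if (config$normalize) {
    stage_log("normalize", "quantile normalization over %d samples",
              nrow(study$samples))
    study <- quantile_normalize(study)
  }

  # -- per-gene contrasts ---------------------------------------------
  deg <- list()
  for (nm in c("M1", "M2", "M3")) {
    stage_log("fit", "contrast %s over %d genes", nm, length(study$genes))
    deg[[nm]] <- run_transcriptome(study, contrast_spec(nm),
                                   alpha = config$fdr_alpha)
    write_tsv(as.data.frame(deg[[nm]]),
              file.path(outdir, paste0("deg_", nm, ".tsv")))
    nconv <- sum(!deg[[nm]]$converged)
    if (nconv) stage_log("fit", "%d gene(s) flagged non-converged in %s",
                         nconv, nm)
  }
  baseline <- list(
    baseline_response = baseline_differences(study, "response",
                                             alpha = config$fdr_alpha),
    baseline_case = baseline_differences(study, "case",
                                         alpha = config$fdr_alpha)
  )
  for (nm in names(baseline))
    write_tsv(as.data.frame(baseline[[nm]]),
              file.path(outdir, paste0(nm, ".tsv")))

  counts <- summarize_counts(c(deg, baseline), alpha = config$fdr_alpha)
  write_tsv(counts, file.path(outdir, "summary_counts.tsv"))
  manifest$stages$contrasts <- counts

  # top-10 style table per longitudinal contrast
  top10 <- do.call(rbind, lapply(names(deg), function(nm) {
    h <- utils::head(as.data.frame(deg[[nm]]), 10)
    cbind(contrast = nm, h[, c("gene", "estimate", "p", "q")])
  }))
  write_tsv(top10, file.path(outdir, "top_genes.tsv"))

  # -- panel screen + Monte-Carlo ------------------------------------
  panel <- if (is.null(config$panel)) circadian_panel()
           else read_panel(config$panel)
  screens <- list(); mc <- list()
  for (nm in names(deg)) {
    sc <- screen_panel(deg[[nm]], panel, alpha_unc = config$alpha_unc,
                       alpha_fdr = config$fdr_alpha)
    if (length(sc$missing))
      stage_log("panel", "%s: %d panel gene(s) missing from universe",
                nm, length(sc$missing))
    screens[[nm]] <- sc
    write_tsv(sc$table, file.path(outdir, paste0("panel_", nm, ".tsv")))
    mc[[nm]] <- montecarlo_set_test(
      deg[[nm]], panel, b_draws = config$b_draws,
      alpha_unc = config$alpha_unc, seed = config$seed
    )
  }
  mc_tab <- data.frame(
    contrast = names(mc),
    m = vapply(mc, `[[`, numeric(1), "m"),
    observed = vapply(mc, `[[`, numeric(1), "observed"),
    p_emp = vapply(mc, `[[`, numeric(1), "p_emp"),
    analytic_p = vapply(mc, `[[`, numeric(1), "analytic_p")
  )
  write_tsv(mc_tab, file.path(outdir, "panel_montecarlo.tsv"))

  # -- enrichment -----------------------------------------------------
  gsea <- list()
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt, exclude = config$exclude_sets)
    stage_log("gsea", "%d sets after exclusions", length(sets))
    for (nm in names(deg)) {
      ranked <- make_ranked_list(deg[[nm]])
      gsea[[nm]] <- gsea_preranked(ranked, sets, n_perm = config$n_perm,
                                   seed = config$seed)
      write_tsv(as.data.frame(gsea[[nm]]),
                file.path(outdir, paste0("gsea_", nm, ".tsv")))
    }

    # -- time-course gene-set analysis -------------------------------
    stage_log("tcgsa", "cohorts: %s", paste(config$cohorts, collapse = ", "))
    tc <- run_tcgsa_collection(study, sets, cohorts = config$cohorts,
                               alpha = config$fdr_alpha,
                               ref = config$tcgsa_ref, seed = config$seed)
    for (cohort in names(tc)) {
      write_tsv(tc[[cohort]]$table,
                file.path(outdir, paste0("tcgsa_", cohort, ".tsv")))
      if (length(tc[[cohort]]$excluded))
        stage_log("tcgsa", "%s: excluded non-converged set(s): %s", cohort,
                  paste(tc[[cohort]]$excluded, collapse = ", "))
      render_trend_heatmap(tc[[cohort]],
                           file.path(outdir, paste0("trends_", cohort, ".png")),
                           alpha = config$fdr_alpha)
    }
    manifest$stages$tcgsa <- lapply(tc, function(el)
      list(n_significant = el$n_significant, excluded = el$excluded))
  } else {
    tc <- NULL
    stage_log("gsea", "no GMT supplied; enrichment and time-course stages skipped")
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("report", "outputs written to %s", outdir)
  invisible(list(study = study, deg = deg, baseline = baseline,
                 counts = counts, screens = screens, mc = mc,
                 gsea = gsea, tcgsa = tc, manifest = manifest))
}

# Stable textual fingerprint of the analysis parameters (paths are
# excluded so runs into different directories remain comparable).
config_fingerprint <- function(config) {
  keep <- setdiff(names(config), c("expr", "meta", "gmt", "panel", "outdir"))
  txt <- paste(deparse(unclass(config)[keep]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}
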