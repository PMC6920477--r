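#' Cohort filters for longitudinal analyses
#'
#' @param study an [expression_study()].
#' @param cohort one of \code{"patients"}, \code{"controls"},
#'   \code{"responders"}, \code{"non_responders"}, \code{"all"}.
#' @return Logical vector over samples.
#' @keywords internal
cohort_mask <- function(study, cohort) {
  g <- study$samples$group
  switch(cohort,
         all = rep(TRUE, length(g)),
         patients = g != "control",
         controls = g == "control",
         responders = g == "responder",
         non_responders = g == "non_responder",
         stop("unknown cohort: ", cohort))
}

# Long-format stacked data for one gene set: per-gene z-scores over the
# cohort samples, with T3 protocol violators removed.
tcgsa_stack <- function(study, gene_set, cohort) {
  keep <- cohort_mask(study, cohort)
  keep <- keep & !(study$samples$timepoint == "T3" &
                     study$samples$protocol_violation)
  s <- study$samples[keep, , drop = FALSE]
  genes <- intersect(toupper(study$genes), unique(toupper(gene_set)))
  genes <- study$genes[toupper(study$genes) %in% genes]
  if (length(genes) < 1) stop("no set gene present in study")
  vals <- study$values[genes, keep, drop = FALSE]
  # standardize each gene over the analyzed cohort
  mu <- rowMeans(vals)
  sd_ <- apply(vals, 1, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- (vals - mu) / sd_
  d <- data.frame(
    value = as.vector(t(z)),
    gene = factor(rep(genes, each = nrow(s)), levels = genes),
    subject = factor(rep(s$subject_id, length(genes))),
    tp = factor(rep(s$timepoint, length(genes)), levels = TIMEPOINTS),
    stringsAsFactors = FALSE
  )
  d$tp2 <- as.numeric(d$tp == "T2")
  d$tp3 <- as.numeric(d$tp == "T3")
  list(data = d, genes = genes, samples = s, z = z)
}

#' Time-course likelihood-ratio test for one gene set
#'
#' Tests whether a gene set's expression changes over the three
#' timepoints, accounting for between-gene and between-subject
#' variability. Member genes are standardized (per-gene z-score over the
#' analyzed cohort) and stacked; the null model has gene-specific
#' intercepts and a subject random intercept, and the alternative adds
#' fixed timepoint effects plus gene-specific random time deviations
#' (independent variance components for T2 and T3). Both models are
#' fitted by maximum likelihood and compared by likelihood ratio.
#'
#' The reference distribution for the statistic is configurable:
#' \code{"chisq"} refers it to chi-square with df = 2 (the added fixed
#' effects), \code{"mixture"} to an equal mixture of chi-square(2) and
#' chi-square(4) acknowledging the two boundary variance components, and
#' \code{"perm"} to a within-subject timepoint-permutation null.
#'
#' @param study an [expression_study()].
#' @param gene_set character vector of member gene symbols.
#' @param cohort cohort label (see [cohort_mask()]); samples from T3
#'   flagged as protocol violations are always excluded.
#' @param ref reference distribution: \code{"chisq"} (default),
#'   \code{"mixture"}, or \code{"perm"}.
#' @param n_perm permutations when \code{ref = "perm"}.
#' @param n_clusters maximum number of trend clusters to extract.
#' @param seed seed for the permutation reference.
#' @return Object of class \code{trajectory_result}: list with
#'   \code{set}, \code{lrt_stat}, \code{df}, \code{p}, \code{q}
#'   (\code{NA} until adjusted collection-wide), \code{converged},
#'   \code{n_genes_used}, \code{cohort}, \code{ref} and \code{trends}
#'   (a [extract_trends()] matrix). Fit failures yield
#'   \code{converged = FALSE} with no p-value, never an error.
#' @export
tcgsa_lrt <- function(study, gene_set, cohort = "patients",
                      ref = c("chisq", "mixture", "perm"),
                      n_perm = 200, n_clusters = 5, seed = 1L) {
  ref <- match.arg(ref)
  res <- structure(
    list(set = attr(gene_set, "set_name") %||% "gene_set",
         lrt_stat = NA_real_, df = 2L, p = NA_real_, q = NA_real_,
         converged = FALSE, n_genes_used = 0L, cohort = cohort, ref = ref,
         trends = NULL),
    class = "trajectory_result"
  )
  stk <- tryCatch(tcgsa_stack(study, gene_set, cohort), error = function(e) NULL)
  if (is.null(stk)) return(res)
  res$n_genes_used <- length(stk$genes)
  if (length(stk$genes) < 2 || length(unique(stk$data$subject)) < 3)
    return(res)

  lrt <- tryCatch(tcgsa_fit_lrt(stk$data), error = function(e) NULL)
  if (is.null(lrt) || !is.finite(lrt)) return(res)
  res$lrt_stat <- max(lrt, 0)
  res$converged <- TRUE
  res$p <- switch(
    ref,
    chisq = stats::pchisq(res$lrt_stat, df = 2, lower.tail = FALSE),
    mixture = 0.5 * stats::pchisq(res$lrt_stat, df = 2, lower.tail = FALSE) +
              0.5 * stats::pchisq(res$lrt_stat, df = 4, lower.tail = FALSE),
    perm = tcgsa_perm_p(stk$data, res$lrt_stat, n_perm, seed)
  )
  res$trends <- tryCatch(
    extract_trends(study, gene_set, cohort, n_clusters = n_clusters),
    error = function(e) NULL
  )
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tcgsa_fit_lrt <- function(d) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  f0 <- value ~ 0 + gene + (1 | subject)
  f1 <- value ~ 0 + gene + tp + (1 | subject) +
    (0 + tp2 | gene) + (0 + tp3 | gene)
  m0 <- suppressMessages(suppressWarnings(
    lme4::lmer(f0, data = d, REML = FALSE, control = ctrl)))
  m1 <- suppressMessages(suppressWarnings(
    lme4::lmer(f1, data = d, REML = FALSE, control = ctrl)))
  2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0)))
}

# Within-subject permutation null: timepoint labels are shuffled across
# each subject's visits, which preserves subject and gene structure while
# destroying any time trend.
tcgsa_perm_p <- function(d, observed, n_perm, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  # permute at the (subject, timepoint) visit level, identically for all
  # genes of the stack
  visits <- unique(d[, c("subject", "tp")])
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm_tp <- visits$tp
    for (subj in unique(visits$subject)) {
      i <- which(visits$subject == subj)
      perm_tp[i] <- visits$tp[i][sample.int(length(i))]
    }
    key <- paste(d$subject, d$tp)
    new_tp <- perm_tp[match(key, paste(visits$subject, visits$tp))]
    dp <- d
    dp$tp <- factor(new_tp, levels = TIMEPOINTS)
    dp$tp2 <- as.numeric(dp$tp == "T2")
    dp$tp3 <- as.numeric(dp$tp == "T3")
    stat <- tryCatch(tcgsa_fit_lrt(dp), error = function(e) NA_real_)
    if (is.finite(stat) && stat >= observed) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("trajectory_result [", x$set, "] cohort:", x$cohort, "\n")
  if (!x$converged) {
    cat("model did not converge; set excluded from inference\n")
  } else {
    cat(sprintf("LRT = %.3f, ref = %s, p = %.4g%s, genes used = %d\n",
                x$lrt_stat, x$ref, x$p,
                if (is.na(x$q)) "" else sprintf(", q = %.4g", x$q),
                x$n_genes_used))
  }
  invisible(x)
}

#' Run time-course gene-set analysis over a collection
#'
#' Applies [tcgsa_lrt()] to every set of a collection, separately per
#' cohort, adjusts p-values within cohort across converged sets by
#' Benjamini-Hochberg, and reports non-converging sets as excluded.
#'
#' @param study an [expression_study()].
#' @param sets a [gene_set_collection()].
#' @param cohorts character vector drawn from \code{"patients"},
#'   \code{"controls"}, \code{"responders"}, \code{"non_responders"}.
#' @param alpha FDR threshold for the significance summary.
#' @param ... passed to [tcgsa_lrt()].
#' @return Named list (one element per cohort) of class
#'   \code{tcgsa_results}; each element is a list with \code{results}
#'   (per-set \code{trajectory_result}s), \code{table} (per-set summary
#'   data.frame), \code{excluded} (non-converged set names) and
#'   \code{n_significant}.
#' @export
run_tcgsa_collection <- function(study, sets, cohorts = "patients",
                                 alpha = 0.05, ...) {
  stopifnot(inherits(sets, "gene_set_collection"))
  known <- c("patients", "controls", "responders", "non_responders")
  bad <- setdiff(cohorts, known)
  if (length(bad)) stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (cohort in cohorts) {
    if (!any(cohort_mask(study, cohort)))
      stop("cohort has no samples: ", cohort)
    results <- list()
    for (nm in names(sets$sets)) {
      gs <- sets$sets[[nm]]
      attr(gs, "set_name") <- nm
      results[[nm]] <- tcgsa_lrt(study, gs, cohort = cohort, ...)
    }
    conv <- vapply(results, function(r) r$converged, logical(1))
    pvals <- vapply(results, function(r) r$p %||% NA_real_, numeric(1))
    qvals <- rep(NA_real_, length(results))
    if (any(conv)) qvals[conv] <- bh_fdr(pvals[conv])
    for (i in seq_along(results)) results[[i]]$q <- qvals[i]
    tab <- data.frame(
      set = names(results),
      lrt_stat = vapply(results, function(r) r$lrt_stat, numeric(1)),
      p = pvals, q = qvals, converged = conv,
      n_genes_used = vapply(results, function(r) r$n_genes_used, integer(1)),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(!tab$converged, tab$p, tab$set), , drop = FALSE]
    rownames(tab) <- NULL
    out[[cohort]] <- list(
      cohort = cohort, results = results, table = tab,
      excluded = names(results)[!conv],
      n_significant = sum(conv & !is.na(qvals) & qvals < alpha),
      alpha = alpha
    )
  }
  structure(out, class = "tcgsa_results")
}

#' @export
print.tcgsa_results <- function(x, ...) {
  for (cohort in names(x)) {
    el <- x[[cohort]]
    cat(sprintf("[%s] %d/%d sets significant at q < %.3g; excluded: %s\n",
                cohort, el$n_significant, nrow(el$table), el$alpha,
                if (length(el$excluded)) paste(el$excluded, collapse = ", ")
                else "none"))
  }
  invisible(x)
}

#' Extract per-set expression trends
#'
#' For each member gene, computes the median standardized expression
#' over the cohort's subjects at each timepoint, anchored to zero at T1,
#' then groups genes into trends by agglomerative hierarchical
#' clustering (Euclidean distance, complete linkage) of the trend
#' vectors. Each trend row is the within-cluster median trajectory.
#'
#' @param study an [expression_study()].
#' @param gene_set character vector of member symbols.
#' @param cohort cohort label.
#' @param n_clusters maximum number of trends (clusters); the effective
#'   number never exceeds the gene count.
#' @return Object of class \code{trend_matrix}: a clusters-by-timepoints
#'   numeric matrix (first column exactly zero) with attribute
#'   \code{membership}, a named list mapping each row to its genes.
#' @export
extract_trends <- function(study, gene_set, cohort = "patients",
                           n_clusters = 5) {
  stk <- tcgsa_stack(study, gene_set, cohort)
  z <- stk$z
  s <- stk$samples
  gene_trend <- t(vapply(
    rownames(z),
    function(g) {
      med <- vapply(TIMEPOINTS,
                    function(tp) stats::median(z[g, s$timepoint == tp]),
                    numeric(1))
      med - med[1]
    },
    numeric(3)
  ))
  colnames(gene_trend) <- TIMEPOINTS
  k <- max(1L, min(n_clusters, nrow(gene_trend)))
  if (nrow(gene_trend) == 1 || k == 1) {
    cl <- rep(1L, nrow(gene_trend))
  } else {
    hc <- stats::hclust(stats::dist(gene_trend), method = "complete")
    cl <- stats::cutree(hc, k = k)
  }
  trends <- t(vapply(
    sort(unique(cl)),
    function(ci) apply(gene_trend[cl == ci, , drop = FALSE], 2, stats::median),
    numeric(3)
  ))
  colnames(trends) <- TIMEPOINTS
  rownames(trends) <- paste0("trend", sort(unique(cl)))
  membership <- split(rownames(gene_trend), cl)
  names(membership) <- rownames(trends)
  structure(trends, membership = membership, cohort = cohort,
            class = c("trend_matrix", "matrix"))
}

#' Render a trend heatmap
#'
#' Draws the trend rows of all significant, converged sets of one cohort
#' as a heatmap: rows are trends (hierarchically ordered), columns are
#' timepoints, and a diverging palette runs blue (downregulated relative
#' to T1) through white to red (upregulated). Sets can be excluded from
#' visualization (e.g. for non-homogeneous within-set expression).
#'
#' @param cohort_result one element of a [run_tcgsa_collection()] result.
#' @param out_path output PNG path.
#' @param alpha significance threshold on q.
#' @param exclude set names to leave out of the drawing.
#' @param width,height device size in pixels.
#' @return Invisibly, the matrix that was drawn (or \code{NULL} when
#'   nothing was significant, in which case a placeholder is written and
#'   a warning raised).
#' @export
render_trend_heatmap <- function(cohort_result, out_path, alpha = 0.05,
                                 exclude = character(),
                                 width = 640, height = 640) {
  tab <- cohort_result$table
  sig <- tab$set[tab$converged & !is.na(tab$q) & tab$q < alpha]
  sig <- setdiff(sig, exclude)
  rows <- list()
  for (nm in sig) {
    tr <- cohort_result$results[[nm]]$trends
    if (is.null(tr)) next
    m <- unclass(tr)
    rownames(m) <- paste(nm, rownames(m), sep = ":")
    rows[[nm]] <- m
  }
  if (!length(rows)) {
    warning("no significant converged set to draw; writing placeholder")
    grDevices::png(out_path, width = width, height = height)
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no significant gene set")
    grDevices::dev.off()
    return(invisible(NULL))
  }
  mat <- do.call(rbind, rows)
  ord <- if (nrow(mat) > 1)
    stats::hclust(stats::dist(mat), method = "complete")$order
  else 1L
  mat <- mat[ord, , drop = FALSE]
  lim <- max(abs(mat), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  grDevices::png(out_path, width = width, height = height)
  old <- graphics::par(mar = c(4, 10, 2, 1))
  graphics::image(
    x = seq_len(ncol(mat)), y = seq_len(nrow(mat)), z = t(mat),
    zlim = c(-lim, lim), col = pal, axes = FALSE, xlab = "timepoint",
    ylab = "", main = paste("trend dynamics -", cohort_result$cohort)
  )
  graphics::axis(1, at = seq_len(ncol(mat)), labels = colnames(mat))
  graphics::axis(2, at = seq_len(nrow(mat)), labels = rownames(mat),
                 las = 2, cex.axis = 0.6)
  graphics::par(old)
  grDevices::dev.off()
  invisible(mat)
}
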