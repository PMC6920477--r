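#' Build a signed -log10(p) ranked list
#'
#' Each gene's score is \code{direction * -log10(p)}: magnitude reflects
#' evidence strength, sign reflects direction of expression change.
#' p-values are floored at the smallest positive double before the log;
#' ties in score are broken deterministically by gene symbol.
#'
#' @param results a \code{deg_results} data.frame (see
#'   [run_transcriptome()]); rows with \code{converged = FALSE} are
#'   dropped with a message.
#' @return data.frame of class \code{ranked_list} with columns
#'   \code{gene} and \code{score}, sorted by score descending.
#' @export
make_ranked_list <- function(results) {
  stopifnot(is.data.frame(results), all(c("gene", "p") %in% names(results)))
  if ("converged" %in% names(results) && any(!results$converged)) {
    message("dropping ", sum(!results$converged),
            " non-converged gene(s) from ranked list")
    results <- results[results$converged, , drop = FALSE]
  }
  if (!nrow(results)) stop("no usable results to rank")
  if (anyDuplicated(results$gene))
    stop("duplicate genes in results: ",
         paste(unique(results$gene[duplicated(results$gene)]), collapse = ", "))
  p <- pmax(results$p, .Machine$double.xmin)
  dir <- if ("direction" %in% names(results)) results$direction
         else sign(results$estimate)
  score <- dir * (-log10(p))
  ord <- order(-score, results$gene)
  out <- data.frame(gene = toupper(results$gene[ord]), score = score[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"))
}

# Weighted Kolmogorov-Smirnov-style running sum for one set of hit
# positions (indices into the ranked list). Returns the signed maximum
# deviation. Hits advance by |score|^weight (normalized); misses retreat
# by 1/(N - m).
running_sum_es <- function(scores, hit_idx, weight) {
  N <- length(scores)
  m <- length(hit_idx)
  inc <- abs(scores[hit_idx])^weight
  tot <- sum(inc)
  if (tot == 0) inc[] <- 1 / m else inc <- inc / tot
  step <- rep(-1 / (N - m), N)
  step[hit_idx] <- inc
  rs <- cumsum(step)
  peak <- which.max(abs(rs))
  rs[peak]
}

#' Preranked gene-set enrichment analysis
#'
#' From-scratch weighted running-sum enrichment over a signed ranked
#' list. For each gene set the enrichment score (ES) is the maximum
#' deviation of a running sum that increments at member genes by
#' \code{|score|^weight} (normalized to sum 1) and decrements at
#' non-members by \code{1/(N - m)}. The null distribution comes from
#' gene-label permutations of set membership: random same-size gene sets
#' drawn from the list. The normalized enrichment score (NES) divides ES
#' by the mean |null ES| of matching sign, the permutation p-value is
#' one-sided within sign, and FDR q follows the positive/negative
#' pooled-null convention; a within-direction Benjamini-Hochberg
#' adjustment of the permutation p-values is reported alongside as
#' \code{q_bh}.
#'
#' @param ranked a [make_ranked_list()] result or data.frame with
#'   \code{gene}, \code{score}.
#' @param sets a [gene_set_collection()].
#' @param n_perm number of membership permutations (>= 100).
#' @param weight running-sum weight exponent (0 = classic KS, default 1).
#' @param seed integer seed for the permutation draw.
#' @param min_size sets with fewer overlapping genes are skipped.
#' @return data.frame of class \code{gsea_results}: \code{set},
#'   \code{n_members_in_list}, \code{es}, \code{nes}, \code{p_perm},
#'   \code{q}, \code{q_bh}, sorted by p then |nes| descending.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight = 1,
                           seed = 1L, min_size = 1L) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  stopifnot(inherits(sets, "gene_set_collection"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  genes <- toupper(ranked$gene)
  if (anyDuplicated(genes)) stop("ranked list has duplicate genes")
  scores <- ranked$score
  if (any(!is.finite(scores))) stop("ranked scores must be finite")
  N <- length(genes)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  overlap <- lapply(sets$sets, function(g) which(genes %in% g))
  sizes <- lengths(overlap)
  full <- names(sets$sets)[sizes >= N]
  if (length(full))
    warning("set(s) covering the whole list skipped: ",
            paste(full, collapse = ", "))
  keep <- sizes >= min_size & sizes < N
  overlap <- overlap[keep]
  sizes <- sizes[keep]
  if (!length(overlap)) stop("no gene set overlaps the ranked list")

  es <- vapply(overlap, running_sum_es, numeric(1),
               scores = scores, weight = weight)

  # one null ES matrix per distinct set size
  null_by_size <- new.env(parent = emptyenv())
  for (m in sort(unique(sizes))) {
    nm <- as.character(m)
    null_by_size[[nm]] <- vapply(
      seq_len(n_perm),
      function(b) running_sum_es(scores, sort(sample.int(N, m)), weight),
      numeric(1)
    )
  }

  p_perm <- nes <- numeric(length(es))
  null_nes_pos <- null_nes_neg <- list()
  for (i in seq_along(es)) {
    nulls <- null_by_size[[as.character(sizes[i])]]
    pos <- nulls[nulls >= 0]
    neg <- nulls[nulls < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (es[i] >= 0) {
      p_perm[i] <- (sum(pos >= es[i]) + 1) / (length(pos) + 1)
      nes[i] <- if (is.na(mean_pos)) NA_real_ else es[i] / mean_pos
    } else {
      p_perm[i] <- (sum(neg <= es[i]) + 1) / (length(neg) + 1)
      nes[i] <- if (is.na(mean_neg)) NA_real_ else -abs(es[i]) / mean_neg
    }
    null_nes_pos[[i]] <- if (!is.na(mean_pos)) pos / mean_pos else numeric(0)
    null_nes_neg[[i]] <- if (!is.na(mean_neg)) neg / mean_neg else numeric(0)
  }

  # classical pooled-null FDR on NES
  pool_pos <- unlist(null_nes_pos)
  pool_neg <- unlist(null_nes_neg)
  obs_pos <- nes[nes >= 0 & !is.na(nes)]
  obs_neg <- nes[nes < 0 & !is.na(nes)]
  q <- rep(NA_real_, length(es))
  for (i in seq_along(es)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      null_frac <- if (length(pool_pos)) mean(pool_pos >= nes[i]) else 0
      obs_frac <- mean(obs_pos >= nes[i])
    } else {
      null_frac <- if (length(pool_neg)) mean(pool_neg <= nes[i]) else 0
      obs_frac <- mean(obs_neg <= nes[i])
    }
    q[i] <- min(1, null_frac / max(obs_frac, 1 / length(es)))
  }
  q_bh <- rep(NA_real_, length(es))
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & (if (sgn > 0) nes >= 0 else nes < 0))
    if (length(idx)) q_bh[idx] <- bh_fdr(p_perm[idx])
  }

  out <- data.frame(
    set = names(overlap), n_members_in_list = unname(sizes),
    es = unname(es), nes = unname(nes), p_perm = unname(p_perm),
    q = unname(q), q_bh = unname(q_bh), stringsAsFactors = FALSE
  )
  out <- out[order(out$p_perm, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gsea_results", "data.frame"),
            n_perm = n_perm, weight = weight, seed = seed)
}

#' @export
print.gsea_results <- function(x, n = 10, ...) {
  cat("gsea_results:", nrow(x), "sets,", attr(x, "n_perm"),
      "permutations, weight", attr(x, "weight"), "\n")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Monte-Carlo over-representation test for a gene panel
#'
#' Estimates the probability of observing at least as many nominally
#' significant genes (uncorrected p below \code{alpha_unc}) in a random
#' gene set of the same size as the panel, drawing sets without
#' replacement from the analyzed universe. Because the draw is without
#' replacement the exact null is hypergeometric; the analytic upper tail
#' is always reported alongside the empirical estimate as a cross-check.
#'
#' @param results a \code{deg_results} data.frame (the analyzed
#'   universe).
#' @param panel character vector of gene symbols; members absent from
#'   the universe are dropped with a warning.
#' @param b_draws Monte-Carlo iterations (>= 1000).
#' @param alpha_unc uncorrected significance threshold in (0, 1).
#' @param seed integer seed.
#' @return Object of class \code{mc_set_test}: list with \code{m}
#'   (panel size used), \code{observed}, \code{b_draws}, \code{exceed},
#'   \code{p_emp} = (exceed + 1) / (b_draws + 1), \code{analytic_p}
#'   (hypergeometric tail), \code{alpha_unc}, \code{n_universe},
#'   \code{k_significant} and \code{missing} genes.
#' @export
montecarlo_set_test <- function(results, panel, b_draws = 10000,
                                alpha_unc = 0.05, seed = 1L) {
  stopifnot(is.data.frame(results), all(c("gene", "p") %in% names(results)))
  if (b_draws < 1000) stop("b_draws must be at least 1000")
  if (alpha_unc <= 0 || alpha_unc >= 1) stop("alpha_unc must be in (0, 1)")
  universe <- toupper(results$gene)
  panel <- unique(toupper(panel))
  missing <- setdiff(panel, universe)
  if (length(missing))
    warning("panel gene(s) absent from results: ",
            paste(missing, collapse = ", "))
  panel <- setdiff(panel, missing)
  m <- length(panel)
  if (m == 0) stop("no panel gene present in the results universe")

  sig <- results$p < alpha_unc
  N <- length(universe)
  K <- sum(sig)
  observed <- sum(sig[universe %in% panel])

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  draws <- vapply(seq_len(b_draws),
                  function(b) sum(sig[sample.int(N, m)]), integer(1))
  exceed <- sum(draws >= observed)
  structure(
    list(m = m, observed = observed, b_draws = b_draws, exceed = exceed,
         p_emp = (exceed + 1) / (b_draws + 1),
         analytic_p = stats::phyper(observed - 1, K, N - K, m,
                                    lower.tail = FALSE),
         alpha_unc = alpha_unc, n_universe = N, k_significant = K,
         missing = missing),
    class = "mc_set_test"
  )
}

#' @export
print.mc_set_test <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo panel test: %d of %d panel genes at p < %.3g\n",
    x$observed, x$m, x$alpha_unc))
  cat(sprintf("universe %d genes (%d significant); %d draws\n",
              x$n_universe, x$k_significant, x$b_draws))
  cat(sprintf("empirical p = %.4g (analytic hypergeometric p = %.4g)\n",
              x$p_emp, x$analytic_p))
  if (length(x$missing))
    cat("panel genes not in universe:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Screen a gene panel against contrast results
#'
#' Restricts a results table to a target panel, annotating direction and
#' both uncorrected and FDR significance flags, in the reporting style of
#' a targeted-panel table.
#'
#' @param results a \code{deg_results} data.frame.
#' @param panel character vector of gene symbols.
#' @param alpha_unc uncorrected threshold for the nominal flag.
#' @param alpha_fdr q-value threshold for the FDR flag.
#' @return List of class \code{panel_screen} with \code{table} (one row
#'   per panel gene found, ordered as the panel) and \code{missing}
#'   (panel genes absent from the results).
#' @export
screen_panel <- function(results, panel, alpha_unc = 0.05, alpha_fdr = 0.05) {
  stopifnot(is.data.frame(results), all(c("gene", "p", "q") %in% names(results)))
  panel <- unique(toupper(panel))
  universe <- toupper(results$gene)
  idx <- match(panel, universe)
  missing <- panel[is.na(idx)]
  found <- panel[!is.na(idx)]
  tab <- results[idx[!is.na(idx)], , drop = FALSE]
  tab <- as.data.frame(tab)
  tab$gene <- found
  tab$regulation <- ifelse(tab$direction > 0, "up",
                           ifelse(tab$direction < 0, "down", "none"))
  tab$sig_unc <- tab$p < alpha_unc
  tab$sig_fdr <- !is.na(tab$q) & tab$q < alpha_fdr
  rownames(tab) <- NULL
  structure(list(table = tab, missing = missing,
                 alpha_unc = alpha_unc, alpha_fdr = alpha_fdr),
            class = "panel_screen")
}

#' @export
print.panel_screen <- function(x, ...) {
  cat("panel screen:", nrow(x$table), "genes found,",
      length(x$missing), "missing\n")
  cat(sprintf("nominal p < %.3g: %d;  FDR q < %.3g: %d\n",
              x$alpha_unc, sum(x$table$sig_unc),
              x$alpha_fdr, sum(x$table$sig_fdr)))
  print(x$table[, intersect(c("gene", "estimate", "p", "q", "regulation",
                              "sig_unc", "sig_fdr"), names(x$table))])
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
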