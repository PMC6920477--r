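# Shared fixtures and independent oracles. Oracles are deliberately
# naive re-implementations, kept separate from the package code paths
# they check.

# -- tiny studies -----------------------------------------------------

# paired two-timepoint study, one group, optional per-gene shift at T2
make_paired_study <- function(n_subjects, n_genes = 1, shift_t2 = 0,
                              group = "responder", sigma_u = 0.7,
                              sigma_e = 0.5, seed = 1) {
  set.seed(seed)
  subj <- sprintf("S%03d", seq_len(n_subjects))
  samples <- data.frame(
    sample_id = c(paste0(subj, "_T1"), paste0(subj, "_T2")),
    subject_id = rep(subj, 2),
    timepoint = rep(c("T1", "T2"), each = n_subjects),
    group = group,
    age = rep(runif(n_subjects, 20, 70), 2),
    sex = rep(sample(c("M", "F"), n_subjects, TRUE), 2),
    protocol_violation = FALSE,
    stringsAsFactors = FALSE
  )
  shift <- rep_len(shift_t2, n_genes)
  u <- rnorm(n_subjects, 0, sigma_u)
  vals <- t(vapply(seq_len(n_genes), function(g) {
    rep(u, 2) + shift[g] * (samples$timepoint == "T2") +
      rnorm(2 * n_subjects, 0, sigma_e)
  }, numeric(2 * n_subjects)))
  rownames(vals) <- sprintf("G%04d", seq_len(n_genes))
  colnames(vals) <- samples$sample_id
  expression_study(vals, samples)
}

# hand-built three-timepoint study from an explicit value array
make_manual_study <- function(values, subjects, timepoints,
                              group = "responder") {
  samples <- data.frame(
    sample_id = paste(subjects, timepoints, sep = "_"),
    subject_id = subjects, timepoint = timepoints, group = group,
    age = 40, sex = "M", protocol_violation = FALSE,
    stringsAsFactors = FALSE
  )
  colnames(values) <- samples$sample_id
  expression_study(values, samples)
}

# synthetic 50-set collection shaped like a curated hallmark-style
# collection, including a heme-metabolism set for exclusion tests
make_hallmark_like <- function(universe, n_sets = 50, size = 15, seed = 99) {
  set.seed(seed)
  nms <- c("HALLMARK_HEME_METABOLISM",
           sprintf("HALLMARK_SET_%02d", seq_len(n_sets - 1)))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, min(size, length(universe) - 1)))
  names(sets) <- nms
  gene_set_collection(sets, source = "synthetic hallmark-like fixture")
}

# deg-results-shaped table built directly from chosen p-values
make_results_table <- function(p, genes = sprintf("G%05d", seq_along(p)),
                               direction = NULL) {
  if (is.null(direction)) direction <- rep(1L, length(p))
  data.frame(gene = genes, estimate = direction * 1,
             lrt_stat = 1, df = 1L, p = p, q = p, direction = direction,
             converged = TRUE, stringsAsFactors = FALSE)
}

# -- independent oracles ----------------------------------------------

# brute-force step-up BH: sort, scale, running minimum from the top
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(scaled)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force weighted running-sum enrichment score, written as an
# explicit position-by-position loop
oracle_es <- function(scores, member, weight) {
  N <- length(scores)
  hits <- which(member)
  nr <- sum(abs(scores[hits])^weight)
  rs <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (member[i]) {
      rs <- rs + if (nr == 0) 1 / length(hits) else abs(scores[i])^weight / nr
    } else {
      rs <- rs - 1 / (N - length(hits))
    }
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Closed-form ML likelihood-ratio statistic for a time effect on
# balanced paired data. The likelihood factorizes into the per-subject
# difference space (which carries the time effect) and the sum space
# (which carries intercept and subject-constant covariates): when the
# between-subject variance estimate is interior the statistic is
# n * log(1 + t^2/(n-1)) with t the paired t-statistic; when it hits the
# sigma_u = 0 boundary the model collapses to a common variance and the
# profile log-likelihood changes branch. Both branches are evaluated
# exactly per model.
oracle_paired_lrt_p <- function(study, gene = study$genes[1]) {
  s <- study$samples
  y <- study$values[gene, ]
  subj <- unique(s$subject_id)
  n <- length(subj)
  y1 <- y[paste0(subj, "_T1")]
  y2 <- y[paste0(subj, "_T2")]
  d <- (y2 - y1) / sqrt(2)
  sm <- (y2 + y1) / sqrt(2)
  meta <- s[match(subj, s$subject_id), ]
  Xs <- cbind(1, meta$age, as.numeric(meta$sex == "F"))
  ssb <- sum(stats::lm.fit(Xs, sm)$residuals^2)
  B <- ssb / n
  A1 <- sum((d - mean(d))^2) / n # h1: difference mean free
  A0 <- sum(d^2) / n             # h0: difference mean zero
  loglik <- function(A) {
    if (B >= A) -(n / 2) * (log(A) + log(B)) - n
    else -n * log((A + B) / 2) - n
  }
  lrt <- 2 * (loglik(A1) - loglik(A0))
  pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
}

expect_file_md5_equal <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}

# small but complete pipeline configuration used by the end-to-end tests
small_pipeline_config <- function(outdir, seed = 5) {
  part <- matrix(c(14L, 14L, 12L, 8L, 8L, 7L, 6L, 6L, 6L), nrow = 3,
                 byrow = TRUE)
  genes <- c(circadian_panel(), sprintf("G%03d", 1:37)) # 60 genes
  sets <- gene_set_collection(list(
    CIRCADIAN = circadian_panel(),
    BLOCK_A = sprintf("G%03d", 1:15),
    BLOCK_B = sprintf("G%03d", 16:30)
  ))
  gmt <- file.path(outdir, "sets.gmt")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(sets, gmt)
  sim <- sim_config(
    n_genes = length(genes), gene_names = genes, participation = part,
    gene_sets = sets, seed = seed,
    effects = list(
      effect_spec("set_coherent_trajectory", set_name = "BLOCK_A",
                  magnitude = 1, timepoint_profile = c(0, 0, 1)),
      effect_spec("time_main", genes = circadian_panel()[1:8],
                  magnitude = 0.9, timepoint_profile = c(0, 1, 0.3))
    )
  )
  pipeline_config(simulate = sim, gmt = gmt,
                  outdir = file.path(outdir, "run"),
                  n_perm = 200, b_draws = 1000, seed = seed,
                  cohorts = "patients")
}
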