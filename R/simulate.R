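#' Default per-group participation pattern
#'
#' Participation counts per group and timepoint for the study design the
#' simulator emulates: 60 responders (60/56/53 across T1/T2/T3), 16
#' non-responders (16/16/13) and 15 controls with complete follow-up,
#' i.e. 91 samples at T1 and 259 samples in total.
#'
#' @return 3x3 integer matrix, rows \code{responder}, \code{non_responder},
#'   \code{control}; columns \code{T1}, \code{T2}, \code{T3}.
#' @export
default_participation <- function() {
  matrix(c(60L, 56L, 53L,
           16L, 16L, 13L,
           15L, 15L, 15L),
         nrow = 3, byrow = TRUE,
         dimnames = list(GROUPS, TIMEPOINTS))
}

#' Specify an injected effect for the simulator
#'
#' @param kind one of \code{"time_main"} (change over timepoints shared by
#'   the restricted cohort), \code{"group_by_time"} (change confined to
#'   one comparison group, i.e. a group-by-time interaction),
#'   \code{"baseline_shift"} (constant offset at every timepoint for one
#'   group) or \code{"set_coherent_trajectory"} (a \code{time_main}
#'   profile shared coherently by all genes of one gene set).
#' @param genes character vector of target gene symbols, or \code{NULL}
#'   when \code{set_name} is given.
#' @param set_name name of a gene set in the collection supplied to
#'   [sim_config()]; resolved to its member genes before sampling.
#' @param magnitude effect size in log-intensity units; scales
#'   \code{timepoint_profile}.
#' @param timepoint_profile numeric length-3 multiplier per timepoint;
#'   must be 0 at T1 (T1 anchors baseline). Ignored for
#'   \code{baseline_shift}.
#' @param group_restriction \code{NULL} (patients), one of
#'   \code{"responder"}, \code{"non_responder"}, \code{"control"},
#'   \code{"patients"}, or \code{"all"}.
#' @return An object of class \code{effect_spec}.
#' @export
effect_spec <- function(kind = c("time_main", "group_by_time",
                                 "baseline_shift", "set_coherent_trajectory"),
                        genes = NULL, set_name = NULL, magnitude = 1,
                        timepoint_profile = c(0, 1, 1),
                        group_restriction = NULL) {
  kind <- match.arg(kind)
  if (is.null(genes) && is.null(set_name))
    stop("effect_spec needs `genes` or `set_name`")
  if (kind != "baseline_shift") {
    if (length(timepoint_profile) != 3)
      stop("timepoint_profile must have one value per timepoint (T1, T2, T3)")
    if (timepoint_profile[1] != 0)
      stop("timepoint_profile must be zero at T1")
  }
  if (kind == "group_by_time" && is.null(group_restriction))
    stop("group_by_time effects need a group_restriction")
  if (!is.null(group_restriction) &&
      !group_restriction %in% c(GROUPS, "patients", "all"))
    stop("unknown group_restriction: ", group_restriction)
  structure(
    list(kind = kind, genes = genes, set_name = set_name,
         magnitude = magnitude, timepoint_profile = timepoint_profile,
         group_restriction = group_restriction),
    class = "effect_spec"
  )
}

#' Simulation configuration
#'
#' Collects every knob of the generative model:
#' \deqn{y_{gij} = b_g + u_i + \beta_{age,g}\,age_i + \beta_{sex,g}\,1[F_i]
#'   + \sum_k e_{k}(g, i, j) + \varepsilon_{gij}}
#' with subject intercepts \eqn{u_i \sim N(0, \sigma_u^2)} and residuals
#' \eqn{\varepsilon \sim N(0, \sigma_e^2)}, all on the log-intensity
#' scale. Defaults mirror the emulated study: the participation pattern of
#' [default_participation()], patient ages ~ N(43.5, 14.8^2) and control
#' ages ~ N(40.5, 15.9^2) truncated to [18, 80], sex counts per group as
#' observed (36M/24F responders, 7M/9F non-responders, 7M/8F controls),
#' and two protocol-violating patients flagged at T3.
#'
#' @param n_genes number of genes.
#' @param participation integer matrix as in [default_participation()];
#'   row maxima define group sizes.
#' @param baseline_mean,baseline_sd scalars: per-gene baselines are drawn
#'   N(baseline_mean, baseline_sd^2); or give \code{baseline_mean} as a
#'   length-\code{n_genes} vector to fix them.
#' @param subject_intercept_sd,residual_sd sigma_u and sigma_e
#'   (log-intensity units, > 0).
#' @param age_effect,sex_effect scalar or per-gene slopes (per year of
#'   age; additive shift for sex F).
#' @param effects list of [effect_spec()] objects.
#' @param gene_sets optional [gene_set_collection()] used to resolve
#'   \code{set_name} targets.
#' @param gene_names optional character vector of gene symbols (default
#'   \code{G00001...}).
#' @param n_protocol_violators number of patients whose T3 sample is
#'   flagged as a recovery-protocol violation.
#' @param seed integer seed; the same config and seed reproduce the study
#'   bitwise.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       participation = default_participation(),
                       baseline_mean = 7, baseline_sd = 1.5,
                       subject_intercept_sd = 0.5, residual_sd = 0.5,
                       age_effect = 0, sex_effect = 0,
                       effects = list(),
                       gene_sets = NULL,
                       gene_names = NULL,
                       n_protocol_violators = 2,
                       seed = 1L) {
  stopifnot(n_genes >= 1, subject_intercept_sd > 0, residual_sd > 0)
  participation <- as.matrix(participation)
  if (!all(dim(participation) == c(3, 3)))
    stop("participation must be a 3x3 matrix (groups x timepoints)")
  dimnames(participation) <- list(GROUPS, TIMEPOINTS)
  if (any(participation < 0))
    stop("participation counts must be non-negative")
  if (is.null(gene_names)) {
    gene_names <- sprintf("G%05d", seq_len(n_genes))
  } else if (length(gene_names) != n_genes || anyDuplicated(gene_names)) {
    stop("gene_names must be ", n_genes, " unique symbols")
  }
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
    tg <- resolve_effect_genes(e, gene_sets)
    unknown <- setdiff(tg, gene_names)
    if (length(unknown))
      stop("effect targets unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  structure(
    list(n_genes = n_genes, participation = participation,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         subject_intercept_sd = subject_intercept_sd,
         residual_sd = residual_sd,
         age_effect = age_effect, sex_effect = sex_effect,
         effects = effects, gene_sets = gene_sets,
         gene_names = gene_names,
         n_protocol_violators = n_protocol_violators,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

resolve_effect_genes <- function(effect, gene_sets) {
  if (!is.null(effect$genes)) return(toupper(effect$genes))
  if (is.null(gene_sets) || !effect$set_name %in% names(gene_sets$sets))
    stop("effect references gene set '", effect$set_name,
         "' absent from the supplied collection")
  gene_sets$sets[[effect$set_name]]
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Deterministic sex assignment matching observed per-group counts
group_sexes <- function(group, n) {
  n_male <- switch(group,
                   responder = round(n * 36 / 60),
                   non_responder = round(n * 7 / 16),
                   control = round(n * 7 / 15))
  sample(c(rep("M", n_male), rep("F", n - n_male)))
}

#' Simulate a synthetic cohort
#'
#' Draws an [expression_study()] from the generative model described in
#' [sim_config()]. Dropout is missing-at-random within group: subjects
#' are permuted once per group and the first \code{participation[g, t]}
#' of the permutation are retained at timepoint \code{t}, so monotone
#' participation counts yield nested dropout.
#'
#' @param config a [sim_config()].
#' @return An [expression_study()]; identical config and seed give a
#'   bitwise-identical study.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  part <- config$participation
  group_sizes <- apply(part, 1, max)
  subjects <- data.frame(
    subject_id = character(0), group = character(0),
    age = numeric(0), sex = character(0), stringsAsFactors = FALSE
  )
  for (g in GROUPS) {
    n <- group_sizes[[g]]
    if (n == 0) next
    ids <- sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n))
    if (g == "non_responder") ids <- sprintf("N%02d", seq_len(n))
    age <- if (g == "control") rtruncnorm1(n, 40.53, 15.90, 18, 80)
           else rtruncnorm1(n, 43.54, 14.80, 18, 80)
    subjects <- rbind(subjects, data.frame(
      subject_id = ids, group = g, age = age,
      sex = group_sexes(g, n), stringsAsFactors = FALSE
    ))
  }

  # dropout: one permutation per group; first k subjects participate
  rows <- list()
  for (g in GROUPS) {
    subj_g <- subjects[subjects$group == g, , drop = FALSE]
    if (!nrow(subj_g)) next
    perm <- sample(nrow(subj_g))
    for (tp in TIMEPOINTS) {
      k <- part[g, tp]
      if (k > nrow(subj_g))
        stop("participation count exceeds group size for ", g, " at ", tp)
      keep <- subj_g[perm[seq_len(k)], , drop = FALSE]
      if (!nrow(keep)) next
      keep$timepoint <- tp
      rows[[length(rows) + 1L]] <- keep
    }
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- paste(samples$subject_id, samples$timepoint, sep = "_")
  samples$protocol_violation <- FALSE

  # protocol violators: patients flagged at T3 only
  if (config$n_protocol_violators > 0) {
    t3_pat <- samples$timepoint == "T3" & samples$group != "control"
    cand <- samples$subject_id[t3_pat]
    nv <- min(config$n_protocol_violators, length(cand))
    viol <- sample(cand, nv)
    samples$protocol_violation[t3_pat & samples$subject_id %in% viol] <- TRUE
  }

  n_genes <- config$n_genes
  baseline <- if (length(config$baseline_mean) == n_genes) {
    as.numeric(config$baseline_mean)
  } else {
    stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  }
  age_eff <- rep_len(config$age_effect, n_genes)
  sex_eff <- rep_len(config$sex_effect, n_genes)

  u <- stats::rnorm(nrow(subjects), 0, config$subject_intercept_sd)
  names(u) <- subjects$subject_id

  n_samp <- nrow(samples)
  values <- matrix(baseline, nrow = n_genes, ncol = n_samp)
  values <- values + rep(u[samples$subject_id], each = n_genes)
  values <- values + outer(age_eff, samples$age)
  values <- values + outer(sex_eff, as.numeric(samples$sex == "F"))

  tp_idx <- match(samples$timepoint, TIMEPOINTS)
  for (e in config$effects) {
    tg <- resolve_effect_genes(e, config$gene_sets)
    gi <- match(tg, config$gene_names)
    in_scope <- effect_sample_mask(e, samples)
    if (e$kind == "baseline_shift") {
      add <- e$magnitude * as.numeric(in_scope)
    } else {
      add <- e$magnitude * e$timepoint_profile[tp_idx] * as.numeric(in_scope)
    }
    values[gi, ] <- values[gi, ] + rep(add, each = length(gi))
  }

  values <- values + matrix(stats::rnorm(n_genes * n_samp, 0, config$residual_sd),
                            n_genes, n_samp)
  dimnames(values) <- list(config$gene_names, samples$sample_id)
  expression_study(values, samples)
}

effect_sample_mask <- function(effect, samples) {
  restr <- effect$group_restriction
  if (is.null(restr)) restr <- if (effect$kind == "group_by_time") stop() else "patients"
  switch(restr,
         all = rep(TRUE, nrow(samples)),
         patients = samples$group != "control",
         samples$group == restr)
}

#' Ground truth of injected effects
#'
#' One row per gene and contrast, recording the effect size each gene
#' truly carries for the contrast an injected effect targets:
#' \code{time_main} effects target M1, \code{group_by_time} effects
#' restricted to responders/non-responders target M2 and those restricted
#' to \code{"patients"} target M3, \code{baseline_shift} targets the
#' baseline comparison, and \code{set_coherent_trajectory} targets the
#' time-course gene-set analysis. Effect size is the injected shift at T2
#' (at any timepoint for baseline shifts; the largest profile value for
#' trajectories).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{true_effect} (0 for untouched genes) and \code{is_true}.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  contrasts <- c("M1", "M2", "M3", "baseline", "trajectory")
  out <- expand.grid(gene = config$gene_names, contrast = contrasts,
                     stringsAsFactors = FALSE)
  out$true_effect <- 0
  for (e in config$effects) {
    tg <- resolve_effect_genes(e, config$gene_sets)
    target_contrast <- switch(
      e$kind,
      time_main = "M1",
      baseline_shift = "baseline",
      set_coherent_trajectory = "trajectory",
      group_by_time = if (identical(e$group_restriction, "patients")) "M3" else "M2"
    )
    size <- if (e$kind == "baseline_shift") e$magnitude
            else if (e$kind == "set_coherent_trajectory")
              e$magnitude * e$timepoint_profile[which.max(abs(e$timepoint_profile))]
            else e$magnitude * e$timepoint_profile[2]
    sel <- out$gene %in% tg & out$contrast == target_contrast
    out$true_effect[sel] <- out$true_effect[sel] + size
  }
  out$is_true <- out$true_effect != 0
  out
}

#' Write simulator outputs to disk
#'
#' Emits the expression TSV, metadata TSV and truth-table TSV for a
#' config, as a convenience wrapper for scripted use.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, named vector of the three paths.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_cohort(config)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             meta = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(study, paths[["expr"]], paths[["meta"]])
  utils::write.table(truth_table(config), paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
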