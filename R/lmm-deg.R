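#' Specify a differential-expression contrast
#'
#' The three longitudinal contrasts compare expression between the
#' pre-intervention (T1) and post-intervention (T2) samples with a
#' random intercept per subject and age/sex covariates:
#' \describe{
#'   \item{M1}{time effect in all patients (responders plus
#'     non-responders); tested term is the T2 indicator.}
#'   \item{M2}{responder-vs-non-responder by time interaction, patients
#'     only; reference level is non-responder.}
#'   \item{M3}{patient-vs-control by time interaction, patients plus
#'     controls; reference level is control.}
#' }
#' In each case the alternative model h1 carries the tested term, the
#' null model h0 omits it (retaining all main effects), h0 is nested in
#' h1, and the likelihood-ratio statistic is referred to chi-square with
#' 1 degree of freedom. A positive estimate means higher expression at T2
#' (M1) or a larger T2-T1 change in responders/patients (M2/M3).
#'
#' @param name \code{"M1"}, \code{"M2"} or \code{"M3"}.
#' @return An object of class \code{contrast_spec}.
#' @export
contrast_spec <- function(name = c("M1", "M2", "M3")) {
  name <- match.arg(name)
  structure(list(name = name), class = "contrast_spec")
}

# Assemble the per-sample design for a T1/T2 contrast. Returns NULL-free
# data.frame plus the tested coefficient name and h1/h0 formulas.
contrast_design <- function(study, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  s <- study$samples
  keep <- s$timepoint %in% c("T1", "T2")
  if (contrast$name %in% c("M1", "M2")) keep <- keep & s$group != "control"
  s <- s[keep, , drop = FALSE]
  d <- data.frame(
    subject = factor(s$subject_id),
    tp = factor(s$timepoint, levels = c("T1", "T2")),
    age = s$age,
    sex = factor(s$sex, levels = c("M", "F")),
    stringsAsFactors = FALSE
  )
  if (contrast$name == "M2") {
    if (!all(c("responder", "non_responder") %in% s$group))
      stop("M2 needs both responders and non-responders")
    d$grp <- factor(s$group, levels = c("non_responder", "responder"))
  } else if (contrast$name == "M3") {
    if (!"control" %in% s$group || !any(s$group != "control"))
      stop("M3 needs both patients and controls")
    d$grp <- factor(ifelse(s$group == "control", "control", "patient"),
                    levels = c("control", "patient"))
  }
  covar <- "age + sex"
  forms <- switch(
    contrast$name,
    M1 = list(h1 = paste("y ~ tp +", covar, "+ (1 | subject)"),
              h0 = paste("y ~", covar, "+ (1 | subject)"),
              term = "tpT2"),
    M2 = list(h1 = paste("y ~ grp * tp +", covar, "+ (1 | subject)"),
              h0 = paste("y ~ grp + tp +", covar, "+ (1 | subject)"),
              term = "grpresponder:tpT2"),
    M3 = list(h1 = paste("y ~ grp * tp +", covar, "+ (1 | subject)"),
              h0 = paste("y ~ grp + tp +", covar, "+ (1 | subject)"),
              term = "grppatient:tpT2")
  )
  list(data = d, keep = which(keep), h1 = stats::as.formula(forms$h1),
       h0 = stats::as.formula(forms$h0), term = forms$term)
}

# Template-and-refit engine: both nested models are fitted once by ML on
# a dummy response, then refitted per gene, which avoids re-deriving the
# identical random-effects structure thousands of times.
deg_engine <- function(study, contrast, genes = study$genes) {
  des <- contrast_design(study, contrast)
  d <- des$data
  vals <- study$values[, des$keep, drop = FALSE]
  # deterministic dummy response for the template fits; every gene is
  # refitted onto its real response afterwards
  d$y <- sin(seq_len(nrow(d)) * 1.7) + cos(seq_len(nrow(d)) * 0.3)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  tmpl1 <- lme4::lmer(des$h1, data = d, REML = FALSE, control = ctrl)
  tmpl0 <- lme4::lmer(des$h0, data = d, REML = FALSE, control = ctrl)

  n <- length(genes)
  out <- data.frame(
    gene = genes, estimate = NA_real_, lrt_stat = NA_real_, df = 1L,
    p = NA_real_, q = NA_real_, direction = 0L, converged = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    y <- vals[genes[i], ]
    if (stats::sd(y) == 0) { # degenerate: no information, recorded not thrown
      out$p[i] <- 1
      next
    }
    res <- tryCatch({
      f0 <- refit_ml(tmpl0, y)
      f1 <- refit_ml(tmpl1, y)
      lrt <- 2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0)))
      est <- unname(lme4::fixef(f1)[des$term])
      c(est = est, lrt = lrt)
    }, error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res))) {
      out$p[i] <- 1
      next
    }
    lrt <- max(res[["lrt"]], 0)
    out$estimate[i] <- res[["est"]]
    out$lrt_stat[i] <- lrt
    out$p[i] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    out$direction[i] <- sign(res[["est"]])
    out$converged[i] <- TRUE
  }
  out
}

refit_ml <- function(template, y) {
  suppressMessages(suppressWarnings(lme4::refit(template, newresp = y)))
}

#' Likelihood-ratio test for one gene
#'
#' Fits the nested random-intercept models of a [contrast_spec()] by
#' maximum likelihood for a single gene and returns the likelihood-ratio
#' contrast of the tested term.
#'
#' @param study an [expression_study()].
#' @param gene gene symbol present in \code{study}.
#' @param contrast a [contrast_spec()].
#' @return One-row data.frame with columns \code{gene}, \code{estimate},
#'   \code{lrt_stat}, \code{df}, \code{p}, \code{q} (equal to \code{p}
#'   for a single gene), \code{direction} and \code{converged}. Genes
#'   with no expression variance are flagged \code{converged = FALSE}
#'   with \code{p = 1}; no error is thrown.
#' @export
fit_gene_lrt <- function(study, gene, contrast) {
  validate_study(study)
  if (!gene %in% study$genes) stop("gene not in study: ", gene)
  out <- deg_engine(study, contrast, genes = gene)
  out$q <- out$p
  out
}

#' Transcriptome-wide likelihood-ratio screen
#'
#' Runs [fit_gene_lrt()] for every gene of a contrast, adjusts p-values
#' across converged genes by Benjamini-Hochberg, and sorts by p.
#'
#' @param study an [expression_study()].
#' @param contrast a [contrast_spec()] or contrast name.
#' @param alpha FDR threshold used by [summary()] reporting.
#' @return A data.frame of class \code{deg_results}, one row per gene,
#'   sorted by p ascending.
#' @export
run_transcriptome <- function(study, contrast, alpha = 0.05) {
  validate_study(study)
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  out <- deg_engine(study, contrast)
  conv <- out$converged
  out$q[conv] <- bh_fdr(out$p[conv])
  out$q[!conv & out$p == 1] <- 1
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("deg_results", "data.frame"),
            contrast = contrast$name, alpha = alpha)
}

#' @export
summary.deg_results <- function(object, alpha = attr(object, "alpha"), ...) {
  sig <- !is.na(object$q) & object$q < alpha & object$converged
  res <- data.frame(
    contrast = attr(object, "contrast"),
    n_genes = nrow(object),
    n_converged = sum(object$converged),
    n_sig = sum(sig),
    n_up = sum(sig & object$direction > 0),
    n_down = sum(sig & object$direction < 0),
    alpha = alpha
  )
  class(res) <- c("deg_summary", "data.frame")
  res
}

#' @export
print.deg_results <- function(x, n = 10, ...) {
  cat("deg_results for contrast", attr(x, "contrast"), "-",
      nrow(x), "genes\n")
  s <- summary(x)
  cat(sprintf("significant at q < %.3g: %d (%d up, %d down)\n",
              s$alpha, s$n_sig, s$n_up, s$n_down))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Baseline (T1) group comparison per gene
#'
#' Ordinary linear model on T1 samples only, \code{expression ~ group +
#' age + sex}, with a two-sided Wald test on the group coefficient.
#' Fitted by a single QR decomposition shared across genes.
#'
#' @param study an [expression_study()].
#' @param comparison \code{"response"} (responder vs non-responder,
#'   patients only; reference non-responder) or \code{"case"} (patient
#'   vs control; reference control).
#' @param alpha FDR threshold used for reporting.
#' @return A data.frame of class \code{deg_results} with columns
#'   \code{gene}, \code{estimate}, \code{t_stat}, \code{p}, \code{q},
#'   \code{direction}, \code{converged}, sorted by p.
#' @export
baseline_differences <- function(study, comparison = c("response", "case"),
                                 alpha = 0.05) {
  validate_study(study)
  comparison <- match.arg(comparison)
  s <- study$samples
  keep <- s$timepoint == "T1"
  if (comparison == "response") keep <- keep & s$group != "control"
  s <- s[keep, , drop = FALSE]
  grp <- if (comparison == "response") {
    if (!all(c("responder", "non_responder") %in% s$group))
      stop("both responders and non-responders required at T1")
    as.numeric(s$group == "responder")
  } else {
    if (!"control" %in% s$group || !any(s$group != "control"))
      stop("both patients and controls required at T1")
    as.numeric(s$group != "control")
  }
  X <- cbind(1, grp, s$age, as.numeric(s$sex == "F"))
  colnames(X) <- c("intercept", "group", "age", "sexF")
  Y <- t(study$values[, keep, drop = FALSE]) # samples x genes
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("baseline design is rank-deficient")
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dfres
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  est <- coefs["group", ]
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = dfres)
  zero_var <- apply(Y, 2, stats::sd) == 0
  p[zero_var] <- 1
  out <- data.frame(
    gene = study$genes, estimate = unname(est), t_stat = unname(tval),
    p = unname(p), q = NA_real_,
    direction = as.integer(sign(unname(est))),
    converged = !zero_var, stringsAsFactors = FALSE
  )
  out$direction[zero_var] <- 0L
  out$q[!zero_var] <- bh_fdr(out$p[!zero_var])
  out$q[zero_var] <- 1
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("deg_results", "data.frame"),
            contrast = paste0("baseline_", comparison), alpha = alpha)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment. q-values are monotone
#' non-decreasing in p-rank and bounded by 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
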