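#' @keywords internal
"_PACKAGE"

TIMEPOINTS <- c("T1", "T2", "T3")
GROUPS <- c("responder", "non_responder", "control")

#' Construct an expression study
#'
#' An \code{expression_study} couples a genes-by-samples matrix of
#' log-scale intensities with per-sample metadata (subject, timepoint,
#' group, age, sex, protocol-violation flag). It is the single substrate
#' every analysis stage in the package consumes.
#'
#' @param values numeric matrix, genes in rows, samples in columns;
#'   rownames are gene symbols, colnames are sample ids. All values must
#'   be finite.
#' @param samples data.frame with one row per column of \code{values} and
#'   columns \code{sample_id}, \code{subject_id}, \code{timepoint}
#'   (\code{"T1"}/\code{"T2"}/\code{"T3"}), \code{group}
#'   (\code{"responder"}/\code{"non_responder"}/\code{"control"}),
#'   \code{age}, \code{sex} (\code{"M"}/\code{"F"}) and, optionally,
#'   \code{protocol_violation} (logical; defaults to \code{FALSE}).
#'
#' @return An object of class \code{expression_study}: a list with
#'   elements \code{genes}, \code{samples} and \code{values}.
#'
#' @details Sample metadata rows are reordered to match the column order
#'   of \code{values}. Validation enforces: unique gene symbols, unique
#'   (subject, timepoint) pairs, group and sex constant within subject,
#'   and finite expression values. Missing visits (dropout) are simply
#'   absent columns; no sentinel values are used and all models run on
#'   available cases.
#'
#' @seealso [read_expression()], [simulate_cohort()], [quantile_normalize()]
#' @export
expression_study <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene symbols as rownames and sample ids as colnames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "timepoint", "group", "age", "sex")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"protocol_violation" %in% names(samples))
    samples$protocol_violation <- FALSE

  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$timepoint <- as.character(samples$timepoint)
  samples$group <- as.character(samples$group)
  samples$sex <- as.character(samples$sex)
  samples$age <- as.numeric(samples$age)
  samples$protocol_violation <- as.logical(samples$protocol_violation)

  extra <- setdiff(samples$sample_id, colnames(values))
  absent <- setdiff(colnames(values), samples$sample_id)
  if (length(extra) || length(absent))
    stop(
      "sample ids disagree between matrix and metadata;",
      if (length(absent)) paste0(" missing from metadata: ", paste(absent, collapse = ", ")),
      if (length(extra)) paste0(" missing from matrix: ", paste(extra, collapse = ", "))
    )
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  study <- structure(
    list(genes = rownames(values), samples = samples, values = values),
    class = "expression_study"
  )
  validate_study(study)
  study
}

validate_study <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  genes <- study$genes
  samples <- study$samples
  values <- study$values
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  bad_tp <- setdiff(unique(samples$timepoint), TIMEPOINTS)
  if (length(bad_tp))
    stop("unknown timepoint(s): ", paste(bad_tp, collapse = ", "))
  bad_grp <- setdiff(unique(samples$group), GROUPS)
  if (length(bad_grp))
    stop("unknown group(s): ", paste(bad_grp, collapse = ", "))
  bad_sex <- setdiff(unique(samples$sex), c("M", "F"))
  if (length(bad_sex))
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  if (any(!is.finite(samples$age)) || any(samples$age <= 0))
    stop("ages must be positive and finite")
  key <- paste(samples$subject_id, samples$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  # group and sex must not change within subject
  for (col in c("group", "sex")) {
    per_subj <- tapply(samples[[col]], samples$subject_id,
                       function(x) length(unique(x)))
    if (any(per_subj > 1))
      stop(col, " varies within subject(s): ",
           paste(names(per_subj)[per_subj > 1], collapse = ", "))
  }
  invisible(study)
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$genes), "genes x",
      nrow(x$samples), "samples\n")
  tab <- table(group = x$samples$group, timepoint = x$samples$timepoint)
  print(tab)
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Read an expression study from TSV files
#'
#' @param expr_path path to a genes-by-samples TSV: first column gene
#'   symbols, remaining columns one per sample, header row of sample ids.
#' @param meta_path path to a sample-metadata TSV with columns
#'   \code{sample_id}, \code{subject_id}, \code{timepoint}, \code{group},
#'   \code{age}, \code{sex}, \code{protocol_violation}.
#'
#' @return An [expression_study()].
#' @export
read_expression <- function(expr_path, meta_path) {
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  expr <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(expr) < 2)
    stop("expression table needs a gene column plus at least one sample column")
  genes <- as.character(expr[[1]])
  mat <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(expr[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(expr[, -1, drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   genes[bad[1, 1]], colnames(expr)[-1][bad[1, 2]]))
    mode(mat) <- "numeric"
  }
  rownames(mat) <- genes
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  expression_study(mat, meta)
}

#' Write an expression study to TSV files
#'
#' Serializes the matrix and metadata in the canonical form
#' [read_expression()] accepts, so that write-then-read is the identity.
#'
#' @param study an [expression_study()].
#' @param expr_path,meta_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(study, expr_path, meta_path) {
  validate_study(study)
  df <- data.frame(gene = study$genes, study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(study$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(expr = expr_path, meta = meta_path))
}

#' Subset an expression study by samples
#'
#' @param study an [expression_study()].
#' @param keep logical or integer index over samples.
#' @return The subsetted study.
#' @export
subset_samples <- function(study, keep) {
  expression_study(study$values[, keep, drop = FALSE],
                   study$samples[keep, , drop = FALSE])
}

#' Quantile-normalize an expression study
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of order statistics. Within-sample rank order is
#' preserved; ties within a sample receive the mean of the reference
#' values across the tied ranks.
#'
#' @param study an [expression_study()] with at least two samples.
#' @return A normalized [expression_study()]. Applying the function twice
#'   gives the same result as applying it once.
#' @export
quantile_normalize <- function(study) {
  validate_study(study)
  x <- study$values
  if (ncol(x) < 2)
    stop("quantile normalization needs at least two samples")
  sorted <- apply(x, 2, sort)
  reference <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    assigned <- reference[rank(x[, j], ties.method = "first")]
    # tied values share the mean of the reference values across their ranks
    out[, j] <- stats::ave(assigned, match(x[, j], x[, j]), FUN = mean)
  }
  study$values <- out
  study
}
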