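# The filter cascade applied to each quantification method before the
# differential statistic, in fixed order:
#   1. peptide filter (>= 2 peptides in at least one biological sample)
#   2. total-area normalization to 1e6 per sample, then log2(x + 1)
#   3. >= 3-fold biological-over-control enrichment on raw areas, per
#      condition, both conditions required
#   4. presence in >= 2 of 3 biological replicates of at least one condition
# Normalization factors are computed once on the peptide-filtered table and
# not recomputed after the later filters unless explicitly requested.

filter_report <- function(stage, before, after) {
  structure(list(stage = stage,
                 proteins_in = length(before),
                 proteins_out = length(after),
                 removed = setdiff(before, after)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d (removed %d)\n", x$stage, x$proteins_in,
              x$proteins_out, length(x$removed)))
  invisible(x)
}

#' Peptide-count filter
#'
#' Retains proteins identified with at least `min_peptides` peptides in at
#' least one biological sample of either condition; competition-control
#' samples are ignored for this criterion.
#'
#' @param dataset a [quant_dataset()].
#' @param min_peptides minimum peptide count (default 2).
#' @return list with `data` (filtered dataset) and `report`.
#' @export
filter_min_peptides <- function(dataset, min_peptides = 2) {
  validate_quant_dataset(dataset)
  bio <- design_samples(dataset$design, assay = "biological")
  pc <- dataset$peptide_counts[, bio, drop = FALSE]
  keep <- apply(pc, 1, max) >= min_peptides
  out <- subset_proteins(dataset, keep)
  list(data = out,
       report = filter_report("min_peptides", dataset$proteins,
                              out$proteins))
}

#' Total-area normalization with log2(x + 1)
#'
#' Scales each sample column so its raw-area total equals `total`
#' (default 1e6) over the proteins currently in the table, then stores
#' `log2_values = log2(normalized + 1)`. Columns whose raw total is zero
#' are left all-zero with a warning.
#'
#' @param dataset a [quant_dataset()].
#' @param total target per-sample total (default 1e6).
#' @return a `normalized_dataset` (a `quant_dataset` carrying `normalized`
#'   and `log2_values` matrices alongside the raw areas).
#' @export
normalize_total_area <- function(dataset, total = 1e6) {
  validate_quant_dataset(dataset)
  if (length(dataset$proteins) == 0) {
    dataset$normalized <- dataset$areas
    dataset$log2_values <- dataset$areas
    class(dataset) <- c("normalized_dataset", "quant_dataset")
    return(dataset)
  }
  sums <- colSums(dataset$areas)
  zero <- sums == 0
  if (any(zero)) {
    warning("sample column(s) with zero total left unnormalized: ",
            paste(dataset$design$sample_id[zero], collapse = ", "))
  }
  scale <- ifelse(zero, 0, total / sums)
  normalized <- sweep(dataset$areas, 2, scale, "*")
  dataset$normalized <- normalized
  dataset$log2_values <- log2(normalized + 1)
  class(dataset) <- c("normalized_dataset", "quant_dataset")
  dataset
}

condition_means <- function(dataset, assay) {
  n <- length(dataset$proteins)
  m <- vapply(CONDITIONS, function(cond) {
    ids <- design_samples(dataset$design, assay = assay, condition = cond)
    if (length(ids) == 0) return(rep(NA_real_, n))
    rowMeans(dataset$areas[, ids, drop = FALSE])
  }, numeric(n))
  matrix(m, nrow = n, ncol = length(CONDITIONS),
         dimnames = list(NULL, CONDITIONS))
}

#' Competition-control enrichment filter
#'
#' Retains proteins whose mean raw biological peak area is at least
#' `ratio`-fold (inclusive) the mean raw competition-control area in *both*
#' conditions. A condition whose control mean is 0 passes iff the
#' biological mean is > 0. Operates on raw areas regardless of whether the
#' dataset has been normalized.
#'
#' @param dataset a [quant_dataset()] whose design includes
#'   competition-control samples for every condition.
#' @param ratio fold-enrichment threshold (default 3).
#' @return list with `data` and `report`.
#' @export
filter_control_enrichment <- function(dataset, ratio = 3) {
  validate_quant_dataset(dataset)
  for (cond in CONDITIONS) {
    if (length(design_samples(dataset$design, "competition_control",
                              cond)) == 0) {
      stop("no competition-control samples for condition '", cond, "'")
    }
  }
  bio <- condition_means(dataset, "biological")
  ctrl <- condition_means(dataset, "competition_control")
  pass <- ifelse(ctrl == 0, bio > 0, bio >= ratio * ctrl)
  keep <- rowSums(pass) == length(CONDITIONS)
  if (length(dataset$proteins) == 0) keep <- logical(0)
  out <- subset_proteins(dataset, keep)
  list(data = out,
       report = filter_report("control_enrichment", dataset$proteins,
                              out$proteins))
}

#' Replicate-presence filter
#'
#' Retains proteins identified (raw area > 0) in at least `min_reps`
#' biological replicates of at least one condition.
#'
#' @param dataset a [quant_dataset()].
#' @param min_reps minimum replicates (default 2).
#' @return list with `data` and `report`.
#' @export
filter_replicate_presence <- function(dataset, min_reps = 2) {
  validate_quant_dataset(dataset)
  present <- vapply(CONDITIONS, function(cond) {
    ids <- design_samples(dataset$design, "biological", cond)
    rowSums(dataset$areas[, ids, drop = FALSE] > 0) >= min_reps
  }, logical(length(dataset$proteins)))
  keep <- rowSums(matrix(present, ncol = length(CONDITIONS))) > 0
  out <- subset_proteins(dataset, keep)
  list(data = out,
       report = filter_report("replicate_presence", dataset$proteins,
                              out$proteins))
}

#' Full preprocessing cascade
#'
#' Applies, in order: peptide filter, total-area normalization with
#' pseudocount-1 log2 transform, control-enrichment filter (on raw areas),
#' replicate-presence filter; returns the surviving proteins' normalized
#' dataset plus one report per filter stage.
#'
#' @param dataset a [quant_dataset()].
#' @param min_peptides peptide threshold (default 2).
#' @param total normalization target (default 1e6).
#' @param ratio control-enrichment fold threshold (default 3).
#' @param min_reps presence threshold (default 2).
#' @param renormalize_after_filters recompute normalization factors on the
#'   final surviving set (default FALSE: factors from the peptide-filtered
#'   table are kept, so filtered columns sum to <= `total`).
#' @return list with `data` (a `normalized_dataset`) and `reports`.
#' @export
preprocess <- function(dataset, min_peptides = 2, total = 1e6, ratio = 3,
                       min_reps = 2, renormalize_after_filters = FALSE) {
  s1 <- filter_min_peptides(dataset, min_peptides)
  norm <- normalize_total_area(s1$data, total)
  s2 <- filter_control_enrichment(norm, ratio)
  s3 <- filter_replicate_presence(s2$data, min_reps)
  out <- s3$data
  if (renormalize_after_filters && length(out$proteins) > 0) {
    out <- normalize_total_area(out, total)
  }
  list(data = out, reports = list(s1$report, s2$report, s3$report))
}
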