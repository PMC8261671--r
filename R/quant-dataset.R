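#' Construct a protein quantification dataset
#'
#' A `quant_dataset` bundles the protein-level raw peak areas of one
#' quantification method with per-sample peptide counts and the sample
#' design. A raw area of 0 means "not identified in this sample".
#'
#' @param proteins character vector of protein IDs (opaque, case-sensitive).
#' @param areas numeric matrix, proteins x samples, of raw peak areas
#'   (non-negative; 0 = not identified).
#' @param peptide_counts integer matrix of the same dimension; when `NULL`,
#'   a per-protein vector may be supplied via `peptides_per_protein` and is
#'   replicated across samples.
#' @param design a [sample_design()] with one row per column of `areas`.
#' @param peptides_per_protein optional numeric vector recycled across
#'   samples when `peptide_counts` is `NULL`.
#' @return An object of class `quant_dataset`.
#' @export
quant_dataset <- function(proteins, areas, peptide_counts = NULL, design,
                          peptides_per_protein = NULL) {
  proteins <- as.character(proteins)
  areas <- as.matrix(areas)
  if (is.null(peptide_counts)) {
    if (is.null(peptides_per_protein)) {
      stop("supply peptide_counts or peptides_per_protein")
    }
    peptide_counts <- matrix(as.integer(peptides_per_protein),
                             nrow = length(proteins), ncol = nrow(design))
  }
  peptide_counts <- as.matrix(peptide_counts)
  storage.mode(areas) <- "double"
  if (!all(dim(areas) == c(length(proteins), nrow(design)))) {
    stop("areas must be |proteins| x |design| (", length(proteins), " x ",
         nrow(design), "), got ", paste(dim(areas), collapse = " x "))
  }
  if (!all(dim(peptide_counts) == dim(areas))) {
    stop("peptide_counts dimensions differ from areas")
  }
  dimnames(areas) <- list(proteins, design$sample_id)
  dimnames(peptide_counts) <- list(proteins, design$sample_id)
  x <- structure(
    list(proteins = proteins, areas = areas,
         peptide_counts = peptide_counts, design = design),
    class = "quant_dataset"
  )
  validate_quant_dataset(x)
  storage.mode(x$peptide_counts) <- "integer"
  x
}

#' Validate a quant_dataset
#' @param x a `quant_dataset`.
#' @return `x` invisibly.
#' @export
validate_quant_dataset <- function(x) {
  validate_design(x$design)
  n_p <- length(x$proteins)
  n_s <- nrow(x$design)
  if (!all(dim(x$areas) == c(n_p, n_s))) {
    stop("areas must be |proteins| x |design| (",
         n_p, " x ", n_s, "), got ", paste(dim(x$areas), collapse = " x "))
  }
  if (!all(dim(x$peptide_counts) == dim(x$areas))) {
    stop("peptide_counts dimensions differ from areas")
  }
  if (anyDuplicated(x$proteins)) {
    stop("duplicate protein IDs: ",
         paste(unique(x$proteins[duplicated(x$proteins)]), collapse = ", "))
  }
  if (any(is.na(x$areas)) || any(x$areas < 0)) {
    bad <- which(is.na(x$areas) | x$areas < 0, arr.ind = TRUE)[1, ]
    stop("negative or NA area for protein ", x$proteins[bad[1]],
         ", sample ", x$design$sample_id[bad[2]])
  }
  pc <- x$peptide_counts
  if (any(is.na(pc)) || any(pc < 0) || any(pc != round(pc))) {
    stop("peptide_counts must be non-negative integers")
  }
  invisible(x)
}

#' Restrict a dataset to a subset of proteins (order preserved)
#' @param x a `quant_dataset` (or `normalized_dataset`).
#' @param keep character vector of protein IDs, or logical vector.
#' @export
subset_proteins <- function(x, keep) {
  if (is.logical(keep)) keep <- x$proteins[keep]
  idx <- match(keep, x$proteins)
  if (anyNA(idx)) stop("unknown protein IDs: ",
                       paste(keep[is.na(idx)], collapse = ", "))
  x$proteins <- x$proteins[idx]
  x$areas <- x$areas[idx, , drop = FALSE]
  x$peptide_counts <- x$peptide_counts[idx, , drop = FALSE]
  for (f in c("normalized", "log2_values")) {
    if (!is.null(x[[f]])) x[[f]] <- x[[f]][idx, , drop = FALSE]
  }
  x
}

#' @export
print.quant_dataset <- function(x, ...) {
  cat(sprintf("<%s> %d proteins x %d samples (method %s)\n",
              class(x)[1], length(x$proteins), nrow(x$design),
              paste(unique(x$design$method), collapse = ",")))
  tab <- table(x$design$condition, x$design$assay)
  print(tab)
  invisible(x)
}
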