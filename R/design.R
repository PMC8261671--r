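#' @keywords internal
CONDITIONS <- c("untreated", "stress")

#' @keywords internal
ASSAYS <- c("biological", "competition_control")

#' Construct a sample design table
#'
#' A sample design describes every MS run of a RIC experiment: which
#' condition it belongs to (`untreated` or `stress`), whether it is a
#' biological pulldown or a poly(A) competition control, its replicate index
#' and the quantification method that produced the values.
#'
#' @param sample_id character vector of unique sample labels.
#' @param condition character vector, each `"untreated"` or `"stress"`.
#' @param assay character vector, each `"biological"` or
#'   `"competition_control"`.
#' @param replicate positive integer vector of replicate indices.
#' @param method character scalar or vector naming the quantification method
#'   (e.g. `"TOP3"`, `"iBAQ"`, `"LFQ"`).
#' @return A `data.frame` of class `sample_design`.
#' @export
#' @examples
#' sample_design(c("u1", "s1"), c("untreated", "stress"),
#'               "biological", c(1L, 1L), "TOP3")
sample_design <- function(sample_id, condition, assay, replicate, method) {
  design <- data.frame(
    sample_id = as.character(sample_id),
    condition = as.character(condition),
    assay = as.character(assay),
    replicate = as.integer(replicate),
    method = as.character(method),
    stringsAsFactors = FALSE
  )
  class(design) <- c("sample_design", "data.frame")
  validate_design(design)
  design
}

#' Validate a sample design
#'
#' @param design a `sample_design` or plain data.frame with columns
#'   `sample_id`, `condition`, `assay`, `replicate`, `method`.
#' @return the design, invisibly, after validation.
#' @export
validate_design <- function(design) {
  required <- c("sample_id", "condition", "assay", "replicate", "method")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0) {
    stop("sample design lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    dup <- unique(design$sample_id[duplicated(design$sample_id)])
    stop("duplicate sample_id in design: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(design$condition), CONDITIONS)
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CONDITIONS, collapse = "/"), ")")
  }
  bad <- setdiff(unique(design$assay), ASSAYS)
  if (length(bad) > 0) {
    stop("unknown assay(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ASSAYS, collapse = "/"), ")")
  }
  if (any(is.na(design$replicate)) || any(design$replicate < 1)) {
    stop("replicate indices must be positive integers")
  }
  invisible(design)
}

#' Canonical RIC design: 3 biological replicates per condition plus matched
#' poly(A) competition controls (12 samples) for one quantification method.
#'
#' @param method quantification method label.
#' @param n_reps biological replicates per condition (default 3).
#' @export
canonical_design <- function(method = "TOP3", n_reps = 3) {
  grid <- expand.grid(
    replicate = seq_len(n_reps),
    assay = ASSAYS,
    condition = CONDITIONS,
    stringsAsFactors = FALSE
  )
  tag <- ifelse(grid$assay == "biological", "bio", "ctrl")
  ids <- paste(method, grid$condition, tag, grid$replicate, sep = "_")
  sample_design(ids, grid$condition, grid$assay, grid$replicate, method)
}

# sample ids matching an (assay, condition) cell; condition = NULL -> all
design_samples <- function(design, assay = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(assay)) keep <- keep & design$assay == assay
  if (!is.null(condition)) keep <- keep & design$condition == condition
  design$sample_id[keep]
}
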