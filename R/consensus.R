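#' Cross-method consensus calls
#'
#' Integrates per-method differential tables over the union of their
#' protein universes. A protein is selected when at least `min_methods`
#' methods call it significant (FDR percentage at or below `cutoff`) *and*
#' the selecting methods agree on the direction of change; direction
#' disagreements are flagged `discordant` and never selected. A protein
#' absent from a method's table (it failed that method's filters) simply
#' counts as not significant there.
#'
#' @param tables list of `differential_table`s (one per method) from
#'   [call_differential()] / [assign_fdr()].
#' @param min_methods minimum number of selecting methods (default 2).
#' @param cutoff FDR percentage cutoff re-applied to `fdr_percent`
#'   (default 5).
#' @return a `consensus_table` data.frame with one row per union protein:
#'   per-method `avg_fc.<m>` / `fdr.<m>` / `sig.<m>` columns,
#'   `n_significant_methods`, `consensus_direction`
#'   (`less`/`more`/`discordant`/`none`) and `selected`.
#' @export
integrate_methods <- function(tables, min_methods = 2, cutoff = 5) {
  if (length(tables) < 2) stop("consensus requires >= 2 methods")
  methods <- vapply(tables, function(t) t$method[1], character(1))
  if (anyDuplicated(methods)) {
    stop("duplicate method labels: ",
         paste(unique(methods[duplicated(methods)]), collapse = ", "))
  }
  proteins <- sort(unique(unlist(lapply(tables, `[[`, "protein_id"))))
  n <- length(proteins)
  fc <- fdr <- matrix(NA_real_, n, length(methods),
                      dimnames = list(proteins, methods))
  for (i in seq_along(tables)) {
    idx <- match(tables[[i]]$protein_id, proteins)
    fc[idx, i] <- tables[[i]]$avg_fc
    fdr[idx, i] <- tables[[i]]$fdr_percent
  }
  sig <- !is.na(fdr) & fdr <= cutoff
  n_sig <- rowSums(sig)
  direction <- vapply(seq_len(n), function(i) {
    if (n_sig[i] == 0) return("none")
    signs <- sign(fc[i, sig[i, ]])
    if (all(signs > 0)) "more"
    else if (all(signs < 0)) "less"
    else "discordant"
  }, character(1))
  selected <- n_sig >= min_methods & direction %in% c("less", "more")
  out <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
  for (i in seq_along(methods)) {
    out[[paste0("avg_fc.", methods[i])]] <- fc[, i]
    out[[paste0("fdr.", methods[i])]] <- fdr[, i]
    out[[paste0("sig.", methods[i])]] <- sig[, i]
  }
  out$n_significant_methods <- n_sig
  out$consensus_direction <- direction
  out$selected <- selected
  class(out) <- c("consensus_table", "data.frame")
  out
}
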