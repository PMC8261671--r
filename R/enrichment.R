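# Hypergeometric statistics: Venn-overlap significance and gene-set
# over-representation analysis (ORA) against a fixed background, with
# Benjamini-Hochberg adjustment. Tail probabilities are computed in log
# space from log-gamma binomial coefficients so that extreme overlaps
# (p ~ 1e-114 and far below) remain representable via log10(p).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Upper-tail hypergeometric probability, log-space
#'
#' Exact P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of an
#' overlap of at least `k` between a set of size `K` and a set of size `n`
#' drawn from a universe of size `N`. The observed overlap is included in
#' the tail (P(X >= k), the standard over-representation convention).
#'
#' @param N universe size.
#' @param K size of the first set.
#' @param n size of the second set.
#' @param k observed overlap.
#' @return list with `p_value` (may underflow to 0 below ~1e-308) and
#'   `log10_p` (always finite for valid input).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N) {
    stop("invalid hypergeometric arguments: need 0 <= K, n <= N")
  }
  if (k > min(K, n) || k < max(0, K + n - N)) {
    stop("overlap k = ", k, " outside the feasible range [",
         max(0, K + n - N), ", ", min(K, n), "]")
  }
  i <- k:min(K, n)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  log_p <- min(logsumexp(log_terms), 0)  # guard rounding above 1
  list(p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Significance of the overlap between two sets
#'
#' @param set1,set2 character vectors, both subsets of `universe`.
#' @param universe character vector defining the universe.
#' @return an `overlap_test`: list with `N`, `K`, `n`, `k`, `p_value`,
#'   `log10_p`.
#' @export
overlap_test <- function(set1, set2, universe) {
  set1 <- unique(set1); set2 <- unique(set2); universe <- unique(universe)
  out1 <- setdiff(set1, universe)
  out2 <- setdiff(set2, universe)
  if (length(out1) + length(out2) > 0) {
    stop("member(s) outside the universe: ",
         paste(utils::head(c(out1, out2), 10), collapse = ", "))
  }
  k <- length(intersect(set1, set2))
  p <- hypergeom_upper_tail(length(universe), length(set1),
                            length(set2), k)
  structure(list(N = length(universe), K = length(set1), n = length(set2),
                 k = k, p_value = p$p_value, log10_p = p$log10_p),
            class = "overlap_test")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (with monotonicity enforcement); input
#' order is preserved in the output.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[o] * m / (m:1)))
  adj[order(o)]
}

#' Over-representation analysis against a fixed background
#'
#' For each gene set, the overlap with the foreground is tested with the
#' upper-tail hypergeometric probability using the background as the
#' universe; category members outside the background are ignored.
#' Categories whose overlap is below `min_overlap` (default 2) are dropped
#' before Benjamini-Hochberg adjustment across the emitted rows.
#'
#' @param foreground character vector, a subset of `background`.
#' @param collection a `gene_set_collection` ([read_gmt()] or
#'   [gene_set_collection()]).
#' @param background character vector, the universe (e.g. all 6,725
#'   protein-coding genes).
#' @param min_overlap minimum overlap for a category to be tested
#'   (default 2).
#' @return data.frame with columns `set`, `category_size`,
#'   `foreground_size`, `overlap`, `p`, `log10_p`, `adjusted_p`.
#' @export
ora <- function(foreground, collection, background, min_overlap = 2) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) stop("foreground is empty")
  stray <- setdiff(foreground, background)
  if (length(stray) > 0) {
    stop("foreground member(s) outside the background: ",
         paste(utils::head(stray, 10), collapse = ", "))
  }
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]]$members, background)
    overlap <- length(intersect(members, foreground))
    if (overlap < min_overlap) return(NULL)
    p <- hypergeom_upper_tail(length(background), length(members),
                              length(foreground), overlap)
    data.frame(set = nm, category_size = length(members),
               foreground_size = length(foreground), overlap = overlap,
               p = p$p_value, log10_p = p$log10_p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(set = character(0), category_size = integer(0),
                       foreground_size = integer(0), overlap = integer(0),
                       p = numeric(0), log10_p = numeric(0),
                       stringsAsFactors = FALSE)
  }
  rows$adjusted_p <- benjamini_hochberg(rows$p)
  rows[order(rows$p), , drop = FALSE]
}
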