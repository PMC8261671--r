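# Paralog specialization: classify duplicated gene pairs against a query
# set (e.g. the detected mRBPome, or the differential set), compare protein
# abundances of RNA-binding vs non-binding pair members (Mann-Whitney), and
# test category over-representation among the "unique" (one-in-pair)
# proteins using all paired proteins as the background.

#' Classify paralog pairs against a query set
#'
#' Partitions pairs into those with both members in the query set, exactly
#' one member in it, or neither.
#'
#' @param pairs a `paralog_table` ([read_paralog_pairs()] /
#'   [paralog_table()]).
#' @param query_set character vector of protein IDs.
#' @return a `paralog_classification`: list with data.frames `both`,
#'   `one` (columns `in_member`, `out_member`), `neither`, and `counts`.
#' @export
classify_pairs <- function(pairs, query_set) {
  in_a <- pairs$a %in% query_set
  in_b <- pairs$b %in% query_set
  both <- pairs[in_a & in_b, , drop = FALSE]
  one_idx <- xor(in_a, in_b)
  one <- data.frame(
    in_member = ifelse(in_a[one_idx], pairs$a[one_idx], pairs$b[one_idx]),
    out_member = ifelse(in_a[one_idx], pairs$b[one_idx], pairs$a[one_idx]),
    stringsAsFactors = FALSE
  )
  neither <- pairs[!(in_a | in_b), , drop = FALSE]
  structure(list(
    both = as.data.frame(both), one = one, neither = as.data.frame(neither),
    counts = c(both = nrow(both), one = nrow(one), neither = nrow(neither),
               total = nrow(pairs))
  ), class = "paralog_classification")
}

#' @export
print.paralog_classification <- function(x, ...) {
  cat(sprintf(
    "paralog pairs: %d both-in (%d proteins), %d one-in, %d neither (of %d)\n",
    x$counts[["both"]], 2 * x$counts[["both"]], x$counts[["one"]],
    x$counts[["neither"]], x$counts[["total"]]))
  invisible(x)
}

# U statistic for group 1 from midranks
u_statistic <- function(g1, g2) {
  r <- rank(c(g1, g2))
  sum(r[seq_along(g1)]) - length(g1) * (length(g1) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided test that two samples come from the same distribution. For
#' small untied samples (n1 + n2 <= `exact_limit`) the p-value is exact,
#' by full enumeration of the label assignments; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param group1,group2 numeric vectors (non-empty).
#' @param exact_limit largest n1 + n2 for which the exact enumeration is
#'   attempted (default 20).
#' @return a `mann_whitney_result`: list with `U` (for group 1), `n1`,
#'   `n2`, `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(group1, group2, exact_limit = 20) {
  if (length(group1) == 0 || length(group2) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(group1); n2 <- length(group2)
  u_obs <- u_statistic(group1, group2)
  combined <- c(group1, group2)
  ties <- anyDuplicated(combined) > 0
  mu <- n1 * n2 / 2
  if (!ties && n1 + n2 <= exact_limit) {
    # enumerate every way of labelling n1 of the pooled values as group 1
    idx <- utils::combn(n1 + n2, n1)
    r <- rank(combined)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    tie_tab <- table(combined)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approx"
  }
  structure(list(U = u_obs, n1 = n1, n2 = n2, p_value = p,
                 method = method),
            class = "mann_whitney_result")
}

#' Paralog specialization report
#'
#' Runs the three analyses of the specialization question: (1) pair
#' classification against the RNA-binding set and against the differential
#' set; (2) a Mann-Whitney comparison of protein abundance between the
#' RNA-binding members of one-in pairs and their non-binding partners;
#' (3) over-representation of gene sets among the unique (one-in-pair)
#' differential proteins, with all paired proteins as the background.
#'
#' @param pairs a `paralog_table`.
#' @param rbp_set character vector: detected RNA binders.
#' @param differential_set character vector: differential RNA binders.
#' @param abundance named numeric vector mapping protein ID to abundance;
#'   proteins without a value are dropped from the comparison with a
#'   warning.
#' @param collection optional `gene_set_collection` for step (3).
#' @param background optional character vector; defaults to all paired
#'   proteins.
#' @param min_overlap ORA minimum overlap (default 2).
#' @return list with `rbp_classification`, `differential_classification`,
#'   `abundance_test` (a `mann_whitney_result` or `NULL` with
#'   `abundance_note`), `enrichment` (data.frame or `NULL`).
#' @export
specialization_report <- function(pairs, rbp_set, differential_set,
                                  abundance = NULL, collection = NULL,
                                  background = NULL, min_overlap = 2) {
  cls_rbp <- classify_pairs(pairs, rbp_set)
  cls_diff <- classify_pairs(pairs, differential_set)

  abundance_test <- NULL
  abundance_note <- NULL
  if (nrow(cls_rbp$one) == 0) {
    abundance_note <- "no one-in pairs: abundance comparison skipped"
  } else if (is.null(abundance)) {
    abundance_note <- "no abundance table supplied"
  } else {
    have <- cls_rbp$one$in_member %in% names(abundance) &
      cls_rbp$one$out_member %in% names(abundance)
    if (any(!have)) {
      warning(sum(!have), " one-in pair(s) dropped: abundance missing")
    }
    if (sum(have) == 0) {
      abundance_note <- "no one-in pair with abundance for both members"
    } else {
      abundance_test <- mann_whitney(
        unname(abundance[cls_rbp$one$in_member[have]]),
        unname(abundance[cls_rbp$one$out_member[have]])
      )
    }
  }

  enrichment <- NULL
  unique_diff <- cls_diff$one$in_member
  if (length(differential_set) == 0 || length(unique_diff) == 0) {
    warning("no unique differential paralogs: enrichment skipped")
  } else if (!is.null(collection)) {
    if (is.null(background)) background <- unique(c(pairs$a, pairs$b))
    enrichment <- ora(unique_diff, collection, background, min_overlap)
  }

  list(rbp_classification = cls_rbp,
       differential_classification = cls_diff,
       abundance_test = abundance_test,
       abundance_note = abundance_note,
       enrichment = enrichment)
}
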