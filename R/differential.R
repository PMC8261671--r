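# Differential association statistic for unpaired replicate designs:
# the average pairwise log2 fold-change (every stress replicate against
# every untreated replicate), a shuffle-based null of resampled mean
# fold-changes, a fold-change threshold grid giving the percentage of null
# means beyond each threshold (the empirical FDR), and an ordinary
# least-squares line FDR ~ threshold used to assign an FDR to every
# observed average fold-change.

#' Average pairwise log2 fold-changes
#'
#' For each protein, forms every ordered cross-condition pair
#' (stress replicate i, untreated replicate j) of log2-transformed
#' normalized values and records the difference; the per-protein statistic
#' is the arithmetic mean of those pairwise fold-changes (9 pairs in the
#' canonical 3x3 design). Within-condition pairs are never formed.
#'
#' @param norm a `normalized_dataset` from [preprocess()] or
#'   [normalize_total_area()].
#' @return a `pairwise_fc`: list with `fc` (proteins x pairs matrix),
#'   `avg_fc` (named vector), `pairs` (labels), `proteins`.
#' @export
compute_pairwise_fcs <- function(norm) {
  if (is.null(norm$log2_values)) {
    stop("dataset has no log2_values; run normalize_total_area() first")
  }
  s_ids <- design_samples(norm$design, "biological", "stress")
  u_ids <- design_samples(norm$design, "biological", "untreated")
  if (length(s_ids) == 0 || length(u_ids) == 0) {
    stop("need >= 1 biological replicate in each condition")
  }
  pairs <- expand.grid(stress = s_ids, untreated = u_ids,
                       stringsAsFactors = FALSE)
  fc <- norm$log2_values[, pairs$stress, drop = FALSE] -
    norm$log2_values[, pairs$untreated, drop = FALSE]
  colnames(fc) <- paste(pairs$stress, pairs$untreated, sep = "/")
  rownames(fc) <- norm$proteins
  avg <- rowMeans(fc)
  structure(list(fc = fc, avg_fc = avg, pairs = colnames(fc),
                 proteins = norm$proteins),
            class = "pairwise_fc")
}

#' Shuffle-based null distribution of mean fold-changes
#'
#' Pools every per-protein pairwise fold-change into one global vector;
#' each of `n_experiments` random experiments draws `pairs-per-protein`
#' values from the pool without replacement and records their mean. The
#' spread of those null means is what the FDR grid is computed from.
#'
#' @param pairwise a [compute_pairwise_fcs()] result.
#' @param n_experiments number of random experiments (default 10000).
#' @param seed RNG seed (bit-reproducible given the seed).
#' @return a partially filled `null_model`: `pooled_fcs`, `null_means`,
#'   `n_experiments`, `seed`.
#' @export
build_null_distribution <- function(pairwise, n_experiments = 10000,
                                    seed = 1) {
  pool <- as.vector(pairwise$fc)
  k <- ncol(pairwise$fc)
  if (length(pool) < k) {
    stop("fold-change pool (", length(pool),
         ") smaller than one experiment's draw (", k, ")")
  }
  set.seed(seed)
  null_means <- vapply(seq_len(n_experiments), function(i) {
    mean(pool[sample.int(length(pool), k)])
  }, numeric(1))
  structure(list(pooled_fcs = pool, null_means = null_means,
                 pairs_per_protein = k, n_experiments = n_experiments,
                 seed = seed),
            class = "null_model")
}

#' Sign-flip variant of the shuffle null
#'
#' Alternative null (`shuffle_scope = within_protein_signflip`): each
#' random experiment picks one protein uniformly, flips the sign of each of
#' its pairwise fold-changes independently with probability 1/2, and
#' records the mean. Preserves the within-protein correlation structure
#' that global pooling discards. Not used by the default pipeline.
#'
#' @inheritParams build_null_distribution
#' @return a `null_model` as in [build_null_distribution()].
#' @export
build_null_distribution_signflip <- function(pairwise, n_experiments = 10000,
                                             seed = 1) {
  k <- ncol(pairwise$fc)
  n_p <- nrow(pairwise$fc)
  if (n_p < 1) stop("no proteins in the fold-change table")
  set.seed(seed)
  null_means <- vapply(seq_len(n_experiments), function(i) {
    row <- pairwise$fc[sample.int(n_p, 1), ]
    mean(row * sample(c(-1, 1), k, replace = TRUE))
  }, numeric(1))
  structure(list(pooled_fcs = as.vector(pairwise$fc),
                 null_means = null_means, pairs_per_protein = k,
                 n_experiments = n_experiments, seed = seed,
                 shuffle_scope = "within_protein_signflip"),
            class = "null_model")
}

#' Default threshold grid for a tail mode
#'
#' Signed mode: -10 to 10 in 0.5 increments (41 thresholds, the literal
#' grid). Folded mode (default elsewhere): 0 to 10 in 0.5 increments,
#' applied to |null mean|.
#' @param tail_mode `"folded"` or `"signed"`.
#' @export
default_thresholds <- function(tail_mode = c("folded", "signed")) {
  tail_mode <- match.arg(tail_mode)
  if (tail_mode == "signed") seq(-10, 10, by = 0.5) else seq(0, 10, by = 0.5)
}

#' Percentage of null means beyond each threshold (the FDR grid)
#'
#' @param null_means numeric vector of resampled mean fold-changes.
#' @param thresholds ascending numeric grid; defaults per `tail_mode`.
#' @param tail_mode `"folded"` (percent of |null| >= t) or `"signed"`
#'   (percent of null >= t).
#' @return numeric vector of percentages in [0, 100], one per threshold.
#' @export
compute_fdr_grid <- function(null_means, thresholds = NULL,
                             tail_mode = c("folded", "signed")) {
  tail_mode <- match.arg(tail_mode)
  if (is.null(thresholds)) thresholds <- default_thresholds(tail_mode)
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  x <- if (tail_mode == "folded") abs(null_means) else null_means
  vapply(thresholds, function(t) 100 * (sum(x >= t) / length(x)),
         numeric(1))
}

#' Ordinary least-squares fit of the FDR grid on its thresholds
#'
#' @param thresholds,grid_fdr parallel numeric vectors.
#' @return named vector `c(intercept, slope)`.
#' @export
fit_fdr_model <- function(thresholds, grid_fdr) {
  if (length(thresholds) != length(grid_fdr)) {
    stop("thresholds and grid_fdr lengths differ")
  }
  if (length(unique(thresholds)) < 2) {
    stop("singular fit: need >= 2 distinct thresholds")
  }
  fit <- stats::lm.fit(cbind(1, thresholds), grid_fdr)
  cf <- unname(fit$coefficients)
  c(intercept = cf[1], slope = cf[2])
}

#' Complete a null model: grid, linear coefficients
#'
#' @param model a `null_model` from [build_null_distribution()].
#' @param thresholds grid (defaults per `tail_mode`).
#' @param tail_mode `"folded"` (default) or `"signed"`.
#' @return the model with `thresholds`, `grid_fdr`, `intercept`, `slope`,
#'   `tail_mode` filled in.
#' @export
fit_null_model <- function(model, thresholds = NULL,
                           tail_mode = c("folded", "signed")) {
  tail_mode <- match.arg(tail_mode)
  if (is.null(thresholds)) thresholds <- default_thresholds(tail_mode)
  grid <- compute_fdr_grid(model$null_means, thresholds, tail_mode)
  cf <- fit_fdr_model(thresholds, grid)
  model$thresholds <- thresholds
  model$grid_fdr <- grid
  model$intercept <- cf[["intercept"]]
  model$slope <- cf[["slope"]]
  model$tail_mode <- tail_mode
  model
}

#' Assign FDRs to observed average fold-changes
#'
#' The fitted line is evaluated at |avg_fc| (for negative fold-changes the
#' mirrored model is used, i.e. the line is applied to -avg_fc) and clamped
#' to [0, 100]. A protein is significant when its FDR percentage is at or
#' below `cutoff`; its direction is `more` (avg_fc > 0) or `less`
#' (avg_fc < 0).
#'
#' @param avg_fc named numeric vector of average log2 fold-changes.
#' @param model a fitted `null_model` (see [fit_null_model()]).
#' @param cutoff FDR percentage cutoff (default 5).
#' @param method method label recorded in the table.
#' @return a `differential_table` data.frame: `protein_id`, `avg_fc`,
#'   `fdr_percent`, `significant`, `direction`, `method`.
#' @export
assign_fdr <- function(avg_fc, model, cutoff = 5, method = NA_character_) {
  if (is.null(model$intercept)) stop("null model is not fitted")
  raw <- model$intercept + model$slope * abs(avg_fc)
  fdr <- pmin(pmax(raw, 0), 100)
  direction <- ifelse(avg_fc > 0, "more",
                      ifelse(avg_fc < 0, "less", NA_character_))
  out <- data.frame(
    protein_id = if (is.null(names(avg_fc))) as.character(seq_along(avg_fc))
                 else names(avg_fc),
    avg_fc = unname(avg_fc),
    fdr_percent = unname(fdr),
    significant = unname(fdr <= cutoff),
    direction = unname(direction),
    method = method,
    stringsAsFactors = FALSE
  )
  class(out) <- c("differential_table", "data.frame")
  out
}

#' End-to-end differential call for one quantification method
#'
#' @param norm a preprocessed `normalized_dataset`.
#' @param n_experiments random experiments for the null (default 10000).
#' @param thresholds grid override (defaults per `tail_mode`).
#' @param tail_mode `"folded"` (default) or `"signed"`.
#' @param cutoff FDR percentage cutoff (default 5).
#' @param seed RNG seed for the shuffle null.
#' @param method method label; defaults to the design's method.
#' @return list with `table` (a `differential_table`), `null_model`, and
#'   `pairwise`.
#' @export
call_differential <- function(norm, n_experiments = 10000, thresholds = NULL,
                              tail_mode = c("folded", "signed"), cutoff = 5,
                              seed = 1, method = NULL) {
  tail_mode <- match.arg(tail_mode)
  if (is.null(method)) method <- unique(norm$design$method)[1]
  pw <- compute_pairwise_fcs(norm)
  nm <- build_null_distribution(pw, n_experiments, seed)
  nm <- fit_null_model(nm, thresholds, tail_mode)
  tab <- assign_fdr(pw$avg_fc, nm, cutoff, method)
  list(table = tab, null_model = nm, pairwise = pw)
}

#' Serialize a fitted null model to JSON
#' @param model a fitted `null_model`.
#' @param path output path.
#' @export
write_null_model <- function(model, path) {
  out <- list(
    n_experiments = model$n_experiments,
    pairs_per_protein = model$pairs_per_protein,
    pool_size = length(model$pooled_fcs),
    pool_mean = mean(model$pooled_fcs),
    pool_sd = stats::sd(model$pooled_fcs),
    tail_mode = model$tail_mode,
    thresholds = model$thresholds,
    grid_fdr = model$grid_fdr,
    intercept = model$intercept,
    slope = model$slope,
    seed = model$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
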