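# QC summaries (replicate and cross-method Pearson correlations,
# fold-change dispersion) and the end-to-end pipeline driver.

#' Pearson correlation with detected-in-both filtering
#'
#' Product-moment correlation after removing positions where both entries
#' are missing/zero (undetected in both samples) or either is `NA`.
#' Returns `NA` with a reason attribute when fewer than 3 complete pairs
#' remain or either vector has zero variance.
#'
#' @param x,y numeric vectors of equal length.
#' @param drop_zero_pairs drop positions where both values are 0
#'   (default TRUE; the convention used for sample-vs-sample log2
#'   intensity correlations).
#' @return the correlation, or `NA` with attribute `reason`.
#' @export
pearson_correlation <- function(x, y, drop_zero_pairs = TRUE) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- !(is.na(x) | is.na(y))
  if (drop_zero_pairs) keep <- keep & !(x == 0 & y == 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  stats::cor(x, y)
}

#' Standard deviation of the average fold-changes of a method
#'
#' Sample (n - 1) standard deviation of `avg_fc` over all retained
#' proteins; the per-method dispersion statistic reported alongside the
#' differential calls.
#'
#' @param table a `differential_table`.
#' @return numeric scalar.
#' @export
fc_dispersion <- function(table) {
  if (nrow(table) < 2) stop("fc_dispersion needs >= 2 proteins")
  stats::sd(table$avg_fc)
}

# correlation matrix over the columns of a log2-value matrix
sample_correlation_matrix <- function(log2_values, raw_areas) {
  ids <- colnames(log2_values)
  n <- length(ids)
  r <- diag(1, n)
  dimnames(r) <- list(ids, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      detected <- raw_areas[, i] > 0 & raw_areas[, j] > 0
      val <- if (sum(detected) >= 3) {
        pearson_correlation(log2_values[detected, i],
                            log2_values[detected, j],
                            drop_zero_pairs = FALSE)
      } else NA_real_
      r[i, j] <- r[j, i] <- as.numeric(val)
    }
  }
  r
}

#' QC report for a multi-method run
#'
#' @param norm_list named list of preprocessed `normalized_dataset`s.
#' @param diff_list named list of [call_differential()] results, parallel
#'   to `norm_list`.
#' @param reports optional list of per-method filter reports.
#' @param meta optional metadata list echoed into the report.
#' @return a `qc_report`: per-method biological-replicate correlation
#'   matrices, a cross-method correlation matrix on avg_fc over shared
#'   proteins, per-method fold-change dispersions, filter reports,
#'   metadata.
#' @export
qc_report <- function(norm_list, diff_list, reports = NULL, meta = list()) {
  methods <- names(norm_list)
  replicate_cor <- lapply(methods, function(m) {
    norm <- norm_list[[m]]
    bio <- design_samples(norm$design, assay = "biological")
    sample_correlation_matrix(norm$log2_values[, bio, drop = FALSE],
                              norm$areas[, bio, drop = FALSE])
  })
  names(replicate_cor) <- methods

  fc_tabs <- lapply(diff_list, `[[`, "table")
  shared <- Reduce(intersect, lapply(fc_tabs, `[[`, "protein_id"))
  method_cor <- diag(1, length(methods))
  dimnames(method_cor) <- list(methods, methods)
  if (length(shared) >= 3) {
    fcs <- vapply(fc_tabs, function(t) {
      t$avg_fc[match(shared, t$protein_id)]
    }, numeric(length(shared)))
    for (i in seq_along(methods)) {
      for (j in seq_along(methods)[-seq_len(i)]) {
        method_cor[i, j] <- method_cor[j, i] <-
          as.numeric(pearson_correlation(fcs[, i], fcs[, j],
                                         drop_zero_pairs = FALSE))
      }
    }
  }
  dispersion <- vapply(fc_tabs, fc_dispersion, numeric(1))
  structure(list(replicate_correlation = replicate_cor,
                 method_correlation = method_cor,
                 fc_dispersion = dispersion,
                 filter_reports = reports,
                 meta = meta),
            class = "qc_report")
}

#' Pipeline configuration
#'
#' @param simulate optional [simulation_params()]: generate the inputs.
#' @param inputs optional named list (one entry per method) of
#'   `list(quant = <path>)`; requires `design`.
#' @param design optional design TSV path or `sample_design` covering all
#'   methods (ignored when simulating).
#' @param min_peptides,total,ratio,min_reps,renormalize_after_filters
#'   preprocessing settings (see [preprocess()]).
#' @param n_experiments,tail_mode,fdr_cutoff differential settings.
#' @param min_methods consensus rule (default 2).
#' @param seed master seed; per-method null seeds are `seed + method index`.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL, design = NULL,
                            min_peptides = 2, total = 1e6, ratio = 3,
                            min_reps = 2, renormalize_after_filters = FALSE,
                            n_experiments = 10000,
                            tail_mode = c("folded", "signed"),
                            fdr_cutoff = 5, min_methods = 2, seed = 1,
                            out_dir = NULL) {
  structure(list(simulate = simulate, inputs = inputs, design = design,
                 min_peptides = min_peptides, total = total, ratio = ratio,
                 min_reps = min_reps,
                 renormalize_after_filters = renormalize_after_filters,
                 n_experiments = n_experiments,
                 tail_mode = match.arg(tail_mode),
                 fdr_cutoff = fdr_cutoff, min_methods = min_methods,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Preprocesses each method's quantification table, calls differential
#' proteins per method, integrates methods into a consensus and assembles
#' a QC report. With `config$simulate` set, inputs are generated by
#' [simulate_ric_experiment()] and the returned object additionally
#' carries the ground truth and recovery metrics. With `config$out_dir`
#' set, deterministic TSV/JSON artifacts are written (two runs with the
#' same config are byte-identical).
#'
#' @param config a [pipeline_config()].
#' @return list: `differential` (per-method), `consensus`, `qc`,
#'   `preprocessed`, and when simulating `truth` + `recovery`.
#' @export
run_pipeline <- function(config) {
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_ric_experiment(config$simulate)
    datasets <- sim$datasets
    truth <- sim$truth
  } else {
    if (is.null(config$inputs) || is.null(config$design)) {
      stop("config needs either 'simulate' or 'inputs' + 'design'")
    }
    full_design <- if (is.character(config$design)) {
      read_design(config$design)
    } else config$design
    datasets <- lapply(names(config$inputs), function(m) {
      d <- full_design[full_design$method == m, , drop = FALSE]
      if (nrow(d) == 0) stop("design has no samples for method '", m, "'")
      read_quant_table(config$inputs[[m]]$quant, d)
    })
    names(datasets) <- names(config$inputs)
  }
  if (length(datasets) < 2) stop("consensus requires >= 2 methods")

  norm_list <- list()
  reports <- list()
  diff_list <- list()
  for (i in seq_along(datasets)) {
    m <- names(datasets)[i]
    pp <- preprocess(datasets[[i]], config$min_peptides, config$total,
                     config$ratio, config$min_reps,
                     config$renormalize_after_filters)
    norm_list[[m]] <- pp$data
    reports[[m]] <- pp$reports
    diff_list[[m]] <- call_differential(
      pp$data, n_experiments = config$n_experiments,
      tail_mode = config$tail_mode, cutoff = config$fdr_cutoff,
      seed = config$seed + i, method = m)
  }
  consensus <- integrate_methods(lapply(diff_list, `[[`, "table"),
                                 config$min_methods, config$fdr_cutoff)
  meta <- list(seed = config$seed, tail_mode = config$tail_mode,
               n_experiments = config$n_experiments,
               fdr_cutoff = config$fdr_cutoff,
               min_methods = config$min_methods,
               null_seeds = config$seed + seq_along(datasets))
  qc <- qc_report(norm_list, diff_list, reports, meta)

  result <- list(differential = diff_list, consensus = consensus, qc = qc,
                 preprocessed = norm_list)
  if (!is.null(truth)) {
    result$truth <- truth
    result$recovery <- summarize_truth(truth, consensus)
  }
  if (!is.null(config$out_dir)) write_pipeline_results(result, config)
  result
}

# deterministic writers: no timestamps, fixed column orders
write_pipeline_results <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(result$differential)) {
    utils::write.table(result$differential[[m]]$table,
                       file.path(config$out_dir,
                                 paste0("differential_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_null_model(result$differential[[m]]$null_model,
                     file.path(config$out_dir,
                               paste0("null_model_", m, ".json")))
  }
  utils::write.table(result$consensus,
                     file.path(config$out_dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$truth)) {
    utils::write.table(result$truth,
                       file.path(config$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    seed = config$seed, tail_mode = config$tail_mode,
    n_experiments = config$n_experiments, fdr_cutoff = config$fdr_cutoff,
    min_methods = config$min_methods, min_peptides = config$min_peptides,
    ratio = config$ratio, min_reps = config$min_reps,
    fc_dispersion = as.list(result$qc$fc_dispersion),
    n_selected = sum(result$consensus$selected)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
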