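# In-code fixture builders shared across test files.

# 12-sample canonical design (3 bio + 3 ctrl per condition) for one method
toy_design <- function(method = "M1") canonical_design(method = method)

# quant_dataset with explicit per-(condition, assay) area triples
# each of u_bio, u_ctrl, s_bio, s_ctrl: proteins x 3 matrix
build_quant <- function(u_bio, u_ctrl, s_bio, s_ctrl, peptides = 5,
                        method = "M1", proteins = NULL) {
  u_bio <- rbind(u_bio); u_ctrl <- rbind(u_ctrl)
  s_bio <- rbind(s_bio); s_ctrl <- rbind(s_ctrl)
  n <- nrow(u_bio)
  if (is.null(proteins)) proteins <- sprintf("P%d", seq_len(n))
  d <- canonical_design(method = method)
  areas <- matrix(0, n, 12)
  blocks <- list(u_bio, u_ctrl, s_bio, s_ctrl)
  sel <- list(design_samples(d, "biological", "untreated"),
              design_samples(d, "competition_control", "untreated"),
              design_samples(d, "biological", "stress"),
              design_samples(d, "competition_control", "stress"))
  colnames(areas) <- d$sample_id
  for (i in 1:4) areas[, sel[[i]]] <- blocks[[i]]
  pc <- matrix(peptides, n, 12)
  pc[areas == 0] <- 0
  quant_dataset(proteins, areas, pc, d)
}

# a normalized_dataset with prescribed log2 values for the biological
# samples (controls zero), bypassing preprocessing; untreated/stress each
# proteins x n_reps
fake_norm <- function(untreated_log2, stress_log2, method = "M1") {
  untreated_log2 <- rbind(untreated_log2)
  stress_log2 <- rbind(stress_log2)
  n <- nrow(untreated_log2)
  n_reps <- ncol(untreated_log2)
  d <- canonical_design(method = method, n_reps = n_reps)
  log2v <- matrix(0, n, nrow(d), dimnames = list(NULL, d$sample_id))
  log2v[, design_samples(d, "biological", "untreated")] <- untreated_log2
  log2v[, design_samples(d, "biological", "stress")] <- stress_log2
  proteins <- sprintf("P%d", seq_len(n))
  x <- quant_dataset(proteins, 2^log2v - 1, matrix(5L, n, nrow(d)), d)
  x$normalized <- 2^log2v - 1
  x$log2_values <- log2v
  class(x) <- c("normalized_dataset", "quant_dataset")
  x
}

# a fitted null model with prescribed line, for assign_fdr unit tests
fake_model <- function(intercept, slope, tail_mode = "folded") {
  structure(list(intercept = intercept, slope = slope,
                 tail_mode = tail_mode, n_experiments = 0),
            class = "null_model")
}

# minimal differential_table built from avg_fc values via a fixed line
fake_diff_table <- function(avg_fc, fdr, method) {
  out <- data.frame(protein_id = names(avg_fc), avg_fc = unname(avg_fc),
                    fdr_percent = unname(fdr),
                    significant = unname(fdr <= 5),
                    direction = ifelse(avg_fc > 0, "more",
                                       ifelse(avg_fc < 0, "less",
                                              NA_character_)),
                    method = method, stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

# sample one value from a vector, safe for length-1 vectors
samp1 <- function(v) v[sample.int(length(v), 1)]

extdata <- function(name) {
  system.file("extdata", name, package = "ricdiff", mustWork = TRUE)
}
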