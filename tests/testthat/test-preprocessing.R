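# preprocessing: the filter cascade and total-area normalization

test_that("peptide filter uses the max over biological samples only", {
  d <- toy_design()
  areas <- matrix(10, 3, 12, dimnames = list(NULL, d$sample_id))
  pc <- matrix(0L, 3, 12, dimnames = list(NULL, d$sample_id))
  bio <- design_samples(d, "biological")
  pc[1, bio] <- c(1L, 2L, 0L, 1L, 1L, 1L)  # max 2 -> retained
  pc[2, bio] <- 1L                          # max 1 -> removed
  pc[3, bio] <- c(0L, 0L, 2L, 0L, 0L, 0L)  # max 2 -> retained
  pc[2, design_samples(d, "competition_control")] <- 9L  # ignored
  x <- quant_dataset(c("A", "B", "C"), areas, pc, d)
  res <- filter_min_peptides(x)
  expect_equal(res$data$proteins, c("A", "C"))
  expect_equal(res$report$proteins_in, 3)
  expect_equal(res$report$proteins_out, 2)
  expect_equal(res$report$removed, "B")
})

test_that("normalization scales each column to the target and logs", {
  x <- build_quant(u_bio = cbind(c(2, 3, 5), c(1, 1, 2), c(4, 4, 2)),
                   u_ctrl = matrix(1, 3, 3),
                   s_bio = matrix(1, 3, 3), s_ctrl = matrix(1, 3, 3))
  norm <- normalize_total_area(x)
  u1 <- design_samples(x$design, "biological", "untreated")[1]
  expect_equal(unname(norm$normalized[, u1]), c(2e5, 3e5, 5e5))
  expect_equal(colSums(norm$normalized), colSums(norm$normalized) * 0 + 1e6,
               ignore_attr = TRUE)
  # pseudocount-1 log2: normalized 0 -> 0, 1 -> 1, 3 -> 2
  expect_equal(log2(c(0, 1, 3) + 1), c(0, 1, 2))
  expect_equal(norm$log2_values, log2(norm$normalized + 1))
  expect_true(all(norm$log2_values >= 0))
})

test_that("all-zero sample columns are preserved with a warning", {
  x <- build_quant(u_bio = cbind(c(5, 5), c(0, 0), c(3, 3)),
                   u_ctrl = matrix(1, 2, 3),
                   s_bio = matrix(2, 2, 3), s_ctrl = matrix(1, 2, 3))
  expect_warning(norm <- normalize_total_area(x), "zero total")
  zero_col <- design_samples(x$design, "biological", "untreated")[2]
  expect_equal(unname(norm$normalized[, zero_col]), c(0, 0))
})

test_that("control-enrichment filter: inclusive threshold, both
           conditions, zero-control convention", {
  mk <- function(u_bio_mean, s_bio_mean, u_ctrl_mean, s_ctrl_mean) {
    build_quant(u_bio = matrix(u_bio_mean, 1, 3),
                u_ctrl = matrix(u_ctrl_mean, 1, 3),
                s_bio = matrix(s_bio_mean, 1, 3),
                s_ctrl = matrix(s_ctrl_mean, 1, 3))
  }
  # boundary inclusive: 10 >= 9 and 9 >= 9
  expect_length(filter_control_enrichment(mk(10, 9, 3, 3))$data$proteins, 1)
  # 8 < 9 in stress -> removed
  expect_length(filter_control_enrichment(mk(10, 8, 3, 3))$data$proteins, 0)
  # control mean 0 passes iff biological mean > 0 (D-pre-3)
  expect_length(filter_control_enrichment(mk(10, 5, 3, 0))$data$proteins, 1)
  expect_length(filter_control_enrichment(mk(10, 0, 3, 0))$data$proteins, 0)
  # missing control samples for a condition is a configuration error
  d <- toy_design()
  keep <- !(d$assay == "competition_control" & d$condition == "stress")
  d2 <- d[keep, ]
  x <- quant_dataset("A", matrix(1, 1, sum(keep)),
                     matrix(2L, 1, sum(keep)), d2)
  expect_error(filter_control_enrichment(x), "no competition-control")
})

test_that("replicate-presence filter needs 2 of 3 in one condition", {
  x <- build_quant(
    u_bio = rbind(c(0, 5, 7), c(0, 0, 4), c(9, 9, 9)),
    u_ctrl = matrix(0, 3, 3),
    s_bio = rbind(c(0, 0, 3), c(6, 0, 0), c(1, 1, 0)),
    s_ctrl = matrix(0, 3, 3))
  res <- filter_replicate_presence(x)
  # P1: 2 nonzero untreated -> kept; P2: 1 and 1 -> removed;
  # P3: kept regardless of stress pattern
  expect_equal(res$data$proteins, c("P1", "P3"))
  expect_equal(res$report$removed, "P2")
})

test_that("the full cascade reproduces the hand-computed toy fixture", {
  design <- read_design(extdata("toy_design.tsv"))
  x <- read_quant_table(extdata("toy_quant.tsv"), design)
  pp <- preprocess(x)
  expected <- read.delim(extdata("toy_expected_stages.tsv"),
                         stringsAsFactors = FALSE)
  got <- do.call(rbind, lapply(pp$reports, function(r) {
    data.frame(stage = r$stage, proteins_in = r$proteins_in,
               proteins_out = r$proteins_out,
               removed = paste(sort(r$removed), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  expect_equal(got, expected)
  survivors <- readLines(extdata("toy_expected_survivors.txt"))
  expect_identical(pp$data$proteins, survivors)
})

test_that("filters never add proteins; already-clean data passes through", {
  sim <- simulate_ric_experiment(simulation_params(n_proteins = 200,
                                                   seed = 2))
  x <- sim$datasets$LFQ
  pp <- preprocess(x)
  prev <- x$proteins
  for (r in pp$reports) {
    expect_true(all(setdiff(prev, r$removed) %in% prev))
    expect_lte(r$proteins_out, r$proteins_in)
    expect_equal(r$proteins_in - r$proteins_out, length(r$removed))
    prev <- setdiff(prev, r$removed)
  }
  expect_setequal(pp$data$proteins, prev)

  # idempotence: stages 1, 4, 5 remove nothing on a second pass
  pp2 <- preprocess(pp$data)
  for (r in pp2$reports) expect_length(r$removed, 0)
})

test_that("normalization conservation after filtering", {
  sim <- simulate_ric_experiment(simulation_params(n_proteins = 300,
                                                   seed = 4))
  # default: factors fixed on the peptide-filtered table -> sums <= 1e6
  pp <- preprocess(sim$datasets$TOP3)
  expect_true(all(colSums(pp$data$normalized) <= 1e6 * (1 + 1e-9)))
  # renormalized: every nonzero column sums to exactly 1e6
  pp <- preprocess(sim$datasets$TOP3, renormalize_after_filters = TRUE)
  sums <- colSums(pp$data$normalized)
  nz <- sums > 0
  expect_equal(sums[nz], rep(1e6, sum(nz)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("every protein failing the peptide filter empties the output", {
  x <- build_quant(u_bio = matrix(4, 2, 3), u_ctrl = matrix(1, 2, 3),
                   s_bio = matrix(4, 2, 3), s_ctrl = matrix(1, 2, 3),
                   peptides = 1)
  pp <- preprocess(x)
  expect_length(pp$data$proteins, 0)
  expect_equal(pp$reports[[1]]$proteins_out, 0)
})
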