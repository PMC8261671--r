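# Synthetic RIC experiment generator.
#
# The generator emulates the structure of a poly(A)-capture differential
# RBPome study: a shared latent proteome observed through three correlated
# label-free quantification readouts (TOP3/iBAQ/LFQ), 3 biological
# replicates per condition plus matched poly(A) competition controls,
# lognormal base abundance, method-specific scaling of the true stress
# effect, replicate noise in log2 units, competition-control suppression
# for genuine poly(A) binders, abundance-dependent dropout, and peptide
# counts tied to abundance. Every draw flows from one seeded RNG, so equal
# seeds give bit-identical output.

#' Simulation parameters
#'
#' Defaults encode the canonical study conditions: 3 biological replicates
#' per condition plus matched controls; ~80% of detected proteins genuine
#' poly(A) binders; ~25% of binders truly differential with ~58% of effects
#' positive; replicate noise sd 0.5 in log2 units; per-method effect scales
#' TOP3 1.5, iBAQ 0.8, LFQ 1.0 (TOP3 overestimates and LFQ/iBAQ
#' underestimate relative changes); competition controls suppressed 20-fold
#' for true binders.
#'
#' @param n_proteins number of simulated proteins (default 1000).
#' @param f_rbp fraction of proteins that genuinely bind poly(A) RNA.
#' @param f_diff fraction of binders that truly change association.
#' @param f_up fraction of true effects with positive sign.
#' @param effect_mean,effect_sd mean and sd of the absolute true log2
#'   effect (truncated normal, left-truncated at 0).
#' @param sigma_rep replicate noise sd, log2 units.
#' @param method_scales named numeric vector of per-method multipliers on
#'   the true effect.
#' @param control_suppression ratio of competition-control to biological
#'   mean area for true binders (default 1/20).
#' @param dropout_midpoint,dropout_steepness logistic missingness on the
#'   latent log2 cell intensity: P(dropout) =
#'   plogis(dropout_steepness * (dropout_midpoint - latent log2)).
#' @param n_reps biological replicates per condition.
#' @param seed RNG seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_proteins = 1000,
                              f_rbp = 0.8,
                              f_diff = 0.25,
                              f_up = 0.58,
                              effect_mean = 1.5,
                              effect_sd = 0.75,
                              sigma_rep = 0.5,
                              method_scales = c(TOP3 = 1.5, iBAQ = 0.8,
                                                LFQ = 1.0),
                              control_suppression = 1 / 20,
                              dropout_midpoint = 8,
                              dropout_steepness = 0.8,
                              n_reps = 3,
                              seed = 1) {
  p <- list(n_proteins = as.integer(n_proteins), f_rbp = f_rbp,
            f_diff = f_diff, f_up = f_up, effect_mean = effect_mean,
            effect_sd = effect_sd, sigma_rep = sigma_rep,
            method_scales = method_scales,
            control_suppression = control_suppression,
            dropout_midpoint = dropout_midpoint,
            dropout_steepness = dropout_steepness,
            n_reps = as.integer(n_reps), seed = as.integer(seed))
  class(p) <- "simulation_params"
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  if (p$n_proteins < 10) {
    stop("n_proteins must be >= 10 (the pipeline degenerates below that)")
  }
  fracs <- c(f_rbp = p$f_rbp, f_diff = p$f_diff, f_up = p$f_up)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (p$effect_sd < 0 || p$sigma_rep < 0) stop("sds must be >= 0")
  if (any(p$method_scales <= 0)) stop("method_scales must be > 0")
  if (is.null(names(p$method_scales)) || anyDuplicated(names(p$method_scales))) {
    stop("method_scales must carry unique method names")
  }
  invisible(p)
}

# |delta| ~ Normal(mean, sd) truncated at 0, via inverse CDF so exactly one
# uniform is consumed per protein (stable draw budget across parameters).
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate a multi-method RIC experiment with known ground truth
#'
#' @param params a [simulation_params()].
#' @return list with `datasets` (named list, one [quant_dataset()] per
#'   method), `truth` (data.frame: `protein_id`, `is_rbp`,
#'   `is_differential`, `true_delta`) and `params`.
#' @details Subgroup sizes are deterministic rounds
#'   (`n_rbp = round(f_rbp * n_proteins)` etc.) assigned to the head of a
#'   seeded random protein order, so count-based checks are exact. The
#'   latent truth is shared across methods; replicate noise and dropout are
#'   drawn independently per method.
#' @export
simulate_ric_experiment <- function(params = simulation_params()) {
  validate_simulation_params(params)
  p <- params
  set.seed(p$seed)
  n <- p$n_proteins
  proteins <- sprintf("P%04d", seq_len(n))

  # (1) latent base abundance, arbitrary MS intensity units
  base <- stats::rlnorm(n, meanlog = log(1e4), sdlog = 1.5)
  log2_base <- log2(base)

  # (2) deterministic subgroup counts on a seeded random order
  ord <- sample.int(n)
  n_rbp <- round(p$f_rbp * n)
  n_diff <- round(p$f_diff * n_rbp)
  n_up <- round(p$f_up * n_diff)
  is_rbp <- logical(n); is_rbp[ord[seq_len(n_rbp)]] <- TRUE
  is_diff <- logical(n)
  if (n_diff > 0) is_diff[ord[seq_len(n_diff)]] <- TRUE
  sign_up <- logical(n)
  if (n_up > 0) sign_up[ord[seq_len(n_up)]] <- TRUE

  # (3) true signed log2 effects
  mag <- rtruncnorm_pos(n, p$effect_mean, p$effect_sd)
  true_delta <- ifelse(is_diff, ifelse(sign_up, mag, -mag), 0)

  lambda_pep <- pmax(0, log2_base - 8)

  datasets <- list()
  for (m in names(p$method_scales)) {
    design <- canonical_design(method = m, n_reps = p$n_reps)
    n_s <- nrow(design)
    stress <- design$condition == "stress"
    ctrl <- design$assay == "competition_control"
    # latent log2 mean per cell: condition effect scaled per method;
    # controls of true binders suppressed control_suppression-fold
    latent <- outer(log2_base, rep(1, n_s)) +
      outer(p$method_scales[[m]] * true_delta, as.numeric(stress)) +
      outer(ifelse(is_rbp, log2(p$control_suppression), 0),
            as.numeric(ctrl))
    noise <- matrix(stats::rnorm(n * n_s, 0, p$sigma_rep), n, n_s)
    areas <- 2^(latent + noise)
    # (6) abundance-dependent dropout on the latent (pre-noise) intensity
    p_drop <- stats::plogis(p$dropout_steepness *
                              (p$dropout_midpoint - latent))
    dropped <- matrix(stats::runif(n * n_s), n, n_s) < p_drop
    areas[dropped] <- 0
    # (7) peptide counts: 1 + Poisson(max(0, log2 base - 8)), 0 if dropped
    pc <- matrix(1L + stats::rpois(n * n_s, rep(lambda_pep, n_s)), n, n_s)
    pc[dropped] <- 0L
    datasets[[m]] <- quant_dataset(proteins, areas, pc, design)
  }

  truth <- data.frame(protein_id = proteins, is_rbp = is_rbp,
                      is_differential = is_diff, true_delta = true_delta,
                      stringsAsFactors = FALSE)
  list(datasets = datasets, truth = truth, params = p)
}

#' Score a consensus call against simulation ground truth
#'
#' Sensitivity and precision are computed over the proteins present in the
#' consensus table (i.e. that survived preprocessing in at least one
#' method); truly differential proteins lost before the consensus stage do
#' not count against sensitivity.
#'
#' @param truth the `truth` data.frame from [simulate_ric_experiment()].
#' @param consensus a consensus table from [integrate_methods()].
#' @return list with `sensitivity`, `precision`, `direction_agreement`
#'   (each `NA` when undefined), and the counts `tp`, `fp`, `fn`.
#' @export
summarize_truth <- function(truth, consensus) {
  unknown <- setdiff(consensus$protein_id, truth$protein_id)
  if (length(unknown) > 0) {
    stop("consensus contains protein IDs absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  idx <- match(consensus$protein_id, truth$protein_id)
  is_diff <- truth$is_differential[idx]
  delta <- truth$true_delta[idx]
  sel <- consensus$selected
  tp <- sum(sel & is_diff)
  fp <- sum(sel & !is_diff)
  fn <- sum(!sel & is_diff)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  agree <- NA_real_
  if (tp > 0) {
    tpi <- which(sel & is_diff)
    want <- ifelse(delta[tpi] > 0, "more", "less")
    agree <- mean(consensus$consensus_direction[tpi] == want)
  }
  list(sensitivity = sens, precision = prec, direction_agreement = agree,
       tp = tp, fp = fp, fn = fn)
}

#' Write a simulated experiment to a directory
#'
#' Emits one quantification TSV per method, one design TSV per method, a
#' combined design, a `truth.tsv`, and an `abundance.tsv` (latent-free
#' observed mean biological areas, usable by the paralog analysis).
#'
#' @param sim result of [simulate_ric_experiment()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  designs <- list()
  for (m in names(sim$datasets)) {
    write_quant_table(sim$datasets[[m]], file.path(dir, paste0("quant_", m, ".tsv")))
    designs[[m]] <- as.data.frame(sim$datasets[[m]]$design)
  }
  write_design(do.call(rbind, c(designs, make.row.names = FALSE)),
               file.path(dir, "design.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  d1 <- sim$datasets[[1]]
  bio <- design_samples(d1$design, assay = "biological")
  ab <- data.frame(protein_id = d1$proteins,
                   abundance = rowMeans(d1$areas[, bio, drop = FALSE]))
  utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
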