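#' Container for planted simulation parameters
#'
#' Holds every ground-truth quantity a simulation planted, so downstream
#' recovery tests can compare estimates against the truth. All components are
#' optional; each generator fills in the ones it controls.
#'
#' @param affinity Matrix transcript x RBP of positive binding affinities.
#' @param expression Named vector of positive expression abundances.
#' @param member_sets Named list of planted gene sets.
#' @param translated_proportion Named vector (or per-condition list) of values
#'   in \[0, 1\].
#' @param half_life Named vector of half-lives in minutes (> 0, may be `Inf`).
#' @param true_fold_enrichment Named vector of positive fold enrichments.
#' @param inconsistent_genes Character vector of transcripts with planted
#'   replicate disagreement above the filter threshold.
#' @param extra List of any additional planted values.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(affinity = NULL, expression = NULL,
                         member_sets = NULL, translated_proportion = NULL,
                         half_life = NULL, true_fold_enrichment = NULL,
                         inconsistent_genes = NULL, extra = NULL) {
  if (!is.null(expression) && any(expression <= 0)) {
    stop("planted expression values must be positive", call. = FALSE)
  }
  if (!is.null(affinity) && any(affinity <= 0)) {
    stop("planted affinities must be positive", call. = FALSE)
  }
  if (!is.null(translated_proportion)) {
    tp <- unlist(translated_proportion)
    if (any(tp < 0 | tp > 1)) {
      stop("planted translated proportions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(half_life) && any(half_life <= 0)) {
    stop("planted half-lives must be positive", call. = FALSE)
  }
  structure(
    list(
      affinity = affinity, expression = expression,
      member_sets = member_sets,
      translated_proportion = translated_proportion,
      half_life = half_life,
      true_fold_enrichment = true_fold_enrichment,
      inconsistent_genes = inconsistent_genes,
      extra = extra
    ),
    class = "ground_truth"
  )
}

#' Simulate a panel of RBP-binding experiments with known truth
#'
#' Draws per-transcript expression abundances and per-RBP binding affinities
#' from the configured lognormal priors, then emits one experiment per
#' replicate of each RBP series:
#'
#' * `CRAC_COUNT`: overdispersed counts with expectation
#'   `depth * affinity * expression / sum(affinity * expression)` (a
#'   gamma-mixed count draw with the configured dispersion; dispersion 0
#'   rounds the expectation half-up). Raw counts therefore confound binding
#'   with abundance, which is what the interactome normalization removes.
#' * `RIP_SCORE`: log-affinity plus Gaussian noise, a continuous score
#'   monotone in affinity at zero noise.
#' * `CLIP_CALL`: binary calls, 1 for the top `bound_fraction` of affinities.
#'
#' @param config A [sim_config()].
#' @return A list with `experiments` (list of [binding_experiment()]) and
#'   `truth` (a [ground_truth()] with `affinity` and `expression`).
#' @export
simulate_binding_experiments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "binding"))
  tx <- config$transcripts
  n <- length(tx)
  expression <- stats::setNames(
    stats::rlnorm(n, config$expression_meanlog, config$expression_sdlog), tx
  )
  rbp_ids <- names(config$rbp_specs)
  affinity <- matrix(NA_real_, n, length(rbp_ids),
                     dimnames = list(tx, rbp_ids))
  experiments <- list()
  for (spec in config$rbp_specs) {
    a <- stats::rlnorm(n, spec$affinity_meanlog, spec$affinity_sdlog)
    affinity[, spec$rbp_id] <- a
    for (r in seq_len(spec$n_replicates)) {
      values <- switch(
        spec$assay,
        CRAC_COUNT = {
          mu <- spec$depth * (a * expression) / sum(a * expression)
          if (config$dispersion == 0) {
            round_half_up(mu)
          } else {
            stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
          }
        },
        RIP_SCORE = log(a) +
          if (spec$score_noise_sd > 0) {
            stats::rnorm(n, 0, spec$score_noise_sd)
          } else 0,
        CLIP_CALL = {
          k <- max(1L, round(n * spec$bound_fraction))
          as.numeric(a >= sort(a, decreasing = TRUE)[k])
        }
      )
      experiments[[length(experiments) + 1L]] <- binding_experiment(
        rbp_id = spec$rbp_id, assay = spec$assay, replicate = r,
        values = stats::setNames(as.numeric(values), tx)
      )
    }
  }
  list(
    experiments = experiments,
    truth = ground_truth(affinity = affinity, expression = expression)
  )
}

# Discretized Gaussian bump over fraction indices, renormalized over 1..F.
peak_weights <- function(n_fractions, center, width) {
  w <- exp(-((seq_len(n_fractions) - center)^2) / (2 * width^2))
  w / sum(w)
}

#' Simulate a polysome-gradient profile with planted translated proportions
#'
#' Each transcript's gradient mass is a two-component mixture: a share
#' `1 - theta` in the light-fraction bump (free mRNPs) and `theta` in the
#' polysomal bump. Observed fraction quantities are the mixture mass times a
#' per-fraction spike recovery factor (uniform in
#' `1 +/- spike_perturbation`) times multiplicative lognormal noise; the
#' spike RNA is emitted per fraction with the same recovery factors, so
#' spike correction can undo them.
#'
#' @param config A [sim_config()]; the `polysome` block sets the gradient
#'   geometry and noise.
#' @param theta Named vector, transcript -> translated proportion in \[0, 1\].
#' @param condition Condition label (also offsets the stage seed so different
#'   conditions get independent noise).
#' @param total_quantity Arbitrary-unit total gradient mass per transcript.
#' @param spike_quantity Arbitrary-unit spike amount per fraction before
#'   recovery perturbation.
#' @return A list with `profile` (a [polysome_profile()]) and `truth`
#'   (planted `translated_proportion` plus the recovery factors in `extra`).
#' @export
simulate_polysome_profiles <- function(config, theta, condition = "wt",
                                       total_quantity = 1000,
                                       spike_quantity = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(theta)) || !all(nzchar(names(theta)))) {
    stop("`theta` must be a named vector (transcript -> proportion)",
         call. = FALSE)
  }
  if (any(theta < 0 | theta > 1)) {
    stop("`theta` values must lie in [0, 1]", call. = FALSE)
  }
  ps <- config$polysome
  seed <- (child_seed(config$seed, "polysome") +
             sum(utf8ToInt(condition))) %% 2147483647
  set.seed(as.integer(seed))
  nf <- ps$n_fractions
  light <- peak_weights(nf, ps$light_peak_fraction, ps$peak_width)
  poly <- peak_weights(nf, ps$poly_peak_fraction, ps$peak_width)
  recovery <- stats::runif(nf, 1 - ps$spike_perturbation,
                           1 + ps$spike_perturbation)
  q <- t(vapply(names(theta), function(t) {
    mix <- (1 - theta[[t]]) * light + theta[[t]] * poly
    total_quantity * mix * recovery * rlnorm_cv(nf, ps$noise_cv)
  }, numeric(nf)))
  spike <- spike_quantity * recovery * rlnorm_cv(nf, ps$noise_cv)
  profile <- polysome_profile(
    quantities = q, spike = spike, condition = condition,
    fraction_classes = if (nf == 14L) default_fraction_classes(nf) else NULL
  )
  list(
    profile = profile,
    truth = ground_truth(
      translated_proportion = theta,
      extra = list(spike_recovery = recovery, condition = condition)
    )
  )
}

#' Simulate a cycloheximide-chase series
#'
#' Relative protein amounts decay as `2^(-t / half_life)` (defined as 1 at
#' `t = 0` before noise) with multiplicative lognormal noise of the
#' configured coefficient of variation. `half_life = Inf` is the no-decay
#' flag value and yields a constant series at 1 (before noise).
#'
#' @param config A [sim_config()]; the `chase` block sets time points and
#'   noise.
#' @param half_life True half-life in minutes (> 0; `Inf` allowed).
#' @param protein,condition Labels (also offset the stage seed).
#' @return A [chase_series()].
#' @export
simulate_chase_series <- function(config, half_life, protein = "protein",
                                  condition = "wt") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(half_life) || length(half_life) != 1L || is.na(half_life) ||
      half_life <= 0) {
    stop("`half_life` must be positive", call. = FALSE)
  }
  cs <- config$chase
  seed <- (child_seed(config$seed, "chase") +
             sum(utf8ToInt(paste(protein, condition)))) %% 2147483647
  set.seed(as.integer(seed))
  t <- cs$time_points
  amounts <- 2^(-t / half_life)
  amounts <- amounts * rlnorm_cv(length(t), cs$noise_cv)
  chase_series(protein = protein, condition = condition,
               times = t, amounts = amounts)
}

#' Simulate RIP-qPCR well tables with planted fold enrichments
#'
#' Builds input and IP quantities for a bait-tagged and a no-tag sample such
#' that the noiseless roundtrip through [quantify_rip()] returns the planted
#' fold enrichments exactly: the no-tag sample recovers a constant background
#' percent of input, and the tagged sample's bait-normalized recovery is
#' `fold` times the no-tag one. Quantities are converted to Ct values as
#' `-log_E(quantity) + offset` plus Gaussian Ct noise, replicated
#' `n_replicates` times per well.
#'
#' @param config A [sim_config()]; the `qpcr` block sets efficiency, noise,
#'   input fraction, background and bait recoveries.
#' @param fold_enrichment Named vector, transcript -> planted fold over the
#'   no-tag control (positive).
#' @return A list with `wells` (a data frame with columns `target`, `sample`,
#'   `fraction`, `replicate`, `ct`, `dilution_factor`, `efficiency`,
#'   `input_fraction`), `sample_map` (list naming the no-tag sample and the
#'   bait recoveries) and `truth`.
#' @export
simulate_rip_qpcr <- function(config, fold_enrichment) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(fold_enrichment)) || any(fold_enrichment <= 0)) {
    stop("`fold_enrichment` must be a named vector of positive folds",
         call. = FALSE)
  }
  qs <- config$qpcr
  set.seed(child_seed(config$seed, "qpcr"))
  targets <- names(fold_enrichment)
  bait <- qs$bait_recovery
  rows <- list()
  for (tg in targets) {
    input_q <- stats::rlnorm(1, meanlog = 2, sdlog = 0.5)
    pct <- c(
      tagged = unname(fold_enrichment[[tg]] * qs$background_percent *
                        bait[["tagged"]] / bait[["no_tag"]]),
      no_tag = qs$background_percent
    )
    for (smp in c("tagged", "no_tag")) {
      q <- c(
        input = input_q,
        ip = pct[[smp]] / 100 * input_q / qs$input_fraction
      )
      for (frac in names(q)) {
        ct0 <- -log(q[[frac]], base = qs$efficiency) + qs$ct_offset
        ct <- ct0 + if (qs$ct_noise_sd > 0) {
          stats::rnorm(qs$n_replicates, 0, qs$ct_noise_sd)
        } else rep(0, qs$n_replicates)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, sample = smp, fraction = frac,
          replicate = seq_len(qs$n_replicates), ct = ct,
          dilution_factor = 1, efficiency = qs$efficiency,
          input_fraction = qs$input_fraction
        )
      }
    }
  }
  list(
    wells = do.call(rbind, rows),
    sample_map = list(no_tag = "no_tag", bait_recovery = bait),
    truth = ground_truth(true_fold_enrichment = fold_enrichment)
  )
}

#' Simulate dye-swap microarray replicate log-ratios
#'
#' Emits two replicates per gene (the second dye-swapped, i.e. its stored
#' log2 ratio is sign-flipped) around a planted true log2 fold change, with a
#' per-gene inconsistency parameter: a gene with inconsistency `d` has its
#' two oriented replicates placed at `true -/+ d/sqrt(2)`, so the
#' between-replicate standard deviation equals `d` exactly at zero noise.
#'
#' @param config A [sim_config()] (supplies the stage seed).
#' @param true_log2 Named vector of true log2 mutant/wild-type ratios.
#' @param inconsistency Optional named vector of non-negative per-gene
#'   replicate disagreements (genes not listed get 0).
#' @param noise_sd Additional Gaussian noise per replicate.
#' @return A list with `replicates` (data frame `gene`, `replicate`,
#'   `log2_ratio`, `dye_swapped`, `intensity`) and `truth`
#'   (`inconsistent_genes` = genes with planted inconsistency > 0.5).
#' @export
simulate_dye_swap_replicates <- function(config, true_log2,
                                         inconsistency = NULL,
                                         noise_sd = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(true_log2))) {
    stop("`true_log2` must be a named vector", call. = FALSE)
  }
  set.seed(child_seed(config$seed, "microarray"))
  genes <- names(true_log2)
  d <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(inconsistency)) {
    if (any(inconsistency < 0)) {
      stop("`inconsistency` must be non-negative", call. = FALSE)
    }
    d[names(inconsistency)] <- inconsistency
  }
  noise <- function() if (noise_sd > 0) stats::rnorm(length(genes), 0, noise_sd) else 0
  r1 <- true_log2 - d / sqrt(2) + noise()
  r2 <- true_log2 + d / sqrt(2) + noise()
  intensity <- stats::runif(length(genes), 8, 16)
  replicates <- rbind(
    data.frame(gene = genes, replicate = 1L, log2_ratio = unname(r1),
               dye_swapped = FALSE, intensity = intensity),
    data.frame(gene = genes, replicate = 2L, log2_ratio = unname(-r2),
               dye_swapped = TRUE, intensity = intensity)
  )
  list(
    replicates = replicates[order(replicates$gene, replicates$replicate), ],
    truth = ground_truth(
      inconsistent_genes = genes[d > 0.5],
      extra = list(true_log2 = true_log2, inconsistency = d)
    )
  )
}
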