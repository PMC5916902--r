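#' Describe one RBP assay series for the binding simulator
#'
#' One `rbp_spec` describes a series of replicate experiments for a single
#' RNA-binding protein: the assay technology, the sequencing depth (for
#' crosslink-count assays), and the lognormal prior from which the RBP's
#' per-transcript binding affinities are drawn.
#'
#' @param rbp_id Character identifier of the RBP.
#' @param assay One of `"CRAC_COUNT"` (overdispersed crosslink read counts),
#'   `"RIP_SCORE"` (noisy continuous scores monotone in affinity) or
#'   `"CLIP_CALL"` (binary bound/unbound calls thresholded on affinity).
#' @param n_replicates Number of replicate experiments (>= 1).
#' @param depth Expected total count per CRAC replicate (> 0).
#' @param affinity_meanlog,affinity_sdlog Log-scale location and spread of the
#'   lognormal affinity prior.
#' @param score_noise_sd Gaussian noise (log-affinity scale) added to RIP
#'   scores.
#' @param bound_fraction Fraction of transcripts called bound in a CLIP
#'   experiment (top of the affinity distribution).
#' @return An object of class `rbp_spec`.
#' @export
rbp_spec <- function(rbp_id,
                     assay = c("CRAC_COUNT", "RIP_SCORE", "CLIP_CALL"),
                     n_replicates = 1L,
                     depth = 1e6,
                     affinity_meanlog = 0,
                     affinity_sdlog = 1,
                     score_noise_sd = 0.5,
                     bound_fraction = 0.25) {
  assay <- match.arg(assay)
  stopifnot(is.character(rbp_id), length(rbp_id) == 1L, nzchar(rbp_id))
  assert_scalar_number(n_replicates, "n_replicates")
  if (n_replicates < 1) stop("`n_replicates` must be at least 1", call. = FALSE)
  assert_scalar_number(depth, "depth", positive = TRUE)
  assert_scalar_number(affinity_sdlog, "affinity_sdlog", nonneg = TRUE)
  assert_scalar_number(score_noise_sd, "score_noise_sd", nonneg = TRUE)
  if (bound_fraction <= 0 || bound_fraction >= 1) {
    stop("`bound_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      rbp_id = rbp_id, assay = assay,
      n_replicates = as.integer(n_replicates), depth = depth,
      affinity_meanlog = affinity_meanlog, affinity_sdlog = affinity_sdlog,
      score_noise_sd = score_noise_sd, bound_fraction = bound_fraction
    ),
    class = "rbp_spec"
  )
}

#' Default RBP panel for the binding simulator
#'
#' Mirrors the structure of real RBP-interactome panels: one specific RBP
#' whose binding affinities span orders of magnitude (lognormal sdlog 1.3),
#' co-measured with general mRNA-metabolism factors that bind broadly with a
#' much narrower affinity spread (sdlog 0.5). The general factors' libraries
#' track bulk transcript abundance, which is precisely the shared signal the
#' per-transcript unit normalization exploits to cancel expression from the
#' specific RBP's profile.
#'
#' @param n_replicates Replicates per RBP.
#' @param depth Expected total count per replicate.
#' @return List of three [rbp_spec()]s (`rbp_a` specific, `rbp_b`/`rbp_c`
#'   general).
#' @export
default_binding_panel <- function(n_replicates = 2L, depth = 1e6) {
  list(
    rbp_spec("rbp_a", "CRAC_COUNT", n_replicates = n_replicates,
             depth = depth, affinity_sdlog = 1.3),
    rbp_spec("rbp_b", "CRAC_COUNT", n_replicates = n_replicates,
             depth = depth, affinity_sdlog = 0.5),
    rbp_spec("rbp_c", "CRAC_COUNT", n_replicates = n_replicates,
             depth = depth, affinity_sdlog = 0.5)
  )
}

#' Polysome-gradient simulation parameters
#'
#' The simulated gradient carries two discretized Gaussian bumps over the
#' fraction index: an untranslated light-fraction peak and a polysomal peak.
#' Defaults place them at fractions 3 and 11 of a 14-fraction gradient with a
#' width of 1 fraction, so that essentially all of each bump's mass falls
#' inside its fraction class (light = 1-6, polysomes = 9-13).
#'
#' @param n_fractions Number of gradient fractions (>= 3).
#' @param light_peak_fraction,poly_peak_fraction Centers of the two bumps.
#' @param peak_width Standard deviation of the bumps, in fractions.
#' @param noise_cv Coefficient of variation of multiplicative lognormal noise
#'   applied per fraction quantity.
#' @param spike_perturbation Half-width of the uniform per-fraction recovery
#'   factor (0.3 means recoveries drawn in \[0.7, 1.3\]).
#' @return An object of class `polysome_spec`.
#' @export
polysome_spec <- function(n_fractions = 14L,
                          light_peak_fraction = 3L,
                          poly_peak_fraction = 11L,
                          peak_width = 1.0,
                          noise_cv = 0.1,
                          spike_perturbation = 0.3) {
  assert_scalar_number(n_fractions, "n_fractions")
  if (n_fractions < 3) stop("`n_fractions` must be at least 3", call. = FALSE)
  assert_scalar_number(peak_width, "peak_width", positive = TRUE)
  assert_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (spike_perturbation < 0 || spike_perturbation >= 1) {
    stop("`spike_perturbation` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_fractions = as.integer(n_fractions),
      light_peak_fraction = as.integer(light_peak_fraction),
      poly_peak_fraction = as.integer(poly_peak_fraction),
      peak_width = peak_width, noise_cv = noise_cv,
      spike_perturbation = spike_perturbation
    ),
    class = "polysome_spec"
  )
}

#' Cycloheximide-chase simulation parameters
#'
#' @param time_points Sampling times in minutes; must include 0.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @return An object of class `chase_spec`.
#' @export
chase_spec <- function(time_points = c(0, 15, 30, 45, 60, 90),
                       noise_cv = 0.05) {
  stopifnot(is.numeric(time_points), length(time_points) >= 2L)
  if (!0 %in% time_points) stop("`time_points` must include 0", call. = FALSE)
  if (is.unsorted(time_points, strictly = TRUE)) {
    stop("`time_points` must be strictly increasing", call. = FALSE)
  }
  assert_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  structure(list(time_points = time_points, noise_cv = noise_cv),
            class = "chase_spec")
}

#' RIP-qPCR simulation parameters
#'
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @param ct_noise_sd Gaussian noise added to each Ct value, in cycles.
#' @param n_replicates Technical qPCR replicates per well.
#' @param input_fraction Share of total material the input aliquot represents.
#' @param background_percent Percent-of-input recovered in the no-tag control.
#' @param bait_recovery Named positive scalars: amount of purified bait per
#'   sample (names `tagged`, `no_tag`).
#' @param ct_offset Additive Ct offset (the arbitrary qPCR intercept).
#' @return An object of class `qpcr_spec`.
#' @export
qpcr_spec <- function(efficiency = 2,
                      ct_noise_sd = 0.2,
                      n_replicates = 3L,
                      input_fraction = 0.1,
                      background_percent = 0.05,
                      bait_recovery = c(tagged = 1.2, no_tag = 0.8),
                      ct_offset = 25) {
  if (!is_scalar_number(efficiency) || efficiency <= 1 || efficiency > 2) {
    stop("`efficiency` must lie in (1, 2]", call. = FALSE)
  }
  assert_scalar_number(ct_noise_sd, "ct_noise_sd", nonneg = TRUE)
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("`input_fraction` must lie in (0, 1]", call. = FALSE)
  }
  assert_scalar_number(background_percent, "background_percent", positive = TRUE)
  stopifnot(all(c("tagged", "no_tag") %in% names(bait_recovery)),
            all(bait_recovery > 0))
  structure(
    list(
      efficiency = efficiency, ct_noise_sd = ct_noise_sd,
      n_replicates = as.integer(n_replicates),
      input_fraction = input_fraction,
      background_percent = background_percent,
      bait_recovery = bait_recovery, ct_offset = ct_offset
    ),
    class = "qpcr_spec"
  )
}

#' Configure a synthetic-data simulation
#'
#' Bundles every parameter of the synthetic universe: transcript count, the
#' lognormal expression prior whose spread creates the abundance confound the
#' interactome normalization must remove, the count overdispersion, and the
#' per-assay sub-specifications.
#'
#' @param n_transcripts Number of transcripts in the universe (>= 2).
#' @param rbp_specs List of [rbp_spec()] objects with unique `rbp_id`s.
#' @param expression_meanlog,expression_sdlog Lognormal expression prior.
#'   The default `sdlog = 1.5` makes transcript abundance the dominant signal
#'   in raw crosslink counts.
#' @param dispersion Non-negative count overdispersion; counts are drawn from
#'   a gamma-mixed (negative binomial) model with `size = 1/dispersion`, and
#'   `dispersion = 0` means deterministic half-up rounding of the expectation.
#' @param seed Integer global seed; stage seeds derive from it via
#'   [child_seed()].
#' @param polysome,chase,qpcr Assay sub-specifications.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000L,
                       rbp_specs = default_binding_panel(),
                       expression_meanlog = 0,
                       expression_sdlog = 1.5,
                       dispersion = 0.2,
                       seed = 1L,
                       polysome = polysome_spec(),
                       chase = chase_spec(),
                       qpcr = qpcr_spec()) {
  assert_scalar_number(n_transcripts, "n_transcripts")
  if (n_transcripts < 2) stop("`n_transcripts` must be at least 2", call. = FALSE)
  stopifnot(is.list(rbp_specs), length(rbp_specs) >= 1L,
            all(vapply(rbp_specs, inherits, TRUE, "rbp_spec")))
  ids <- vapply(rbp_specs, `[[`, "", "rbp_id")
  if (anyDuplicated(ids)) stop("`rbp_specs` must have unique rbp_ids", call. = FALSE)
  assert_scalar_number(expression_sdlog, "expression_sdlog", nonneg = TRUE)
  assert_scalar_number(dispersion, "dispersion", nonneg = TRUE)
  assert_scalar_number(seed, "seed")
  stopifnot(inherits(polysome, "polysome_spec"), inherits(chase, "chase_spec"),
            inherits(qpcr, "qpcr_spec"))
  n <- as.integer(n_transcripts)
  structure(
    list(
      n_transcripts = n,
      transcripts = sprintf("t%05d", seq_len(n)),
      rbp_specs = stats::setNames(rbp_specs, ids),
      expression_meanlog = expression_meanlog,
      expression_sdlog = expression_sdlog,
      dispersion = dispersion,
      seed = as.integer(seed),
      polysome = polysome, chase = chase, qpcr = qpcr
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data simulation config\n")
  cat("  transcripts:", x$n_transcripts, "\n")
  cat("  RBP series: ",
      paste(sprintf("%s[%s x%d]",
                    names(x$rbp_specs),
                    vapply(x$rbp_specs, `[[`, "", "assay"),
                    vapply(x$rbp_specs, `[[`, 1L, "n_replicates")),
            collapse = ", "), "\n")
  cat("  expression lognormal(", x$expression_meanlog, ",",
      x$expression_sdlog, "), dispersion", x$dispersion, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
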