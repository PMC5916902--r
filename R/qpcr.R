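#' Convert a Ct value to a relative quantity
#'
#' `quantity = dilution_factor * efficiency^(-ct)`: one amplification cycle
#' at perfect efficiency (E = 2) halves the apparent quantity per extra
#' cycle. Quantities are arbitrary-unit and comparable within a primer pair.
#'
#' @param ct Numeric Ct values (finite).
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @param dilution_factor Positive dilution factor(s) of the template.
#' @return Positive relative quantities.
#' @export
ct_to_relative_quantity <- function(ct, efficiency = 2, dilution_factor = 1) {
  if (any(!is.finite(ct))) stop("`ct` must be finite", call. = FALSE)
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("`efficiency` must lie in (1, 2]", call. = FALSE)
  }
  if (any(dilution_factor <= 0)) {
    stop("`dilution_factor` must be positive", call. = FALSE)
  }
  dilution_factor * efficiency^(-ct)
}

#' Average technical qPCR replicates on the Ct scale
#'
#' Technical replicates are averaged arithmetically on the Ct scale before
#' exponentiation; a spread above 0.5 cycles between technical replicates of
#' a well raises a warning naming the well.
#'
#' @param wells Data frame with columns `target`, `sample`, `fraction`, `ct`
#'   (and optionally `dilution_factor`, `efficiency`, `input_fraction`,
#'   carried through unchanged; they must be constant within a well).
#' @param sd_warn Spread threshold in cycles (default 0.5).
#' @return A data frame with one row per (target, sample, fraction).
#' @export
average_technical_replicates <- function(wells, sd_warn = 0.5) {
  needed <- c("target", "sample", "fraction", "ct")
  if (!all(needed %in% names(wells))) {
    stop("`wells` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(wells$target, wells$sample, wells$fraction, drop = TRUE)
  out <- lapply(split(wells, key), function(w) {
    if (nrow(w) > 1L && stats::sd(w$ct) > sd_warn) {
      warning(sprintf(
        "technical replicate spread > %.1f cycles for %s/%s/%s",
        sd_warn, w$target[1L], w$sample[1L], w$fraction[1L]), call. = FALSE)
    }
    row <- w[1L, setdiff(names(w), c("ct", "replicate")), drop = FALSE]
    row$ct <- mean(w$ct)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent of input recovered in an immunoprecipitate
#'
#' `percent_ip = 100 * ip_quantity / (input_quantity / input_fraction)`: the
#' measured input quantity is first scaled up to the total material by the
#' share the input aliquot represents, and the IP recovery is expressed as a
#' percentage of that total.
#'
#' @param ip_quantity Non-negative IP quantity (arbitrary units).
#' @param input_quantity Positive input quantity (same units).
#' @param input_fraction Share of total material the input aliquot
#'   represents, in (0, 1].
#' @return Percent of input (>= 0).
#' @export
percent_ip <- function(ip_quantity, input_quantity, input_fraction = 1) {
  if (any(input_quantity <= 0)) {
    stop("`input_quantity` must be positive", call. = FALSE)
  }
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("`input_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(ip_quantity < 0)) {
    stop("`ip_quantity` must be non-negative", call. = FALSE)
  }
  100 * ip_quantity / (input_quantity / input_fraction)
}

#' Normalize percent-of-IP values to bait recovery and a no-tag control
#'
#' Each percent-of-IP is first divided by its sample's bait recovery (the
#' amount of purified bait protein), then by the bait-normalized value of
#' the no-tag control for the same target, so the no-tag control maps to
#' exactly 1.
#'
#' @param percents Data frame with columns `target`, `sample`, `percent_ip`.
#' @param bait_recovery Named positive vector, sample -> bait amount.
#' @param no_tag Name of the no-tag control sample.
#' @param pseudocount Optional positive value added to all bait-normalized
#'   percents when the no-tag value is 0 (with a warning); by default a zero
#'   no-tag value is an error.
#' @return The input data frame with an added `fold_over_no_tag` column.
#' @export
fold_over_control <- function(percents, bait_recovery, no_tag = "no_tag",
                              pseudocount = NULL) {
  needed <- c("target", "sample", "percent_ip")
  if (!all(needed %in% names(percents))) {
    stop("`percents` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!no_tag %in% percents$sample) {
    stop("no-tag sample not present: ", no_tag, call. = FALSE)
  }
  missing <- setdiff(unique(percents$sample), names(bait_recovery))
  if (length(missing) > 0L) {
    stop("bait recovery missing for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(bait_recovery <= 0)) {
    stop("bait recoveries must be positive", call. = FALSE)
  }
  normalized <- percents$percent_ip / bait_recovery[percents$sample]
  out <- do.call(rbind, lapply(split(seq_len(nrow(percents)), percents$target),
    function(idx) {
      p <- percents[idx, , drop = FALSE]
      v <- normalized[idx]
      ref <- v[p$sample == no_tag]
      if (length(ref) != 1L) {
        stop("expected exactly one no-tag value per target", call. = FALSE)
      }
      if (ref == 0) {
        if (is.null(pseudocount)) {
          stop("no-tag value is 0 for target ", p$target[1L],
               " (enable a pseudocount to proceed)", call. = FALSE)
        }
        warning("zero no-tag value for target ", p$target[1L],
                "; applying pseudocount", call. = FALSE)
        v <- v + pseudocount
        ref <- ref + pseudocount
      }
      p$fold_over_no_tag <- unname(v / ref)
      p
    }))
  rownames(out) <- NULL
  out
}

#' Quantify an RNA immunoprecipitation from a qPCR well table
#'
#' Full path from Ct values to fold enrichments: technical replicates are
#' averaged on the Ct scale, converted to relative quantities, expressed as
#' percent of input per (target, sample), then normalized to bait recovery
#' and to the no-tag control.
#'
#' @param wells Data frame of wells: `target`, `sample`, `fraction`
#'   (`"input"`/`"ip"`), `ct`, and optionally `dilution_factor`,
#'   `efficiency`, `input_fraction`, `replicate`.
#' @param sample_map List with `no_tag` (sample name) and `bait_recovery`
#'   (named positive vector).
#' @param pseudocount Passed to [fold_over_control()].
#' @return Data frame with one row per (target, sample): `percent_ip` and
#'   `fold_over_no_tag`.
#' @export
quantify_rip <- function(wells, sample_map, pseudocount = NULL) {
  stopifnot(is.list(sample_map), !is.null(sample_map$no_tag),
            !is.null(sample_map$bait_recovery))
  if (is.null(wells$dilution_factor)) wells$dilution_factor <- 1
  if (is.null(wells$efficiency)) wells$efficiency <- 2
  if (is.null(wells$input_fraction)) wells$input_fraction <- 1
  agg <- average_technical_replicates(wells)
  agg$quantity <- ct_to_relative_quantity(agg$ct, agg$efficiency,
                                          agg$dilution_factor)
  percents <- do.call(rbind, lapply(
    split(agg, interaction(agg$target, agg$sample, drop = TRUE)),
    function(g) {
      ip <- g[g$fraction == "ip", , drop = FALSE]
      input <- g[g$fraction == "input", , drop = FALSE]
      if (nrow(ip) != 1L || nrow(input) != 1L) {
        stop("each (target, sample) needs exactly one input and one ip well",
             call. = FALSE)
      }
      data.frame(
        target = g$target[1L], sample = g$sample[1L],
        percent_ip = percent_ip(ip$quantity, input$quantity,
                                input$input_fraction)
      )
    }))
  rownames(percents) <- NULL
  fold_over_control(percents, sample_map$bait_recovery,
                    no_tag = sample_map$no_tag, pseudocount = pseudocount)
}
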