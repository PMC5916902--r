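#' Default fraction classes for a 14-fraction sucrose gradient
#'
#' Fractions 1-6 hold free, untranslated mRNPs (`LIGHT`), 7-8 span the 80S
#' monosome (`MONOSOME`, excluded from both the untranslated and translated
#' numerators), 9-13 hold polysomes (`POLYSOME`) and fraction 14 is left
#' `UNASSIGNED`.
#'
#' @param n_fractions Number of fractions; the built-in map is defined for
#'   14, other gradients must supply their own class map.
#' @return Character vector of classes, one per fraction.
#' @export
default_fraction_classes <- function(n_fractions = 14L) {
  if (n_fractions != 14L) {
    stop("built-in class map is defined for 14 fractions; supply ",
         "`fraction_classes` explicitly for other gradients", call. = FALSE)
  }
  c(rep("LIGHT", 6), rep("MONOSOME", 2), rep("POLYSOME", 5), "UNASSIGNED")
}

fraction_class_levels <- c("LIGHT", "MONOSOME", "POLYSOME", "UNASSIGNED")

#' Per-fraction quantities from one polysome gradient
#'
#' @param quantities Either a numeric matrix (rows = targets, columns =
#'   fractions 1..F) or a long data frame with columns `target`, `fraction`,
#'   `quantity`.
#' @param spike Positive numeric vector of per-fraction spike-RNA quantities
#'   (length F).
#' @param condition Condition label.
#' @param fraction_classes Character vector over
#'   `LIGHT`/`MONOSOME`/`POLYSOME`/`UNASSIGNED`, one per fraction; default is
#'   [default_fraction_classes()] for 14 fractions.
#' @return An object of class `polysome_profile`.
#' @export
polysome_profile <- function(quantities, spike, condition = "",
                             fraction_classes = NULL) {
  if (is.data.frame(quantities)) {
    needed <- c("target", "fraction", "quantity")
    if (!all(needed %in% names(quantities))) {
      stop("long-format quantities need columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    nf <- max(quantities$fraction)
    if (!setequal(unique(quantities$fraction), seq_len(nf))) {
      stop("fractions must be contiguous from 1", call. = FALSE)
    }
    targets <- unique(quantities$target)
    m <- matrix(0, length(targets), nf, dimnames = list(targets, NULL))
    m[cbind(match(quantities$target, targets), quantities$fraction)] <-
      quantities$quantity
    quantities <- m
  }
  stopifnot(is.matrix(quantities), !is.null(rownames(quantities)))
  nf <- ncol(quantities)
  if (length(spike) != nf) {
    stop("`spike` must have one value per fraction", call. = FALSE)
  }
  if (any(!is.finite(spike)) || any(spike <= 0)) {
    stop("spike must be positive in every fraction", call. = FALSE)
  }
  if (any(quantities < 0)) {
    stop("fraction quantities must be non-negative", call. = FALSE)
  }
  if (is.null(fraction_classes)) {
    fraction_classes <- default_fraction_classes(nf)
  }
  if (length(fraction_classes) != nf ||
      !all(fraction_classes %in% fraction_class_levels)) {
    stop("`fraction_classes` must assign LIGHT/MONOSOME/POLYSOME/UNASSIGNED ",
         "to every fraction", call. = FALSE)
  }
  structure(
    list(condition = condition, n_fractions = nf, quantities = quantities,
         spike = spike, fraction_classes = fraction_classes,
         spike_corrected = FALSE),
    class = "polysome_profile"
  )
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat(sprintf("<polysome_profile> condition '%s': %d targets x %d fractions%s\n",
              x$condition, nrow(x$quantities), x$n_fractions,
              if (x$spike_corrected) " (spike-corrected)" else ""))
  invisible(x)
}

#' Correct fraction quantities for spike-RNA recovery
#'
#' Divides each fraction's quantities by the fraction's relative spike
#' recovery `spike(f) / mean(spike)`: a fraction that recovered more spike
#' than average is scaled down proportionally. Using the mean-centered spike
#' makes the correction unit-free and preserves between-target ratios within
#' a fraction.
#'
#' @param profile A [polysome_profile()].
#' @return The profile with corrected quantities (`spike_corrected = TRUE`).
#' @export
spike_correct <- function(profile) {
  stopifnot(inherits(profile, "polysome_profile"))
  rel <- profile$spike / mean(profile$spike)
  profile$quantities <- sweep(profile$quantities, 2, rel, "/")
  profile$spike_corrected <- TRUE
  profile
}

#' Normalized fraction distribution of one target
#'
#' @param profile A [polysome_profile()] (typically spike-corrected).
#' @param target Target id (row of the profile).
#' @return Numeric vector of per-fraction proportions summing to 1.
#' @export
fraction_distribution <- function(profile, target) {
  stopifnot(inherits(profile, "polysome_profile"))
  if (!target %in% rownames(profile$quantities)) {
    stop("target not in profile: ", target, call. = FALSE)
  }
  v <- profile$quantities[target, ]
  if (any(v < 0)) stop("negative fraction quantity", call. = FALSE)
  total <- sum(v)
  if (total <= 0) stop("all-zero target: ", target, call. = FALSE)
  v / total
}

#' Summarize a fraction distribution into translated proportions
#'
#' The translated proportion is the distribution mass in `POLYSOME`
#' fractions; the heavy-polysome proportion is the mass in the configured
#' heavy subrange (gradient-specific; default fractions 11-13, the part of
#' the gradient with four or more ribosomes per mRNA). `MONOSOME` and
#' `UNASSIGNED` mass counts in the denominator (the distribution sums to 1)
#' but in neither numerator.
#'
#' @param distribution Numeric per-fraction proportions (summing to 1).
#' @param fraction_classes Class per fraction (see [polysome_profile()]).
#' @param heavy_fractions Integer fraction indices of the heavy-polysome
#'   subrange.
#' @param target,condition Labels carried into the summary.
#' @return An object of class `translation_summary`.
#' @export
translated_proportion <- function(distribution, fraction_classes,
                                  heavy_fractions = 11:13,
                                  target = "", condition = "") {
  if (length(fraction_classes) != length(distribution) ||
      !all(fraction_classes %in% fraction_class_levels)) {
    stop("class map must cover all fractions", call. = FALSE)
  }
  structure(
    list(
      target = target, condition = condition,
      distribution = distribution,
      fraction_classes = fraction_classes,
      translated_proportion = sum(distribution[fraction_classes == "POLYSOME"]),
      heavy_polysome_proportion =
        sum(distribution[intersect(heavy_fractions,
                                   seq_along(distribution))])
    ),
    class = "translation_summary"
  )
}

#' @export
print.translation_summary <- function(x, ...) {
  cat(sprintf(
    "<translation_summary> %s [%s]: translated %.3f, heavy polysome %.3f\n",
    x$target, x$condition, x$translated_proportion,
    x$heavy_polysome_proportion))
  invisible(x)
}

#' Spike-correct and summarize every target of a profile
#'
#' @param profile A [polysome_profile()].
#' @param targets Targets to summarize (default all rows).
#' @param heavy_fractions Passed to [translated_proportion()].
#' @return Named list of `translation_summary` objects.
#' @export
summarize_translation <- function(profile, targets = NULL,
                                  heavy_fractions = 11:13) {
  stopifnot(inherits(profile, "polysome_profile"))
  if (!profile$spike_corrected) profile <- spike_correct(profile)
  targets <- targets %||% rownames(profile$quantities)
  stats::setNames(lapply(targets, function(tg) {
    translated_proportion(
      fraction_distribution(profile, tg), profile$fraction_classes,
      heavy_fractions = heavy_fractions, target = tg,
      condition = profile$condition
    )
  }), targets)
}

#' Tabulate translation summaries
#'
#' @param summaries List of `translation_summary` objects.
#' @return Data frame with one row per summary.
#' @export
translation_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(target = s$target, condition = s$condition,
               translated_proportion = s$translated_proportion,
               heavy_polysome_proportion = s$heavy_polysome_proportion)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Compare one target's translation between two conditions
#'
#' Reports the per-fraction difference of distributions (condition b minus
#' condition a) and the differences in translated and heavy-polysome
#' proportions. Positive deltas mean more translation in condition b.
#'
#' @param summary_a,summary_b `translation_summary` objects for the same
#'   target over the same fraction layout.
#' @return An object of class `translation_shift`.
#' @export
compare_conditions <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "translation_summary"),
            inherits(summary_b, "translation_summary"))
  if (summary_a$target != summary_b$target) {
    stop("summaries are for different targets", call. = FALSE)
  }
  if (length(summary_a$distribution) != length(summary_b$distribution) ||
      !identical(summary_a$fraction_classes, summary_b$fraction_classes)) {
    stop("mismatched fraction counts or classes", call. = FALSE)
  }
  structure(
    list(
      target = summary_a$target,
      condition_a = summary_a$condition, condition_b = summary_b$condition,
      delta_distribution = summary_b$distribution - summary_a$distribution,
      delta_translated = summary_b$translated_proportion -
        summary_a$translated_proportion,
      delta_heavy = summary_b$heavy_polysome_proportion -
        summary_a$heavy_polysome_proportion
    ),
    class = "translation_shift"
  )
}

#' @export
print.translation_shift <- function(x, ...) {
  cat(sprintf(
    "<translation_shift> %s: %s -> %s, delta translated %+0.3f, delta heavy %+0.3f\n",
    x$target, x$condition_a, x$condition_b, x$delta_translated,
    x$delta_heavy))
  invisible(x)
}

#' Read a polysome profile from a long-format TSV
#'
#' The table has columns `condition`, `target`, `fraction`, `quantity`;
#' spike rows are identified by a reserved target name.
#'
#' @param path Path to the TSV.
#' @param condition Condition to extract.
#' @param spike_target Reserved target name holding the spike RNA.
#' @param fraction_classes Optional class map.
#' @return A [polysome_profile()].
#' @export
read_polysome_profile <- function(path, condition,
                                  spike_target = "spike",
                                  fraction_classes = NULL) {
  tab <- utils::read.delim(path)
  tab <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(tab) == 0L) stop("condition not in table: ", condition,
                            call. = FALSE)
  spike_rows <- tab[tab$target == spike_target, , drop = FALSE]
  if (nrow(spike_rows) == 0L) {
    stop("no spike rows (target == '", spike_target, "')", call. = FALSE)
  }
  spike <- spike_rows$quantity[order(spike_rows$fraction)]
  polysome_profile(tab[tab$target != spike_target,
                       c("target", "fraction", "quantity")],
                   spike = spike, condition = condition,
                   fraction_classes = fraction_classes)
}
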