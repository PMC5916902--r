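#' Combine dye-swap microarray replicates per gene
#'
#' Dye-swapped replicates have their stored log2 ratio sign-flipped back to
#' the common orientation before averaging. The between-replicate standard
#' deviation uses the n-1 denominator (two replicates give
#' `|difference| / sqrt(2)`); genes with a single replicate get an `NA`
#' standard deviation and are flagged.
#'
#' @param replicates Data frame with columns `gene`, `log2_ratio`,
#'   `dye_swapped` (logical) and optionally `intensity`.
#' @return Data frame with one row per gene: `n_replicates`, `mean_log2`,
#'   `sd`, `mean_intensity`, `single_replicate`.
#' @export
combine_dye_swap_replicates <- function(replicates) {
  needed <- c("gene", "log2_ratio", "dye_swapped")
  if (!all(needed %in% names(replicates)) || nrow(replicates) == 0L) {
    stop("`replicates` must be a non-empty data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  oriented <- ifelse(replicates$dye_swapped,
                     -replicates$log2_ratio, replicates$log2_ratio)
  intensity <- replicates$intensity %||% rep(NA_real_, nrow(replicates))
  out <- do.call(rbind, lapply(split(seq_len(nrow(replicates)),
                                     replicates$gene), function(idx) {
    v <- oriented[idx]
    data.frame(
      gene = replicates$gene[idx[1L]],
      n_replicates = length(v),
      mean_log2 = mean(v),
      sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
      mean_intensity = mean(intensity[idx]),
      single_replicate = length(v) < 2L
    )
  }))
  rownames(out) <- NULL
  out
}

#' Filter genes by between-replicate standard deviation
#'
#' Genes whose replicate standard deviation strictly exceeds the threshold
#' are removed (a gene at exactly the threshold is retained); genes with an
#' undefined standard deviation (single replicate) are removed with a flag.
#'
#' @param comparisons Output of [combine_dye_swap_replicates()].
#' @param threshold Standard-deviation cutoff (default 0.5 log2 units).
#' @return The retained rows; attribute `removed` is a data frame of removed
#'   genes with a `reason` column, attribute `n_removed` the count.
#' @export
filter_by_replicate_sd <- function(comparisons, threshold = 0.5) {
  stopifnot(is.data.frame(comparisons), "sd" %in% names(comparisons))
  undefined <- is.na(comparisons$sd)
  high <- !undefined & comparisons$sd > threshold
  removed_idx <- which(undefined | high)
  removed <- data.frame(
    gene = comparisons$gene[removed_idx],
    reason = ifelse(undefined[removed_idx],
                    "single replicate", "sd above threshold")
  )
  kept <- comparisons[!(undefined | high), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "removed") <- removed
  attr(kept, "n_removed") <- nrow(removed)
  attr(kept, "threshold") <- threshold
  kept
}

#' Stratify expression changes by binding category
#'
#' Splits per-gene averaged log2 ratios by their binding category (the four
#' quartile groups from the interactome module) and summarizes each
#' category's distribution (n, quartiles, median), plus a rank test of each
#' category against the non-bound baseline. The Mann-Whitney-Wilcoxon test
#' is the default; Welch's t-test is available. No multiple-testing
#' correction is applied by default; Benjamini-Hochberg can be switched on.
#'
#' @param comparisons Output of [combine_dye_swap_replicates()] (typically
#'   after [filter_by_replicate_sd()]).
#' @param categories Named character/factor vector, gene -> category; must
#'   cover every analyzed gene.
#' @param baseline Category used as the comparison baseline (default
#'   `VERY_LOW_NONE`).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return An object of class `category_stratification` with `summary` (per
#'   category) and `tests` (per non-baseline category).
#' @export
stratify_by_binding_category <- function(comparisons, categories,
                                         baseline = "VERY_LOW_NONE",
                                         test = c("wilcoxon", "welch"),
                                         p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(comparisons),
            all(c("gene", "mean_log2") %in% names(comparisons)))
  categories <- stats::setNames(as.character(categories), names(categories))
  uncovered <- setdiff(comparisons$gene, names(categories))
  if (length(uncovered) > 0L) {
    stop("category absent from the map for gene(s): ",
         paste(utils::head(uncovered, 5L), collapse = ", "), call. = FALSE)
  }
  cat_of <- categories[comparisons$gene]
  values <- split(comparisons$mean_log2, cat_of)
  if (any(lengths(values) == 0L)) stop("empty category", call. = FALSE)
  if (!baseline %in% names(values)) {
    stop("baseline category not present: ", baseline, call. = FALSE)
  }
  summary <- do.call(rbind, lapply(names(values), function(cat) {
    v <- values[[cat]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = cat, n = length(v),
               q1 = q[1L], median = q[2L], q3 = q[3L])
  }))
  others <- setdiff(names(values), baseline)
  pvals <- vapply(others, function(cat) {
    p <- tryCatch(
      if (test == "wilcoxon") {
        stats::wilcox.test(values[[cat]], values[[baseline]],
                           exact = FALSE)$p.value
      } else {
        stats::t.test(values[[cat]], values[[baseline]])$p.value
      },
      error = function(e) NaN
    )
    # degenerate comparisons (e.g. all values tied) carry no evidence
    if (!is.finite(p)) 1 else p
  }, numeric(1))
  if (p_adjust == "BH") pvals <- stats::p.adjust(pvals, "BH")
  structure(
    list(
      summary = summary,
      tests = data.frame(category = others, baseline = baseline,
                         test = test, p_value = unname(pvals)),
      baseline = baseline, test = test, p_adjust = p_adjust,
      genes_by_category = split(comparisons$gene, cat_of)
    ),
    class = "category_stratification"
  )
}

#' @export
print.category_stratification <- function(x, ...) {
  cat("<category_stratification> baseline:", x$baseline,
      "| test:", x$test, "\n")
  print(x$summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
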