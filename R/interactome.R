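#' A single RBP-binding experiment
#'
#' Raw per-transcript measurements from one replicate of one assay: crosslink
#' read counts (CRAC), continuous association scores (RIP) or binary
#' bound/unbound calls (CLIP).
#'
#' @param rbp_id Character identifier of the RBP.
#' @param assay One of `"CRAC_COUNT"`, `"RIP_SCORE"`, `"CLIP_CALL"`.
#' @param replicate Integer replicate index (>= 1).
#' @param values Named numeric vector, transcript -> measurement. CRAC counts
#'   must be non-negative integers; CLIP calls must be 0/1.
#' @return An object of class `binding_experiment`.
#' @export
binding_experiment <- function(rbp_id, assay, replicate, values) {
  assay <- match.arg(assay, c("CRAC_COUNT", "RIP_SCORE", "CLIP_CALL"))
  stopifnot(is.character(rbp_id), length(rbp_id) == 1L)
  if (!is.numeric(replicate) || replicate < 1) {
    stop("`replicate` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(values) || is.null(names(values)) ||
      anyDuplicated(names(values))) {
    stop("`values` must be a named numeric vector with unique transcript ids",
         call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (assay == "CRAC_COUNT") {
    if (any(values < 0) || any(values != round_half_up(values))) {
      stop("CRAC_COUNT values must be non-negative integers", call. = FALSE)
    }
  }
  if (assay == "CLIP_CALL" && !all(values %in% c(0, 1))) {
    stop("CLIP_CALL values must be 0 or 1", call. = FALSE)
  }
  structure(
    list(rbp_id = rbp_id, assay = assay, replicate = as.integer(replicate),
         values = values),
    class = "binding_experiment"
  )
}

#' @export
print.binding_experiment <- function(x, ...) {
  cat(sprintf("<binding_experiment> %s %s rep %d: %d transcripts\n",
              x$rbp_id, x$assay, x$replicate, length(x$values)))
  invisible(x)
}

experiment_label <- function(e) {
  sprintf("%s.%s.r%d", e$rbp_id, tolower(sub("_.*", "", e$assay)), e$replicate)
}

#' Depth-normalize a CRAC experiment to hits per million
#'
#' Scales raw crosslink counts so they sum to one million within the library,
#' removing sequencing-depth differences between experiments.
#'
#' @param experiment A `CRAC_COUNT` [binding_experiment()].
#' @return The experiment with hpm-normalized values (no longer integer).
#' @export
hits_per_million <- function(experiment) {
  stopifnot(inherits(experiment, "binding_experiment"))
  total <- sum(experiment$values)
  if (total <= 0) stop("empty library: all counts are zero", call. = FALSE)
  experiment$values <- experiment$values * 1e6 / total
  attr(experiment, "normalized") <- c(attr(experiment, "normalized"), "hpm")
  # values are no longer integer counts; relax the class invariant
  experiment$assay <- "CRAC_COUNT"
  class(experiment) <- c("binding_experiment_hpm", "binding_experiment")
  experiment
}

#' Unit-normalize each transcript across experiments
#'
#' For each transcript, the vector of hpm values across all supplied
#' experiments is divided by its Euclidean norm, so the per-transcript sum of
#' squares equals 1. Because transcript abundance inflates a transcript's
#' counts in every library by a common factor, this step cancels abundance
#' and leaves relative preferences between RBPs. Transcripts with an all-zero
#' vector are left at zero and flagged (attribute `degenerate_transcripts`),
#' not treated as an error.
#'
#' @param experiments List of hpm-normalized [binding_experiment()]s sharing
#'   one transcript universe.
#' @return The list with normalized values; the attribute
#'   `degenerate_transcripts` names the all-zero transcripts.
#' @export
unit_norm_per_transcript <- function(experiments) {
  stopifnot(is.list(experiments), length(experiments) >= 1L,
            all(vapply(experiments, inherits, TRUE, "binding_experiment")))
  tx <- names(experiments[[1L]]$values)
  for (e in experiments) {
    if (!setequal(names(e$values), tx)) {
      stop("experiments have mismatched transcript universes", call. = FALSE)
    }
  }
  m <- vapply(experiments, function(e) e$values[tx], numeric(length(tx)))
  m <- matrix(m, nrow = length(tx), dimnames = list(tx, NULL))
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  m[!zero, ] <- m[!zero, , drop = FALSE] / norms[!zero]
  out <- Map(function(e, j) {
    e$values <- stats::setNames(m[, j], tx)
    attr(e, "normalized") <- c(attr(e, "normalized"), "unit_norm")
    e
  }, experiments, seq_along(experiments))
  attr(out, "degenerate_transcripts") <- tx[zero]
  out
}

#' Rescale an experiment's values to the unit interval
#'
#' Affine min-max rescaling within the experiment: the minimum maps to 0, the
#' maximum to 1. A constant experiment is set to all zeros with a degeneracy
#' warning rather than an error.
#'
#' @param experiment A [binding_experiment()] with finite values.
#' @return The experiment with values in \[0, 1\]; attribute `degenerate` is
#'   `TRUE` when the input was constant.
#' @export
rescale_unit_interval <- function(experiment) {
  stopifnot(inherits(experiment, "binding_experiment"))
  v <- experiment$values
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("degenerate experiment: constant values rescaled to 0",
            call. = FALSE)
    v[] <- 0
    attr(experiment, "degenerate") <- TRUE
  } else {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  }
  experiment$values <- v
  attr(experiment, "normalized") <- c(attr(experiment, "normalized"), "rescale01")
  experiment
}

binding_category_levels <- c("HIGH", "MEDIUM", "LOW", "VERY_LOW_NONE")

#' Cut a scored experiment into four equal-sized binding categories
#'
#' Transcripts are ranked by descending score and split into four contiguous
#' groups whose sizes differ by at most one; when the count is not divisible
#' by 4 the extra members go to the highest categories first. Ties are broken
#' by a stable sort with the transcript id as the final key; an all-tied
#' experiment is categorized in id order with a warning.
#'
#' @param experiment A scored [binding_experiment()] or a named numeric
#'   vector (>= 4 transcripts).
#' @return A named factor with levels `HIGH`, `MEDIUM`, `LOW`,
#'   `VERY_LOW_NONE`, in the input's transcript order.
#' @export
categorize_quartiles <- function(experiment) {
  v <- if (inherits(experiment, "binding_experiment")) {
    experiment$values
  } else {
    experiment
  }
  stopifnot(is.numeric(v), !is.null(names(v)))
  n <- length(v)
  if (n < 4L) stop("at least 4 transcripts are required", call. = FALSE)
  if (length(unique(v)) == 1L) {
    warning("all scores tied; categories assigned in transcript-id order",
            call. = FALSE)
  }
  ord <- order(-v, names(v), method = "radix")
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cat_sorted <- rep(binding_category_levels, times = sizes)
  out <- factor(rep(NA_character_, n), levels = binding_category_levels)
  out[ord] <- cat_sorted
  names(out) <- names(v)
  out
}

#' Assemble a harmonized binding matrix from heterogeneous experiments
#'
#' CRAC count experiments pass through [hits_per_million()], a joint
#' per-transcript unit normalization across all CRAC experiments
#' ([unit_norm_per_transcript()]), per-experiment min-max rescaling to
#' \[0, 1\] ([rescale_unit_interval()]) and quartile categorization. RIP
#' score experiments are quartile-categorized directly (no score is
#' retained). CLIP calls map to `BOUND`/`UNBOUND`. Transcripts with an
#' all-zero CRAC vector keep score 0 and are always categorized
#' `VERY_LOW_NONE`. Every step is recorded, with its parameters, in the
#' matrix's `normalization_log`.
#'
#' @param experiments List of [binding_experiment()]s over one transcript
#'   universe.
#' @param gene_order Optional character vector fixing the transcript row
#'   order (must be a permutation of the universe); default is sorted ids.
#' @return An object of class `binding_matrix` with elements `transcripts`,
#'   `experiments` (data frame `rbp_id`/`assay`/`replicate`), `score` (matrix
#'   in \[0, 1\], `NA` for RIP/CLIP columns), `category` (character matrix)
#'   and `normalization_log` (list of step records).
#' @export
assemble_binding_matrix <- function(experiments, gene_order = NULL) {
  stopifnot(is.list(experiments), length(experiments) >= 1L,
            all(vapply(experiments, inherits, TRUE, "binding_experiment")))
  universe <- names(experiments[[1L]]$values)
  for (e in experiments) {
    if (!setequal(names(e$values), universe)) {
      stop("experiments have mismatched transcript universes", call. = FALSE)
    }
  }
  tx <- if (is.null(gene_order)) sort(universe) else {
    if (!setequal(gene_order, universe)) {
      stop("`gene_order` must be a permutation of the transcript universe",
           call. = FALSE)
    }
    gene_order
  }
  labels <- vapply(experiments, experiment_label, "")
  if (anyDuplicated(labels)) {
    stop("duplicate experiment (rbp_id, assay, replicate) combinations",
         call. = FALSE)
  }
  assays <- vapply(experiments, `[[`, "", "assay")
  log <- list()
  score <- matrix(NA_real_, length(tx), length(experiments),
                  dimnames = list(tx, labels))
  category <- matrix(NA_character_, length(tx), length(experiments),
                     dimnames = list(tx, labels))

  crac_idx <- which(assays == "CRAC_COUNT")
  degenerate_tx <- character(0)
  if (length(crac_idx) > 0L) {
    crac <- lapply(experiments[crac_idx], hits_per_million)
    log[[length(log) + 1L]] <- list(
      step = "hits_per_million", experiments = labels[crac_idx],
      target_sum = 1e6
    )
    crac <- unit_norm_per_transcript(crac)
    degenerate_tx <- attr(crac, "degenerate_transcripts")
    log[[length(log) + 1L]] <- list(
      step = "unit_norm_per_transcript",
      scope = "all CRAC experiments jointly",
      degenerate_transcripts = degenerate_tx
    )
    degenerate_exps <- character(0)
    for (k in seq_along(crac_idx)) {
      e <- withCallingHandlers(
        rescale_unit_interval(crac[[k]]),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (isTRUE(attr(e, "degenerate"))) {
        degenerate_exps <- c(degenerate_exps, labels[crac_idx[k]])
      }
      score[, crac_idx[k]] <- e$values[tx]
      cats <- withCallingHandlers(
        categorize_quartiles(e),
        warning = function(w) invokeRestart("muffleWarning")
      )
      cats <- as.character(cats)[match(tx, names(e$values))]
      names(cats) <- tx
      cats[tx %in% degenerate_tx] <- "VERY_LOW_NONE"
      category[, crac_idx[k]] <- cats
    }
    log[[length(log) + 1L]] <- list(
      step = "rescale_unit_interval", scope = "per experiment",
      degenerate_experiments = degenerate_exps
    )
    log[[length(log) + 1L]] <- list(
      step = "categorize_quartiles", scope = "per CRAC experiment",
      labels = binding_category_levels,
      forced_very_low = degenerate_tx
    )
  }
  rip_idx <- which(assays == "RIP_SCORE")
  for (k in rip_idx) {
    cats <- categorize_quartiles(experiments[[k]])
    category[, k] <- as.character(cats)[match(tx, names(cats))]
  }
  if (length(rip_idx) > 0L) {
    log[[length(log) + 1L]] <- list(
      step = "categorize_quartiles", scope = "per RIP experiment",
      experiments = labels[rip_idx]
    )
  }
  clip_idx <- which(assays == "CLIP_CALL")
  for (k in clip_idx) {
    calls <- experiments[[k]]$values[tx]
    category[, k] <- ifelse(calls == 1, "BOUND", "UNBOUND")
  }
  if (length(clip_idx) > 0L) {
    log[[length(log) + 1L]] <- list(
      step = "clip_passthrough", experiments = labels[clip_idx],
      labels = c("BOUND", "UNBOUND")
    )
  }
  structure(
    list(
      transcripts = tx,
      experiments = data.frame(
        label = labels,
        rbp_id = vapply(experiments, `[[`, "", "rbp_id"),
        assay = assays,
        replicate = vapply(experiments, `[[`, 1L, "replicate"),
        row.names = NULL
      ),
      score = score,
      category = category,
      normalization_log = log
    ),
    class = "binding_matrix"
  )
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("<binding_matrix> %d transcripts x %d experiments\n",
              length(x$transcripts), nrow(x$experiments)))
  tab <- table(x$experiments$assay)
  cat("  assays:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  normalization steps:",
      paste(vapply(x$normalization_log, `[[`, "", "step"), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Write a binding matrix to delimited files
#'
#' Writes the score matrix and the category matrix as TSV (one row per
#' transcript, one column per experiment) and the normalization log as JSON.
#'
#' @param bm A [assemble_binding_matrix()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_binding_matrix <- function(bm, dir, prefix = "binding") {
  stopifnot(inherits(bm, "binding_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    score = file.path(dir, paste0(prefix, "_scores.tsv")),
    category = file.path(dir, paste0(prefix, "_categories.tsv")),
    log = file.path(dir, paste0(prefix, "_normalization_log.json"))
  )
  write_tsv_file(data.frame(transcript = bm$transcripts, bm$score,
                            check.names = FALSE), paths[["score"]])
  write_tsv_file(data.frame(transcript = bm$transcripts, bm$category,
                            check.names = FALSE), paths[["category"]])
  jsonlite::write_json(bm$normalization_log, paths[["log"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read binding experiments from a counts TSV plus metadata sidecar
#'
#' The counts table has one row per transcript (first column `transcript`)
#' and one column per experiment; the YAML sidecar is a list of column
#' records, each with `column`, `rbp_id`, `assay` and `replicate`.
#'
#' @param counts_path Path to the TSV table.
#' @param meta_path Path to the YAML metadata.
#' @return A list of [binding_experiment()]s.
#' @export
read_binding_experiments <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  meta <- yaml::read_yaml(meta_path)
  lapply(meta, function(m) {
    if (!m$column %in% names(tab)) {
      stop("metadata column not found in counts table: ", m$column,
           call. = FALSE)
    }
    binding_experiment(
      rbp_id = m$rbp_id, assay = m$assay, replicate = m$replicate,
      values = stats::setNames(tab[[m$column]], tab$transcript)
    )
  })
}
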