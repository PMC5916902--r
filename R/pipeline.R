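#' Default end-to-end pipeline configuration
#'
#' A fully synthetic run: simulate every assay with ground truth, harmonize
#' the binding experiments, test the planted gene set for enrichment,
#' quantify the RIP-qPCR tables, summarize the polysome gradients, fit
#' protein decay, stratify the dye-swap transcriptome by binding category
#' and scan the generated sequences for the CA-rich consensus motifs.
#'
#' @param seed Global seed; all stage randomness derives from it via
#'   [child_seed()].
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "interactome", "enrichment", "rip", "polysome",
               "turnover", "transcriptome", "scan"),
    simulate = list(
      n_transcripts = 300L,
      dispersion = 0.2,
      expression_sdlog = 1.5,
      rbps = list(
        list(rbp_id = "rbp_a", assay = "CRAC_COUNT", n_replicates = 2L,
             depth = 5e5, affinity_sdlog = 1.3),
        list(rbp_id = "rbp_b", assay = "CRAC_COUNT", n_replicates = 2L,
             depth = 5e5, affinity_sdlog = 0.5),
        list(rbp_id = "rbp_c", assay = "CRAC_COUNT", n_replicates = 2L,
             depth = 5e5, affinity_sdlog = 0.5),
        list(rbp_id = "rbp_d", assay = "RIP_SCORE"),
        list(rbp_id = "rbp_e", assay = "CLIP_CALL")
      )
    ),
    enrichment = list(set_size = 25L, n_perm = 1000L),
    rip = list(folds = c(target_a = 10, target_b = 5, target_c = 1)),
    polysome = list(n_targets = 4L, theta_a = 0.25, theta_b = 0.7,
                    conditions = c("wt", "mutant")),
    turnover = list(half_lives = c(wt = 60, mutant = 30),
                    protein = "nup_reporter"),
    transcriptome = list(downshift = -0.3, noise_sd = 0.2,
                         n_inconsistent = 10L, inconsistency = 0.8),
    scan = list(n_sequences = 20L, seq_length = 300L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [default_pipeline_config()]; missing blocks fall back to the
#' defaults.
#'
#' @param path Path to the YAML file.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 1L)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

stage_order <- c("simulate", "interactome", "enrichment", "rip", "polysome",
                 "turnover", "transcriptome", "scan")

#' Run the full synthetic-analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' outputs as plain-text tables/JSON under `outdir`, and returns a
#' machine-readable run report (per-stage status, parameters, output
#' checksums, record counts, collected warnings). Any stage failure is
#' recorded and aborts all downstream stages; identical configuration and
#' seed yield byte-identical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]), or a
#'   path to a YAML file.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return An object of class `run_report` (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir,
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(stage_order, config$stages %||% stage_order)
  state <- new.env(parent = emptyenv())
  report <- list(seed = config$seed, stages = list())
  failed <- FALSE
  for (st in stages) {
    if (failed) {
      report$stages[[st]] <- list(status = "skipped",
                                  reason = "upstream stage failed")
      next
    }
    warns <- character(0)
    res <- tryCatch(
      {
        out <- withCallingHandlers(
          run_stage(st, config, state, outdir),
          warning = function(w) {
            warns <<- c(warns, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        )
        out$status <- "ok"
        out$warnings <- warns
        if (length(out$outputs) > 0L) {
          sums <- tools::md5sum(unlist(out$outputs))
          out$checksums <- as.list(stats::setNames(unname(sums),
                                                   basename(names(sums))))
          # record basenames so the report is outdir-independent
          out$outputs <- lapply(out$outputs, basename)
        }
        out
      },
      error = function(e) list(status = "error",
                               message = conditionMessage(e))
    )
    report$stages[[st]] <- res
    if (identical(res$status, "error")) failed <- TRUE
  }
  class(report) <- "run_report"
  write_json_file(unclass(report), file.path(outdir, "run_report.json"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    cat(sprintf("  %-13s %s%s\n", st, s$status,
                if (!is.null(s$n_records)) {
                  sprintf(" (%d records)", s$n_records)
                } else ""))
  }
  invisible(x)
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing input for ", what, ": ",
         if (is.null(path)) "no path configured" else path, call. = FALSE)
  }
  path
}

run_stage <- function(stage, config, state, outdir) {
  switch(stage,
    simulate = stage_simulate(config, state, outdir),
    interactome = stage_interactome(config, state, outdir),
    enrichment = stage_enrichment(config, state, outdir),
    rip = stage_rip(config, state, outdir),
    polysome = stage_polysome(config, state, outdir),
    turnover = stage_turnover(config, state, outdir),
    transcriptome = stage_transcriptome(config, state, outdir),
    scan = stage_scan(config, state, outdir),
    stop("unknown stage: ", stage, call. = FALSE)
  )
}

stage_simulate <- function(config, state, outdir) {
  sc <- config$simulate %||% list()
  rbps <- lapply(sc$rbps %||% default_pipeline_config()$simulate$rbps,
                 function(r) do.call(rbp_spec, r))
  cfg <- sim_config(
    n_transcripts = sc$n_transcripts %||% 300L,
    rbp_specs = rbps,
    expression_sdlog = sc$expression_sdlog %||% 1.5,
    dispersion = sc$dispersion %||% 0.2,
    seed = config$seed
  )
  state$sim_config <- cfg
  binding <- simulate_binding_experiments(cfg)
  state$binding <- binding

  # planted gene set: the top-affinity targets of the first RBP
  ec <- config$enrichment %||% list()
  set_size <- ec$set_size %||% 25L
  aff1 <- binding$truth$affinity[, 1L]
  gene_set <- names(sort(aff1, decreasing = TRUE))[seq_len(set_size)]
  state$gene_set <- gene_set

  # polysome profiles for a few targets, two conditions
  pc <- config$polysome %||% list()
  n_targets <- pc$n_targets %||% 4L
  targets <- cfg$transcripts[seq_len(n_targets)]
  conditions <- pc$conditions %||% c("wt", "mutant")
  thetas <- list(
    stats::setNames(rep(pc$theta_a %||% 0.25, n_targets), targets),
    stats::setNames(rep(pc$theta_b %||% 0.7, n_targets), targets)
  )
  state$polysome <- Map(function(cond, th) {
    simulate_polysome_profiles(cfg, th, condition = cond)
  }, conditions, thetas)

  # chase series per condition
  tc <- config$turnover %||% list()
  hl <- tc$half_lives %||% c(wt = 60, mutant = 30)
  state$chase <- Map(function(cond, h) {
    simulate_chase_series(cfg, h, protein = tc$protein %||% "nup_reporter",
                          condition = cond)
  }, names(hl), hl)
  state$chase_truth <- hl

  # RIP-qPCR tables
  rc <- config$rip %||% list()
  state$qpcr <- simulate_rip_qpcr(
    cfg, rc$folds %||% c(target_a = 10, target_b = 5, target_c = 1))

  # dye-swap replicate table: the gene set is downshifted
  xc <- config$transcriptome %||% list()
  true_log2 <- stats::setNames(rep(0, cfg$n_transcripts), cfg$transcripts)
  true_log2[gene_set] <- xc$downshift %||% -0.3
  n_inc <- xc$n_inconsistent %||% 10L
  inconsistent <- stats::setNames(
    rep(xc$inconsistency %||% 0.8, n_inc),
    setdiff(cfg$transcripts, gene_set)[seq_len(n_inc)]
  )
  state$microarray <- simulate_dye_swap_replicates(
    cfg, true_log2, inconsistency = inconsistent,
    noise_sd = xc$noise_sd %||% 0.2)

  # transcript sequences with the CA-rich consensus planted in half of them
  nc <- config$scan %||% list()
  n_seq <- nc$n_sequences %||% 20L
  seq_len_nt <- nc$seq_length %||% 300L
  set.seed(child_seed(config$seed, "pipeline"))
  planted <- logical(n_seq)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), seq_len_nt, replace = TRUE),
               collapse = "")
    if (i %% 2L == 0L) {
      planted[i] <<- TRUE
      pos <- sample.int(seq_len_nt - 8L, 1L)
      substr(s, pos, pos + 7L) <- "CATCATCA"
    }
    s
  }, "")
  names(seqs) <- sprintf("seq%03d", seq_len(n_seq))
  state$sequences <- seqs

  # write everything as the delimited formats the analysis stages read
  paths <- character(0)
  counts <- data.frame(
    transcript = cfg$transcripts,
    vapply(binding$experiments, function(e) e$values[cfg$transcripts],
           numeric(cfg$n_transcripts)),
    check.names = FALSE
  )
  names(counts)[-1L] <- vapply(binding$experiments, experiment_label, "")
  paths["counts"] <- write_tsv_file(counts,
                                    file.path(outdir, "binding_counts.tsv"))
  meta <- lapply(binding$experiments, function(e) {
    list(column = experiment_label(e), rbp_id = e$rbp_id, assay = e$assay,
         replicate = e$replicate)
  })
  paths["meta"] <- file.path(outdir, "binding_meta.yaml")
  yaml::write_yaml(meta, paths[["meta"]])

  long <- do.call(rbind, lapply(state$polysome, function(p) {
    pr <- p$profile
    rbind(
      data.frame(condition = pr$condition,
                 target = rep(rownames(pr$quantities),
                              each = pr$n_fractions),
                 fraction = rep(seq_len(pr$n_fractions),
                                nrow(pr$quantities)),
                 quantity = as.vector(t(pr$quantities))),
      data.frame(condition = pr$condition, target = "spike",
                 fraction = seq_len(pr$n_fractions), quantity = pr$spike)
    )
  }))
  paths["polysome"] <- write_tsv_file(long,
                                      file.path(outdir, "polysome_quant.tsv"))

  chase_tab <- do.call(rbind, lapply(state$chase, function(s) {
    data.frame(protein = s$protein, condition = s$condition,
               time_min = s$times, amount = s$amounts)
  }))
  paths["chase"] <- write_tsv_file(chase_tab,
                                   file.path(outdir, "chase_series.tsv"))
  paths["wells"] <- write_tsv_file(state$qpcr$wells,
                                   file.path(outdir, "qpcr_wells.tsv"))
  paths["samples"] <- file.path(outdir, "qpcr_samples.yaml")
  yaml::write_yaml(list(no_tag = state$qpcr$sample_map$no_tag,
                        bait_recovery = as.list(
                          state$qpcr$sample_map$bait_recovery)),
                   paths[["samples"]])
  paths["ratios"] <- write_tsv_file(state$microarray$replicates,
                                    file.path(outdir, "microarray_ratios.tsv"))
  paths["set"] <- file.path(outdir, "gene_set.txt")
  writeLines(gene_set, paths[["set"]])
  paths["fasta"] <- file.path(outdir, "sequences.fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), paths[["fasta"]])
  truth <- list(
    expression = as.list(binding$truth$expression),
    affinity = as.data.frame(binding$truth$affinity),
    gene_set = gene_set,
    translated_proportion = lapply(state$polysome,
                                   function(p) as.list(
                                     p$truth$translated_proportion)),
    half_lives = as.list(hl),
    fold_enrichment = as.list(state$qpcr$truth$true_fold_enrichment),
    inconsistent_genes = state$microarray$truth$inconsistent_genes,
    true_log2 = as.list(true_log2)
  )
  paths["truth"] <- file.path(outdir, "ground_truth.json")
  write_json_file(truth, paths[["truth"]])
  list(params = list(n_transcripts = cfg$n_transcripts,
                     n_experiments = length(binding$experiments),
                     seed = config$seed),
       outputs = as.list(paths),
       n_records = cfg$n_transcripts)
}

stage_interactome <- function(config, state, outdir) {
  experiments <- if (!is.null(state$binding)) {
    state$binding$experiments
  } else {
    ic <- config$interactome %||% list()
    read_binding_experiments(
      require_input(ic$counts, "interactome counts"),
      require_input(ic$meta, "interactome metadata"))
  }
  bm <- assemble_binding_matrix(experiments)
  state$binding_matrix <- bm
  paths <- write_binding_matrix(bm, outdir)
  list(params = list(n_experiments = nrow(bm$experiments)),
       outputs = as.list(paths),
       n_records = length(bm$transcripts))
}

stage_enrichment <- function(config, state, outdir) {
  ec <- config$enrichment %||% list()
  bm <- state$binding_matrix
  if (is.null(bm)) stop("enrichment requires the interactome stage",
                        call. = FALSE)
  crac_cols <- which(bm$experiments$assay == "CRAC_COUNT")
  if (length(crac_cols) == 0L) {
    stop("no CRAC experiment available for ranking", call. = FALSE)
  }
  scores <- stats::setNames(bm$score[, crac_cols[1L]], bm$transcripts)
  set <- if (!is.null(state$gene_set)) state$gene_set else {
    read_gene_set(require_input(ec$set_file, "gene-set file"))$members
  }
  res <- permutation_p_value(
    scores, set, n_perm = ec$n_perm %||% 1000L,
    seed = child_seed(config$seed, "enrichment"),
    weighting_exponent = ec$weighting_exponent %||% 0)
  path <- file.path(outdir, "enrichment_result.json")
  write_json_file(unclass(res), path)
  list(params = list(set_size = res$set_size, n_perm = res$n_perm),
       outputs = list(result = path), n_records = res$universe_size)
}

stage_rip <- function(config, state, outdir) {
  if (is.null(state$qpcr)) stop("rip requires the simulate stage (or well",
                                " tables on disk)", call. = FALSE)
  quant <- quantify_rip(state$qpcr$wells, state$qpcr$sample_map)
  path <- write_tsv_file(quant, file.path(outdir, "rip_quantification.tsv"))
  list(params = list(no_tag = state$qpcr$sample_map$no_tag),
       outputs = list(quantification = path), n_records = nrow(quant))
}

stage_polysome <- function(config, state, outdir) {
  if (is.null(state$polysome)) {
    stop("polysome requires the simulate stage", call. = FALSE)
  }
  summaries <- lapply(state$polysome, function(p) {
    summarize_translation(p$profile)
  })
  tab <- do.call(rbind, lapply(summaries, translation_summary_table))
  rownames(tab) <- NULL
  paths <- c(summaries = write_tsv_file(
    tab, file.path(outdir, "translation_summaries.tsv")))
  if (length(summaries) >= 2L) {
    a <- summaries[[1L]]
    b <- summaries[[2L]]
    shifts <- lapply(intersect(names(a), names(b)), function(tg) {
      s <- compare_conditions(a[[tg]], b[[tg]])
      list(target = s$target, condition_a = s$condition_a,
           condition_b = s$condition_b,
           delta_translated = s$delta_translated,
           delta_heavy = s$delta_heavy,
           delta_distribution = s$delta_distribution)
    })
    paths["shifts"] <- file.path(outdir, "translation_shifts.json")
    write_json_file(shifts, paths[["shifts"]])
  }
  list(params = list(conditions = names(state$polysome)),
       outputs = as.list(paths), n_records = nrow(tab))
}

stage_turnover <- function(config, state, outdir) {
  if (is.null(state$chase)) {
    stop("turnover requires the simulate stage", call. = FALSE)
  }
  fits <- lapply(state$chase, fit_exponential_decay)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(protein = f$protein, condition = f$condition, k = f$k,
               half_life = f$half_life, intercept = f$intercept,
               residual_sd = f$residual_sd)
  }))
  rownames(tab) <- NULL
  path <- write_tsv_file(tab, file.path(outdir, "decay_fits.tsv"))
  list(params = list(n_series = length(fits)),
       outputs = list(fits = path), n_records = nrow(tab))
}

stage_transcriptome <- function(config, state, outdir) {
  if (is.null(state$microarray)) {
    stop("transcriptome requires the simulate stage", call. = FALSE)
  }
  bm <- state$binding_matrix
  if (is.null(bm)) {
    stop("transcriptome requires the interactome stage for categories",
         call. = FALSE)
  }
  comparisons <- combine_dye_swap_replicates(state$microarray$replicates)
  filtered <- filter_by_replicate_sd(comparisons,
                                     threshold = config$transcriptome$sd_threshold %||% 0.5)
  crac_cols <- which(bm$experiments$assay == "CRAC_COUNT")
  categories <- stats::setNames(bm$category[, crac_cols[1L]],
                                bm$transcripts)
  strat <- stratify_by_binding_category(filtered, categories)
  paths <- c(
    comparisons = write_tsv_file(comparisons,
                                 file.path(outdir,
                                           "expression_comparisons.tsv")))
  paths["stratification"] <- file.path(outdir, "stratification.json")
  write_json_file(list(n_removed = attr(filtered, "n_removed"),
                       summary = strat$summary, tests = strat$tests),
                  paths[["stratification"]])
  list(params = list(sd_threshold = attr(filtered, "threshold"),
                     n_removed = attr(filtered, "n_removed")),
       outputs = as.list(paths), n_records = nrow(comparisons))
}

stage_scan <- function(config, state, outdir) {
  nc <- config$scan %||% list()
  fasta <- if (!is.null(state$sequences)) {
    f <- file.path(outdir, "sequences.fasta")
    if (!file.exists(f)) {
      writeLines(paste0(">", names(state$sequences), "\n", state$sequences),
                 f)
    }
    f
  } else {
    require_input(nc$fasta, "scan FASTA")
  }
  motifs <- list(
    motif_spec("CA_octamer", "FIXED_IUPAC", "CAUCAUCA"),
    motif_spec("CNN_repeat", "TRIPLET_REPEAT", "CNN", repeat_count = 6L)
  )
  hits <- scan_fasta(fasta, motifs,
                     overlap_allowed = nc$overlap_allowed %||% TRUE)
  paths <- c(
    hits = write_tsv_file(hits, file.path(outdir, "motif_hits.tsv")),
    bed = write_tsv_file(motif_hits_to_bed(hits),
                         file.path(outdir, "motif_hits.bed")))
  list(params = list(motifs = vapply(motifs, `[[`, "", "motif_id")),
       outputs = as.list(paths), n_records = nrow(hits))
}
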