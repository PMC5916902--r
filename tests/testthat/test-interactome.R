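make_crac <- function(values, rbp = "r1", rep = 1L) {
  binding_experiment(rbp, "CRAC_COUNT", rep, values)
}

test_that("hits per million rescales libraries to a fixed total", {
  e <- hits_per_million(make_crac(c(a = 10, b = 90)))
  expect_equal(e$values, c(a = 1e5, b = 9e5))
  u <- hits_per_million(make_crac(c(a = 1, b = 1, c = 1, d = 1)))
  expect_equal(unname(u$values), rep(250000, 4))
  expect_equal(sum(u$values), 1e6, tolerance = 1e-9)
  expect_error(hits_per_million(make_crac(c(a = 0, b = 0))), "empty library")
})

test_that("per-transcript unit normalization cancels shared magnitude", {
  e1 <- hits_per_million(make_crac(c(a = 3, b = 4), rep = 1L))
  e2 <- hits_per_million(make_crac(c(a = 4, b = 3), rep = 2L))
  # force the 3-4-5 example values directly (already hpm-normalized shape)
  e1$values <- c(a = 3, b = 0)
  e2$values <- c(a = 4, b = 0)
  out <- unit_norm_per_transcript(list(e1, e2))
  expect_equal(out[[1L]]$values[["a"]], 0.6)
  expect_equal(out[[2L]]$values[["a"]], 0.8)
  # all-zero transcript is flagged and left at zero, not an error
  expect_identical(attr(out, "degenerate_transcripts"), "b")
  expect_equal(out[[1L]]$values[["b"]], 0)
  # a single experiment normalizes every nonzero transcript to 1
  single <- e1
  single$values <- c(a = 7, b = 2)
  res <- unit_norm_per_transcript(list(single))
  expect_equal(unname(res[[1L]]$values), c(1, 1))
  # mismatched universes are an error
  e3 <- make_crac(c(a = 1, z = 2))
  expect_error(unit_norm_per_transcript(list(e1, e3)), "mismatched")
})

test_that("unit normalization gives per-transcript sum of squares 1", {
  cfg <- sim_config(n_transcripts = 60, seed = 8,
                    rbp_specs = small_crac_panel())
  sim <- simulate_binding_experiments(cfg)
  hpm <- lapply(sim$experiments, hits_per_million)
  un <- unit_norm_per_transcript(hpm)
  m <- sapply(un, `[[`, "values")
  ss <- rowSums(m^2)
  nondeg <- !rownames(m) %in% attr(un, "degenerate_transcripts")
  expect_true(all(abs(ss[nondeg] - 1) < 1e-9))
})

test_that("min-max rescaling maps to [0, 1] with degenerate inputs warned", {
  e <- make_crac(c(a = 2, b = 4, c = 6))
  r <- rescale_unit_interval(e)
  expect_equal(unname(r$values), c(0, 0.5, 1))
  # idempotent on an already canonical range
  expect_equal(rescale_unit_interval(r)$values, r$values)
  const <- make_crac(c(a = 5, b = 5))
  expect_warning(rc <- rescale_unit_interval(const), "degenerate")
  expect_equal(unname(rc$values), c(0, 0))
})

test_that("quartile categories are equal-sized with remainder to the top", {
  v8 <- stats::setNames(8:1, letters[1:8])
  c8 <- categorize_quartiles(v8)
  expect_equal(as.vector(table(c8)), rep(2L, 4))
  expect_equal(as.character(c8[c("a", "b")]), c("HIGH", "HIGH"))
  v10 <- stats::setNames(10:1, letters[1:10])
  c10 <- categorize_quartiles(v10)
  expect_equal(as.vector(table(c10)[c("HIGH", "MEDIUM", "LOW",
                                      "VERY_LOW_NONE")]),
               c(3L, 3L, 2L, 2L))
  expect_error(categorize_quartiles(stats::setNames(1:3, letters[1:3])),
               "at least 4")
})

test_that("tied scores are categorized stably by transcript id with warning", {
  v <- stats::setNames(rep(1, 8), rev(letters[1:8]))
  expect_warning(cats <- categorize_quartiles(v), "tied")
  expect_equal(as.character(cats[c("a", "b")]), c("HIGH", "HIGH"))
  expect_equal(as.character(cats[c("g", "h")]),
               c("VERY_LOW_NONE", "VERY_LOW_NONE"))
})

test_that("category is a monotone function of score", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    v <- stats::setNames(stats::rnorm(n), paste0("t", seq_len(n)))
    cats <- categorize_quartiles(v)
    rank_of <- c(HIGH = 1, MEDIUM = 2, LOW = 3, VERY_LOW_NONE = 4)
    ord <- order(-v, names(v))
    expect_true(!is.unsorted(rank_of[as.character(cats[ord])]))
    expect_lte(diff(range(table(cats))), 1)
  }
})

test_that("assembled matrices are deterministic and order-invariant", {
  cfg <- sim_config(n_transcripts = 40, seed = 12,
                    rbp_specs = small_crac_panel())
  sim <- simulate_binding_experiments(cfg)
  bm1 <- assemble_binding_matrix(sim$experiments)
  bm2 <- assemble_binding_matrix(sim$experiments)
  expect_identical(bm1, bm2)
  # permuting each experiment's transcript storage order changes nothing
  perm <- sample(seq_len(cfg$n_transcripts))
  shuffled <- lapply(sim$experiments, function(e) {
    e$values <- e$values[perm]
    e
  })
  bm3 <- assemble_binding_matrix(shuffled)
  expect_identical(bm1$score, bm3$score)
  expect_identical(bm1$category, bm3$category)
})

test_that("CLIP calls pass through as BOUND/UNBOUND without scores", {
  clip <- binding_experiment("c1", "CLIP_CALL", 1L, c(a = 1, b = 0, d = 1,
                                                      e = 0))
  bm <- assemble_binding_matrix(list(clip))
  expect_equal(bm$category[c("a", "b"), 1L],
               c(a = "BOUND", b = "UNBOUND"))
  expect_true(all(is.na(bm$score[, 1L])))
})

test_that("normalization recovers affinity ranks and removes expression", {
  cfg <- sim_config(n_transcripts = 600, dispersion = 0.2,
                    expression_sdlog = 1.5, seed = 21,
                    rbp_specs = small_crac_panel(depth = 5e5))
  sim <- simulate_binding_experiments(cfg)
  bm <- assemble_binding_matrix(sim$experiments)
  tx <- bm$transcripts
  for (j in which(bm$experiments$rbp_id == "rbp_a")) {
    aff <- sim$truth$affinity[tx, "rbp_a"]
    s_final <- cor(bm$score[, j], aff, method = "spearman")
    raw <- sim$experiments[[j]]$values[tx]
    s_raw <- cor(raw, aff, method = "spearman")
    expect_gt(s_final, s_raw)
    expect_lt(abs(cor(bm$score[, j], sim$truth$expression[tx],
                      method = "spearman")), 0.15)
  }
})

test_that("binding matrices roundtrip through their TSV/YAML interface", {
  cfg <- sim_config(n_transcripts = 30, seed = 17,
                    rbp_specs = small_crac_panel())
  sim <- simulate_binding_experiments(cfg)
  dir <- withr::local_tempdir()
  counts <- data.frame(
    transcript = cfg$transcripts,
    vapply(sim$experiments, function(e) e$values[cfg$transcripts],
           numeric(cfg$n_transcripts)), check.names = FALSE)
  names(counts)[-1L] <- paste0("col", seq_along(sim$experiments))
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- lapply(seq_along(sim$experiments), function(i) {
    e <- sim$experiments[[i]]
    list(column = paste0("col", i), rbp_id = e$rbp_id, assay = e$assay,
         replicate = e$replicate)
  })
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  back <- read_binding_experiments(file.path(dir, "counts.tsv"),
                                   file.path(dir, "meta.yaml"))
  expect_identical(assemble_binding_matrix(back)$score,
                   assemble_binding_matrix(sim$experiments)$score)
})
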