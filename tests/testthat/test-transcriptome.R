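test_that("dye-swapped replicates are sign-flipped before averaging", {
  reps <- data.frame(
    gene = c("g1", "g1"), log2_ratio = c(0.8, -0.8),
    dye_swapped = c(FALSE, TRUE)
  )
  comp <- combine_dye_swap_replicates(reps)
  expect_equal(comp$mean_log2, 0.8)
  expect_equal(comp$sd, 0)
  oriented <- data.frame(gene = c("g2", "g2"), log2_ratio = c(1.0, 0.6),
                         dye_swapped = c(FALSE, FALSE))
  comp2 <- combine_dye_swap_replicates(oriented)
  expect_equal(comp2$mean_log2, 0.8)
  expect_equal(comp2$sd, abs(1.0 - 0.6) / sqrt(2), tolerance = 1e-12)
  single <- combine_dye_swap_replicates(
    data.frame(gene = "g3", log2_ratio = 0.3, dye_swapped = FALSE))
  expect_true(is.na(single$sd))
  expect_true(single$single_replicate)
})

test_that("applying the dye-swap flag twice is an involution", {
  set.seed(6)
  vals <- stats::rnorm(20)
  reps <- data.frame(gene = paste0("g", 1:20), log2_ratio = vals,
                     dye_swapped = FALSE)
  once <- reps
  once$log2_ratio <- -once$log2_ratio
  once$dye_swapped <- TRUE
  # flipping the stored ratio and the flag together leaves orientation fixed
  expect_equal(combine_dye_swap_replicates(once)$mean_log2,
               combine_dye_swap_replicates(reps)$mean_log2)
})

test_that("the replicate-sd filter is strict at the boundary and monotone", {
  comp <- data.frame(
    gene = c("a", "b", "c", "d"),
    n_replicates = c(2L, 2L, 2L, 1L),
    mean_log2 = c(0, 0, 0, 0),
    sd = c(0.6, 0.5, 0.1, NA),
    mean_intensity = NA_real_, single_replicate = c(FALSE, FALSE, FALSE, TRUE)
  )
  kept <- filter_by_replicate_sd(comp, threshold = 0.5)
  expect_setequal(kept$gene, c("b", "c")) # sd = 0.5 exactly is retained
  removed <- attr(kept, "removed")
  expect_setequal(removed$gene, c("a", "d"))
  expect_equal(removed$reason[removed$gene == "d"], "single replicate")
  # monotone: raising the threshold never drops a retained gene
  for (th in c(0.1, 0.3, 0.5, 0.7)) {
    low <- filter_by_replicate_sd(comp, threshold = th)$gene
    high <- filter_by_replicate_sd(comp, threshold = th + 0.2)$gene
    expect_true(all(low %in% high))
  }
})

test_that("zero-noise synthetic data filters exactly the planted genes", {
  cfg <- sim_config(n_transcripts = 50, seed = 23)
  genes <- paste0("g", sprintf("%02d", 1:40))
  true <- stats::setNames(stats::rnorm(40, 0, 0.2), genes)
  inc <- stats::setNames(c(0.9, 0.7, 0.51, 0.5, 0.3),
                         c("g05", "g11", "g17", "g23", "g31"))
  sim <- simulate_dye_swap_replicates(cfg, true, inconsistency = inc,
                                      noise_sd = 0)
  comp <- combine_dye_swap_replicates(sim$replicates)
  kept <- filter_by_replicate_sd(comp, threshold = 0.5)
  # exactly the genes with planted inconsistency > 0.5 are removed
  expect_setequal(attr(kept, "removed")$gene, c("g05", "g11", "g17"))
  expect_setequal(attr(kept, "removed")$gene, sim$truth$inconsistent_genes)
  # and the means equal the planted fold changes exactly
  expect_equal(stats::setNames(comp$mean_log2, comp$gene)[genes], true,
               tolerance = 1e-12)
})

test_that("stratification is null for identical categories and guarded", {
  comp <- data.frame(gene = paste0("g", 1:40),
                     mean_log2 = rep(c(0.1, 0.1), 20))
  categories <- stats::setNames(
    rep(c("HIGH", "MEDIUM", "LOW", "VERY_LOW_NONE"), each = 10),
    paste0("g", 1:40))
  strat <- stratify_by_binding_category(comp, categories)
  expect_true(all(strat$tests$p_value > 0.9))
  expect_equal(unique(strat$summary$median), 0.1)
  expect_error(
    stratify_by_binding_category(comp, categories[1:10]),
    "category absent")
})

test_that("a planted downshift in the bound category is detected", {
  categories <- stats::setNames(
    rep(c("HIGH", "MEDIUM", "LOW", "VERY_LOW_NONE"), each = 50),
    sprintf("g%03d", 1:200))
  detected <- vapply(1:40, function(i) {
    cfg <- sim_config(n_transcripts = 5, seed = 3000 + i)
    true <- stats::setNames(rep(0, 200), names(categories))
    true[categories == "HIGH"] <- -0.3
    sim <- simulate_dye_swap_replicates(cfg, true, noise_sd = 0.3)
    comp <- combine_dye_swap_replicates(sim$replicates)
    kept <- filter_by_replicate_sd(comp)
    strat <- stratify_by_binding_category(kept, categories)
    strat$tests$p_value[strat$tests$category == "HIGH"] <= 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.8)
})

test_that("Welch's t-test variant is available for pairwise comparisons", {
  set.seed(9)
  comp <- data.frame(gene = sprintf("g%03d", 1:80),
                     mean_log2 = c(stats::rnorm(40, -0.5, 0.2),
                                   stats::rnorm(40, 0, 0.4)))
  categories <- stats::setNames(rep(c("HIGH", "VERY_LOW_NONE"), each = 40),
                                comp$gene)
  strat <- stratify_by_binding_category(comp, categories, test = "welch")
  expect_lt(strat$tests$p_value, 0.01)
  expect_identical(strat$tests$test, "welch")
})
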