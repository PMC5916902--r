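test_that("zero-dispersion CRAC counts equal the rounded expectation", {
  cfg <- sim_config(
    n_transcripts = 50, dispersion = 0, seed = 1,
    rbp_specs = list(rbp_spec("r1", "CRAC_COUNT", depth = 1e5))
  )
  sim <- simulate_binding_experiments(cfg)
  e <- sim$experiments[[1L]]
  a <- sim$truth$affinity[, "r1"]
  expr <- sim$truth$expression
  mu <- 1e5 * (a * expr) / sum(a * expr)
  expect_equal(unname(e$values), unname(floor(mu + 0.5)))
})

test_that("identical config and seed reproduce simulations byte for byte", {
  cfg <- sim_config(n_transcripts = 100, seed = 7,
                    rbp_specs = small_crac_panel())
  s1 <- simulate_binding_experiments(cfg)
  s2 <- simulate_binding_experiments(cfg)
  expect_identical(s1, s2)
  th <- stats::setNames(rep(0.4, 3), cfg$transcripts[1:3])
  expect_identical(simulate_polysome_profiles(cfg, th),
                   simulate_polysome_profiles(cfg, th))
  expect_identical(simulate_chase_series(cfg, 45),
                   simulate_chase_series(cfg, 45))
  expect_identical(simulate_rip_qpcr(cfg, c(x = 3)),
                   simulate_rip_qpcr(cfg, c(x = 3)))
})

test_that("raw CRAC counts are dominated by the expression confound", {
  cfg <- sim_config(n_transcripts = 2000, dispersion = 0.2,
                    expression_sdlog = 1.5, seed = 5,
                    rbp_specs = small_crac_panel(depth = 1e6))
  sim <- simulate_binding_experiments(cfg)
  for (e in sim$experiments) {
    raw <- e$values
    s_expr <- cor(raw, sim$truth$expression[names(raw)], method = "spearman")
    s_aff <- cor(raw, sim$truth$affinity[names(raw), e$rbp_id],
                 method = "spearman")
    expect_gt(s_expr, s_aff)
  }
})

test_that("RIP scores are monotone in affinity and CLIP calls threshold it", {
  cfg <- sim_config(
    n_transcripts = 100, seed = 3,
    rbp_specs = list(
      rbp_spec("rip", "RIP_SCORE", score_noise_sd = 0),
      rbp_spec("clip", "CLIP_CALL", bound_fraction = 0.25)
    )
  )
  sim <- simulate_binding_experiments(cfg)
  rip <- sim$experiments[[1L]]
  expect_equal(cor(rip$values, sim$truth$affinity[, "rip"],
                   method = "spearman"), 1)
  clip <- sim$experiments[[2L]]
  expect_setequal(unique(clip$values), c(0, 1))
  expect_equal(sum(clip$values), 25)
  # bound calls sit strictly above unbound in affinity
  a <- sim$truth$affinity[, "clip"]
  expect_gt(min(a[clip$values == 1]), max(a[clip$values == 0]))
})

test_that("chase series obeys the exact exponential and no-decay limits", {
  cfg <- sim_config(n_transcripts = 10, seed = 1,
                    chase = chase_spec(time_points = c(0, 30, 60),
                                       noise_cv = 0))
  s <- simulate_chase_series(cfg, half_life = 30)
  expect_equal(s$amounts, c(1, 0.5, 0.25))
  flat <- simulate_chase_series(cfg, half_life = Inf)
  expect_equal(flat$amounts, c(1, 1, 1))
  expect_error(simulate_chase_series(cfg, half_life = 0), "positive")
})

test_that("polysome boundary thetas put all mass in a single peak", {
  cfg <- sim_config(
    n_transcripts = 10, seed = 2,
    polysome = polysome_spec(noise_cv = 0, spike_perturbation = 0)
  )
  tx <- cfg$transcripts[1:2]
  up <- simulate_polysome_profiles(
    cfg, stats::setNames(c(1, 0), tx))$profile
  for_target <- function(t) up$quantities[t, ] / sum(up$quantities[t, ])
  bump <- function(center) {
    w <- exp(-((1:14 - center)^2) / (2 * 1^2))
    w / sum(w)
  }
  # theta = 1: the distribution IS the discretized polysomal bump
  expect_equal(unname(for_target(tx[1])), bump(11), tolerance = 1e-12)
  # theta = 0: the distribution IS the light-fraction bump
  expect_equal(unname(for_target(tx[2])), bump(3), tolerance = 1e-12)
})

test_that("polysome mass conservation: mixture components sum to the total", {
  cfg <- sim_config(
    n_transcripts = 5, seed = 9,
    polysome = polysome_spec(noise_cv = 0, spike_perturbation = 0)
  )
  th <- stats::setNames(c(0.3, 0.7), cfg$transcripts[1:2])
  p <- simulate_polysome_profiles(cfg, th, total_quantity = 1000)$profile
  expect_equal(unname(rowSums(p$quantities)), c(1000, 1000), tolerance = 1e-9)
})

test_that("generator contracts reject invalid parameters", {
  expect_error(sim_config(n_transcripts = 1), "at least 2")
  expect_error(rbp_spec("x", depth = 0), "positive")
  expect_error(qpcr_spec(efficiency = 1), "\\(1, 2\\]")
  expect_error(qpcr_spec(efficiency = 2.5), "\\(1, 2\\]")
  expect_error(polysome_spec(n_fractions = 2), "at least 3")
  expect_error(chase_spec(time_points = c(10, 20)), "include 0")
  cfg <- sim_config(n_transcripts = 5, seed = 1)
  expect_error(
    simulate_polysome_profiles(cfg, stats::setNames(1.2, cfg$transcripts[1])),
    "\\[0, 1\\]")
})

test_that("dye-swap generator plants exact replicate disagreement", {
  cfg <- sim_config(n_transcripts = 20, seed = 4)
  genes <- paste0("g", 1:6)
  true <- stats::setNames(c(0, 0, -0.5, 0.2, 0, 0), genes)
  inc <- c(g2 = 0.8, g5 = 0.6, g6 = 0.4)
  sim <- simulate_dye_swap_replicates(cfg, true, inconsistency = inc,
                                      noise_sd = 0)
  comp <- combine_dye_swap_replicates(sim$replicates)
  expect_equal(stats::setNames(comp$mean_log2, comp$gene)[genes],
               true, tolerance = 1e-12)
  sds <- stats::setNames(comp$sd, comp$gene)
  expect_equal(sds[["g2"]], 0.8, tolerance = 1e-12)
  expect_equal(sds[["g1"]], 0, tolerance = 1e-12)
  expect_setequal(sim$truth$inconsistent_genes, c("g2", "g5"))
})
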