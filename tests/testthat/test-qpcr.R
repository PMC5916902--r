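test_that("relative quantities double per cycle at perfect efficiency", {
  q <- ct_to_relative_quantity(c(20, 21), efficiency = 2)
  expect_equal(q[1] / q[2], 2)
  expect_equal(ct_to_relative_quantity(25) / ct_to_relative_quantity(25), 1)
  expect_error(ct_to_relative_quantity(20, efficiency = 1), "\\(1, 2\\]")
  expect_error(ct_to_relative_quantity(Inf), "finite")
})

test_that("percent of IP follows the aliquot arithmetic", {
  expect_equal(percent_ip(5, 100), 5)
  # input aliquot is 10% of total: measured input 10 represents 100 total
  expect_equal(percent_ip(5, 10, input_fraction = 0.1), 5)
  expect_error(percent_ip(5, 0), "positive")
  expect_error(percent_ip(5, 10, input_fraction = 0), "\\(0, 1\\]")
})

test_that("fold over control normalizes to bait and fixes no-tag at 1", {
  percents <- data.frame(
    target = c("x", "x"), sample = c("tag", "no_tag"),
    percent_ip = c(10 * 0.7, 1 * 1.3)
  )
  bait <- c(tag = 0.7, no_tag = 1.3)
  out <- fold_over_control(percents, bait, no_tag = "no_tag")
  expect_equal(out$fold_over_no_tag[out$sample == "no_tag"], 1)
  expect_equal(out$fold_over_no_tag[out$sample == "tag"], 10)
  # zero no-tag errors without a pseudocount, warns with one
  zero <- data.frame(target = "x", sample = c("tag", "no_tag"),
                     percent_ip = c(5, 0))
  expect_error(fold_over_control(zero, c(tag = 1, no_tag = 1)), "no-tag")
  expect_warning(
    ok <- fold_over_control(zero, c(tag = 1, no_tag = 1), pseudocount = 0.01),
    "pseudocount")
  expect_true(all(is.finite(ok$fold_over_no_tag)))
})

test_that("technical replicates average on the Ct scale with spread warning", {
  wells <- data.frame(
    target = "x", sample = "s", fraction = "input",
    ct = c(20, 20.2, 20.1)
  )
  agg <- average_technical_replicates(wells)
  expect_equal(agg$ct, mean(c(20, 20.2, 20.1)))
  noisy <- data.frame(target = "x", sample = "s", fraction = "ip",
                      ct = c(20, 21.5))
  expect_warning(average_technical_replicates(noisy), "spread")
})

test_that("zero-noise synthetic tables roundtrip planted folds exactly", {
  cfg <- sim_config(n_transcripts = 5, seed = 6,
                    qpcr = qpcr_spec(ct_noise_sd = 0))
  folds <- c(nup_a = 10, nup_b = 2.5, ctrl = 1)
  sim <- simulate_rip_qpcr(cfg, folds)
  out <- quantify_rip(sim$wells, sim$sample_map)
  tagged <- out[out$sample == "tagged", ]
  expect_equal(stats::setNames(tagged$fold_over_no_tag, tagged$target)[
    names(folds)], folds, tolerance = 1e-9)
  expect_true(all(out$fold_over_no_tag[out$sample == "no_tag"] == 1))
})

test_that("fold estimates are invariant to per-sample scale", {
  cfg <- sim_config(n_transcripts = 5, seed = 6,
                    qpcr = qpcr_spec(ct_noise_sd = 0))
  sim <- simulate_rip_qpcr(cfg, c(a = 4))
  base <- quantify_rip(sim$wells, sim$sample_map)
  # shifting every Ct of a sample scales all its quantities by a common
  # factor; percent_ip is a within-sample ratio, so folds are unchanged
  shifted <- sim$wells
  idx <- shifted$sample == "tagged"
  shifted$ct[idx] <- shifted$ct[idx] + 1.7
  expect_equal(quantify_rip(shifted, sim$sample_map)$fold_over_no_tag,
               base$fold_over_no_tag, tolerance = 1e-9)
  both <- sim$wells
  both$ct <- both$ct + ifelse(both$sample == "no_tag", 0.9, 0)
  expect_equal(quantify_rip(both, sim$sample_map)$fold_over_no_tag,
               base$fold_over_no_tag, tolerance = 1e-9)
  # but scaling only the IP fraction scales percent_ip and hence the fold
  ip_only <- sim$wells
  sel <- ip_only$sample == "tagged" & ip_only$fraction == "ip"
  ip_only$ct[sel] <- ip_only$ct[sel] + 1
  out <- quantify_rip(ip_only, sim$sample_map)
  tag <- out$sample == "tagged"
  expect_equal(out$fold_over_no_tag[tag] * 2,
               base$fold_over_no_tag[tag], tolerance = 1e-9)
})

test_that("Ct noise propagates like a lognormal on the fold scale", {
  # fold = ratio of 4 quantities, each from a mean of 3 Cts with sd 0.2:
  # sd(log fold) = ln(E) * 0.2 / sqrt(3) * sqrt(4)
  cfg <- sim_config(n_transcripts = 5, seed = 1,
                    qpcr = qpcr_spec(ct_noise_sd = 0.2, n_replicates = 3))
  analytic_sd <- log(2) * 0.2 / sqrt(3) * 2
  logs <- vapply(1:200, function(i) {
    cfg$seed <- i
    sim <- simulate_rip_qpcr(cfg, c(a = 10))
    # the replicate-spread warning fires by design at this noise level
    out <- suppressWarnings(quantify_rip(sim$wells, sim$sample_map))
    log(out$fold_over_no_tag[out$sample == "tagged"] / 10)
  }, numeric(1))
  expect_lt(abs(mean(logs)), 3 * analytic_sd / sqrt(200))
  expect_gt(stats::sd(logs) / analytic_sd, 0.8)
  expect_lt(stats::sd(logs) / analytic_sd, 1.25)
})
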