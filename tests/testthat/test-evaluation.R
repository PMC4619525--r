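test_that("error metrics reproduce hand-computed percentages", {
  obs <- c(100, 200, 300)
  pred <- c(110, 190, 330)
  expect_equal(hospital_level_error(pred, obs), 100 * 50 / 600)
  expect_equal(national_level_error(pred, obs), 5)
  expect_equal(hospital_level_error(obs, obs), 0)
  expect_equal(national_level_error(obs, obs), 0)
  # under/over-estimates cancel nationally but not per hospital
  expect_equal(hospital_level_error(c(150, 150), c(100, 200)), 100 / 3)
  expect_equal(national_level_error(c(150, 150), c(100, 200)), 0)
  expect_error(hospital_level_error(c(1, 2), c(0, 0)), "zero")
  pop <- generate_population(generator_config(seed = 2))
  fit <- fit_poisson(pop, "rbc")
  pr <- predict_counts(fit, pop)
  expect_equal(hospital_level_error(pr, pop, "rbc"),
               hospital_level_error(pr, pop$rbc))
})

test_that("national error never exceeds hospital-level error", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(2:60, 1)
    obs <- rpois(n, lambda = runif(1, 1, 500)) + 1
    pred <- obs * exp(rnorm(n, 0, 0.5))
    expect_lte(national_level_error(pred, obs),
               hospital_level_error(pred, obs) + 1e-12)
  }
})

test_that("error metrics are scale invariant", {
  set.seed(45)
  obs <- rpois(30, 200) + 1
  pred <- obs * exp(rnorm(30, 0, 0.3))
  for (c_mult in c(0.01, 3, 1e4)) {
    expect_equal(hospital_level_error(pred * c_mult, obs * c_mult),
                 hospital_level_error(pred, obs), tolerance = 1e-10)
    expect_equal(national_level_error(pred * c_mult, obs * c_mult),
                 national_level_error(pred, obs), tolerance = 1e-10)
  }
})

test_that("distribution summaries match direct order-statistic computation", {
  expect_equal(summarize_distribution(c(10, 20, 30)),
               c(median = 20, mean = 20, centile_2.5 = 10.5, centile_97.5 = 29.5))
  expect_equal(unname(summarize_distribution(rep(7, 50))), rep(7, 4))
  set.seed(46)
  x <- runif(1000)
  s <- summarize_distribution(x)
  # oracle: R's own interpolated quantile on sorted data
  expect_equal(unname(s["centile_97.5"]),
               unname(quantile(x, 0.975, type = 7)), tolerance = 1e-12)
  expect_equal(unname(s["centile_2.5"]),
               unname(quantile(x, 0.025, type = 7)), tolerance = 1e-12)
  expect_error(summarize_distribution(numeric(0)), "empty")
})

test_that("head-to-head fractions count strict wins only", {
  expect_equal(head_to_head_fraction(c(10, 20, 30), 20), 100 / 3)
  expect_equal(head_to_head_fraction(c(1, 2, 3), 10), 100)
  expect_equal(head_to_head_fraction(rep(5, 10), 5), 0)
  expect_error(head_to_head_fraction(numeric(0), 1), "replicate")
})

test_that("deterministic strategies yield identical replicate errors", {
  pop <- generate_population(generator_config(seed = 14))
  sim <- run_replicates(pop, "larg", scenario("A"), n_reps = 25, seed = 1)
  e <- sim$errors
  for (p in c("rbc", "ffp", "plt")) {
    expect_equal(length(unique(e$hospital_error_pct[e$product == p])), 1)
    expect_equal(length(unique(e$national_error_pct[e$product == p])), 1)
  }
  expect_equal(sim$summary$median, sim$summary$mean)
})

test_that("replicated runs are reproducible from the seed", {
  pop <- generate_population(generator_config(seed = 15))
  a <- run_replicates(pop, "rand", scenario("A"), n_reps = 60, seed = 7)
  b <- run_replicates(pop, "rand", scenario("A"), n_reps = 60, seed = 7)
  expect_identical(a$errors, b$errors)
  expect_identical(a$summary, b$summary)
  c2 <- run_replicates(pop, "rand", scenario("A"), n_reps = 60, seed = 8)
  expect_false(identical(a$errors, c2$errors))
})

test_that("independent Monte Carlo runs agree within their centile band", {
  pop <- generate_population(generator_config(seed = 16))
  a <- run_replicates(pop, "rand", scenario("A"), n_reps = 500, seed = 1,
                      products = "rbc")
  b <- run_replicates(pop, "rand", scenario("A"), n_reps = 500, seed = 2,
                      products = "rbc")
  med_a <- a$summary$median[a$summary$metric == "hospital"]
  band_b <- b$summary[b$summary$metric == "hospital", c("centile_2.5", "centile_97.5")]
  expect_gte(med_a, band_b[[1]])
  expect_lte(med_a, band_b[[2]])
})

test_that("every replicate satisfies the national <= hospital inequality", {
  pop <- generate_population(generator_config(seed = 18))
  for (st in c("larg", "maxvar", "rand", "regvar", "2reg")) {
    sim <- run_replicates(pop, st, scenario("A"), n_reps = 30, seed = 3)
    expect_true(all(sim$errors$national_error_pct <=
                      sim$errors$hospital_error_pct + 1e-9))
  }
})

test_that("selecting the whole population leaves near-zero national error", {
  pop <- generate_population(generator_config(seed = 19))
  for (p in c("rbc", "ffp", "plt")) {
    fit <- fit_poisson(pop, p)
    pr <- predict_counts(fit, pop)
    expect_lt(national_level_error(pr, pop, p), 1e-6)
    # hospital-level error equals the in-sample mean absolute residual share
    expect_equal(hospital_level_error(pr, pop, p),
                 100 * sum(abs(residuals(fit))) / sum(pop[[p]]),
                 tolerance = 1e-9)
  }
})

test_that("2REG replicates draw pairs uniformly and respect the academic rule", {
  pop <- generate_population(generator_config(seed = 20))
  sim <- run_replicates(pop, "2reg", scenario("A"), n_reps = 300, seed = 5)
  pairs <- unique(sim$errors$region_pair)
  expect_gt(length(pairs), 15)  # most of the 21 pairs appear in 300 draws
  expect_true(all(grepl("^R\\d\\+R\\d$", pairs)))
})

test_that("the experiment report has the full scenario x strategy x product shape", {
  pop <- generate_population(generator_config(seed = 22))
  ex <- run_experiment(pop, scenarios = c(A = "A", B = "B", C = "C"),
                       n_reps = 8, n_batches = 2, seed = 1)
  expect_s3_class(ex, "strategy_experiment")
  expect_equal(nrow(ex$summary), 3 * 5 * 3 * 2)  # 90 cells
  expect_true(all(ex$summary$centile_97.5 >= ex$summary$centile_2.5))
  # head-to-head: 3 random x 2 purposive x 3 products x 2 metrics x 3 scenarios
  expect_equal(nrow(ex$head_to_head), 3 * 2 * 3 * 2 * 3)
  expect_true(all(ex$head_to_head$pct_outperform >= 0 &
                    ex$head_to_head$pct_outperform <= 100))
  expect_output(print(ex), "Scenario A")
})

test_that("single-batch experiments equal a direct replicate run", {
  pop <- generate_population(generator_config(seed = 23))
  ex <- run_experiment(pop, scenarios = c(A = "A"), strategies = "rand",
                       n_reps = 40, n_batches = 1, seed = 9)
  direct <- run_replicates(pop, "rand", scenario("A"), n_reps = 40, seed = 9,
                           batch = 1)
  s <- ex$summary
  for (k in seq_len(nrow(s))) {
    d <- direct$summary[direct$summary$product == s$product[k] &
                          direct$summary$metric == s$metric[k], ]
    expect_equal(s$median[k], d$median)
    expect_equal(s$centile_97.5[k], d$centile_97.5)
  }
})

test_that("batch-averaged medians track the pooled-run median", {
  pop <- generate_population(generator_config(seed = 24))
  ex <- run_experiment(pop, scenarios = c(A = "A"), strategies = "rand",
                       n_reps = 300, n_batches = 4, seed = 2, products = "rbc")
  s <- ex$summary[ex$summary$metric == "hospital", ]
  pooled <- median(ex$replicates$hospital_error_pct[
    ex$replicates$product == "rbc"])
  batch_se <- s$batch_sd_median / sqrt(ex$n_batches)
  expect_lt(abs(s$median - pooled), max(3 * batch_se, 0.5))
})

test_that("per-pair evaluation reports every region pair separately", {
  pop <- generate_population(generator_config(seed = 25))
  res <- run_pairs(pop, scenario("A"), n_reps = 5, seed = 1, products = "rbc")
  expect_equal(length(unique(res$region_pair)), 21)
  expect_equal(nrow(res), 21 * 2)  # hospital + national rows per pair
})

test_that("holdout-only errors are computed over non-sampled hospitals", {
  pop <- generate_population(generator_config(seed = 26))
  full <- run_replicates(pop, "larg", scenario("A"), n_reps = 1, seed = 1,
                         products = "rbc")
  hold <- run_replicates(pop, "larg", scenario("A"), n_reps = 1, seed = 1,
                         products = "rbc", holdout_only = TRUE)
  expect_false(isTRUE(all.equal(full$summary$median, hold$summary$median)))
  # oracle: recompute the holdout error by hand
  sel <- select_largest(pop, scenario("A"))
  smp <- pop[match(sel$hospital_ids, pop$hospital_id), ]
  fit <- fit_poisson(smp, "rbc")
  out <- pop[!pop$hospital_id %in% sel$hospital_ids, ]
  expect_equal(hold$summary$median[hold$summary$metric == "hospital"],
               hospital_level_error(predict(fit, out), out$rbc))
})

test_that("reports serialize, validate and round-trip through JSON", {
  pop <- generate_population(generator_config(seed = 27))
  ex <- run_experiment(pop, scenarios = c(A = "A"), n_reps = 5, n_batches = 2,
                       seed = 3)
  rep_list <- as_report(ex)
  expect_true(validate_report(rep_list))
  dir <- tempfile()
  write_report(ex, dir)
  expect_true(file.exists(file.path(dir, "replicates.csv")))
  expect_true(file.exists(file.path(dir, "table.txt")))
  expect_true(validate_report(file.path(dir, "summary.json")))
  broken <- rep_list
  broken$error_summary$median[1] <- -5
  expect_error(validate_report(broken), "median")
  broken2 <- rep_list
  broken2$meta$seed <- NULL
  expect_error(validate_report(broken2), "seed")
})
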