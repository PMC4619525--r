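#' Hospital-level prediction error
#'
#' Sums the absolute prediction error over all hospitals and expresses it as
#' a percentage of the population total:
#' `100 * sum(|pred - obs|) / sum(obs)`.
#'
#' @param pred Numeric vector of predicted counts, aligned with the
#'   population rows.
#' @param pop A `hospital_population`, or directly a numeric vector of
#'   observed counts.
#' @param product Product column to compare against when `pop` is a
#'   population (`"rbc"`, `"ffp"` or `"plt"`).
#' @return Percentage (numeric scalar, >= 0).
#' @seealso [national_level_error()]
#' @examples
#' hospital_level_error(c(110, 190, 330), c(100, 200, 300)) # 8.33...
#' @export
hospital_level_error <- function(pred, pop, product = NULL) {
  obs <- if (is.numeric(pop)) pop else pop[[match.arg(product, PRODUCTS)]]
  stopifnot(length(pred) == length(obs))
  total <- sum(obs)
  if (total <= 0) stop_validation("population total is zero: error metric undefined")
  100 * sum(abs(pred - obs)) / total
}

#' National-level prediction error
#'
#' Absolute deviation of the summed prediction (the national estimate) from
#' the true population total, as a percentage of that total:
#' `100 * |sum(pred) - sum(obs)| / sum(obs)`. By the triangle inequality it
#' never exceeds the hospital-level error on the same inputs.
#'
#' @inheritParams hospital_level_error
#' @return Percentage (numeric scalar, >= 0).
#' @export
national_level_error <- function(pred, pop, product = NULL) {
  obs <- if (is.numeric(pop)) pop else pop[[match.arg(product, PRODUCTS)]]
  stopifnot(length(pred) == length(obs))
  total <- sum(obs)
  if (total <= 0) stop_validation("population total is zero: error metric undefined")
  100 * abs(sum(pred) - total) / total
}

#' Summarize a simulated error distribution
#'
#' Median, mean and the 95% centiles (2.5th and 97.5th percentiles, linear
#' interpolation between order statistics).
#'
#' @param values Nonempty numeric vector.
#' @return Named numeric vector `median`, `mean`, `centile_2.5`,
#'   `centile_97.5`.
#' @export
summarize_distribution <- function(values) {
  if (length(values) == 0 || anyNA(values)) {
    stop_validation("cannot summarize an empty (or NA-holding) sequence")
  }
  c(median = stats::median(values), mean = mean(values),
    centile_2.5 = interp_centile(values, 0.025),
    centile_97.5 = interp_centile(values, 0.975))
}

# linear interpolation between sorted order statistics
interp_centile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Fraction of random-strategy replicates that beat a purposive strategy
#'
#' Percentage of replicate errors strictly below the (deterministic)
#' purposive strategy's error; ties count as not outperforming.
#'
#' @param random_errors Nonempty numeric vector of replicate errors.
#' @param purposive_error Scalar error of the purposive strategy.
#' @return Percentage in `[0, 100]`.
#' @export
head_to_head_fraction <- function(random_errors, purposive_error) {
  if (length(random_errors) == 0) stop_validation("no replicate errors supplied")
  100 * mean(random_errors < purposive_error)
}

#' Replicated evaluation of one sampling strategy
#'
#' Simulates one strategy `n_reps` times on a population: each replicate
#' draws a selection, fits the Poisson prediction model for each requested
#' product, predicts counts for every hospital, and computes the
#' hospital-level and national-level errors. For the deterministic
#' strategies (`larg`, `maxvar`) the selection is evaluated once and
#' replicated logically. For `"2reg"` each replicate first draws a region
#' pair uniformly from [enumerate_region_pairs()] (unless `pair` fixes one).
#' Replicates whose model fit fails (rank-deficient design or
#' non-convergence) are counted in `failed` and excluded from summaries.
#'
#' @param pop A `hospital_population`.
#' @param strategy One of `"larg"`, `"maxvar"`, `"rand"`, `"regvar"`,
#'   `"2reg"`.
#' @param scen A [scenario()].
#' @param n_reps Number of replicates.
#' @param seed Master seed; the actual stream is derived from
#'   `(seed, strategy, scenario, batch)` via [derive_seed()] so strategies
#'   never perturb each other's draws.
#' @param products Products to evaluate (default all three).
#' @param holdout_only Compute errors over non-sampled hospitals only,
#'   instead of the whole population (default `FALSE`).
#' @param per_type_slopes Passed to [fit_poisson()].
#' @param pair Optional fixed region pair for `"2reg"`.
#' @param batch Batch label mixed into the derived seed.
#' @return An object of class `strategy_sim`: per-replicate errors
#'   (`$errors`), number of `$failed` replicates, and a `$summary` data
#'   frame (median / mean / 95% centiles per product and error level).
#' @examples
#' pop <- generate_population(generator_config(seed = 7))
#' run_replicates(pop, "rand", scenario("A"), n_reps = 50, seed = 1)
#' @export
run_replicates <- function(pop, strategy, scen = scenario("A"), n_reps = 1000,
                           seed = 1L, products = PRODUCTS,
                           holdout_only = FALSE, per_type_slopes = FALSE,
                           pair = NULL, batch = 1L) {
  strategy <- match.arg(tolower(strategy), STRATEGIES)
  scen <- scenario(scen)
  check_feasible(pop, scen)
  stopifnot(n_reps >= 1)
  products <- match.arg(products, PRODUCTS, several.ok = TRUE)
  deterministic <- strategy %in% c("larg", "maxvar")

  Xpop <- model_matrix_hospitals(pop, per_type_slopes)
  obs <- as.matrix(as.data.frame(pop)[products])
  all_rows <- seq_len(nrow(pop))
  pairs <- if (strategy == "2reg" && is.null(pair)) {
    enumerate_region_pairs(attr(pop, "regions"))
  }

  eval_selection <- function(sel) {
    rows <- match(sel$hospital_ids, pop$hospital_id)
    keep <- if (holdout_only) setdiff(all_rows, rows) else all_rows
    smp <- as.data.frame(pop)[rows, , drop = FALSE]
    out <- matrix(NA_real_, length(products), 2)
    for (k in seq_along(products)) {
      fit <- fit_poisson(smp, products[k], per_type_slopes)
      if (!fit$converged) return(NULL)
      predicted <- exp(drop(Xpop %*% fit$coefficients))
      o <- obs[keep, k]
      p <- predicted[keep]
      total <- sum(o)
      if (total <= 0) stop_validation("population total is zero for ", products[k])
      out[k, 1] <- 100 * sum(abs(p - o)) / total
      out[k, 2] <- 100 * abs(sum(p) - total) / total
    }
    out
  }
  safe_eval <- function(sel) {
    tryCatch(eval_selection(sel),
             hospsample_validation_error = function(e) NULL)
  }

  err <- array(NA_real_, c(n_reps, length(products), 2))
  pair_label <- rep(NA_character_, n_reps)
  if (deterministic) {
    sel <- draw_selection(pop, strategy, scen)
    one <- safe_eval(sel)
    if (is.null(one)) stop_validation("the deterministic ", strategy,
                                      " selection could not be evaluated")
    for (r in seq_len(n_reps)) err[r, , ] <- one
  } else {
    set.seed(derive_seed(seed, strategy, paste(scen, collapse = "-"), batch))
    for (r in seq_len(n_reps)) {
      p_r <- pair
      if (strategy == "2reg" && is.null(p_r)) {
        p_r <- pairs[sample.int(nrow(pairs), 1), ]
      }
      sel <- switch(strategy,
                    rand = select_random(pop, scen),
                    regvar = select_regvar(pop, scen),
                    "2reg" = select_two_regions(pop, scen, p_r))
      one <- safe_eval(sel)
      if (!is.null(one)) {
        err[r, , ] <- one
        if (strategy == "2reg") pair_label[r] <- paste(sort(p_r), collapse = "+")
      }
    }
  }

  ok <- !is.na(err[, 1, 1])
  if (!any(ok)) stop_validation("all ", n_reps, " replicates failed")
  errors <- data.frame(
    replicate = rep(which(ok), times = length(products)),
    product = rep(products, each = sum(ok)),
    hospital_error_pct = as.vector(err[ok, , 1]),
    national_error_pct = as.vector(err[ok, , 2]),
    region_pair = rep(pair_label[ok], times = length(products)),
    stringsAsFactors = FALSE)

  summ <- do.call(rbind, lapply(seq_along(products), function(k) {
    rbind(
      data.frame(product = products[k], metric = "hospital",
                 t(summarize_distribution(err[ok, k, 1]))),
      data.frame(product = products[k], metric = "national",
                 t(summarize_distribution(err[ok, k, 2]))))
  }))
  rownames(summ) <- NULL

  structure(list(strategy = strategy, scenario = scen, products = products,
                 n_reps = n_reps, failed = sum(!ok), seed = seed,
                 batch = batch, holdout_only = holdout_only,
                 errors = errors, summary = summ),
            class = "strategy_sim")
}

#' @export
print.strategy_sim <- function(x, digits = 1, ...) {
  cat(sprintf("Strategy simulation [%s], scenario %s, %d replicates (%d failed)\n",
              toupper(x$strategy), paste(x$scenario, collapse = "/"),
              x$n_reps, x$failed))
  s <- x$summary
  s[, 3:6] <- round(s[, 3:6], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Full comparison experiment over scenarios and strategies
#'
#' Runs every requested scenario x strategy combination: deterministic
#' strategies are evaluated once; random strategies are run in `n_batches`
#' independent batches of `n_reps` replicates, the per-batch summary
#' statistics are averaged for the report, and the dispersion of batch
#' medians is reported alongside. Head-to-head win fractions of each random
#' strategy against each purposive strategy (percentage of replicates with a
#' strictly lower error; ties do not count as wins) are computed per batch
#' and averaged.
#'
#' @inheritParams run_replicates
#' @param scenarios Named vector or list of scenarios (default the three
#'   standard sizes A/B/C).
#' @param strategies Strategy labels to include (default all five).
#' @param n_batches Number of independent batches per random strategy.
#' @return An object of class `strategy_experiment` with elements
#'   `$summary` (one row per scenario x strategy x product x error level),
#'   `$head_to_head` (win fractions), and `$replicates` (tidy per-replicate
#'   errors).
#' @examples
#' pop <- generate_population(generator_config(seed = 7))
#' ex <- run_experiment(pop, scenarios = c(A = "A"), n_reps = 20,
#'                      n_batches = 2, seed = 1)
#' print(ex)
#' @export
run_experiment <- function(pop, scenarios = c(A = "A", B = "B", C = "C"),
                           strategies = STRATEGIES, n_reps = 1000,
                           n_batches = 10, seed = 1L, products = PRODUCTS,
                           holdout_only = FALSE, per_type_slopes = FALSE) {
  stopifnot(n_reps >= 1, n_batches >= 1)
  strategies <- match.arg(tolower(strategies), STRATEGIES, several.ok = TRUE)
  if (is.null(names(scenarios))) {
    names(scenarios) <- if (is.character(scenarios)) toupper(scenarios) else
      paste0("S", seq_along(scenarios))
  }
  scen_list <- lapply(scenarios, scenario)

  summary_rows <- list()
  h2h_rows <- list()
  rep_rows <- list()
  stat_cols <- c("median", "mean", "centile_2.5", "centile_97.5")

  for (sc in names(scen_list)) {
    scen <- scen_list[[sc]]
    det_err <- list()  # purposive per-product/metric errors for head-to-head
    random_sims <- list()
    for (st in strategies) {
      if (st %in% c("larg", "maxvar")) {
        sim <- run_replicates(pop, st, scen, n_reps = 1, seed = seed,
                              products = products, holdout_only = holdout_only,
                              per_type_slopes = per_type_slopes)
        s <- sim$summary
        summary_rows[[length(summary_rows) + 1]] <-
          cbind(scenario = sc, strategy = st, s[c("product", "metric", stat_cols)],
                batch_sd_median = 0, failed = sim$failed,
                n_reps_total = n_reps)
        det_err[[st]] <- s
        rep_rows[[length(rep_rows) + 1]] <-
          cbind(scenario = sc, strategy = st, batch = 1L, sim$errors)
      } else {
        batches <- lapply(seq_len(n_batches), function(b) {
          run_replicates(pop, st, scen, n_reps = n_reps, seed = seed,
                         products = products, holdout_only = holdout_only,
                         per_type_slopes = per_type_slopes, batch = b)
        })
        random_sims[[st]] <- batches
        per_batch <- lapply(batches, `[[`, "summary")
        avg <- per_batch[[1]]
        stats_arr <- sapply(per_batch, function(s) as.matrix(s[stat_cols]),
                            simplify = "array")
        avg[stat_cols] <- apply(stats_arr, c(1, 2), mean)
        batch_sd <- apply(sapply(per_batch, function(s) s$median), 1,
                          stats::sd)
        if (n_batches == 1) batch_sd <- rep(0, nrow(avg))
        summary_rows[[length(summary_rows) + 1]] <-
          cbind(scenario = sc, strategy = st,
                avg[c("product", "metric", stat_cols)],
                batch_sd_median = batch_sd,
                failed = sum(vapply(batches, `[[`, 0L, "failed")),
                n_reps_total = n_reps * n_batches)
        for (b in seq_len(n_batches)) {
          rep_rows[[length(rep_rows) + 1]] <-
            cbind(scenario = sc, strategy = st, batch = b, batches[[b]]$errors)
        }
      }
    }
    # head-to-head: random vs purposive, averaged over batches
    for (st in intersect(names(random_sims), RANDOM_STRATEGIES)) {
      for (pu in intersect(names(det_err), c("maxvar", "larg"))) {
        for (p in products) {
          for (met in c("hospital", "national")) {
            col <- paste0(met, "_error_pct")
            ref <- det_err[[pu]]
            ref_val <- ref[ref$product == p & ref$metric == met, "median"]
            fr <- vapply(random_sims[[st]], function(sim) {
              e <- sim$errors
              head_to_head_fraction(e[e$product == p, col], ref_val)
            }, 0)
            h2h_rows[[length(h2h_rows) + 1]] <-
              data.frame(scenario = sc, random_strategy = st,
                         purposive_strategy = pu, product = p, metric = met,
                         pct_outperform = mean(fr), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  structure(list(summary = do.call(rbind, summary_rows),
                 head_to_head = if (length(h2h_rows)) do.call(rbind, h2h_rows),
                 replicates = do.call(rbind, rep_rows),
                 scenarios = scen_list, strategies = strategies,
                 products = products, n_reps = n_reps, n_batches = n_batches,
                 seed = seed, holdout_only = holdout_only,
                 population_size = nrow(pop)),
            class = "strategy_experiment")
}

#' @export
print.strategy_experiment <- function(x, ...) {
  cat(sprintf("Sampling-strategy experiment: %d hospitals, seed %d, %d x %d replicates\n",
              x$population_size, x$seed, x$n_batches, x$n_reps))
  fmt_cell <- function(row) {
    if (row$strategy %in% c("larg", "maxvar")) {
      sprintf("%.0f%%", row$median)
    } else {
      sprintf("%.0f%%; %.0f%% (%.0f%%-%.0f%%)", row$median, row$mean,
              row$centile_2.5, row$centile_97.5)
    }
  }
  for (sc in names(x$scenarios)) {
    scen <- x$scenarios[[sc]]
    cat(sprintf("\nScenario %s (n = %d): median; mean (95%% centiles)\n",
                sc, sum(scen)))
    s <- x$summary[x$summary$scenario == sc, ]
    for (met in c("hospital", "national")) {
      cat(sprintf("  %s-level prediction error\n", met))
      m <- matrix("", length(x$strategies), length(x$products),
                  dimnames = list(toupper(x$strategies), toupper(x$products)))
      for (st in x$strategies) for (p in x$products) {
        row <- s[s$strategy == st & s$product == p & s$metric == met, ]
        m[toupper(st), toupper(p)] <- fmt_cell(row)
      }
      print(m, quote = FALSE)
    }
  }
  invisible(x)
}

#' @export
summary.strategy_experiment <- function(object, ...) {
  object$summary
}

#' @export
plot.strategy_experiment <- function(x, scenario_label = names(x$scenarios)[1],
                                     metric = c("hospital", "national"), ...) {
  metric <- match.arg(metric)
  s <- x$summary[x$summary$scenario == scenario_label & x$summary$metric == metric, ]
  med <- matrix(s$median, nrow = length(x$strategies), byrow = FALSE)
  med <- t(sapply(x$strategies, function(st)
    sapply(x$products, function(p)
      s$median[s$strategy == st & s$product == p])))
  bp <- graphics::barplot(t(med), beside = TRUE,
                          names.arg = toupper(x$strategies),
                          legend.text = toupper(x$products),
                          ylab = sprintf("%s-level prediction error (%%)", metric),
                          main = sprintf("Scenario %s", scenario_label), ...)
  for (i in seq_along(x$strategies)) {
    st <- x$strategies[i]
    if (st %in% RANDOM_STRATEGIES) {
      for (j in seq_along(x$products)) {
        row <- s[s$strategy == st & s$product == x$products[j], ]
        graphics::arrows(bp[j, i], row$centile_2.5, bp[j, i], row$centile_97.5,
                         angle = 90, code = 3, length = 0.03)
      }
    }
  }
  invisible(bp)
}

#' Evaluate two-region sampling separately for every region pair
#'
#' Runs `n_reps` replicates of the 2REG strategy for each of the
#' `choose(k, 2)` region pairs and reports the per-pair error summaries, for
#' inspecting differences between region combinations.
#'
#' @inheritParams run_replicates
#' @return Data frame: one row per pair x product x error level with the
#'   summary statistics.
#' @export
run_pairs <- function(pop, scen = scenario("A"), n_reps = 100, seed = 1L,
                      products = PRODUCTS, holdout_only = FALSE) {
  pairs <- enumerate_region_pairs(attr(pop, "regions"))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sim <- run_replicates(pop, "2reg", scen, n_reps = n_reps, seed = seed,
                          products = products, holdout_only = holdout_only,
                          pair = pairs[i, ], batch = i)
    cbind(region_pair = paste(pairs[i, ], collapse = "+"), sim$summary)
  })
  do.call(rbind, out)
}
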