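test_that("the model roster matches the analysis design", {
  ms <- model_specs()
  expect_equal(nrow(ms), 34)
  # time-with-mother models carry no permutation test
  expect_true(all(ms$permutation[ms$model == "MP1a"] == "none"))
  # proximity models use datastream swaps except the partner-category ones
  prox <- ms[ms$kind == "proximity" & ms$model != "MP1a", ]
  expect_true(all(prox$permutation[!grepl("MP2c", prox$model)] ==
                    "datastream"))
  expect_true(all(prox$permutation[grepl("MP2c", prox$model)] == "node"))
  # grooming models all use node permutations
  expect_true(all(ms$permutation[ms$kind == "grooming" &
                                   ms$model != "MP1a"] == "node"))
  # node-metric models control for the mother's corresponding metric
  expect_true(all(!is.na(ms$mother_metric[ms$model %in%
                                            c("MP2a", "MP2b.1", "MP2b.2")])))
})

sim_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_troop(tiny_config(90L))
      nets <- build_networks(sim$scans, sim$grooming, sim$seasons)
      rk <- rank_table(sim$dominance, sim$seasons, n_restarts = 15)
      resp <- suppressMessages(response_table(nets, sim$population))
      met <- metric_table(nets)
      cache <<- list(sim = sim, nets = nets, rk = rk, resp = resp,
                     met = met)
    }
    cache
  }
})

test_that("model tables join responses with covariates", {
  st <- sim_tables()
  spec <- model_specs()[1, ]   # MP1a proximity
  tab <- suppressMessages(build_model_table(spec, st$resp,
                                            population = st$sim$population,
                                            ranks = st$rk))
  expect_true(all(c("k", "n", "age", "sex", "mother_rank",
                    "mother_offspring_count") %in% names(tab)))
  expect_true(all(tab$k <= tab$n))
  expect_true(all(tab$age <= 60))
  expect_false(anyNA(tab$mother_rank))
  # duplicated (immature, period) rows are an error
  dup <- rbind(st$resp, st$resp[st$resp$response == "mp1a", ][1, ])
  expect_error(suppressMessages(
    build_model_table(spec, dup, population = st$sim$population,
                      ranks = st$rk)), "duplicate")
})

test_that("metric model tables carry the mother's standardized metric", {
  st <- sim_tables()
  ms <- model_specs()
  spec <- ms[ms$model == "MP2a" & ms$kind == "proximity", ]
  tab <- suppressMessages(build_model_table(spec, NULL, metrics = st$met,
                                            population = st$sim$population,
                                            ranks = st$rk))
  expect_true("mother_metric" %in% names(tab))
  expect_false(anyNA(tab$mother_metric))
  key <- paste(tab$troop[1], tab$year[1], tab$period[1], tab$mother_id[1])
  mkey <- paste(st$met$troop, st$met$year, st$met$period, st$met$id)
  expect_equal(tab$mother_metric[1],
               st$met$standardized[st$met$metric == "strength_prox"][
                 match(key, mkey[st$met$metric == "strength_prox"])])
})

test_that("the LMM recovers a known slope from constructed data", {
  set.seed(123)
  n_im <- 40
  moms <- sprintf("m%02d", rep(1:20, each = 2))
  ims <- sprintf("i%02d", 1:n_im)
  rows <- expand.grid(immature_id = ims, period = 1:15)
  rows$mother_id <- moms[match(rows$immature_id, ims)]
  rows$troop <- "J"
  rows$year <- 2014 + (rows$period > 8)
  rows$age <- runif(nrow(rows), 3, 58)
  rows$sex <- factor(rep(c("F", "M"), length.out = n_im)[
    match(rows$immature_id, ims)], levels = c("F", "M"))
  rows$mother_offspring_count <- 2
  rows$mother_rank <- runif(nrow(rows))
  mom_re <- rnorm(20, 0, 0.1)
  rows$value <- 0.5 - 0.02 * rows$age + 0.1 * (rows$sex == "M") +
    mom_re[match(rows$mother_id, unique(moms))] + rnorm(nrow(rows), 0, 0.2)
  fit <- fit_model(rows, "gaussian")
  age_hat <- fit$coefficients$estimate[fit$coefficients$term == "age"]
  age_se <- fit$coefficients$se[fit$coefficients$term == "age"]
  expect_lt(abs(age_hat - (-0.02)), 3 * age_se)
  expect_true(fit$converged)
  # adding a constant shifts only the intercept
  rows2 <- rows
  rows2$value <- rows$value + 5
  fit2 <- fit_model(rows2, "gaussian")
  expect_equal(fit2$coefficients$estimate[fit2$coefficients$term == "age"],
               age_hat, tolerance = 1e-6)
  expect_equal(
    fit2$coefficients$estimate[fit2$coefficients$term == "(Intercept)"] -
      fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"],
    5, tolerance = 1e-6)
  # constant response: flagged degenerate
  rows3 <- rows
  rows3$value <- 1
  expect_warning(fit3 <- fit_model(rows3, "gaussian"), "constant response")
  expect_lt(abs(fit3$coefficients$estimate[
    fit3$coefficients$term == "age"]), 1e-8)
})

test_that("the binomial GLMM recovers a known logit-linear age effect", {
  set.seed(124)
  n_im <- 40
  moms <- sprintf("m%02d", rep(1:20, each = 2))
  ims <- sprintf("i%02d", 1:n_im)
  rows <- expand.grid(immature_id = ims, period = 1:10)
  rows$mother_id <- moms[match(rows$immature_id, ims)]
  rows$troop <- "J"
  rows$year <- 2014 + (rows$period > 5)
  rows$age <- runif(nrow(rows), 3, 58)
  rows$sex <- factor("F", levels = c("F", "M"))
  rows$mother_offspring_count <- 2
  rows$mother_rank <- runif(nrow(rows))
  rows$n <- 40
  eta <- 0.6 - 0.03 * rows$age
  rows$k <- rbinom(nrow(rows), rows$n, plogis(eta))
  fit <- fit_model(rows, "binomial")
  age_hat <- fit$coefficients$estimate[fit$coefficients$term == "age"]
  age_se <- fit$coefficients$se[fit$coefficients$term == "age"]
  expect_lt(abs(age_hat - (-0.03)), 3 * age_se)
  expect_true("OR" %in% names(fit$coefficients))
  expect_true(all(fit$coefficients$OR > 0))
  # all-successes data is flagged degenerate, not fitted
  rows$k <- rows$n
  expect_warning(dg <- fit_model(rows, "binomial"), "constant")
  expect_false(dg$converged)
  expect_true(dg$degenerate)
})

test_that("fits are invariant to row order", {
  st <- sim_tables()
  spec <- model_specs()[1, ]
  tab <- suppressMessages(build_model_table(spec, st$resp,
                                            population = st$sim$population,
                                            ranks = st$rk))
  f1 <- fit_model(tab, "binomial")
  set.seed(9)
  f2 <- fit_model(tab[sample(nrow(tab)), ], "binomial")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("odds-percent conversions match their closed forms", {
  expect_equal(odds_percent(0), 0)
  expect_equal(odds_percent(log(2)), 100)
  # exact inverse of the percent -> OR conversion
  for (b in c(-1.3, -0.2, 0, 0.4, 2)) {
    expect_equal(log(odds_percent(b) / 100 + 1), b, tolerance = 1e-12)
  }
  # worked example from the published coefficients: sex effect on grooming
  # total time with mother at 30 months
  ref <- reference_fixed_effects()
  g <- ref[ref$model == "P1a" & ref$network == "grooming total", ]
  val <- sex_effect_percent(g$estimate[g$term == "sex"], age = 30,
                            beta_age_sex = g$estimate[g$term == "age:sex"])
  expect_equal(val, 62.5, tolerance = 0.1)
})

test_that("age-change percentages follow the OR-ratio formula", {
  expect_equal(age_change_percent(0), 0)
  # published worked examples: grooming-total and proximity age declines
  expect_equal(age_change_percent(-0.0232, "F"), -56.6, tolerance = 0.05)
  expect_equal(age_change_percent(-0.0112, "M", beta_age_sex = -0.0135),
               -58.9, tolerance = 0.05)
  # formula structure: slope scaled over 36 months
  expect_equal(age_change_percent(0.01, "F", t0 = 0, t1 = 100),
               (exp(1) - 1) * 100)
})

test_that("LMM range percentages scale as documented", {
  expect_equal(lmm_range_percent(-0.01, "F", observed_range = 2), -18)
  expect_equal(lmm_range_percent(0, "F", observed_range = 2), 0)
  expect_equal(lmm_range_percent(-0.01, "F", observed_range = 4), -9)
  expect_error(lmm_range_percent(-0.01, "F", observed_range = 0),
               "observed_range")
})
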