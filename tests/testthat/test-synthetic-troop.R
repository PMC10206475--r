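test_that("population matches configuration and is deterministic", {
  cfg <- sim_config(n_matrilines = 4, adults_per_matriline = 3,
                    immatures = default_immatures(8, 4), rng_seed = 9L)
  pop <- make_population(cfg)
  expect_equal(nrow(pop), 4 * 3 + 8)
  expect_equal(sum(!pop$is_adult), 8)
  start <- as.Date("2014-06-01")
  expect_true(all(is_immature_at(pop[!pop$is_adult, ], start)))
  # every immature's mother is an adult female of the same troop
  moms <- pop$mother_id[!pop$is_adult]
  expect_true(all(moms %in% pop$id[pop$is_adult & pop$sex == "F"]))
  expect_identical(pop, make_population(cfg))
  expect_false(identical(pop, make_population(sim_config(
    n_matrilines = 4, adults_per_matriline = 3,
    immatures = default_immatures(8, 4), rng_seed = 10L))))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_matrilines = 0), "counts")
  expect_error(sim_config(lambda0 = 1.5), "lambda0")
  expect_error(sim_config(decay = -0.1), "decay")
  # an immature assigned to a matriline with no adult female
  bad <- default_immatures(4, 2)
  bad$matriline[1] <- 7
  expect_error(sim_config(n_matrilines = 2, immatures = bad),
               "no\\s+adult female|no adult female")
})

test_that("newborn with full inheritance copies the mother's adult row", {
  imm <- data.frame(age_months = 0, sex = "F", matriline = 1)
  cfg <- sim_config(n_matrilines = 3, adults_per_matriline = 3,
                    immatures = imm, lambda0 = 1, rng_seed = 2L)
  pop <- make_population(cfg)
  prop <- latent_propensities(pop, cfg, as.Date("2014-06-01"))
  kid <- pop$id[!pop$is_adult]
  mom <- pop$mother_id[match(kid, pop$id)]
  other_adults <- setdiff(pop$id[pop$is_adult], mom)
  expect_equal(unname(prop$assoc[kid, other_adults]),
               unname(prop$assoc[mom, other_adults]))
})

test_that("without inheritance the immature row is unrelated to the mother's", {
  rs <- vapply(1:60, function(s) {
    imm <- data.frame(age_months = 24, sex = "F", matriline = 1)
    cfg <- sim_config(n_matrilines = 4, adults_per_matriline = 3,
                      immatures = imm, lambda0 = 0, rng_seed = s)
    pop <- make_population(cfg)
    prop <- latent_propensities(pop, cfg, as.Date("2014-06-01"))
    kid <- pop$id[!pop$is_adult]
    mom <- pop$mother_id[match(kid, pop$id)]
    adults <- setdiff(pop$id[pop$is_adult], mom)
    suppressWarnings(cor(prop$assoc[kid, adults], prop$assoc[mom, adults]))
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("male inheritance weight decays strictly faster", {
  imm <- data.frame(age_months = c(36, 36), sex = c("F", "M"),
                    matriline = c(1, 1))
  cfg <- sim_config(immatures = imm, male_extra_decay = 0.02, rng_seed = 3L)
  pop <- make_population(cfg)
  prop <- latent_propensities(pop, cfg, as.Date("2014-06-01"))
  w <- prop$w
  sexes <- pop$sex[match(names(w), pop$id)]
  expect_lt(w[sexes == "M"], w[sexes == "F"])
})

test_that("association propensities are symmetric, bounded, zero-diagonal", {
  cfg <- tiny_config(4L)
  pop <- make_population(cfg)
  prop <- latent_propensities(pop, cfg, as.Date("2014-09-01"))
  expect_equal(prop$assoc, t(prop$assoc))
  expect_true(all(prop$assoc >= 0 & prop$assoc <= 0.95))
  expect_true(all(diag(prop$assoc) == 0))
})

test_that("scan subgroups follow the propensity limits", {
  cfg <- tiny_config(5L)
  pop <- make_population(cfg)
  prop <- latent_propensities(pop, cfg, as.Date("2014-06-15"))
  ids <- pop$id
  # forced dyad: A always with B, everyone else never associates
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A <- ids[1]; B <- ids[2]
  P[A, B] <- P[B, A] <- 1
  forced <- list(assoc = P, groom = P)
  scans <- simulate_scans(pop, forced, cfg, seed = 11L)
  members <- strsplit(scans$subgroup_ids, ";")
  with_A <- vapply(members, function(m) A %in% m, logical(1))
  expect_true(all(vapply(members[with_A], function(m) B %in% m, logical(1))))
  gbi <- gbi_matrix(scans[with_A | vapply(members, function(m) B %in% m,
                                          logical(1)), ])
  expect_equal(unname(sri_matrix(gbi)[A, B]), 1)
  # zero propensity: every focal alone
  none <- list(assoc = P * 0, groom = P * 0)
  scans0 <- simulate_scans(pop, none, cfg, seed = 12L)
  expect_true(all(lengths(strsplit(scans0$subgroup_ids, ";")) == 1))
})

test_that("neighbour inclusion is binomial with the configured propensity", {
  cfg <- sim_config(n_matrilines = 2, adults_per_matriline = 2,
                    immatures = default_immatures(0, 2)[0, ],
                    scans_per_individual_per_month = 250, rng_seed = 6L)
  pop <- make_population(cfg)
  ids <- pop$id
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  P[ids[1], ids[2]] <- P[ids[2], ids[1]] <- 0.5
  scans <- simulate_scans(pop, list(assoc = P), cfg, seed = 21L)
  members <- strsplit(scans$subgroup_ids, ";")
  focal_A <- scans$focal_id == ids[1]
  n <- sum(focal_A)
  k <- sum(vapply(members[focal_A], function(m) ids[2] %in% m, logical(1)))
  ci <- qbinom(c(0.0005, 0.9995), n, 0.5)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("no focal is re-sampled within one simulated hour", {
  cfg <- tiny_config(8L)
  pop <- make_population(cfg)
  prop <- latent_propensities(pop, cfg, as.Date("2014-06-15"))
  scans <- simulate_scans(pop, prop, cfg, seed = 31L)
  by_focal <- split(scans$datetime, scans$focal_id)
  gaps <- unlist(lapply(by_focal, function(t) diff(sort(as.numeric(t)))))
  expect_true(all(gaps >= 3600))
})

test_that("grooming simulation respects propensity and deduplication", {
  cfg <- tiny_config(9L)
  pop <- make_population(cfg)
  ids <- pop$id
  P0 <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  expect_equal(nrow(simulate_grooming(pop, list(groom = P0), cfg, seed = 2L)),
               0)
  # two events of one dyad 10 minutes apart collapse to one record
  ev <- groom_fixture(c("A", "A"), c("B", "B"))
  ev$datetime <- as.POSIXct("2014-06-01 10:00:00", tz = "UTC") +
    c(0, 600)
  expect_equal(nrow(matrinet:::dedupe_grooming(ev)), 1)
  # 2:1 propensity ratio shows up in event counts (rate kept moderate so the
  # half-hour deduplication rule stays rare)
  cfg2 <- sim_config(n_matrilines = 3, adults_per_matriline = 1,
                     immatures = default_immatures(0, 3)[0, ],
                     grooming_events_per_individual_per_month = 150,
                     rng_seed = 10L)
  pop2 <- make_population(cfg2)
  ids2 <- pop2$id
  G <- matrix(0, 3, 3, dimnames = list(ids2, ids2))
  G[ids2[1], ids2[2]] <- 0.4
  G[ids2[1], ids2[3]] <- 0.2
  ev2 <- simulate_grooming(pop2, list(groom = G), cfg2, seed = 3L)
  kAB <- sum(ev2$giver_id == ids2[1] & ev2$recipient_id == ids2[2])
  kAC <- sum(ev2$giver_id == ids2[1] & ev2$recipient_id == ids2[3])
  expect_gt(kAB / kAC, 1.5)
  expect_lt(kAB / kAC, 2.6)
})

test_that("dominance wins follow the hierarchy steepness limits", {
  cfg <- sim_config(n_matrilines = 3, adults_per_matriline = 2,
                    immatures = default_immatures(0, 3)[0, ],
                    dominance_interactions_per_dyad = 40,
                    dominance_steepness = Inf, rng_seed = 12L)
  pop <- make_population(cfg)
  ranks <- list(J = sample(pop$id))
  dom <- simulate_dominance(pop, cfg, ranks, seed = 4L)
  # deterministic: winner always the higher-ranked of the dyad
  pos <- match(dom$giver_id, ranks$J)
  posl <- match(dom$recipient_id, ranks$J)
  expect_true(all(pos < posl))
  # steepness 0: win proportions near one half per dyad
  cfg0 <- sim_config(n_matrilines = 3, adults_per_matriline = 2,
                     immatures = default_immatures(0, 3)[0, ],
                     dominance_interactions_per_dyad = 300,
                     dominance_steepness = 0, rng_seed = 13L)
  dom0 <- simulate_dominance(pop, cfg0, ranks, seed = 5L)
  first <- ranks$J[1]; second <- ranks$J[2]
  dyad <- (dom0$giver_id == first & dom0$recipient_id == second) |
    (dom0$giver_id == second & dom0$recipient_id == first)
  pw <- mean(dom0$giver_id[dyad] == first)
  expect_gt(pw, 0.35)
  expect_lt(pw, 0.65)
})

test_that("identical configuration and seed give identical record streams", {
  cfg <- tiny_config(20L)
  s1 <- simulate_troop(cfg)
  s2 <- simulate_troop(cfg)
  expect_identical(s1$scans, s2$scans)
  expect_identical(s1$grooming, s2$grooming)
  expect_identical(s1$dominance, s2$dominance)
})

test_that("mother-offspring SRI similarity tracks the inheritance weight", {
  # strong inheritance: mean mother-offspring ego correlation positive in
  # nearly all replicate troops; no inheritance: centred near zero
  mean_r <- function(lambda0, seeds, ...) {
    vapply(seeds, function(s) {
      cfg <- sim_config(
        n_matrilines = 5, adults_per_matriline = 3,
        immatures = data.frame(age_months = c(6, 9, 12, 15, 18, 24),
                               sex = rep(c("F", "M"), 3),
                               matriline = c(1, 2, 3, 4, 5, 1)),
        seasons = data.frame(year = 2014, n_periods = 1),
        lambda0 = lambda0, decay = 0.01, rng_seed = s, ...)
      sim <- simulate_troop(cfg)
      nets <- build_networks(sim$scans, sim$grooming, sim$seasons,
                             min_obs = 1, min_sightings = 1)
      resp <- response_table(nets, sim$population, include = "similarity")
      mean(resp$value[resp$response == "pearson" & resp$kind == "proximity"],
           na.rm = TRUE)
    }, numeric(1))
  }
  strong <- mean_r(0.9, 1:25)
  expect_gte(mean(strong > 0), 0.9)
  # every other channel silenced so the inheritance weight is isolated:
  # age-structured homophily makes some individuals globally more social,
  # and a strong mother-association channel lets offspring meet the
  # mother's associates inside her subgroups (triadic closure through the
  # scan protocol) — both are genuine resemblance pathways distinct from
  # direct row inheritance
  none <- mean_r(0, 26:45, same_sex_slope = 0, age_homophily_strength = 0,
                 mother_assoc = c(intercept = -4, age = 0, sex = 0,
                                  age_sex = 0))
  expect_lt(abs(mean(none)), 0.12)
})
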