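#' Run the full synthetic troop generator
#'
#' Generates a population and, for every troop, season and 30-day period, the
#' proximity scan, grooming and (per season) dominance record streams implied
#' by the latent propensity model. Propensities are re-evaluated at each
#' period midpoint so individuals age through the study. Everything is a
#' deterministic function of the configuration: stage seeds are derived from
#' `config$rng_seed` and the (troop, season, period) coordinates.
#'
#' @param config A [sim_config()].
#' @return A list of class `troop_sim` with elements:
#'   * `population`: the individual roster;
#'   * `scans`, `grooming`, `dominance`: record data frames in the standard
#'     CSV schemas;
#'   * `seasons`: season table (`troop`, `year`, `start_date`, `end_date`);
#'   * `latent_ranks`: per-troop adult female ids in latent rank order;
#'   * `truth`: per (troop, season, period) list with the propensity model
#'     (`assoc` matrix, `w`, `p_mother`, midpoint date) — the ground truth
#'     used by the recovery oracles;
#'   * `config`.
#' @seealso [induced_mp1a_coefficients()], [induced_mp2c3_coefficients()]
#' @export
simulate_troop <- function(config) {
  validate_sim_config(config)
  population <- make_population(config)

  set.seed(config$rng_seed + 17L)
  latent_ranks <- lapply(split(population, population$troop), function(tp) {
    sample(tp$id[tp$is_adult])
  })

  starts <- season_starts(config)
  scans <- list(); grooming <- list(); dominance <- list()
  truth <- list()
  seasons <- data.frame()
  for (tr in unique(population$troop)) {
    for (s in seq_len(nrow(config$seasons))) {
      n_p <- config$seasons$n_periods[s]
      seasons <- rbind(seasons, data.frame(
        troop = tr, year = config$seasons$year[s],
        start_date = starts[s], end_date = starts[s] + n_p * 30 - 1))
    }
  }

  pop_by_troop <- split(population, population$troop)
  troop_i <- 0
  for (tr in names(pop_by_troop)) {
    troop_i <- troop_i + 1
    pop_t <- pop_by_troop[[tr]]
    for (s in seq_len(nrow(config$seasons))) {
      for (p in seq_len(config$seasons$n_periods[s])) {
        period_start <- starts[s] + (p - 1) * 30
        midpoint <- period_start + 15
        prop <- latent_propensities(pop_t, config, midpoint)
        key <- sprintf("%s|%d|%d", tr, config$seasons$year[s], p)
        truth[[key]] <- list(troop = tr, year = config$seasons$year[s],
                             period = p, midpoint = midpoint,
                             assoc = prop$assoc, w = prop$w,
                             p_mother = prop$p_mother)
        base_seed <- stage_seed(config, troop_i, s, p)
        scans[[key]] <- simulate_scans(pop_t, prop, config, period_start,
                                       seed = base_seed + 1L)
        grooming[[key]] <- simulate_grooming(pop_t, prop, config,
                                            period_start,
                                            seed = base_seed + 2L)
      }
      dominance[[paste(tr, s)]] <- simulate_dominance(
        pop_t, config, latent_ranks[tr], starts[s],
        n_days = config$seasons$n_periods[s] * 30,
        seed = stage_seed(config, troop_i, s, 0) + 3L)
    }
  }

  structure(list(
    population = population,
    scans = collapse_records(scans),
    grooming = collapse_records(grooming),
    dominance = collapse_records(dominance),
    seasons = seasons,
    latent_ranks = latent_ranks,
    truth = truth,
    config = config
  ), class = "troop_sim")
}

stage_seed <- function(config, troop_i, season_i, period) {
  (config$rng_seed * 97L + troop_i * 1009L + season_i * 10007L +
     period * 100003L) %% 2000000000L
}

collapse_records <- function(lst) {
  res <- do.call(rbind, lst)
  res <- res[order(res$troop, res$datetime), ]
  rownames(res) <- NULL
  res
}

#' @export
print.troop_sim <- function(x, ...) {
  cat("<troop_sim>\n")
  cat(sprintf("  %d individuals (%d immature at study start), %d troop(s)\n",
              nrow(x$population), sum(!x$population$is_adult),
              length(unique(x$population$troop))))
  cat(sprintf("  %d scan records, %d grooming events, %d dominance interactions\n",
              nrow(x$scans), nrow(x$grooming), nrow(x$dominance)))
  invisible(x)
}

#' Write a synthetic data set to CSV
#'
#' Persists the record streams in the standard input schemas (`scans.csv`,
#' `grooming.csv`, `dominance.csv`, `individuals.csv`, `seasons.csv`), the
#' per-period ground truth (`ground_truth.csv`: id, age, sex, inheritance
#' weight, per-scan mother-association probability, latent rank) and the
#' configuration as YAML (`config.yaml`, if the yaml package is available).
#'
#' @param sim A `troop_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(sim$scans, "scans.csv")
  wr(sim$grooming, "grooming.csv")
  wr(sim$dominance, "dominance.csv")
  ind <- sim$population[, c("id", "sex", "birth_date", "mother_id", "troop")]
  wr(ind, "individuals.csv")
  wr(sim$seasons, "seasons.csv")

  gt <- do.call(rbind, lapply(sim$truth, function(tt) {
    ids <- names(tt$w)
    pop <- sim$population
    rank_of <- function(id) {
      lr <- sim$latent_ranks[[tt$troop]]
      match(pop$mother_id[match(id, pop$id)], lr)
    }
    data.frame(troop = tt$troop, year = tt$year, period = tt$period,
               id = ids,
               age_months = age_months_at(
                 pop$birth_date[match(ids, pop$id)], tt$midpoint),
               sex = pop$sex[match(ids, pop$id)],
               w = unname(tt$w),
               p_mother = unname(tt$p_mother),
               mother_latent_rank = vapply(ids, rank_of, numeric(1)))
  }))
  wr(gt, "ground_truth.csv")
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- sim$config
    cfg$immatures <- as.list(cfg$immatures)
    cfg$seasons <- as.list(cfg$seasons)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
    files <- c(files, file.path(dir, "config.yaml"))
  }
  invisible(files)
}

#' Induced fixed-effect values for the time-with-mother model
#'
#' The mother-association channel of the generator is logit-linear per scan,
#' but the scan protocol mixes three record types for an immature `i`: its own
#' focal scans, its mother's focal scans (in which both are present whenever
#' `i` joins) and third-party focal scans. The marginal proportion of records
#' containing the mother is therefore not the raw channel curve. This oracle
#' computes the exact record-level expectations from the realized propensity
#' matrices,
#' `E[n_i] = m + sum_f m P[f,i]`,
#' `E[k_i] = 2 m p_mother(i) + sum_{f != i, mother} m P[f,i] P[f,mother]`,
#' and fits a weighted binomial GLM of the expected proportions on
#' `age * sex`, giving the generating values that the downstream GLMM is
#' expected to recover.
#'
#' @param sim A `troop_sim` object.
#' @return List with `coefficients` (named: `(Intercept)`, `age`, `sexM`,
#'   `age:sexM`) and the underlying expectation table.
#' @export
induced_mp1a_coefficients <- function(sim) {
  m <- sim$config$scans_per_individual_per_month
  pop <- sim$population
  rows <- list()
  for (tt in sim$truth) {
    P <- tt$assoc
    ids <- rownames(P)
    for (id in names(tt$w)) {
      mom <- pop$mother_id[match(id, pop$id)]
      if (!(mom %in% ids)) next
      others <- setdiff(ids, id)
      En <- m + sum(m * P[others, id])
      third <- setdiff(ids, c(id, mom))
      Ek <- 2 * m * tt$p_mother[[id]] + sum(m * P[third, id] * P[third, mom])
      rows[[length(rows) + 1]] <- data.frame(
        troop = tt$troop, year = tt$year, period = tt$period, id = id,
        age = age_months_at(pop$birth_date[match(id, pop$id)], tt$midpoint),
        sex = pop$sex[match(id, pop$id)], Ek = Ek, En = En)
    }
  }
  tab <- do.call(rbind, rows)
  tab$sex <- factor(tab$sex, levels = c("F", "M"))
  fit <- suppressWarnings(stats::glm(I(Ek / En) ~ age * sex,
                                     family = stats::quasibinomial(),
                                     weights = En, data = tab))
  cf <- stats::coef(fit)
  names(cf) <- sub("sexM:age|age:sexM", "age:sexM", names(cf))
  list(coefficients = cf, table = tab)
}

#' Induced fixed-effect values for the same-sex partner-proportion model
#'
#' For each immature and same-sex troop mate, the probability that the dyad
#' shares at least one subgroup during a period is available in closed form
#' from the propensity matrix and the per-individual scan count `m`:
#' `P(edge ij) = 1 - (1 - P[i,j])^(2m) * prod_f (1 - P[f,i] P[f,j])^m`.
#' Summing over the same-sex category gives the expected numerator of the
#' partner-proportion response; a weighted binomial GLM of the expected
#' proportions on `age * sex` yields the induced generating values for the
#' same-sex partner model.
#'
#' @inheritParams induced_mp1a_coefficients
#' @return List with `coefficients` and the underlying expectation table.
#' @export
induced_mp2c3_coefficients <- function(sim) {
  m <- sim$config$scans_per_individual_per_month
  pop <- sim$population
  rows <- list()
  for (tt in sim$truth) {
    P <- tt$assoc
    ids <- rownames(P)
    sex <- pop$sex[match(ids, pop$id)]
    for (id in names(tt$w)) {
      i <- match(id, ids)
      cat_ids <- ids[sex == sex[i] & ids != id]
      if (length(cat_ids) == 0) next
      p_edge <- vapply(cat_ids, function(j) {
        others <- setdiff(ids, c(id, j))
        1 - (1 - P[id, j])^(2 * m) *
          prod((1 - P[others, id] * P[others, j])^m)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        troop = tt$troop, year = tt$year, period = tt$period, id = id,
        age = age_months_at(pop$birth_date[match(id, pop$id)], tt$midpoint),
        sex = sex[i], Ek = sum(p_edge), n = length(cat_ids))
    }
  }
  tab <- do.call(rbind, rows)
  tab$sex <- factor(tab$sex, levels = c("F", "M"))
  fit <- suppressWarnings(stats::glm(I(Ek / n) ~ age * sex,
                                     family = stats::quasibinomial(),
                                     weights = n, data = tab))
  cf <- stats::coef(fit)
  names(cf) <- sub("sexM:age|age:sexM", "age:sexM", names(cf))
  list(coefficients = cf, table = tab)
}
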