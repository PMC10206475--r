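#' Simulation configuration for a synthetic baboon troop
#'
#' Bundles every parameter of the synthetic troop generator: troop
#' composition, observation effort, and the latent social-propensity model
#' (maternal inheritance, age decay, sex/age homophily). Defaults emulate the
#' field protocol the package is built around: scan sampling of 10 m proximity
#' subgroups at 4--20 scans per individual per month, ad libitum grooming with
#' half-hour dyad deduplication, troops of a few dozen individuals followed
#' over repeated annual field seasons, and immatures aged 0--60 months born to
#' ranked adult females.
#'
#' @param n_matrilines Number of matrilines per troop.
#' @param adults_per_matriline Adult females per matriline.
#' @param immatures Data frame with columns `age_months`, `sex` ("F"/"M") and
#'   `matriline` (integer), one row per immature, giving ages at the start of
#'   the first season. Default: [default_immatures()].
#' @param n_troops Number of troops to simulate.
#' @param seasons Data frame with columns `year` and `n_periods`: each field
#'   season contributes `n_periods` consecutive 30-day observation windows
#'   starting on 1 June of `year`.
#' @param scans_per_individual_per_month Focal proximity scans per individual
#'   per 30-day period (field range 4--20).
#' @param grooming_events_per_individual_per_month Expected grooming events
#'   involving each individual per 30-day period (field range 5--52).
#' @param lambda0 Inheritance weight at age 0, in \[0, 1\]. An immature's
#'   association propensity row is a mixture
#'   `w(i) * mother's row + (1 - w(i)) * homophily kernel`, with
#'   `w(i) = lambda0 * exp(-(decay + male_extra_decay * male) * age_i)`.
#' @param decay Per-month exponential decay of the inheritance weight.
#' @param male_extra_decay Additional per-month decay for males.
#' @param same_sex_slope Per-month increase in same-sex association
#'   propensity with the focal immature's age (homophily kernel term).
#' @param age_bandwidth Bandwidth (months) of the Gaussian age-assortment
#'   kernel in the homophily term.
#' @param age_homophily_strength Peak height of the age-assortment kernel
#'   (per-scan propensity units).
#' @param baseline Baseline per-scan association propensity between any two
#'   troop members.
#' @param within_matriline_extra Additional per-scan propensity between adult
#'   females of the same matriline.
#' @param mother_assoc Named numeric vector `c(intercept, age, sex, age_sex)`:
#'   logit-scale coefficients of the per-scan probability that an immature's
#'   subgroup contains its mother (`age` in months; `sex` = male indicator).
#'   This channel is the known ground truth recovered by the time-with-mother
#'   model.
#' @param dominance_interactions_per_dyad Expected dominance interactions per
#'   adult-female dyad per season.
#' @param dominance_steepness Steepness of the latent hierarchy: the
#'   higher-ranked female of a dyad wins with probability
#'   `plogis(steepness * relative-rank gap)`; `Inf` gives a deterministic
#'   hierarchy, 0 coin flips.
#' @param rng_seed Integer seed; every stochastic stage of the generator is a
#'   deterministic function of the configuration and this seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_matrilines = 10,
                       adults_per_matriline = 4,
                       immatures = default_immatures(20, n_matrilines),
                       n_troops = 1,
                       seasons = data.frame(year = c(2014, 2015),
                                            n_periods = c(3, 2)),
                       scans_per_individual_per_month = 12,
                       grooming_events_per_individual_per_month = 15,
                       lambda0 = 0.9,
                       decay = 0.04,
                       male_extra_decay = 0.01,
                       same_sex_slope = 0.0015,
                       age_bandwidth = 12,
                       age_homophily_strength = 0.06,
                       baseline = 0.01,
                       within_matriline_extra = 0.08,
                       mother_assoc = c(intercept = 0.8, age = -0.025,
                                        sex = 0.4, age_sex = -0.012),
                       dominance_interactions_per_dyad = 4,
                       dominance_steepness = 6,
                       rng_seed = 1L) {
  cfg <- list(
    n_matrilines = n_matrilines,
    adults_per_matriline = adults_per_matriline,
    immatures = immatures,
    n_troops = n_troops,
    seasons = seasons,
    scans_per_individual_per_month = scans_per_individual_per_month,
    grooming_events_per_individual_per_month =
      grooming_events_per_individual_per_month,
    lambda0 = lambda0,
    decay = decay,
    male_extra_decay = male_extra_decay,
    same_sex_slope = same_sex_slope,
    age_bandwidth = age_bandwidth,
    age_homophily_strength = age_homophily_strength,
    baseline = baseline,
    within_matriline_extra = within_matriline_extra,
    mother_assoc = mother_assoc,
    dominance_interactions_per_dyad = dominance_interactions_per_dyad,
    dominance_steepness = dominance_steepness,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default immature roster
#'
#' Ages are spread evenly over 3--57 months, sexes alternate, and matrilines
#' are assigned round-robin so every immature has at least one adult female in
#' its matriline.
#'
#' @param n Number of immatures.
#' @param n_matrilines Number of matrilines available.
#' @return Data frame with columns `age_months`, `sex`, `matriline`.
#' @export
default_immatures <- function(n = 20, n_matrilines = 10) {
  data.frame(
    age_months = round(seq(3, 57, length.out = n)),
    sex = rep(c("F", "M"), length.out = n),
    matriline = rep(seq_len(n_matrilines), length.out = n)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_matrilines, cfg$adults_per_matriline, cfg$n_troops,
              cfg$scans_per_individual_per_month,
              cfg$grooming_events_per_individual_per_month)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("sim_config: all counts must be positive", call. = FALSE)
  }
  if (cfg$lambda0 < 0 || cfg$lambda0 > 1) {
    stop("sim_config: lambda0 must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$decay < 0 || cfg$male_extra_decay < 0) {
    stop("sim_config: decay rates must be non-negative", call. = FALSE)
  }
  im <- cfg$immatures
  if (!is.data.frame(im) ||
      !all(c("age_months", "sex", "matriline") %in% names(im))) {
    stop("sim_config: immatures must have age_months, sex, matriline",
         call. = FALSE)
  }
  if (nrow(im) > 0) {
    if (!all(im$sex %in% c("F", "M"))) {
      stop("sim_config: immature sex must be 'F' or 'M'", call. = FALSE)
    }
    if (any(im$age_months < 0 | im$age_months > 60)) {
      stop("sim_config: immature ages must lie in [0, 60] months",
           call. = FALSE)
    }
    if (any(!(im$matriline %in% seq_len(cfg$n_matrilines)))) {
      stop("sim_config: an immature is assigned to a matriline with no ",
           "adult female", call. = FALSE)
    }
  }
  if (!is.data.frame(cfg$seasons) ||
      !all(c("year", "n_periods") %in% names(cfg$seasons)) ||
      any(cfg$seasons$n_periods <= 0)) {
    stop("sim_config: seasons needs positive n_periods per year",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  troops: %d, matrilines: %d x %d adult females, immatures: %d\n",
              x$n_troops, x$n_matrilines, x$adults_per_matriline,
              nrow(x$immatures)))
  cat(sprintf("  seasons: %s\n",
              paste(sprintf("%d (%d periods)", x$seasons$year,
                            x$seasons$n_periods), collapse = ", ")))
  cat(sprintf("  scans/ind/month: %d, grooming events/ind/month: %d\n",
              x$scans_per_individual_per_month,
              x$grooming_events_per_individual_per_month))
  cat(sprintf("  inheritance: lambda0 = %.2f, decay = %.3f (+%.3f male)\n",
              x$lambda0, x$decay, x$male_extra_decay))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}

# Season start dates: first observation day of each field season (1 June).
season_starts <- function(cfg) {
  as.Date(sprintf("%d-06-01", cfg$seasons$year))
}

# Age in months at a date, using 30-day months to match the 30-day
# aggregation windows used throughout.
age_months_at <- function(birth_date, date) {
  as.numeric(as.Date(date) - as.Date(birth_date)) / 30
}
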