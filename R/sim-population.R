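#' Generate a synthetic troop population
#'
#' Creates adult females organised in matrilines plus the configured immature
#' roster, for each troop. Every immature is assigned a mother drawn from the
#' adult females of its matriline in its troop, so maternity always resolves
#' within the troop. Adult female ages are drawn uniformly between 72 and 240
#' months at the start of the first season. The result is deterministic given
#' the configuration (including `rng_seed`).
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per individual: `id`, `sex`, `birth_date`,
#'   `mother_id`, `troop`, `matriline`, `is_adult`. Immaturity at any date is
#'   age <= 60 months at that date (see [is_immature_at()]).
#' @export
make_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  start <- season_starts(config)[1]
  troop_names <- c("J", "L", "M", paste0("T", seq_len(max(0, config$n_troops - 3)) + 3))
  troop_names <- troop_names[seq_len(config$n_troops)]

  pop <- list()
  for (tr in troop_names) {
    n_ad <- config$n_matrilines * config$adults_per_matriline
    ad_ages <- stats::runif(n_ad, 72, 240)
    ad_matriline <- rep(seq_len(config$n_matrilines),
                        each = config$adults_per_matriline)
    adults <- data.frame(
      id = sprintf("%s.M%02d.A%d", tr, ad_matriline,
                   sequence(rep(config$adults_per_matriline,
                                config$n_matrilines))),
      sex = "F",
      birth_date = start - round(ad_ages * 30),
      mother_id = NA_character_,
      troop = tr,
      matriline = ad_matriline,
      is_adult = TRUE
    )
    im <- config$immatures
    if (nrow(im) > 0) {
      mothers <- vapply(im$matriline, function(m) {
        cand <- adults$id[adults$matriline == m]
        cand[sample.int(length(cand), 1)]
      }, character(1))
      imms <- data.frame(
        id = sprintf("%s.M%02d.I%d", tr, im$matriline,
                     stats::ave(im$matriline, im$matriline,
                                FUN = seq_along)),
        sex = im$sex,
        birth_date = start - round(im$age_months * 30),
        mother_id = mothers,
        troop = tr,
        matriline = im$matriline,
        is_adult = FALSE
      )
    } else {
      imms <- adults[0, ]
    }
    pop[[tr]] <- rbind(adults, imms)
  }
  pop <- do.call(rbind, pop)
  rownames(pop) <- NULL
  pop
}

#' Is an individual immature at a given date?
#'
#' Immatures are individuals aged 60 months or less at the observation date.
#'
#' @param population Data frame from [make_population()] (or any frame with
#'   `birth_date`).
#' @param date Date of evaluation.
#' @return Logical vector.
#' @export
is_immature_at <- function(population, date) {
  age_months_at(population$birth_date, date) <= 60
}
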