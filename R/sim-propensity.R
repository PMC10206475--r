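#' Latent association and grooming propensities at a date
#'
#' Builds the per-scan pairwise association propensity matrix for every troop
#' at a given date. The generative model has three channels:
#'
#' * adult females associate at a `baseline` rate, elevated by
#'   `within_matriline_extra` within a matriline;
#' * the probability that an immature's subgroup contains its mother is
#'   logit-linear in age, sex and their interaction (`mother_assoc`), the
#'   known ground truth of the time-with-mother analysis;
#' * an immature's remaining propensity row is the inheritance mixture
#'   `w(i) * mother's row + (1 - w(i)) * homophily(i, .)`, with
#'   `w(i) = lambda0 * exp(-(decay + male_extra_decay * male) * age_i)` and a
#'   homophily kernel combining a same-sex term growing with the immature's
#'   own age and a Gaussian age-assortment kernel.
#'
#' Immature-immature cells average the two directed mixtures so the matrix
#' stays symmetric. Grooming propensity reuses the association matrix (zero
#' diagonal, no giver bias), so grooming events concentrate on the same dyads
#' as spatial association.
#'
#' @param population Data frame from [make_population()].
#' @param config A [sim_config()].
#' @param at_date Date at which ages (and hence propensities) are evaluated.
#' @return List with elements `assoc` (symmetric matrix, zero diagonal, values
#'   in \[0, 0.95\]), `groom` (same matrix, interpreted as directed rates),
#'   `w` (named inheritance weights for immatures) and `p_mother` (named
#'   per-scan mother-association probabilities for immatures).
#' @export
latent_propensities <- function(population, config, at_date) {
  if (nrow(population) == 0) stop("population is empty", call. = FALSE)
  ids <- population$id
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  age <- age_months_at(population$birth_date, at_date)
  male <- as.numeric(population$sex == "M")
  imm <- !population$is_adult
  w_all <- rep(NA_real_, n)
  p_mom_all <- rep(NA_real_, n)

  for (tr in unique(population$troop)) {
    ti <- which(population$troop == tr)
    ad <- ti[population$is_adult[ti]]
    im <- ti[!population$is_adult[ti]]

    # adult-adult block: matriline-structured baseline
    if (length(ad) > 1) {
      same_mat <- outer(population$matriline[ad], population$matriline[ad],
                        "==")
      B <- config$baseline + config$within_matriline_extra * same_mat
      diag(B) <- 0
      P[ad, ad] <- B
    }

    if (length(im) == 0) next
    mom_idx <- match(population$mother_id[im], ids)
    w <- config$lambda0 *
      exp(-(config$decay + config$male_extra_decay * male[im]) * age[im])
    ma <- config$mother_assoc
    p_mom <- stats::plogis(ma[["intercept"]] + ma[["age"]] * age[im] +
                             ma[["sex"]] * male[im] +
                             ma[["age_sex"]] * age[im] * male[im])
    w_all[im] <- w
    p_mom_all[im] <- p_mom

    homophily <- function(i, j) {
      config$baseline +
        config$same_sex_slope * age[i] * (population$sex[i] == population$sex[j]) +
        config$age_homophily_strength *
          exp(-(age[i] - age[j])^2 / (2 * config$age_bandwidth^2))
    }

    # immature-adult cells (mother cell is the logit-linear channel)
    for (k in seq_along(im)) {
      i <- im[k]
      for (j in ad) {
        if (j == mom_idx[k]) {
          P[i, j] <- P[j, i] <- p_mom[k]
        } else {
          v <- w[k] * P[mom_idx[k], j] + (1 - w[k]) * homophily(i, j)
          P[i, j] <- P[j, i] <- v
        }
      }
    }

    # immature-immature cells: symmetric average of the two directed
    # mixtures; "mother's row" entries are the already-filled
    # mother-to-immature cells
    if (length(im) > 1) {
      for (a in seq_along(im)) {
        for (b in seq_along(im)) {
          if (b <= a) next
          i <- im[a]; j <- im[b]
          via_i <- w[a] * P[mom_idx[a], j] + (1 - w[a]) * homophily(i, j)
          via_j <- w[b] * P[mom_idx[b], i] + (1 - w[b]) * homophily(j, i)
          P[i, j] <- P[j, i] <- (via_i + via_j) / 2
        }
      }
    }
  }

  P <- pmin(pmax(P, 0), 0.95)
  diag(P) <- 0
  list(assoc = P, groom = P,
       w = stats::setNames(w_all[imm], ids[imm]),
       p_mother = stats::setNames(p_mom_all[imm], ids[imm]))
}
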