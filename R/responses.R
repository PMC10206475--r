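#' Proportion of observations spent with the mother
#'
#' For proximity, `k` is the number of scan records whose subgroup contains
#' both the immature and its mother and `n` the number of records containing
#' the immature; for grooming, `k` counts events between immature and mother
#' in either direction and `n` events involving the immature.
#'
#' @param records Records of one troop-period (scan or grooming schema).
#' @param immature_id,mother_id Dyad ids.
#' @param kind `"scan"` or `"grooming"`.
#' @return List with `k`, `n`, `value` (`k/n`, `NA` when `n = 0`).
#' @export
time_with_mother <- function(records, immature_id, mother_id,
                             kind = c("scan", "grooming")) {
  kind <- match.arg(kind)
  if (kind == "scan") {
    members <- subgroup_members(records)
    has_i <- vapply(members, function(m) immature_id %in% m, logical(1))
    has_m <- vapply(members, function(m) mother_id %in% m, logical(1))
    k <- sum(has_i & has_m)
    n <- sum(has_i)
  } else {
    inv_i <- records$giver_id == immature_id | records$recipient_id == immature_id
    inv_m <- records$giver_id == mother_id | records$recipient_id == mother_id
    k <- sum(inv_i & inv_m)
    n <- sum(inv_i)
  }
  list(k = k, n = n, value = if (n > 0) k / n else NA_real_)
}

#' Ego-network similarity between two aligned vectors
#'
#' Pearson correlation (bounded in \[-1, 1\]) and cosine similarity (in
#' \[0, 1\] for non-negative weights) of two identically aligned ego
#' vectors. A zero-variance vector leaves the Pearson coefficient undefined
#' (`NA`); the cosine is still computed unless a vector is all-zero.
#'
#' @param v1,v2 Numeric vectors of equal length (>= 3) with identical column
#'   alignment.
#' @return List with `pearson` and `cosine`.
#' @export
ego_similarity <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  if (length(v1) < 3) {
    stop("ego_similarity: vectors must have length >= 3", call. = FALSE)
  }
  pearson <- if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    NA_real_
  } else {
    stats::cor(v1, v2)
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  cosine <- if (n1 == 0 || n2 == 0) NA_real_ else sum(v1 * v2) / (n1 * n2)
  list(pearson = pearson, cosine = cosine)
}

# Pearson r between an immature's ego vector and another individual's row,
# both with the immature's dyad columns dropped so alignment is identical.
dyad_r <- function(mat, immature, other, drop_ids) {
  v_i <- ego_vector(mat, immature, drop_ids)
  v_o <- ego_vector(mat, other, drop_ids)
  if (length(v_i) < 3) return(NA_real_)
  s_i <- stats::sd(v_i); s_o <- stats::sd(v_o)
  if (is.na(s_i) || is.na(s_o) || s_i == 0 || s_o == 0) return(NA_real_)
  stats::cor(v_i, v_o)
}

#' Binary comparison of mother similarity against a random individual
#'
#' Draws one comparator uniformly among all individuals in the period's
#' network other than the immature and its mother, and scores 1 iff the
#' mother-immature ego-network correlation strictly exceeds the
#' comparator-immature correlation (ties score 0).
#'
#' @param mat Weighted matrix of the period (SRI or grooming proportions).
#' @param immature,mother Dyad ids.
#' @param seed Seed for the comparator draw (recorded for reproducibility).
#' @return List with `score` (0/1 or `NA`), `comparator`, `r_mother`,
#'   `r_comparator`.
#' @export
compare_vs_random <- function(mat, immature, mother, seed = 1L) {
  eligible <- setdiff(rownames(mat), c(immature, mother))
  if (length(eligible) == 0) {
    return(list(score = NA_real_, comparator = NA_character_,
                r_mother = NA_real_, r_comparator = NA_real_))
  }
  set.seed(seed)
  comparator <- eligible[sample.int(length(eligible), 1)]
  drop_ids <- c(immature, mother, comparator)
  r_m <- dyad_r(mat, immature, mother, drop_ids)
  r_c <- dyad_r(mat, immature, comparator, drop_ids)
  score <- if (is.na(r_m) || is.na(r_c)) NA_real_ else as.numeric(r_m > r_c)
  list(score = score, comparator = comparator, r_mother = r_m,
       r_comparator = r_c)
}

#' Binary comparison of mother similarity against the non-mother mean
#'
#' Scores 1 iff the mother-immature ego-network correlation strictly exceeds
#' the arithmetic mean of the correlations between the immature and every
#' other (non-mother, non-self) individual in the period's network.
#'
#' @inheritParams compare_vs_random
#' @return List with `score`, `r_mother`, `r_mean`.
#' @export
compare_vs_mean <- function(mat, immature, mother) {
  eligible <- setdiff(rownames(mat), c(immature, mother))
  if (length(eligible) == 0) {
    return(list(score = NA_real_, r_mother = NA_real_, r_mean = NA_real_))
  }
  drop_ids <- c(immature, mother)
  r_m <- dyad_r(mat, immature, mother, drop_ids)
  r_all <- vapply(eligible, function(o) {
    dyad_r(mat, immature, o, c(immature, mother, o))
  }, numeric(1))
  r_mean <- mean(r_all, na.rm = TRUE)
  score <- if (is.na(r_m) || is.nan(r_mean)) NA_real_ else as.numeric(r_m > r_mean)
  list(score = score, r_mother = r_m, r_mean = r_mean)
}

#' Partner-category proportion
#'
#' Counts the distinct partners of a focal immature that belong to a category
#' — `immature` (age <= 60 months), `peer` (age within +/- 6 months of the
#' focal, inclusive) or `same_sex` — over the number of category members
#' available in the troop-period (the focal excluded). A partner is an
#' individual with a nonzero edge to the focal in the requested direction.
#'
#' @param mat Weight/count matrix of the period (row = out-edges of an id).
#' @param focal Focal immature id.
#' @param category `"immature"`, `"peer"` or `"same_sex"`.
#' @param roster Data frame with `id`, `age_months` (at period midpoint) and
#'   `sex` for every id in the matrix.
#' @param direction `"any"` (default; nonzero edge in either direction, the
#'   rule for symmetric SRI and grooming total), `"out"` (given) or `"in"`
#'   (received).
#' @return List with `k`, `n`, `value` (`NA` when the category is empty).
#' @export
partner_category_proportion <- function(mat, focal,
                                        category = c("immature", "peer",
                                                     "same_sex"),
                                        roster,
                                        direction = c("any", "out", "in")) {
  category <- match.arg(category)
  direction <- match.arg(direction)
  ids <- setdiff(rownames(mat), focal)
  age <- roster$age_months[match(ids, roster$id)]
  sex <- roster$sex[match(ids, roster$id)]
  f_age <- roster$age_months[match(focal, roster$id)]
  f_sex <- roster$sex[match(focal, roster$id)]
  in_cat <- switch(category,
                   immature = age <= 60,
                   peer = abs(age - f_age) <= 6,
                   same_sex = sex == f_sex)
  cat_ids <- ids[which(in_cat)]
  n <- length(cat_ids)
  if (n == 0) return(list(k = 0L, n = 0L, value = NA_real_))
  linked <- switch(direction,
                   any = mat[focal, cat_ids] > 0 | mat[cat_ids, focal] > 0,
                   out = mat[focal, cat_ids] > 0,
                   "in" = mat[cat_ids, focal] > 0)
  list(k = sum(linked), n = n, value = sum(linked) / n)
}

# grooming count matrix in the requested mode, optionally row-normalized
groom_mode_matrix <- function(counts, mode, proportion = FALSE) {
  out <- switch(mode,
                given = counts,
                received = t(counts),
                total = counts + t(counts))
  if (proportion) {
    rs <- rowSums(out)
    out <- out / ifelse(rs == 0, 1, rs)
  }
  out
}

#' Compute every immature response across troop-periods
#'
#' Builds the full response roster for each immature present in each
#' troop-period network: time with mother (proximity and grooming total),
#' mother-offspring ego-network similarity (Pearson and cosine; SRI for
#' proximity, row-proportion matrices for grooming given/received/total),
#' the two binary mother-vs-others comparisons, and the three
#' partner-category proportions. Immaturity and ages are evaluated at the
#' period midpoint; an immature whose mother is absent from a period's
#' network is skipped for the mother-based responses.
#'
#' @param networks A `troop_networks` object.
#' @param population Individual table (`id`, `sex`, `birth_date`,
#'   `mother_id`, `troop`).
#' @param seed Base seed for the random-comparator draws.
#' @param include Response groups to compute: any of `"mp1a"`,
#'   `"similarity"` (Pearson + cosine), `"comparison"` (both comparison
#'   scores; `"vs_random"` / `"vs_mean"` select one), `"partners"`
#'   (category proportions). Restricting the set makes permutation refits
#'   cheap.
#' @return Long data frame: `troop`, `year`, `period`, `kind`, `mode`,
#'   `immature_id`, `response`, `k`, `n`, `value`, `comparator_id`.
#' @export
response_table <- function(networks, population, seed = 1L,
                           include = c("mp1a", "similarity", "comparison",
                                       "partners")) {
  include <- match.arg(include,
                       choices = c("mp1a", "similarity", "comparison",
                                   "vs_random", "vs_mean", "partners"),
                       several.ok = TRUE)
  if ("comparison" %in% include) {
    include <- union(include, c("vs_random", "vs_mean"))
  }
  rows <- list()
  add <- function(net, kind, mode, id, response, value, k = NA_real_,
                  n = NA_real_, comparator = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      troop = net$troop, year = net$year, period = net$period,
      period_start = net$period_start, kind = kind,
      mode = mode, immature_id = id, response = response,
      k = k, n = n, value = value, comparator_id = comparator)
  }
  draw_seed <- function(net, id) {
    (seed + 131L * net$period + 17L * as.integer(net$year %% 100) +
       sum(utf8ToInt(id))) %% 2000000000L
  }

  process <- function(net, kind) {
    midpoint <- net$period_start + 15
    ids <- net$ids
    roster <- data.frame(
      id = ids,
      age_months = age_months_at(
        population$birth_date[match(ids, population$id)], midpoint),
      sex = population$sex[match(ids, population$id)])
    imms <- ids[roster$age_months <= 60 &
                  !is.na(population$mother_id[match(ids, population$id)])]
    sim_mats <- if (kind == "proximity") {
      list(sri = net$sri)
    } else {
      list(given = groom_mode_matrix(net$counts, "given", TRUE),
           received = groom_mode_matrix(net$counts, "received", TRUE),
           total = groom_mode_matrix(net$counts, "total", TRUE))
    }
    part_mats <- if (kind == "proximity") {
      list(sri = list(mat = net$sri, direction = "any"))
    } else {
      list(given = list(mat = net$counts, direction = "out"),
           received = list(mat = net$counts, direction = "in"),
           total = list(mat = net$counts + t(net$counts), direction = "any"))
    }

    for (id in imms) {
      mom <- population$mother_id[match(id, population$id)]
      mom_present <- mom %in% ids

      # time with mother: proximity, and grooming total only
      if (mom_present && "mp1a" %in% include) {
        if (kind == "proximity") {
          tw <- time_with_mother(net$records, id, mom, "scan")
          add(net, kind, "sri", id, "mp1a", tw$value, tw$k, tw$n)
        } else {
          tw <- time_with_mother(net$records, id, mom, "grooming")
          add(net, kind, "total", id, "mp1a", tw$value, tw$k, tw$n)
        }
      }

      for (mode in names(sim_mats)) {
        mat <- sim_mats[[mode]]
        if (!mom_present || length(ids) < 5) next
        if ("similarity" %in% include) {
          v_i <- ego_vector(mat, id, c(id, mom))
          v_m <- ego_vector(mat, mom, c(id, mom))
          sim <- tryCatch(ego_similarity(v_m, v_i),
                          error = function(e) list(pearson = NA, cosine = NA))
          add(net, kind, mode, id, "pearson", sim$pearson)
          add(net, kind, mode, id, "cosine", sim$cosine)
        }
        # binary scores are Bernoulli rows: k = score, n = 1 trial
        if ("vs_random" %in% include) {
          vr <- compare_vs_random(mat, id, mom, seed = draw_seed(net, id))
          add(net, kind, mode, id, "vs_random", vr$score, k = vr$score,
              n = if (is.na(vr$score)) NA_real_ else 1,
              comparator = vr$comparator)
        }
        if ("vs_mean" %in% include) {
          vm <- compare_vs_mean(mat, id, mom)
          add(net, kind, mode, id, "vs_mean", vm$score, k = vm$score,
              n = if (is.na(vm$score)) NA_real_ else 1)
        }
      }

      if (!("partners" %in% include)) next
      for (mode in names(part_mats)) {
        pm <- part_mats[[mode]]
        for (cat in c("immature", "peer", "same_sex")) {
          pp <- partner_category_proportion(pm$mat, id, cat, roster,
                                            pm$direction)
          add(net, kind, mode, id, paste0("prop_", cat), pp$value, pp$k, pp$n)
        }
      }
    }
  }

  for (net in networks$proximity) process(net, "proximity")
  for (net in networks$grooming) process(net, "grooming")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
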