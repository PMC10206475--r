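#' The model roster
#'
#' One row per fitted model/network combination: the time-with-mother models
#' (binomial, no permutation test), the mother-offspring similarity LMM, the
#' two binary similarity-comparison GLMMs, the three node-metric LMMs (which
#' additionally control for the mother's corresponding metric) and the three
#' partner-category GLMMs. The permutation method follows the analysis
#' design: datastream swaps for proximity models except the partner-category
#' ones, node-label permutations for grooming and for proximity
#' partner-category models.
#'
#' @return Data frame: `model`, `kind`, `mode`, `response`, `family`,
#'   `permutation`, `mother_metric`.
#' @export
model_specs <- function() {
  rbind(
    data.frame(model = "MP1a", kind = c("proximity", "grooming"),
               mode = c("sri", "total"), response = "mp1a",
               family = "binomial", permutation = "none",
               mother_metric = NA_character_),
    data.frame(model = "MP1b", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "pearson", family = "gaussian",
               permutation = c("datastream", rep("node", 3)),
               mother_metric = NA_character_),
    data.frame(model = "MP1c.1", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "vs_random", family = "binomial",
               permutation = c("datastream", rep("node", 3)),
               mother_metric = NA_character_),
    data.frame(model = "MP1c.2", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "vs_mean", family = "binomial",
               permutation = c("datastream", rep("node", 3)),
               mother_metric = NA_character_),
    data.frame(model = "MP2a", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "metric", family = "gaussian",
               permutation = c("datastream", rep("node", 3)),
               mother_metric = c("strength_prox", "strength_groom_given",
                                 "strength_groom_received",
                                 "strength_groom_total")),
    data.frame(model = "MP2b.1", kind = c("proximity", "grooming"),
               mode = c("sri", "total"), response = "metric",
               family = "gaussian", permutation = c("datastream", "node"),
               mother_metric = c("eigencent_prox", "eigencent_groom_total")),
    data.frame(model = "MP2b.2", kind = c("proximity", "grooming"),
               mode = c("sri", "total"), response = "metric",
               family = "gaussian", permutation = c("datastream", "node"),
               mother_metric = c("betweenness_prox",
                                 "betweenness_groom_total")),
    data.frame(model = "MP2c.1", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "prop_immature", family = "binomial",
               permutation = "node", mother_metric = NA_character_),
    data.frame(model = "MP2c.2", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "prop_peer", family = "binomial",
               permutation = "node", mother_metric = NA_character_),
    data.frame(model = "MP2c.3", kind = c("proximity", rep("grooming", 3)),
               mode = c("sri", "given", "received", "total"),
               response = "prop_same_sex", family = "binomial",
               permutation = "node", mother_metric = NA_character_)
  )
}

#' Assemble the model table for one model specification
#'
#' Joins the response (or standardized metric) rows for one model/network
#' with the covariates: age in months at the period midpoint, sex, the
#' mother's number of offspring in the troop, the mother's relative rank in
#' that season, troop, year, and the nesting ids. For node-metric models the
#' mother's corresponding standardized metric in the same period is added.
#' Rows with a missing response or missing mother rank/metric are dropped
#' with a message.
#'
#' @param spec One row of [model_specs()].
#' @param responses Output of [response_table()].
#' @param metrics Output of [metric_table()] (needed for metric models).
#' @param population Individual table.
#' @param ranks Output of [rank_table()].
#' @return Data frame ready for [fit_model()], one row per
#'   (immature, troop-period); binomial rows carry `k` and `n`.
#' @export
build_model_table <- function(spec, responses, metrics = NULL, population,
                              ranks) {
  if (spec$response == "metric") {
    met <- metrics[metrics$kind == spec$kind &
                     metrics$metric == spec$mother_metric, ]
    tab <- data.frame(
      troop = met$troop, year = met$year, period = met$period,
      period_start = met$period_start, immature_id = met$id,
      value = met$standardized, k = NA_real_, n = NA_real_)
    # mother's metric joined below once mothers are known
  } else {
    r <- responses[responses$kind == spec$kind & responses$mode == spec$mode &
                     responses$response == spec$response, ]
    tab <- r[, c("troop", "year", "period", "period_start", "immature_id",
                 "value", "k", "n")]
  }
  if (nrow(tab) == 0) return(tab)

  pi <- match(tab$immature_id, population$id)
  tab$age <- age_months_at(population$birth_date[pi], tab$period_start + 15)
  tab$sex <- factor(population$sex[pi], levels = c("F", "M"))
  tab$mother_id <- population$mother_id[pi]

  if (spec$response == "metric") {
    # keep immatures only (the metric table covers everyone)
    tab <- tab[tab$age <= 60 & !is.na(tab$mother_id), ]
    met <- metrics[metrics$kind == spec$kind &
                     metrics$metric == spec$mother_metric, ]
    mkey <- paste(met$troop, met$year, met$period, met$id)
    tab$mother_metric <- met$standardized[
      match(paste(tab$troop, tab$year, tab$period, tab$mother_id), mkey)]
  }

  tab$mother_offspring_count <- vapply(tab$mother_id, function(m) {
    if (is.na(m)) return(NA_real_)
    sum(population$mother_id == m, na.rm = TRUE)
  }, numeric(1))
  rkey <- paste(ranks$troop, ranks$year, ranks$id)
  tab$mother_rank <- ranks$relative_rank[
    match(paste(tab$troop, tab$year, tab$mother_id), rkey)]

  if (anyDuplicated(paste(tab$troop, tab$year, tab$period, tab$immature_id))) {
    stop("build_model_table: duplicate (immature, period) rows", call. = FALSE)
  }

  need <- c("value", "age", "sex", "mother_id", "mother_rank",
            if (spec$response == "metric") "mother_metric",
            if (spec$family == "binomial") c("k", "n"))
  complete <- stats::complete.cases(tab[, need])
  if (any(!complete)) {
    message(sprintf("build_model_table [%s %s %s]: dropping %d row(s) with missing response/covariates",
                    spec$model, spec$kind, spec$mode, sum(!complete)))
  }
  tab <- tab[complete, ]
  rownames(tab) <- NULL
  tab
}

model_formula <- function(tab, family, mother_metric = FALSE) {
  # single-level factors cannot enter the design matrix
  sex_term <- if (length(unique(as.character(tab$sex))) > 1) "age * sex"
              else "age"
  fixed <- c(sex_term, "mother_offspring_count", "mother_rank")
  if (mother_metric) fixed <- c(fixed, "mother_metric")
  if (length(unique(tab$troop)) > 1) fixed <- c(fixed, "troop")
  rand <- character()
  if (length(unique(tab$year)) > 1) rand <- c(rand, "(1 | year)")
  if (length(unique(tab$mother_id)) > 1) {
    rand <- c(rand, "(1 | mother_id / immature_id)")
  }
  lhs <- if (family == "binomial") "cbind(k, n - k)" else "value"
  stats::as.formula(paste(lhs, "~", paste(c(fixed, rand), collapse = " + ")))
}

#' Fit the mixed model for one model table
#'
#' Gaussian responses are fit by REML through [lme4::lmer()]; binomial
#' successes/trials responses by logit-link [lme4::glmer()]. The fixed
#' structure is `age * sex + mother_offspring_count + mother_rank (+ troop)
#' (+ mother_metric)` with random intercepts for year and for immature
#' nested in mother; fixed or random terms whose factor has a single level
#' in the data are dropped automatically and noted. Non-convergence and
#' singular fits are flagged, never silently ignored. The same routine and
#' settings are used for observed and permuted data so permutation inference
#' is internally consistent.
#'
#' @param tab Model table from [build_model_table()].
#' @param family `"gaussian"` or `"binomial"`.
#' @param mother_metric Include the mother's metric covariate?
#' @param nAGQ Integrator order for binomial fits (0 = faster penalized
#'   step, used for permutation refits; 1 = default Laplace).
#' @return Object of class `matrinet_fit`: `coefficients` (term, estimate,
#'   se, and OR for binomial), `converged`, `singular`, `n_rows`,
#'   `n_immatures`, `n_mothers`, `formula`, `backend`.
#' @export
fit_model <- function(tab, family = c("gaussian", "binomial"),
                      mother_metric = FALSE, nAGQ = 1) {
  family <- match.arg(family)
  if (nrow(tab) < 8) stop("fit_model: too few rows to fit", call. = FALSE)
  if (family == "binomial" && (all(tab$k == tab$n) || all(tab$k == 0))) {
    warning("fit_model: binomial response is constant; returning a ",
            "degenerate flagged fit", call. = FALSE)
    terms <- c("(Intercept)", "age", "sexM", "mother_offspring_count",
               "mother_rank", "age:sexM")
    return(structure(list(
      coefficients = data.frame(term = terms, estimate = NA_real_,
                                se = NA_real_, OR = NA_real_),
      converged = FALSE, singular = TRUE, degenerate = TRUE,
      n_rows = nrow(tab), n_immatures = length(unique(tab$immature_id)),
      n_mothers = length(unique(tab$mother_id)),
      formula = NULL, backend = "degenerate (constant binomial response)",
      messages = character(), model = NULL), class = "matrinet_fit"))
  }
  if (family == "gaussian" && stats::sd(tab$value) == 0) {
    warning("fit_model: constant response; slopes are zero and variance ",
            "components degenerate", call. = FALSE)
  }
  tab$year <- factor(tab$year)
  form <- model_formula(tab, family, mother_metric)
  msgs <- character()
  fit <- withCallingHandlers(
    if (family == "gaussian") {
      lme4::lmer(form, data = tab, REML = TRUE)
    } else {
      lme4::glmer(form, data = tab, family = stats::binomial(), nAGQ = nAGQ,
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], row.names = NULL)
  coefs$term <- sub("sexM:age", "age:sexM", coefs$term)
  if (family == "binomial") coefs$OR <- exp(coefs$estimate)
  # a singular (boundary) fit is reported via `singular`, not as
  # non-convergence; only genuine optimizer failures clear the flag
  opt_msgs <- unlist(fit@optinfo$conv$lme4)
  conv_ok <- !any(grepl("failed to converge", c(opt_msgs, msgs)))
  structure(list(
    coefficients = coefs,
    converged = conv_ok,
    singular = lme4::isSingular(fit),
    n_rows = nrow(tab),
    n_immatures = length(unique(tab$immature_id)),
    n_mothers = length(unique(tab$mother_id)),
    formula = form,
    backend = sprintf("lme4::%s%s", if (family == "gaussian") "lmer (REML)"
                      else "glmer (logit)",
                      if (family == "binomial") sprintf(", nAGQ = %d", nAGQ)
                      else ""),
    messages = msgs,
    model = fit
  ), class = "matrinet_fit")
}

#' @export
print.matrinet_fit <- function(x, ...) {
  cat(sprintf("<matrinet_fit> %s | %d rows, %d immatures, %d mothers%s%s\n",
              x$backend, x$n_rows, x$n_immatures, x$n_mothers,
              if (!x$converged) " | NOT CONVERGED" else "",
              if (x$singular) " | singular" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

coef_of <- function(fit, term) {
  cf <- fit$coefficients
  i <- match(term, cf$term)
  if (is.na(i)) stop(sprintf("term '%s' absent from fit", term), call. = FALSE)
  cf$estimate[i]
}

#' Percent change in odds per unit of a predictor
#'
#' `(OR - 1) * 100 = (exp(beta) - 1) * 100`.
#'
#' @param beta Coefficient on the log-odds scale.
#' @return Percent change in odds.
#' @export
odds_percent <- function(beta) (exp(beta) - 1) * 100

#' Percent change in odds between two ages
#'
#' `[(OR_t1 - OR_t0) / OR_t0] * 100`, which for a logit-linear age effect
#' equals `(exp(slope * (t1 - t0)) - 1) * 100` with
#' `slope = beta_age (+ beta_age:sex for males)`. Defaults compare a 1 year
#' old (12 months) to a 4 year old (48 months).
#'
#' @param fit A `matrinet_fit`, or a numeric `beta_age`.
#' @param sex `"F"` or `"M"`.
#' @param t0,t1 Ages (months).
#' @param beta_age_sex Interaction coefficient when `fit` is numeric.
#' @return Percent change.
#' @export
age_change_percent <- function(fit, sex = "F", t0 = 12, t1 = 48,
                               beta_age_sex = 0) {
  if (inherits(fit, "matrinet_fit")) {
    beta_age <- coef_of(fit, "age")
    beta_age_sex <- if ("age:sexM" %in% fit$coefficients$term) {
      coef_of(fit, "age:sexM")
    } else 0
  } else {
    beta_age <- fit
  }
  slope <- beta_age + if (sex == "M") beta_age_sex else 0
  (exp(slope * (t1 - t0)) - 1) * 100
}

#' Percent odds difference between sexes at a given age
#'
#' `(exp(beta_sex + age * beta_age:sex) - 1) * 100`, with the age fixed at
#' the middle of the immature range (30 months) by default.
#'
#' @param fit A `matrinet_fit`, or a numeric `beta_sex`.
#' @param age Age (months) at which the sex contrast is evaluated.
#' @param beta_age_sex Interaction coefficient when `fit` is numeric.
#' @return Percent difference in odds, males relative to females.
#' @export
sex_effect_percent <- function(fit, age = 30, beta_age_sex = 0) {
  if (inherits(fit, "matrinet_fit")) {
    beta_sex <- coef_of(fit, "sexM")
    beta_age_sex <- if ("age:sexM" %in% fit$coefficients$term) {
      coef_of(fit, "age:sexM")
    } else 0
  } else {
    beta_sex <- fit
  }
  odds_percent(beta_sex + age * beta_age_sex)
}

#' LMM effect size as percent of the response range
#'
#' `slope * (t1 - t0) / observed_range * 100`: a linear age effect expressed
#' as the percent of the observed response range covered between two ages.
#'
#' @param fit A `matrinet_fit`, or a numeric slope per month.
#' @param sex `"F"` or `"M"` (adds the interaction slope for males).
#' @param observed_range Max minus min of the fitted response (> 0).
#' @param t0,t1 Ages (months).
#' @param beta_age_sex Interaction coefficient when `fit` is numeric.
#' @return Percent of range.
#' @export
lmm_range_percent <- function(fit, sex = "F", observed_range, t0 = 12,
                              t1 = 48, beta_age_sex = 0) {
  if (observed_range <= 0) {
    stop("lmm_range_percent: observed_range must be > 0", call. = FALSE)
  }
  if (inherits(fit, "matrinet_fit")) {
    slope <- coef_of(fit, "age")
    beta_age_sex <- if ("age:sexM" %in% fit$coefficients$term) {
      coef_of(fit, "age:sexM")
    } else 0
  } else {
    slope <- fit
  }
  slope <- slope + if (sex == "M") beta_age_sex else 0
  slope * (t1 - t0) / observed_range * 100
}

#' Published reference fixed effects
#'
#' Age, sex (male relative to female) and age-by-sex estimates (with
#' standard errors) reported for each model/network in the field study of
#' wild immature chacma baboons whose analysis this package re-implements.
#' Binomial-model estimates are on the logit scale; node-metric estimates on
#' the standardized response scale. Shipped as plain text in
#' `inst/extdata/reference_fixed_effects.csv`; useful as worked-example
#' inputs for the effect-size formulas.
#'
#' @return Data frame: `model`, `network`, `term`, `estimate`, `se`.
#' @export
reference_fixed_effects <- function() {
  path <- system.file("extdata", "reference_fixed_effects.csv",
                      package = "matrinet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
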