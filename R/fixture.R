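# Clinical-like synthetic "original data" with planted structure: a binary
# adverse-event outcome, a smoker/pack-years logical rule, class-shifted
# Gaussian features and independent noise columns. Every planted quantity is
# recorded in a truth record so downstream modules can be tested against
# known ground truth.

#' Fixture parameters
#'
#' @param n Number of rows (>= 4).
#' @param event_prevalence Probability of the adverse event.
#' @param smoker_rate_by_class Length-2 probabilities of smoking,
#'   ordered (non-event class, event class).
#' @param pack_years_meanlog,pack_years_sdlog Log-normal location/scale of
#'   pack-years among smokers (strictly positive draws, so the planted
#'   smoker/pack-years association is exact).
#' @param numeric_effects Named event-vs-non-event mean shifts, in SD
#'   units, for the clinical signal columns. Defaults give a Bayes AUC of
#'   about 0.85 for the planted linear signal.
#' @param n_noise_numeric,n_noise_categorical Counts of independent noise
#'   columns carrying no class signal.
#' @param seed Integer seed.
#' @return An object of class `fixture_params`.
#' @export
fixture_params <- function(n = 2304L, event_prevalence = 0.5,
                           smoker_rate_by_class = c(0.3, 0.7),
                           pack_years_meanlog = log(25),
                           pack_years_sdlog = 0.5,
                           numeric_effects = c(age = 0.7, fvc = -0.7,
                                               dlco = -0.7),
                           n_noise_numeric = 2L, n_noise_categorical = 2L,
                           seed = 1L) {
  if (!is_count(n, min = 4L)) abort("n must be an integer >= 4")
  if (!is_prob(event_prevalence)) abort("event_prevalence must be in (0, 1)")
  if (length(smoker_rate_by_class) != 2L ||
      !all(vapply(smoker_rate_by_class, is_prob, logical(1)))) {
    abort("smoker_rate_by_class must be two probabilities in (0, 1)")
  }
  if (is.null(names(numeric_effects))) {
    abort("numeric_effects must be a named vector")
  }
  structure(list(n = as.integer(n), event_prevalence = event_prevalence,
                 smoker_rate_by_class = smoker_rate_by_class,
                 pack_years_meanlog = pack_years_meanlog,
                 pack_years_sdlog = pack_years_sdlog,
                 numeric_effects = numeric_effects,
                 n_noise_numeric = as.integer(n_noise_numeric),
                 n_noise_categorical = as.integer(n_noise_categorical),
                 seed = as.integer(seed)),
            class = "fixture_params")
}

# base location/scale for the named clinical signal columns; unnamed extras
# fall back to a generic lab scale
signal_scales <- function(names) {
  known <- list(age = c(63, 9), fvc = c(3.3, 0.7), dlco = c(85, 18))
  lapply(names, function(nm) known[[nm]] %||% c(50, 10))
}

noise_numeric_spec <- function(k) {
  known <- list(height = c(164, 8), weight = c(63, 11))
  nms <- c("height", "weight")
  out <- list()
  for (i in seq_len(k)) {
    nm <- if (i <= 2L) nms[i] else sprintf("lab%d", i)
    out[[nm]] <- known[[nm]] %||% c(100, 20)
  }
  out
}

noise_categorical_spec <- function(k) {
  known <- list(sex = list(levels = c("female", "male"),
                           probs = c(0.45, 0.55)),
                stage = list(levels = c("I", "II", "III", "IV"),
                             probs = c(0.3, 0.25, 0.25, 0.2)))
  nms <- c("sex", "stage")
  out <- list()
  for (i in seq_len(k)) {
    nm <- if (i <= 2L) nms[i] else sprintf("marker%d", i)
    out[[nm]] <- known[[nm]] %||%
      list(levels = c("low", "mid", "high"), probs = c(0.5, 0.3, 0.2))
  }
  out
}

# closed-form Bayes AUC of the planted signal: Gaussian shifts (SD units)
# plus the class-dependent smoker Bernoulli. Pack-years add no signal beyond
# smoker status (same distribution in both classes given smoking).
fixture_bayes_auc <- function(numeric_effects, smoker_rate_by_class) {
  d2 <- sum(numeric_effects^2)
  p0 <- smoker_rate_by_class[1]
  p1 <- smoker_rate_by_class[2]
  w <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  pr <- function(s1, s0) {
    (if (s1) p1 else 1 - p1) * (if (s0) p0 else 1 - p0)
  }
  term <- function(s1, s0) {
    shift <- d2 + w * (s1 - s0)
    if (d2 == 0) return(if (shift > 0) 1 else if (shift < 0) 0 else 0.5)
    stats::pnorm(shift / sqrt(2 * d2))
  }
  sum(vapply(0:1, function(s1) sum(vapply(0:1, function(s0)
    pr(s1, s0) * term(s1, s0), numeric(1))), numeric(1)))
}

#' Generate the planted clinical fixture
#'
#' Emulates the statistical structure the divide-and-conquer method
#' assumes: a binary "adverse_event" outcome, a class-dependent "smoker"
#' column, "pack_years" exactly 0 for non-smokers and log-normal for
#' smokers (the planted logical rule), class-shifted Gaussian clinical
#' features, and independent noise columns. Generation redraws (up to 20
#' times from the same seeded stream) until every class-by-smoker cell is
#' non-empty, so the canonical 4-subset partition always exists.
#'
#' @param params A [fixture_params()].
#' @return List with `data` (a [tabular_dataset()] whose schema carries the
#'   planted rule), `rules`, and `truth` (prevalence, effects, smoker
#'   rates, and the closed-form `bayes_auc` of the planted signal).
#' @export
generate_fixture <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  n <- params$n
  sig_names <- names(params$numeric_effects)
  scales <- signal_scales(sig_names)
  noise_num <- noise_numeric_spec(params$n_noise_numeric)
  noise_cat <- noise_categorical_spec(params$n_noise_categorical)

  draw_once <- function() {
    cls <- stats::rbinom(n, 1, params$event_prevalence)
    p_smoke <- params$smoker_rate_by_class[cls + 1L]
    smoker <- stats::rbinom(n, 1, p_smoke)
    if (length(unique(cls)) < 2L) return(NULL)
    if (any(table(cls, smoker) == 0) || length(unique(smoker)) < 2L) {
      return(NULL)
    }
    pack_years <- ifelse(smoker == 1,
                         stats::rlnorm(n, params$pack_years_meanlog,
                                       params$pack_years_sdlog),
                         0)
    df <- data.frame(adverse_event = factor(ifelse(cls == 1, "death",
                                                   "survival"),
                                            levels = c("survival", "death")),
                     smoker = factor(ifelse(smoker == 1, "yes", "no"),
                                     levels = c("no", "yes")),
                     pack_years = pack_years,
                     check.names = FALSE)
    for (k in seq_along(sig_names)) {
      mu <- scales[[k]][1]; sdv <- scales[[k]][2]
      df[[sig_names[k]]] <-
        mu + sdv * (stats::rnorm(n) + params$numeric_effects[k] * cls)
    }
    for (nm in names(noise_num)) {
      df[[nm]] <- stats::rnorm(n, noise_num[[nm]][1], noise_num[[nm]][2])
    }
    for (nm in names(noise_cat)) {
      sp <- noise_cat[[nm]]
      df[[nm]] <- factor(sample(sp$levels, n, replace = TRUE,
                                prob = sp$probs),
                         levels = sp$levels)
    }
    df
  }

  df <- with_seed(params$seed, {
    out <- NULL
    for (attempt in seq_len(20L)) {
      out <- draw_once()
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(df)) {
    abort("could not populate all class-by-smoker cells in 20 attempts")
  }

  cols <- list(
    col_schema("adverse_event", "categorical", c("survival", "death"),
               role = "target"),
    col_schema("smoker", "categorical", c("no", "yes")),
    col_schema("pack_years", "numeric"))
  for (nm in sig_names) cols <- c(cols, list(col_schema(nm, "numeric")))
  for (nm in names(noise_num)) cols <- c(cols, list(col_schema(nm, "numeric")))
  for (nm in names(noise_cat)) {
    cols <- c(cols, list(col_schema(nm, "categorical",
                                    noise_cat[[nm]]$levels)))
  }
  rules <- list(logical_rule("smoker", "no", "pack_years", 0))
  schema <- tabular_schema(cols, rules = rules)
  truth <- list(event_prevalence = params$event_prevalence,
                smoker_rate_by_class = params$smoker_rate_by_class,
                numeric_effects = params$numeric_effects,
                bayes_auc = fixture_bayes_auc(params$numeric_effects,
                                              params$smoker_rate_by_class))
  list(data = tabular_dataset(df, schema), rules = rules, truth = truth)
}

#' Named fixture presets
#'
#' `"nsclc-like"` mirrors a lung-cancer registry study population of 2304
#' patients meant to be split 70/30 into development and validation;
#' `"small"` is a fast 400-row table; `"imbalanced-od"` has a rare (10%)
#' event.
#'
#' @param name Preset name.
#' @param seed Integer seed stored in the returned parameters.
#' @return A [fixture_params()].
#' @export
fixture_presets <- function(name = c("nsclc-like", "small", "imbalanced-od"),
                            seed = 1L) {
  known <- c("nsclc-like", "small", "imbalanced-od")
  if (!is.character(name) || !name[1L] %in% known) {
    abort("unknown preset '%s'; available: %s",
          as.character(name)[1L], paste(known, collapse = ", "))
  }
  switch(name[1L],
         "nsclc-like" = fixture_params(n = 2304L, seed = seed),
         "small" = fixture_params(n = 400L, seed = seed),
         "imbalanced-od" = fixture_params(n = 2304L, event_prevalence = 0.1,
                                          seed = seed))
}
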