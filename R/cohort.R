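#' Questionnaire field vocabularies
#'
#' Canonical categorical vocabularies of the cohort schema. Ordered fields
#' are stored in increasing order (lowest code first), so the integer code of
#' a value is its position minus one: e.g. sun exposure
#' Never/Infrequently/Sometimes/Often/Always codes to 0/1/2/3/4.
#'
#' @return Named list of character vectors, one per categorical field.
#' @export
cohort_vocabularies <- function() {
  list(
    age_band = c("<40", "40-50", ">=50"),
    gender = c("Male", "Female"),
    bmi_band = c("<25", ">=25"),
    milk = c("yes", "no"),
    exercise = c("yes", "no"),
    sun_exposure = c("Never", "Infrequently", "Sometimes", "Often", "Always"),
    calcium_band = c("0-7", "1-15", ">16"),
    fish = c("yes", "no"),
    financial_stress = c("yes", "no"),
    family_relationship = c("Happy", "Unhappy"),
    geo_location = c("Urban", "Rural"),
    aqi_band = c("VeryPoor", "Poor", "Moderate", "Good"),
    health_issues = c("yes", "no"),
    season = c("Winter", "Spring", "Summer", "Fall")
  )
}

# Fields whose categories carry an intrinsic order (low -> high code).
ordered_fields <- function() {
  c("age_band", "bmi_band", "sun_exposure", "calcium_band", "aqi_band")
}

# Binary fields and the category coded as 1.
binary_fields <- function() {
  c(
    gender = "Male", milk = "yes", exercise = "yes", fish = "yes",
    financial_stress = "yes", family_relationship = "Happy",
    geo_location = "Urban", health_issues = "yes"
  )
}

#' Seasonal serum baseline presets
#'
#' Two sets of per-season serum 25-OH-D baselines (ng/mL). The `"table"`
#' preset (default elsewhere) is the structured seasonal summary
#' (12.5/18.5/22.0/15.0 with SDs 1.5/1.5/2.0/1.5); the `"narrative"` preset
#' is the alternative set of seasonal means (11.33/16.38/22.55/16.56). Only
#' the summer (1.43) and fall (1.07) SDs accompany the narrative means;
#' winter and spring are set to their midpoint 1.25.
#'
#' @param which `"table"` or `"narrative"`.
#' @return List with named numeric vectors `mean` and `sd` (per season).
#' @export
seasonal_preset <- function(which = c("table", "narrative")) {
  which <- match.arg(which)
  seasons <- c("Winter", "Spring", "Summer", "Fall")
  if (which == "table") {
    list(
      mean = stats::setNames(c(12.5, 18.5, 22.0, 15.0), seasons),
      sd = stats::setNames(c(1.5, 1.5, 2.0, 1.5), seasons)
    )
  } else {
    list(
      mean = stats::setNames(c(11.33, 16.38, 22.55, 16.56), seasons),
      sd = stats::setNames(c(1.25, 1.25, 1.43, 1.07), seasons)
    )
  }
}

# Feature-importance effect weights (percent) and effect directions on serum.
# Positive sign: higher code -> higher serum.
default_effect_table <- function() {
  tibble::tibble(
    feature = c(
      "family_relationship", "exercise", "calcium_band", "age_band",
      "sun_exposure", "milk", "health_issues", "bmi_band",
      "financial_stress", "fish", "fdsk_score", "gender"
    ),
    weight = c(15, 12, 11, 10, 9, 9, 9, 8, 6, 5, 5, 2),
    sign = c(+1, +1, +1, -1, +1, +1, -1, -1, -1, +1, +1, +1)
  )
}

#' Synthetic cohort generator configuration
#'
#' Builds and validates the configuration of [generate_cohort()]. Defaults
#' reproduce the reference study conditions: 512 records, class proportions
#' 21.88/26.17/26.95/25.00 percent with exact per-class counts, seasonal
#' serum baselines from the `"table"` preset, and effect weights taken from
#' the reported feature-importance percentages (rescaled to sum to one) with
#' an overall questionnaire effect amplitude `effect_scale` in ng/mL.
#'
#' @param n_records Number of cohort rows.
#' @param class_proportions Length-4 non-negative vector summing to 1, in
#'   severity-level order (Optimal first).
#' @param exact_counts If `TRUE`, rows are resampled per class until counts
#'   equal the largest-remainder allocation of `n_records * class_proportions`.
#' @param effect_weights Named non-negative weights per questionnaire feature;
#'   rescaled internally to sum to 1.
#' @param effect_scale Amplitude (ng/mL) multiplying the weighted sum of
#'   centered feature codes in the latent serum model.
#' @param seasonal_mean,seasonal_sd Named per-season baseline mean and SD
#'   (ng/mL) of the seasonal serum component.
#' @param noise_sd SD (ng/mL) of the feature-independent residual noise.
#' @param missing_rate Fraction of maskable cells set missing (see
#'   [inject_missingness()]).
#' @param outlier_rate Fraction of rows whose FDSK score receives an
#'   additive outlying shift (fixture for IQR capping).
#' @param seed Integer seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_records = 64, seed = 1)
cohort_config <- function(n_records = 512,
                          class_proportions = c(0.2188, 0.2617, 0.2695, 0.2500),
                          exact_counts = TRUE,
                          effect_weights = NULL,
                          effect_scale = 30,
                          seasonal_mean = seasonal_preset("table")$mean,
                          seasonal_sd = seasonal_preset("table")$sd,
                          noise_sd = 0.5,
                          missing_rate = 0,
                          outlier_rate = 0,
                          seed = 1L) {
  eff <- default_effect_table()
  if (!is.null(effect_weights)) {
    if (is.null(names(effect_weights)) ||
      !all(names(effect_weights) %in% eff$feature)) {
      abort("`effect_weights` must be named by questionnaire feature.")
    }
    eff$weight[match(names(effect_weights), eff$feature)] <- effect_weights
  }
  if (any(eff$weight < 0)) abort("effect weights must be non-negative.")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1.")
  }
  if (length(class_proportions) != 4 || any(class_proportions < 0)) {
    abort("`class_proportions` must be 4 non-negative values.")
  }
  seasons <- c("Winter", "Spring", "Summer", "Fall")
  if (!all(seasons %in% names(seasonal_mean)) ||
    !all(seasons %in% names(seasonal_sd))) {
    abort("`seasonal_mean`/`seasonal_sd` must be named by season.")
  }
  if (any(seasonal_sd <= 0) || noise_sd < 0) {
    abort("seasonal SDs must be positive and `noise_sd` non-negative.")
  }
  if (missing_rate < 0 || missing_rate >= 1 || outlier_rate < 0 || outlier_rate > 1) {
    abort("`missing_rate` must be in [0, 1) and `outlier_rate` in [0, 1].")
  }
  if (n_records < 0) abort("`n_records` must be non-negative.")
  structure(
    list(
      n_records = as.integer(n_records),
      class_proportions = class_proportions,
      exact_counts = isTRUE(exact_counts),
      effects = eff,
      effect_scale = effect_scale,
      seasonal_mean = seasonal_mean[seasons],
      seasonal_sd = seasonal_sd[seasons],
      noise_sd = noise_sd,
      missing_rate = missing_rate,
      outlier_rate = outlier_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Largest-remainder allocation of n across proportions; ties favour the
# earlier class.
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Centered code in [-1, 1] for one feature value.
centered_code <- function(feature, value) {
  vocab <- cohort_vocabularies()
  if (feature == "fdsk_score") {
    return((value - 5.5) / 5.5)
  }
  v <- vocab[[feature]]
  code <- match(value, v) - 1
  m <- length(v) - 1
  (code - m / 2) / (m / 2)
}

# Draw a batch of raw cohort rows (no class conditioning).
draw_rows <- function(n, config) {
  vocab <- cohort_vocabularies()
  draw_cat <- function(v) sample(v, n, replace = TRUE)
  out <- tibble::tibble(
    age_band = draw_cat(vocab$age_band),
    gender = draw_cat(vocab$gender),
    bmi_band = draw_cat(vocab$bmi_band),
    milk = draw_cat(vocab$milk),
    exercise = draw_cat(vocab$exercise),
    sun_exposure = draw_cat(vocab$sun_exposure),
    calcium_band = draw_cat(vocab$calcium_band),
    fish = draw_cat(vocab$fish),
    financial_stress = draw_cat(vocab$financial_stress),
    family_relationship = draw_cat(vocab$family_relationship),
    geo_location = draw_cat(vocab$geo_location),
    aqi_band = draw_cat(vocab$aqi_band),
    health_issues = draw_cat(vocab$health_issues),
    fdsk_score = rtrunc_norm(n, mean = 6, sd = 2, lower = 0, upper = 11),
    season = draw_cat(vocab$season)
  )
  eff <- config$effects
  w <- eff$weight / sum(eff$weight)
  contrib <- rep(0, n)
  for (j in seq_len(nrow(eff))) {
    contrib <- contrib +
      w[j] * eff$sign[j] * centered_code(eff$feature[j], out[[eff$feature[j]]])
  }
  serum <- config$seasonal_mean[out$season] +
    config$effect_scale * contrib +
    rnorm(n, 0, config$noise_sd)
  out$serum_25ohd <- pmax(as.numeric(serum), 0)
  out$severity <- assign_severity(out$serum_25ohd)
  out
}

# Truncated normal by rejection (bounds far enough that yield is high).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic questionnaire cohort
#'
#' Simulates cohort records under a latent serum model: per-season baseline
#' plus a weighted sum of centered questionnaire feature codes (amplitude
#' `effect_scale`) plus Gaussian noise. Severity is assigned from the latent
#' serum by [assign_severity()], so severity is consistent with serum in
#' every generated row. With `exact_counts`, rows are resampled per class
#' until counts equal the largest-remainder allocation of
#' `n_records * class_proportions`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with the questionnaire fields, `season`, `serum_25ohd`
#'   (ng/mL) and `severity` (factor).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_records = 128, seed = 7))
#' table(cohort$severity)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_records
  empty <- draw_rows(0, config)
  if (n == 0) {
    return(empty)
  }
  set.seed(derive_seed(config$seed, "generator"))
  if (!config$exact_counts) {
    out <- draw_rows(n, config)
  } else {
    target <- largest_remainder(n, config$class_proportions)
    names(target) <- severity_labels()
    buckets <- vector("list", 4)
    have <- integer(4)
    for (batch in seq_len(500)) {
      rows <- draw_rows(max(4L * n, 256L), config)
      cls <- as.integer(rows$severity)
      for (k in 1:4) {
        need <- target[k] - have[k]
        if (need > 0) {
          take <- which(cls == k)
          take <- take[seq_len(min(need, length(take)))]
          if (length(take)) {
            buckets[[k]] <- c(buckets[[k]], list(rows[take, ]))
            have[k] <- have[k] + length(take)
          }
        }
      }
      if (all(have >= target)) break
    }
    if (!all(have >= target)) {
      abort(paste0(
        "exact class counts unattainable under the configured latent model; ",
        "short classes: ",
        paste(severity_labels()[have < target], collapse = ", ")
      ))
    }
    out <- dplyr::bind_rows(buckets)
    out <- out[sample.int(nrow(out)), ]
  }
  if (config$outlier_rate > 0) {
    hit <- runif(n) < config$outlier_rate
    out$fdsk_score[hit] <- out$fdsk_score[hit] + runif(sum(hit), 10, 20)
  }
  out <- tibble::as_tibble(out)
  if (config$missing_rate > 0) {
    out <- inject_missingness(out, config$missing_rate,
      seed = derive_seed(config$seed, "missingness")
    )
  }
  out
}

#' Set cells missing completely at random
#'
#' Masks an expected fraction `rate` of maskable cells (every column except
#' `severity`) as missing, independently and uniformly (MCAR). Observed
#' cells are left unchanged.
#'
#' @param data A cohort tibble.
#' @param rate Fraction in `[0, 1)` of cells to mask.
#' @param seed Integer seed; the same seed yields the same mask.
#' @return The tibble with masked cells set to `NA`.
#' @export
inject_missingness <- function(data, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort("`rate` must be in [0, 1).")
  }
  if (rate == 0 || nrow(data) == 0) {
    return(data)
  }
  cols <- setdiff(names(data), "severity")
  set.seed(seed)
  for (cl in cols) {
    mask <- runif(nrow(data)) < rate
    data[[cl]][mask] <- NA
  }
  data
}

#' Write / read a cohort CSV
#'
#' Cohorts are stored as UTF-8 CSV with a header row and empty strings for
#' missing cells. `read_cohort()` is a light reader used for round-trips;
#' [load_cohort()] additionally validates vocabularies.
#'
#' @param data Cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble.
#' @export
write_cohort <- function(data, path) {
  out <- data
  if ("severity" %in% names(out)) out$severity <- as.character(out$severity)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path,
    na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      fdsk_score = readr::col_double(),
      serum_25ohd = readr::col_double(),
      .default = readr::col_character()
    )
  )
  if ("severity" %in% names(out)) {
    out$severity <- factor(out$severity, levels = severity_labels())
  }
  tibble::as_tibble(out)
}
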