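#' @keywords internal
#' @useDynLib cbcgnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# ---- configuration ---------------------------------------------------------

#' Default class-conditional feature parameters for the cohort generator
#'
#' Means/SDs are clinically plausible values for adult non-ICU inpatients, not
#' estimates from any specific hospital dataset. Units: age in years,
#' hemoglobin in mmol/L, red blood cells in Tpt/L, white blood cells in Gpt/L,
#' mean corpuscular volume in fL, platelets in Gpt/L. The control white blood
#' cell center sits in the physiological 4-8 Gpt/L range; the sepsis class
#' shifts WBC and MCV up, platelets, hemoglobin and RBC down, and age up.
#'
#' @return Named list, one entry per continuous feature, each with `control`
#'   and `sepsis` `(mean, sd)` pairs and truncation bounds.
#' @export
default_feature_params <- function() {
  list(
    age        = list(control = c(58, 18),   sepsis = c(67, 16),   lower = 18,  upper = 100),
    hemoglobin = list(control = c(8.4, 1.1), sepsis = c(7.3, 1.3), lower = 2,   upper = 13),
    rbc        = list(control = c(4.6, 0.55), sepsis = c(4.1, 0.65), lower = 1.5, upper = 8),
    wbc        = list(control = c(7.0, 2.2), sepsis = c(11.5, 5.0), lower = 0.3, upper = 60),
    mcv        = list(control = c(89, 5.5),  sepsis = c(93, 7),    lower = 55,  upper = 130),
    platelets  = list(control = c(250, 75),  sepsis = c(180, 95),  lower = 5,   upper = 1200)
  )
}

#' Configuration for the synthetic CBC cohort generator
#'
#' The defaults encode the structural descriptors of routine-care CBC data
#' that the generator is meant to emulate: strong class imbalance, about two
#' thirds of sepsis cases occurring as singleton measurements, and in-sequence
#' sepsis concentrated at the final position of a patient's sequence
#' (92.14%). Sequence lengths follow a shifted geometric distribution
#' (support >= 1) so singletons occur naturally.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; cohorts are pure functions of (config, seed).
#' @param sepsis_measurement_prevalence Target fraction of measurements
#'   labeled sepsis (measurement-level, not patient-level).
#' @param singleton_sepsis_fraction Fraction of sepsis cases whose patient has
#'   exactly one measurement.
#' @param last_position_sepsis_fraction Among in-sequence sepsis cases,
#'   probability the sepsis measurement is the patient's final one.
#' @param mean_sequence_length Mean of the shifted-geometric sequence-length
#'   distribution (must be >= 1).
#' @param feature_params Class-conditional feature means/SDs, see
#'   [default_feature_params()].
#' @param p_female Length-2 numeric: probability of female sex for control and
#'   sepsis patients.
#' @param between_patient_frac Fraction of each continuous feature's control
#'   variance attributed to a stable per-patient random effect (repeated
#'   measurements of one patient are correlated, which is what patient-centric
#'   graphs exploit).
#' @param split_fractions Named fractions (train, validation, internal_test,
#'   external_test); patients, not measurements, are assigned to splits.
#' @param external_shift Named additive offsets applied to feature means for
#'   external-split patients (mild site shift).
#' @param external_prevalence_multiplier Multiplier on the sepsis prevalence
#'   for the external site.
#' @return An object of class `cbc_cohort_config`.
#' @export
cohort_config <- function(n_patients = 5000,
                          seed = 1L,
                          sepsis_measurement_prevalence = 0.04,
                          singleton_sepsis_fraction = 2 / 3,
                          last_position_sepsis_fraction = 0.9214,
                          mean_sequence_length = 2.5,
                          feature_params = default_feature_params(),
                          p_female = c(control = 0.5, sepsis = 0.45),
                          between_patient_frac = 0.5,
                          split_fractions = c(train = 0.6, validation = 0.1,
                                              internal_test = 0.15,
                                              external_test = 0.15),
                          external_shift = c(age = 1.5, hemoglobin = -0.1,
                                             rbc = -0.05, wbc = 0.3,
                                             mcv = 0.8, platelets = -8),
                          external_prevalence_multiplier = 1.25) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    sepsis_measurement_prevalence = sepsis_measurement_prevalence,
    singleton_sepsis_fraction = singleton_sepsis_fraction,
    last_position_sepsis_fraction = last_position_sepsis_fraction,
    mean_sequence_length = mean_sequence_length,
    feature_params = feature_params,
    p_female = p_female,
    between_patient_frac = between_patient_frac,
    split_fractions = split_fractions,
    external_shift = external_shift,
    external_prevalence_multiplier = external_prevalence_multiplier
  )
  class(cfg) <- "cbc_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  frac_fields <- c("sepsis_measurement_prevalence", "singleton_sepsis_fraction",
                   "last_position_sepsis_fraction", "between_patient_frac")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_config(sprintf("`%s` must be a single fraction in [0, 1], got %s",
                          f, format(v)))
    }
  }
  if (cfg$n_patients < 1) stop_config("`n_patients` must be >= 1")
  if (cfg$mean_sequence_length < 1) {
    stop_config("`mean_sequence_length` must be >= 1")
  }
  for (nm in names(cfg$feature_params)) {
    fp <- cfg$feature_params[[nm]]
    if (fp$control[2] <= 0 || fp$sepsis[2] <= 0) {
      stop_config(sprintf("feature `%s` has non-positive SD", nm))
    }
  }
  sf <- cfg$split_fractions
  need <- c("train", "validation", "internal_test", "external_test")
  if (!all(need %in% names(sf)) || any(sf < 0) || abs(sum(sf) - 1) > 1e-8) {
    stop_config("`split_fractions` must name train/validation/internal_test/external_test and sum to 1")
  }
  if (any(cfg$p_female < 0 | cfg$p_female > 1)) {
    stop_config("`p_female` entries must be fractions in [0, 1]")
  }
  invisible(cfg)
}

stop_config <- function(msg) {
  stop(errorCondition(paste0("invalid generator configuration: ", msg),
                      class = c("cbcgnn_config_error", "error")))
}

cbc_feature_names <- function() {
  c("age", "sex", "hemoglobin", "rbc", "wbc", "mcv", "platelets")
}

cohort_columns <- function() {
  c("patient_id", "position", "age", "sex", "hemoglobin", "rbc", "wbc",
    "mcv", "platelets", "label", "split")
}

# inverse-CDF truncated normal; vectorized over mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  x <- stats::qnorm(pa + u * (pb - pa), mean, sd)
  pmin(pmax(x, lower), upper)
}

# ---- generation ------------------------------------------------------------

#' Generate a synthetic CBC cohort
#'
#' Simulates `n_patients` patients, each with a variable-length sequence of
#' complete blood count measurements. A sepsis patient carries exactly one
#' sepsis-labeled measurement; with probability `singleton_sepsis_fraction`
#' the patient is a singleton, otherwise the sepsis measurement sits at the
#' final sequence position with probability `last_position_sepsis_fraction`
#' (uniform over earlier positions otherwise). Continuous features are
#' truncated normals with class-conditional means; control measurements share
#' a per-patient random effect so that repeated measurements are correlated.
#' Patients (never single measurements) are assigned to the four splits;
#' external-split patients receive small additive mean shifts and a slightly
#' different prevalence, emulating a second site.
#'
#' @param config A [cohort_config()] object.
#' @return A `cbc_cohort`: a data.frame with columns
#'   `patient_id, position, age, sex, hemoglobin, rbc, wbc, mcv, platelets,
#'   label, split`, ordered by patient then position.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  p_geo <- 1 / config$mean_sequence_length  # E[1 + Geom(p)] = 1/p

  # split assignment by patient
  counts <- diff(round(cumsum(c(0, config$split_fractions)) * n))
  names(counts) <- names(config$split_fractions)
  split_pat <- sample(rep(names(counts), counts))

  # per-split sepsis-patient probability solving the measurement-level
  # prevalence: pi = q / (q * E_s + (1 - q) * E_c)
  e_c <- 1 / p_geo
  e_s <- config$singleton_sepsis_fraction +
    (1 - config$singleton_sepsis_fraction) * (1 + 1 / p_geo)
  q_for <- function(prev) {
    prev <- min(prev, 0.999)
    q <- prev * e_c / (1 - prev * e_s + prev * e_c)
    min(max(q, 0), 1)
  }
  prev <- config$sepsis_measurement_prevalence
  q <- ifelse(split_pat == "external_test",
              q_for(prev * config$external_prevalence_multiplier),
              q_for(prev))

  is_sepsis_pat <- stats::runif(n) < q
  singleton <- is_sepsis_pat & (stats::runif(n) < config$singleton_sepsis_fraction)

  len <- 1L + stats::rgeom(n, p_geo)
  len[singleton] <- 1L
  in_seq_sepsis <- is_sepsis_pat & !singleton
  # in-sequence sepsis patients need length >= 2 (memoryless re-draw)
  len[in_seq_sepsis] <- 2L + stats::rgeom(sum(in_seq_sepsis), p_geo)

  sepsis_pos <- rep(NA_integer_, n)
  sepsis_pos[singleton] <- 1L
  if (any(in_seq_sepsis)) {
    idx <- which(in_seq_sepsis)
    at_last <- stats::runif(length(idx)) < config$last_position_sepsis_fraction
    sepsis_pos[idx[at_last]] <- len[idx[at_last]]
    early <- idx[!at_last]
    if (length(early)) {
      sepsis_pos[early] <- vapply(len[early], function(l) {
        sample.int(l - 1L, 1L)
      }, integer(1))
    }
  }

  # patient-level attributes
  p_fem <- ifelse(is_sepsis_pat, config$p_female[["sepsis"]],
                  config$p_female[["control"]])
  sex_pat <- as.integer(stats::runif(n) < p_fem)
  ext_pat <- split_pat == "external_test"

  fp <- config$feature_params
  shift_for <- function(nm) {
    ifelse(ext_pat, ifelse(is.na(config$external_shift[nm]), 0,
                           config$external_shift[nm]), 0)
  }
  age_mean <- ifelse(is_sepsis_pat, fp$age$sepsis[1], fp$age$control[1]) +
    shift_for("age")
  age_sd <- ifelse(is_sepsis_pat, fp$age$sepsis[2], fp$age$control[2])
  age_pat <- rtruncnorm(n, age_mean, age_sd, fp$age$lower, fp$age$upper)

  # expand to measurements
  m_total <- sum(len)
  pat_idx <- rep(seq_len(n), len)
  position <- sequence(len)
  label <- as.integer(!is.na(sepsis_pos[pat_idx]) &
                        position == sepsis_pos[pat_idx])

  blood <- c("hemoglobin", "rbc", "wbc", "mcv", "platelets")
  between <- sqrt(config$between_patient_frac)
  within <- sqrt(1 - config$between_patient_frac)
  cols <- list()
  for (nm in blood) {
    pars <- fp[[nm]]
    # stable patient offset, scaled from the control SD
    offset_pat <- stats::rnorm(n, 0, between * pars$control[2])
    ctrl_mean <- pars$control[1] + shift_for(nm) + offset_pat
    sep_mean <- pars$sepsis[1] + shift_for(nm)
    mu <- ifelse(label == 1L, sep_mean[pat_idx], ctrl_mean[pat_idx])
    sd <- ifelse(label == 1L, pars$sepsis[2], within * pars$control[2])
    cols[[nm]] <- rtruncnorm(m_total, mu, sd, pars$lower, pars$upper)
  }

  cohort <- data.frame(
    patient_id = sprintf("P%06d", pat_idx),
    position = as.integer(position),
    age = age_pat[pat_idx],
    sex = sex_pat[pat_idx],
    hemoglobin = cols$hemoglobin,
    rbc = cols$rbc,
    wbc = cols$wbc,
    mcv = cols$mcv,
    platelets = cols$platelets,
    label = label,
    split = split_pat[pat_idx],
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cbc_cohort", "data.frame")
  cohort
}

# ---- descriptor statistics -------------------------------------------------

#' Descriptor statistics of a cohort
#'
#' Computes the structural descriptors that characterize routine-care CBC
#' data: sepsis prevalence, the fraction of sepsis measurements that are
#' singletons (their patient has exactly one measurement), and -- among
#' in-sequence sepsis measurements -- the fraction occurring at their
#' patient's final position.
#'
#' @param cohort A `cbc_cohort` data.frame.
#' @return A list with `n_measurements`, `n_patients`, `sepsis_prevalence`,
#'   `singleton_sepsis_fraction`, `last_position_sepsis_fraction`,
#'   `sequence_length_histogram`, and `undefined` (TRUE when there are no
#'   sepsis measurements so the placement fractions are undefined `NA`).
#' @export
cohort_stats <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  seq_len_pat <- tapply(cohort$position, cohort$patient_id, max)
  max_pos <- as.vector(seq_len_pat[cohort$patient_id])
  is_sep <- cohort$label == 1L
  n_sep <- sum(is_sep)

  if (n_sep == 0) {
    singleton_frac <- NA_real_
    last_frac <- NA_real_
    undefined <- TRUE
  } else {
    undefined <- FALSE
    singleton <- is_sep & max_pos == 1L
    singleton_frac <- sum(singleton) / n_sep
    in_seq <- is_sep & max_pos >= 2L
    if (!any(in_seq)) {
      last_frac <- NA_real_
    } else {
      last_frac <- sum(cohort$position[in_seq] == max_pos[in_seq]) / sum(in_seq)
    }
  }

  list(
    n_measurements = nrow(cohort),
    n_patients = length(seq_len_pat),
    sepsis_prevalence = n_sep / nrow(cohort),
    singleton_sepsis_fraction = singleton_frac,
    last_position_sepsis_fraction = last_frac,
    sequence_length_histogram = table(as.vector(seq_len_pat)),
    undefined = undefined
  )
}

# ---- serialization ---------------------------------------------------------

#' Write a cohort to CSV
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces the doubles exactly.
#'
#' @param cohort A `cbc_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in c("age", "hemoglobin", "rbc", "wbc", "mcv", "platelets")) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out[, cohort_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Expects the exact column set
#' `patient_id,position,age,sex,hemoglobin,rbc,wbc,mcv,platelets,label,split`;
#' missing or extra columns, or non-numeric cells in numeric columns, raise a
#' parse error naming the offending column (and row).
#'
#' @param path CSV path written by [write_cohort()] (or compatible).
#' @return A `cbc_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- cohort_columns()
  missing_cols <- setdiff(need, names(raw))
  extra_cols <- setdiff(names(raw), need)
  if (length(missing_cols)) {
    stop(sprintf("cohort file is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(extra_cols)) {
    stop(sprintf("cohort file has unexpected column(s): %s",
                 paste(extra_cols, collapse = ", ")))
  }
  raw <- raw[, need]
  num_cols <- c("position", "age", "sex", "hemoglobin", "rbc", "wbc", "mcv",
                "platelets", "label")
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]) & nzchar(raw[[nm]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column `%s`, row %d",
                   raw[[nm]][bad[1]], nm, bad[1]))
    }
    raw[[nm]] <- v
  }
  raw$position <- as.integer(raw$position)
  raw$sex <- as.integer(raw$sex)
  raw$label <- as.integer(raw$label)
  class(raw) <- c("cbc_cohort", "data.frame")
  raw
}
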