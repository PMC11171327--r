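#' Growth parameters for a simulated tumor trajectory
#'
#' The simulated volume follows a piecewise-exponential model measured from
#' treatment start (day 0 is both enrollment and first-dose day; growth before
#' enrollment is not modeled).  Untreated (control) tumors grow at
#' `k_control` throughout.  Treated tumors regress at `k_regress` (<= 0) for
#' `effect_days`, then regrow at `k_regrow`.  Measured volumes carry
#' multiplicative lognormal noise (caliper error scales with tumor size), and
#' a model volume below `detect_floor` is recorded as exactly 0, emulating a
#' tumor too small to measure.
#'
#' @param v0 Baseline volume at day 0, mm^3; must be >= 100 (enrollment rule).
#' @param k_control Per-day exponential growth rate of the untreated tumor.
#' @param k_regress Per-day rate during drug effect (<= 0 for regression).
#' @param effect_days Duration of drug effect in days; 0 means no treatment
#'   effect and the tumor grows at `k_control` throughout.
#' @param k_regrow Per-day regrowth rate after the drug effect wears off.
#' @param cv_noise Coefficient of variation of the multiplicative lognormal
#'   measurement noise; 0 gives noise-free closed-form trajectories.
#' @param measure_interval_days Measurement cadence in days (weekly caliper
#'   schedule by default).
#' @param horizon_days Study horizon in days.
#' @param treatment_end_day Last scheduled dosing day (default 7: one dose on
#'   day 1 plus five daily doses from day 3).
#' @param detect_floor Volume in mm^3 below which a tumor is recorded as
#'   unmeasurable (exactly 0).
#' @param seed Integer seed making the trajectory reproducible.
#' @return An object of class `"growth_params"`.
#' @export
growth_params <- function(v0 = 150, k_control = 0.1, k_regress = 0,
                          effect_days = 0, k_regrow = k_control,
                          cv_noise = 0.15, measure_interval_days = 7L,
                          horizon_days = 91, treatment_end_day = 7,
                          detect_floor = 1, seed = 1L) {
  if (v0 < 100)
    stop("v0 must be >= 100 mm^3 (enrollment threshold)", call. = FALSE)
  if (measure_interval_days < 1)
    stop("measure_interval_days must be >= 1", call. = FALSE)
  if (cv_noise < 0) stop("cv_noise must be >= 0", call. = FALSE)
  if (effect_days < 0) stop("effect_days must be >= 0", call. = FALSE)
  if (k_regress > 0)
    stop("k_regress must be <= 0 (regression during drug effect)",
         call. = FALSE)
  structure(
    list(v0 = v0, k_control = k_control, k_regress = k_regress,
         effect_days = effect_days, k_regrow = k_regrow,
         cv_noise = cv_noise,
         measure_interval_days = as.integer(measure_interval_days),
         horizon_days = horizon_days,
         treatment_end_day = treatment_end_day,
         detect_floor = detect_floor, seed = as.integer(seed)),
    class = "growth_params")
}

# Noise-free model volume at time t under the piecewise-exponential law.
model_volume <- function(p, t) {
  if (p$effect_days <= 0) return(p$v0 * exp(p$k_control * t))
  ifelse(t <= p$effect_days,
         p$v0 * exp(p$k_regress * t),
         p$v0 * exp(p$k_regress * p$effect_days) *
           exp(p$k_regrow * (t - p$effect_days)))
}

#' Simulate one tumor-volume trajectory
#'
#' Volumes are the piecewise-exponential model volume times an i.i.d.
#' lognormal factor with log-scale sd `cv_noise` (median 1), measured on the
#' weekly grid up to the study horizon.  The series is truncated at the first
#' measurement reaching 400% of baseline (the study-termination rule): no
#' measurement after the first quadrupling is recorded.  Model volumes below
#' the detection floor are recorded as exactly 0.
#'
#' @param params A [growth_params()] object.
#' @return A [trajectory()].
#' @examples
#' p <- growth_params(v0 = 100, k_control = 0.1, cv_noise = 0, seed = 1)
#' simulate_trajectory(p)$volumes  # 100, 201.4, 405.5 -> truncated at day 14
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  p <- params
  days <- seq(0, p$horizon_days, by = p$measure_interval_days)
  vm <- model_volume(p, days)
  eps <- if (p$cv_noise > 0) {
    set.seed(p$seed)
    exp(stats::rnorm(length(days), mean = 0, sd = p$cv_noise))
  } else rep(1, length(days))
  v <- pmax(0, vm * eps)
  v[v < p$detect_floor] <- 0
  v[1] <- max(v[1], p$detect_floor)          # baseline is measurable by design
  hit <- which(v >= 4 * v[1])
  if (length(hit)) {
    keep <- seq_len(hit[1])
    days <- days[keep]; v <- v[keep]
  }
  trajectory(days = days, volumes = v, treatment_end_day = p$treatment_end_day)
}

#' Archetype growth parameters for each response category
#'
#' Returns noise-capable parameter sets whose noise-free trajectories are
#' classified exactly as the requested category, used for classifier recovery
#' tests and demonstration cohorts.
#'
#' @param category One of `"PD"`, `"SD"`, `"PR"`, `"CR"`, `"MCR"`.
#' @param cv_noise Measurement noise CV (default 0, the deterministic
#'   archetype).
#' @param seed Seed stored in the parameter set.
#' @return A [growth_params()] object.
#' @export
archetype_params <- function(category, cv_noise = 0, seed = 1L) {
  category <- match.arg(category, c("PD", "SD", "PR", "CR", "MCR"))
  base <- list(v0 = 150, cv_noise = cv_noise, seed = seed, horizon_days = 91)
  args <- switch(category,
    PD  = list(k_control = 0.1, effect_days = 0),
    SD  = list(k_regress = 0, effect_days = 91, k_regrow = 0),
    PR  = list(k_regress = -0.10, effect_days = 14, k_regrow = 0.08),
    CR  = list(k_regress = -0.40, effect_days = 18, k_regrow = 0.45),
    MCR = list(k_regress = -0.35, effect_days = 91, k_regrow = 0))
  do.call(growth_params, c(base, args))
}

#' Cohort specification
#'
#' @param arms A list of arms, each a list with fields `arm` (name), `params`
#'   (a [growth_params()]), `n` (animals, >= 1), and optionally `archetype`
#'   (intended response category, for recovery tests).
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(arms) {
  for (a in arms) {
    if (is.null(a$arm) || is.null(a$params) || is.null(a$n))
      stop("each arm needs fields `arm`, `params`, `n`", call. = FALSE)
    if (a$n < 1) stop("n_animals must be >= 1", call. = FALSE)
    stopifnot(inherits(a$params, "growth_params"))
  }
  structure(list(arms = arms), class = "cohort_spec")
}

# Deterministic sub-seed scheme: the master seed plus a stride-97 counter,
# reduced modulo the largest representable integer.
sub_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 97 * counter) %% .Machine$integer.max)
}

#' Simulate a multi-arm cohort
#'
#' Each animal gets an independent sub-seed derived from the master seed by a
#' fixed counter scheme, so the whole cohort is reproducible and individual
#' animals can be re-simulated in isolation.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed.
#' @param model_id Model identifier stamped on every trajectory.
#' @return List of [trajectory()] objects.
#' @export
simulate_cohort <- function(spec, seed = 1L, model_id = "model") {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  counter <- 0L
  for (a in spec$arms) {
    for (j in seq_len(a$n)) {
      counter <- counter + 1L
      p <- a$params
      p$seed <- sub_seed(seed, counter)
      tr <- simulate_trajectory(p)
      tr$arm <- a$arm
      tr$animal_id <- sprintf("%s_%02d", a$arm, j)
      tr$model_id <- model_id
      out[[counter]] <- tr
    }
  }
  out
}

#' Simulate a dose-response plate
#'
#' Signals follow a four-parameter logistic curve with multiplicative
#' Gaussian noise: `signal = 4PL(conc) * (1 + N(0, cv))`.
#'
#' @param top,bottom,hill,ic50 True 4PL parameters.
#' @param concentrations Dose vector (same unit as `ic50`); zeros allowed
#'   (signal at zero dose is `top`).
#' @param cv Noise coefficient of variation (0 = noise-free).
#' @param replicates Technical replicates per dose.
#' @param seed Integer seed.
#' @return A data.frame with columns `concentration`, `replicate`, `signal`.
#' @export
simulate_dose_response <- function(top = 1, bottom = 0, hill = 1, ic50 = 100,
                                   concentrations = 10^seq(-1, 3.5,
                                                           length.out = 8),
                                   cv = 0, replicates = 1L, seed = 1L) {
  conc <- rep(concentrations, each = replicates)
  mu <- four_pl(conc, top = top, bottom = bottom, hill = hill, ic50 = ic50)
  if (cv > 0) {
    set.seed(seed)
    mu <- mu * (1 + stats::rnorm(length(mu), sd = cv))
  }
  data.frame(concentration = conc,
             replicate = rep(seq_len(replicates), times = length(concentrations)),
             signal = mu)
}

#' Simulate a read-pair alignment summary table
#'
#' Builds per-read-pair alignment metrics (score, mismatches, matched length,
#' summed over mates) against the human and mouse genomes with known true
#' origin, for testing graft/host read disambiguation.  Unambiguous pairs
#' score at least `score_margin` higher on their true genome; ambiguous pairs
#' have identical metrics on both.
#'
#' @param n_human,n_mouse,n_ambiguous Pair counts per class.
#' @param score_margin Minimum score advantage of the true genome for
#'   unambiguous pairs.
#' @param seed Integer seed.
#' @return A data.frame with columns `read_id`, `score_h`, `nm_h`, `mlen_h`,
#'   `aligned_h`, `score_m`, `nm_m`, `mlen_m`, `aligned_m`, `true_origin`.
#' @export
simulate_read_pairs <- function(n_human = 100, n_mouse = 100,
                                n_ambiguous = 20, score_margin = 5,
                                seed = 1L) {
  set.seed(seed)
  n <- n_human + n_mouse + n_ambiguous
  origin <- rep(c("human", "mouse", "ambiguous"),
                c(n_human, n_mouse, n_ambiguous))
  base_score <- round(stats::runif(n, 150, 200))
  nm <- stats::rpois(n, 2)
  mlen <- round(stats::runif(n, 150, 200))
  margin <- score_margin + round(stats::runif(n, 0, 20))
  df <- data.frame(read_id = sprintf("rp%05d", seq_len(n)),
                   score_h = base_score, nm_h = nm, mlen_h = mlen,
                   aligned_h = TRUE,
                   score_m = base_score, nm_m = nm, mlen_m = mlen,
                   aligned_m = TRUE,
                   true_origin = origin, stringsAsFactors = FALSE)
  h <- origin == "human"; m <- origin == "mouse"
  df$score_m[h] <- df$score_m[h] - margin[h]
  df$score_h[m] <- df$score_h[m] - margin[m]
  df
}
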