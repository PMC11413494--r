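# Synthetic trial generator. Emulates the statistical structure of
# strike-simulator field trials: species-specific jump propensities,
# timing and performance distributions (truncated normals parameterized by
# published mean +/- SE and per-metric n), forward ballistics for jump
# displacement/airborne time, tape-measure rounding (0.01 m) and
# frame-period quantization with +/- 2 frames of digitization error.

FIXED_TRIAL_COLUMNS <- c(
  "species", "individual_id", "mass_g", "fps", "mode",
  "reaction_ms", "takeoff_ms", "displacement_m", "airborne_s",
  "hit_by_cork", "premature", "offscreen", "poor_video"
)

# Inverse-CDF truncated normal draw; deterministic under the session RNG.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Closed-form mean of a truncated Normal(mean, sd) on [lower, upper].
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Read a species-profile table
#'
#' A species profile holds the generative parameters for one species: body
#' mass (g), jump propensity, reaction-time and take-off-time moments (ms),
#' and — for species whose jumps were measurable — take-off speed (m/s) and
#' angle (degrees). Moments are given as mean and standard error with the
#' per-metric sample size `n_*`; the generator recovers the population SD
#' as `se * sqrt(n)`. `takeoff_scramble_mean_ms`, when present, gives a
#' separate mean take-off time for scramble maneuvers (scrambles require
#' reorienting before escape and are slower than jumps).
#'
#' @param path CSV file with the profile columns (see the packaged default,
#'   `system.file("extdata", "species_profiles.csv", package = "escapekin")`)
#' @return data.frame of validated species profiles
#' @export
read_species_profiles <- function(path) {
  prof <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_profiles(prof)
  prof
}

#' Default species profiles
#'
#' Generative parameters for the six study species: three kangaroo rats
#' (DIME, DIDE, DISP), desert pocket mouse (CHPE), white-throated woodrat
#' (NEAL) and California ground squirrel (OTBE). Timing/performance moments
#' and per-metric sample sizes follow the study's summary table; jump
#' propensities follow the observed per-species jump/trial counts; the
#' ground squirrel is recorded at 120 fps and the others at 240-250 fps.
#' Woodrats and ground squirrels have no jump performance parameters
#' because they almost never jumped.
#'
#' @return data.frame of species profiles
#' @export
default_species_profiles <- function() {
  path <- system.file("extdata", "species_profiles.csv",
                      package = "escapekin", mustWork = TRUE)
  read_species_profiles(path)
}

validate_profiles <- function(prof) {
  required <- c("species", "mass_mean_g", "mass_se_g", "n_mass",
                "jump_propensity", "reaction_mean_ms", "reaction_se_ms",
                "n_reaction", "takeoff_mean_ms", "takeoff_se_ms",
                "n_takeoff", "fps")
  missing <- setdiff(required, names(prof))
  if (length(missing))
    stop("profile table lacks columns: ", paste(missing, collapse = ", "))
  bad_code <- !grepl("^[A-Z]{4}$", prof$species)
  if (any(bad_code))
    stop("unknown species_code (expected a 4-letter code): ",
         paste(prof$species[bad_code], collapse = ", "))
  if (anyDuplicated(prof$species))
    stop("duplicated species codes in profile table")
  if (any(prof$jump_propensity < 0 | prof$jump_propensity > 1, na.rm = TRUE) ||
      anyNA(prof$jump_propensity))
    stop("jump_propensity must lie in [0, 1]")
  if (!all(prof$fps %in% c(120, 240, 250)))
    stop("fps must be one of 120, 240, 250")
  pos_cols <- c("mass_mean_g", "mass_se_g", "reaction_mean_ms",
                "reaction_se_ms", "takeoff_mean_ms", "takeoff_se_ms",
                "speed_mean_ms1", "speed_se_ms1",
                "angle_mean_deg", "angle_se_deg")
  for (cl in intersect(pos_cols, names(prof))) {
    v <- prof[[cl]]
    if (any(v <= 0, na.rm = TRUE))
      stop("profile column ", cl, " must be > 0 where present")
  }
  invisible(prof)
}

#' Censoring rates for simulated trials
#'
#' Probabilities that a trial is censored for each of the reasons seen in
#' field data: the cork strikes the animal before it reacts
#' (`p_hit_by_cork`), the animal moves before the cork does
#' (`p_premature_react`), the jump lands off-screen (`p_offscreen`), and
#' the video is too poor to score (`p_poor_video`). Defaults approximate
#' the rates at which such trials occur in strike-simulator field work
#' (hits are the most common, premature reactions rare).
#'
#' @param p_hit_by_cork,p_premature_react,p_offscreen,p_poor_video
#'   probabilities in \[0, 1\]
#' @return list of class `censoring_rates`
#' @export
censoring_rates <- function(p_hit_by_cork = 0.10, p_premature_react = 0.01,
                            p_offscreen = 0.04, p_poor_video = 0.05) {
  p <- c(p_hit_by_cork, p_premature_react, p_offscreen, p_poor_video)
  if (any(p < 0 | p > 1))
    stop("censoring rates must lie in [0, 1]")
  structure(list(p_hit_by_cork = p_hit_by_cork,
                 p_premature_react = p_premature_react,
                 p_offscreen = p_offscreen,
                 p_poor_video = p_poor_video),
            class = "censoring_rates")
}

#' Generate a synthetic trial table
#'
#' Simulates `n_per_species` strike-simulator trials for every species in
#' `profiles`. Escape mode is Bernoulli in the species' jump propensity.
#' Reaction and take-off times are truncated normal (lower bound 4 ms) with
#' SD recovered as `se * sqrt(n)`; where a profile provides a separate
#' scramble take-off mean, scrambles use it. For jumps of species with
#' performance parameters, take-off speed (truncated > 0) and angle
#' (truncated to (0, 90) degrees) are drawn and converted to horizontal
#' displacement and airborne time by [forward_ballistics()], so the latent
#' trial obeys the ballistic equations exactly. Measurement noise is then
#' applied: displacement rounded to 0.01 m (tape measure) and every timing
#' quantized to the species frame period with a uniform jitter of up to 2
#' frames either way (digitization error).
#'
#' Censored fields are set to `NA` with the corresponding flag raised:
#' a cork hit or poor video hides the timing fields, an off-screen landing
#' or poor video hides the performance fields, a premature reaction hides
#' reaction time.
#'
#' The latent (noise-free) jump parameters are attached as
#' `attr(x, "latent")` for diagnostic use.
#'
#' @param profiles species-profile data.frame (see
#'   [default_species_profiles()])
#' @param n_per_species trials per species (>= 1)
#' @param censoring a [censoring_rates()] object
#' @param seed integer seed; identical inputs and seed give identical output
#' @param measurement_noise set `FALSE` to skip rounding/quantization
#' @return data.frame with the fixed trial columns
#' @export
generate_trials <- function(profiles, n_per_species,
                            censoring = censoring_rates(), seed,
                            measurement_noise = TRUE) {
  validate_profiles(profiles)
  if (!inherits(censoring, "censoring_rates"))
    censoring <- do.call(censoring_rates, as.list(censoring))
  stopifnot(n_per_species >= 1, length(n_per_species) == 1)
  if (missing(seed) || is.null(seed)) stop("seed is required")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  out <- vector("list", nrow(profiles))
  latents <- vector("list", nrow(profiles))
  row_offset <- 0L
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    n <- as.integer(n_per_species)
    period_ms <- 1000 / p$fps

    mass <- pmax(round(rtruncnorm(
      n, p$mass_mean_g, p$mass_se_g * sqrt(p$n_mass), lower = 0)), 1)
    jumped <- stats::runif(n) < p$jump_propensity
    mode <- ifelse(jumped, "jump", "scramble")

    reaction <- rtruncnorm(
      n, p$reaction_mean_ms, p$reaction_se_ms * sqrt(p$n_reaction), lower = 4)
    to_mean <- rep(p$takeoff_mean_ms, n)
    scr_mean <- if ("takeoff_scramble_mean_ms" %in% names(p))
      p$takeoff_scramble_mean_ms else NA_real_
    if (!is.na(scr_mean)) to_mean[!jumped] <- scr_mean
    takeoff <- rtruncnorm(
      n, to_mean, p$takeoff_se_ms * sqrt(p$n_takeoff), lower = 4)

    displacement <- rep(NA_real_, n)
    airborne <- rep(NA_real_, n)
    has_perf <- all(c("speed_mean_ms1", "angle_mean_deg") %in% names(p)) &&
      !is.na(p$speed_mean_ms1) && !is.na(p$angle_mean_deg)
    lat <- NULL
    if (has_perf && any(jumped)) {
      nj <- sum(jumped)
      speed <- rtruncnorm(nj, p$speed_mean_ms1,
                          p$speed_se_ms1 * sqrt(p$n_speed), lower = 0)
      angle <- rtruncnorm(nj, p$angle_mean_deg,
                          p$angle_se_deg * sqrt(p$n_angle),
                          lower = 0, upper = 90)
      fb <- forward_ballistics(speed, angle)
      displacement[jumped] <- fb$displacement_m
      airborne[jumped] <- fb$airborne_s
      lat <- data.frame(
        row = row_offset + which(jumped), species = p$species,
        speed = speed, angle_deg = angle,
        displacement_m = fb$displacement_m, airborne_s = fb$airborne_s)
    }

    if (measurement_noise) {
      jit_r <- sample(-2:2, n, replace = TRUE)
      jit_t <- sample(-2:2, n, replace = TRUE)
      jit_a <- sample(-2:2, n, replace = TRUE)
      reaction <- pmax(round(reaction / period_ms) + jit_r, 0) * period_ms
      takeoff <- pmax(round(takeoff / period_ms) + jit_t, 1) * period_ms
      meas <- !is.na(airborne)
      airborne[meas] <- pmax(round(airborne[meas] * p$fps) + jit_a[meas], 1) /
        p$fps
      displacement <- round(displacement, 2)
    }

    hit <- stats::runif(n) < censoring$p_hit_by_cork
    premature <- !hit & stats::runif(n) < censoring$p_premature_react
    offscreen <- jumped & stats::runif(n) < censoring$p_offscreen
    poor <- stats::runif(n) < censoring$p_poor_video

    reaction[hit | premature | poor] <- NA_real_
    takeoff[hit | poor] <- NA_real_
    displacement[offscreen | poor] <- NA_real_
    airborne[offscreen | poor] <- NA_real_

    out[[i]] <- data.frame(
      species = p$species,
      individual_id = sprintf("%s_%03d", p$species, seq_len(n)),
      mass_g = mass, fps = p$fps, mode = mode,
      reaction_ms = reaction, takeoff_ms = takeoff,
      displacement_m = displacement, airborne_s = airborne,
      hit_by_cork = hit, premature = premature,
      offscreen = offscreen, poor_video = poor,
      stringsAsFactors = FALSE)
    latents[[i]] <- lat
    row_offset <- row_offset + n
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  lat_all <- do.call(rbind, latents[!vapply(latents, is.null, logical(1))])
  attr(trials, "latent") <- lat_all
  trials
}

#' Expected trial means implied by a species profile
#'
#' Closed-form expectations of the generated (pre-noise) metrics:
#' truncated-normal means for reaction time, take-off time (a
#' propensity-weighted mixture of jump and scramble means when the profile
#' separates them), take-off speed and take-off angle. Used to check
#' parameter recovery of the simulation/analysis round trip.
#'
#' @param profile one profile row
#' @return named list of expected means (NA where the profile lacks the
#'   metric)
#' @export
expected_trial_means <- function(profile) {
  p <- profile
  reaction <- truncnorm_mean(p$reaction_mean_ms,
                             p$reaction_se_ms * sqrt(p$n_reaction), lower = 4)
  sd_t <- p$takeoff_se_ms * sqrt(p$n_takeoff)
  to_jump <- truncnorm_mean(p$takeoff_mean_ms, sd_t, lower = 4)
  scr_mean <- if ("takeoff_scramble_mean_ms" %in% names(p) &&
                  !is.na(p$takeoff_scramble_mean_ms))
    p$takeoff_scramble_mean_ms else p$takeoff_mean_ms
  to_scr <- truncnorm_mean(scr_mean, sd_t, lower = 4)
  takeoff <- p$jump_propensity * to_jump + (1 - p$jump_propensity) * to_scr
  speed <- angle <- NA_real_
  if (all(c("speed_mean_ms1", "angle_mean_deg") %in% names(p)) &&
      !is.na(p$speed_mean_ms1) && !is.na(p$angle_mean_deg)) {
    speed <- truncnorm_mean(p$speed_mean_ms1,
                            p$speed_se_ms1 * sqrt(p$n_speed), lower = 0)
    angle <- truncnorm_mean(p$angle_mean_deg,
                            p$angle_se_deg * sqrt(p$n_angle),
                            lower = 0, upper = 90)
  }
  list(reaction_ms = reaction, takeoff_ms = takeoff,
       takeoff_ms_jump = to_jump, takeoff_ms_scramble = to_scr,
       takeoff_speed = speed, takeoff_angle_deg = angle)
}
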