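# End-to-end orchestration: trial-table I/O, the study's exclusion rules,
# jump-frequency accounting, and the full analysis report.

#' @keywords internal
validate_trials <- function(trials) {
  missing <- setdiff(FIXED_TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  dup <- duplicated(trials$individual_id)
  if (any(dup))
    stop("duplicate individual_id (each animal is tested once): ",
         paste(unique(trials$individual_id[dup]), collapse = ", "))
  bad_mode <- !trials$mode %in% c("jump", "scramble")
  if (any(bad_mode))
    stop("invalid mode token at row(s) ",
         paste(which(bad_mode), collapse = ", "),
         ": ", paste(unique(trials$mode[bad_mode]), collapse = ", "))
  scr_disp <- trials$mode == "scramble" & !is.na(trials$displacement_m)
  if (any(scr_disp))
    stop("scramble trials must not carry a displacement (row(s) ",
         paste(which(scr_disp), collapse = ", "), ")")
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' Expects the fixed trial header written by [write_trials()] /
#' [generate_trials()]. Structural problems (missing columns, duplicated
#' individual ids, unknown mode tokens) are rejected with the offending
#' row numbers.
#'
#' @param path CSV file path
#' @return validated trial data.frame
#' @export
read_trials <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    # zero-byte file: empty table with the fixed schema
    return(empty_trial_table())
  }
  header <- gsub("\"", "", strsplit(first, ",", fixed = TRUE)[[1]])
  missing <- setdiff(FIXED_TRIAL_COLUMNS, header)
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(species = "character",
                                           individual_id = "character",
                                           mode = "character"))
  if (nrow(trials) == 0) {
    missing <- setdiff(FIXED_TRIAL_COLUMNS, names(trials))
    if (length(missing))
      stop("trial table lacks columns: ", paste(missing, collapse = ", "))
    return(empty_trial_table())
  }
  for (cl in c("hit_by_cork", "premature", "offscreen", "poor_video"))
    trials[[cl]] <- as.logical(trials[[cl]])
  for (cl in c("mass_g", "fps", "reaction_ms", "takeoff_ms",
               "displacement_m", "airborne_s"))
    trials[[cl]] <- as.numeric(trials[[cl]])
  validate_trials(trials)
  trials
}

empty_trial_table <- function() {
  data.frame(species = character(), individual_id = character(),
             mass_g = numeric(), fps = numeric(), mode = character(),
             reaction_ms = numeric(), takeoff_ms = numeric(),
             displacement_m = numeric(), airborne_s = numeric(),
             hit_by_cork = logical(), premature = logical(),
             offscreen = logical(), poor_video = logical(),
             stringsAsFactors = FALSE)
}

#' Write a trial table to CSV
#'
#' @param trials trial data.frame
#' @param path output CSV path
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, FIXED_TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' Filter trials for the reaction/take-off time analyses
#'
#' Removes trials in which the animal was struck by the cork before
#' reacting, reacted before the cork moved, or the video was too poor to
#' score. Both escape modes (jumps and scrambles) are retained. The number
#' of rows removed by each rule (first matching rule counts) is attached
#' as `attr(x, "exclusions")`.
#'
#' @param trials trial data.frame
#' @return filtered subset with an `exclusions` attribute
#' @export
filter_for_reaction <- function(trials) {
  validate_trials(trials)
  rule <- ifelse(trials$hit_by_cork, "hit_by_cork",
          ifelse(trials$premature, "premature",
          ifelse(trials$poor_video, "poor_video", "kept")))
  out <- trials[rule == "kept", , drop = FALSE]
  excl <- c(hit_by_cork = sum(rule == "hit_by_cork"),
            premature = sum(rule == "premature"),
            poor_video = sum(rule == "poor_video"))
  attr(out, "exclusions") <- excl
  out
}

#' Filter trials for the jump-performance analyses
#'
#' Keeps jump trials whose landing stayed on screen, whose video quality
#' was adequate, and whose displacement and airborne time were measured.
#' Scrambles, off-screen jumps, poor-video trials and jumps missing a
#' measurement are removed; per-rule counts (first matching rule) are
#' attached as `attr(x, "exclusions")`.
#'
#' @param trials trial data.frame
#' @return filtered subset with an `exclusions` attribute
#' @export
filter_for_performance <- function(trials) {
  validate_trials(trials)
  rule <- ifelse(trials$mode != "jump", "scramble",
          ifelse(trials$offscreen, "offscreen",
          ifelse(trials$poor_video, "poor_video",
          ifelse(is.na(trials$displacement_m) | is.na(trials$airborne_s),
                 "missing_measurement", "kept"))))
  out <- trials[rule == "kept", , drop = FALSE]
  excl <- c(scramble = sum(rule == "scramble"),
            offscreen = sum(rule == "offscreen"),
            poor_video = sum(rule == "poor_video"),
            missing_measurement = sum(rule == "missing_measurement"))
  attr(out, "exclusions") <- excl
  out
}

# round to nearest integer, ties away from zero (matches reported percents,
# e.g. 30/48 -> 62.5 -> 63)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-species jump frequencies
#'
#' Counts jumps and trials per species and reports the jump percentage,
#' rounded to the nearest integer (ties away from zero). A species with
#' zero trials gets an `NA` percentage.
#'
#' @param trials trial data.frame
#' @return data.frame with `species`, `jumps`, `trials`, `percent`
#' @export
jump_frequency <- function(trials) {
  validate_trials(trials)
  species <- sort(unique(trials$species))
  out <- do.call(rbind, lapply(species, function(sp) {
    sel <- trials$species == sp
    nt <- sum(sel)
    nj <- sum(trials$mode[sel] == "jump")
    data.frame(species = sp, jumps = nj, trials = nt,
               percent = if (nt > 0) round_half_away(100 * nj / nt)
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Analysis configuration
#'
#' @param metrics performance metrics to size-correct and feed to the
#'   PERMANOVA. The default set is take-off time, take-off angle and jump
#'   height; `c("takeoff_speed", "jump_height_m", "takeoff_angle_deg")` is
#'   the alternative velocity-based set.
#' @param n_perm PERMANOVA permutations
#' @param seed seed for the permutation null
#' @param alpha significance level for Tukey letter displays
#' @param logistic_species species used for the jump-probability logistic
#'   regression and the scramble-vs-jump comparison; `NULL` picks the
#'   species with the largest balanced sample of both maneuvers (at least
#'   `min_mode_n` of each)
#' @param min_mode_n minimum per-mode sample size for the mode analyses
#' @param min_perf_n minimum measured jumps for a species to enter the
#'   multivariate performance comparison
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(metrics = c("takeoff_ms", "takeoff_angle_deg",
                                        "jump_height_m"),
                            n_perm = 999, seed = 1L, alpha = 0.05,
                            logistic_species = NULL, min_mode_n = 5L,
                            min_perf_n = 2L) {
  known <- c("takeoff_ms", "takeoff_speed", "jump_height_m",
             "takeoff_angle_deg")
  bad <- setdiff(metrics, known)
  if (length(bad))
    stop("unknown performance metric(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")")
  if (length(metrics) < 2) stop("need at least 2 performance metrics")
  structure(list(metrics = metrics, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), alpha = alpha,
                 logistic_species = logistic_species,
                 min_mode_n = as.integer(min_mode_n),
                 min_perf_n = as.integer(min_perf_n)),
            class = "analysis_config")
}

# djb2 string hash, for config provenance
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Run the full escape-response analysis
#'
#' Orchestrates the whole pipeline on a trial table: per-species jump
#' frequencies; a mean +/- SE summary table; the multivariate jump
#' performance comparison (ballistic reconstruction, allometric size
#' correction, unit standardization, PERMANOVA across species); one-way
#' linear models with Tukey HSD letter displays for reaction time and
#' take-off time; and, for the species with an adequate sample of both
#' maneuvers, a logistic regression of jump probability on reaction time
#' and a scramble-vs-jump take-off time comparison.
#'
#' Sections are present only when their preconditions hold: the PERMANOVA
#' needs at least two species with `min_perf_n` measured jumps each
#' (species that almost never jump drop out, as in field data sets), and
#' the mode analyses need a species with both maneuvers well represented.
#'
#' @param trials trial data.frame
#' @param config an [analysis_config()]
#' @return list of class `analysis_report`
#' @export
run_full_analysis <- function(trials, config = analysis_config()) {
  if (!inherits(config, "analysis_config"))
    config <- do.call(analysis_config, config)
  validate_trials(trials)

  report <- list()
  report$jump_frequency <- jump_frequency(trials)
  report$summary <- summarize_trials(trials)

  # --- timing analyses (reaction, take-off) ---------------------------------
  rt <- filter_for_reaction(trials)
  report$exclusions <- list(reaction = as.list(attr(rt, "exclusions")))
  report$reaction <- timing_section(rt$reaction_ms, rt$species, config)
  report$takeoff <- timing_section(rt$takeoff_ms, rt$species, config)

  # --- multivariate jump performance ----------------------------------------
  pf <- filter_for_performance(trials)
  report$exclusions$performance <- as.list(attr(pf, "exclusions"))
  no_mass <- is.na(pf$mass_g)
  report$exclusions$performance$missing_mass <- sum(no_mass)
  pf <- pf[!no_mass, , drop = FALSE]
  perf <- NULL
  if (nrow(pf) > 0) {
    kin <- compute_kinematics(pf$displacement_m, pf$airborne_s)
    pf <- cbind(pf, kin)
    # a censored metric (e.g. take-off time on a cork-hit trial) drops the
    # row from the multivariate comparison
    complete <- stats::complete.cases(pf[, config$metrics])
    report$exclusions$performance$missing_metric <- sum(!complete)
    pf <- pf[complete, , drop = FALSE]
    counts <- table(pf$species)
    keep_sp <- names(counts)[counts >= config$min_perf_n]
    dropped <- setdiff(names(counts), keep_sp)
    pf_in <- pf[pf$species %in% keep_sp, , drop = FALSE]
    report$exclusions$performance$species_below_min <- nrow(pf) - nrow(pf_in)
    if (length(keep_sp) >= 2) {
      mat <- performance_matrix(pf_in, config$metrics)
      pmv <- permanova(mat, pf_in$species, n_perm = config$n_perm,
                       seed = config$seed)
      perf <- list(metrics = config$metrics,
                   species_included = keep_sp,
                   species_excluded = dropped,
                   n_rows = nrow(pf_in),
                   permanova = unclass(pmv))
    } else {
      perf <- list(metrics = config$metrics, species_included = keep_sp,
                   species_excluded = dropped, n_rows = nrow(pf_in),
                   permanova = NULL,
                   note = "fewer than 2 species with enough measured jumps")
    }
  }
  report$performance <- perf

  # --- escape-mode analyses -------------------------------------------------
  report$mode_analysis <- mode_section(rt, config)

  report$provenance <- list(
    seed = config$seed, n_perm = config$n_perm, alpha = config$alpha,
    metrics = config$metrics, config_hash = config_hash(config),
    n_input = nrow(trials))
  class(report) <- "analysis_report"
  report
}

timing_section <- function(values, species, config) {
  keep <- !is.na(values)
  values <- values[keep]
  species <- species[keep]
  counts <- table(species)
  ok_sp <- names(counts)[counts >= 2]
  if (length(ok_sp) < 2)
    return(list(anova = NULL, tukey = NULL,
                note = "fewer than 2 species with n >= 2"))
  sel <- species %in% ok_sp
  an <- oneway_lm(values[sel], species[sel])
  tk <- tukey_hsd(values[sel], species[sel], alpha = config$alpha)
  an$group_means <- as.list(an$group_means)
  list(anova = an,
       tukey = list(table = tk$table, letters = as.list(tk$letters),
                    alpha = tk$alpha, df = tk$df))
}

mode_section <- function(rt, config) {
  sp <- config$logistic_species
  if (is.null(sp)) {
    # species with the largest balanced sample of jumps and scrambles
    cand <- vapply(unique(rt$species), function(s) {
      sel <- rt$species == s & !is.na(rt$reaction_ms)
      min(sum(rt$mode[sel] == "jump"), sum(rt$mode[sel] == "scramble"))
    }, numeric(1))
    if (!length(cand) || max(cand) < config$min_mode_n)
      return(list(species = NULL,
                  note = "no species with enough trials of both maneuvers"))
    sp <- names(cand)[which.max(cand)]
  }
  sel <- rt$species == sp
  out <- list(species = sp)
  re <- rt$reaction_ms[sel]
  mode <- rt$mode[sel]
  ok <- !is.na(re)
  if (length(unique(mode[ok])) == 2) {
    out$logistic <- logistic_jump(re[ok], mode[ok] == "jump")
    out$reaction_mean_jump <- mean(re[ok & mode == "jump"])
    out$reaction_mean_scramble <- mean(re[ok & mode == "scramble"])
  } else {
    out$logistic <- NULL
    out$note <- "only one maneuver present after filtering"
  }
  to <- rt$takeoff_ms[sel]
  ok_to <- !is.na(to)
  if (all(c("jump", "scramble") %in% mode[ok_to]))
    out$scramble_vs_jump <- scramble_vs_jump(to[ok_to], mode[ok_to])
  out
}

# Recursively turn named atomic vectors into lists so JSON keeps the names.
sanitize_for_json <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, sanitize_for_json))
  if (is.atomic(x) && !is.null(names(x)) && length(x) > 1)
    return(as.list(x))
  x
}

#' Write an analysis report to JSON
#'
#' Serialization is deterministic: identical reports give byte-identical
#' files.
#'
#' @param report an `analysis_report` (or any list)
#' @param path output JSON path
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(sanitize_for_json(unclass(report)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null", null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Escape-response analysis report\n")
  cat("  trials:", x$provenance$n_input, "\n")
  cat("  jump frequency:\n")
  print(x$jump_frequency)
  if (!is.null(x$performance$permanova))
    cat(sprintf("  PERMANOVA: pseudo-F(%d, %d) = %.3g, p = %.3g\n",
                x$performance$permanova$df_between,
                x$performance$permanova$df_within,
                x$performance$permanova$pseudo_F,
                x$performance$permanova$p_value))
  if (!is.null(x$reaction$anova))
    cat(sprintf("  reaction time: F(%d, %d) = %.3g, p = %.3g\n",
                x$reaction$anova$df_between, x$reaction$anova$df_within,
                x$reaction$anova$F, x$reaction$anova$p))
  if (!is.null(x$takeoff$anova))
    cat(sprintf("  take-off time: F(%d, %d) = %.3g, p = %.3g\n",
                x$takeoff$anova$df_between, x$takeoff$anova$df_within,
                x$takeoff$anova$F, x$takeoff$anova$p))
  invisible(x)
}
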