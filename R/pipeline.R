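## Cohort-level drivers: run the per-animal pipeline over lists of
## recordings and assemble the tidy tables the statistical battery consumes.

#' Per-animal metrics and coordination for a list of recordings
#'
#' Runs [animal_metrics] and [coordination_report] on every recording and
#' binds the results into two tidy data frames.
#'
#' @param recs list of [emg_recording]s.
#' @param bandpass apply the acquisition band-pass (default TRUE; synthetic
#'   recordings are generated in-band, so this mainly exercises realism).
#' @param ... forwarded to [animal_metrics] / [coordination_report].
#' @return list with `metrics` (animal x muscle x parameter rows) and
#'   `coordination` (one interlimb + per-side intralimb row per animal).
#' @export
analyze_cohort <- function(recs, bandpass = TRUE, ...) {
  mm <- list(); cc <- list()
  for (rec in recs) {
    am <- animal_metrics(rec, bandpass = bandpass, ...)
    mm[[length(mm) + 1L]] <- am$metrics
    cr <- tryCatch(coordination_report(rec, bandpass = bandpass, ...),
                   error = function(e) NULL)
    if (!is.null(cr)) {
      df <- do.call(rbind, lapply(cr, as.data.frame))
      df <- cbind(data.frame(group = rec$group, condition = rec$condition),
                  df)
      cc[[length(cc) + 1L]] <- df
    }
  }
  list(metrics = do.call(rbind, mm), coordination = do.call(rbind, cc))
}

## Pull one per-animal column out of a tidy metrics table.
.metric_col <- function(metrics, muscle, parameter, what = "mean") {
  m <- metrics[metrics$muscle == muscle & metrics$parameter == parameter, ,
               drop = FALSE]
  stats::setNames(m[[what]], m$animal_id)
}

#' Treated-vs-control comparison battery
#'
#' Reproduces the between-group analysis on tidy cohort tables: Student's t
#' on cycle duration, burst duration and peak amplitude (per muscle) and on
#' their per-animal CVs; Mann-Whitney on coordination strength (r-values,
#' bounded in \[0, 1\]); Watson U-squared on the pooled interlimb phase
#' samples is left to the caller, which holds the phase sets.
#'
#' @param treated,control `analyze_cohort` results for the two cohorts.
#' @param muscles muscle channels to compare (default `"Sol-L"`, `"TA-L"`).
#' @return tidy data frame: `contrast`, `muscle`, `parameter`, `test_name`,
#'   `statistic`, `p_value`, `effect_direction`, `n_a`, `n_b`.
#' @export
compare_cohorts <- function(treated, control, muscles = c("Sol-L", "TA-L")) {
  rows <- list()
  push <- function(contrast, muscle, parameter, tst) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(contrast = contrast, muscle = muscle, parameter = parameter),
      as.data.frame(tst))
  }
  for (mus in muscles) {
    for (par in c("cycle_duration", "burst_duration", "peak_amplitude")) {
      a <- .metric_col(treated$metrics, mus, par)
      b <- .metric_col(control$metrics, mus, par)
      if (length(a) >= 2 && length(b) >= 2) {
        push("mean", mus, par, compare_groups(a, b, "student_t"))
        push("cv", mus, par,
             compare_cv(.metric_col(treated$metrics, mus, par, "cv"),
                        .metric_col(control$metrics, mus, par, "cv")))
      }
    }
  }
  for (pp in c("interlimb", "intralimb")) {
    a <- treated$coordination$r[treated$coordination$pairing == pp]
    b <- control$coordination$r[control$coordination$pairing == pp]
    if (length(a) >= 2 && length(b) >= 2)
      push("r_value", pp, "coordination_strength",
           compare_groups(a, b, "mann_whitney"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pre/post-drug ratio battery for a paired cohort
#'
#' For each animal's pre/post pair, runs the pipeline on both recordings and
#' expresses the post-drug value of each parameter as a ratio to the
#' pre-drug value: cycle duration, Sol/TA burst duration and peak amplitude,
#' and inter-/intralimb coordination strength (r). Ratios are then tested
#' against unity with [ratio_vs_unity].
#'
#' @param pairs list of `list(pre = , post = )` pairs from
#'   [apply_drug_effect].
#' @param ... forwarded to the per-animal pipeline.
#' @return list with `ratios` (animal x parameter data frame) and `tests`
#'   (one [ratio_vs_unity] row per parameter).
#' @export
drug_trial_battery <- function(pairs, ...) {
  one <- function(rec) {
    am <- animal_metrics(rec, ...)
    cr <- coordination_report(rec, ...)
    cdf <- do.call(rbind, lapply(cr, as.data.frame))
    list(metrics = am$metrics, coord = cdf)
  }
  grab <- function(res, muscle, parameter) {
    v <- res$metrics$mean[res$metrics$muscle == muscle &
                            res$metrics$parameter == parameter]
    if (length(v)) v[1] else NA_real_
  }
  grab_r <- function(res, pairing) {
    v <- res$coord$r[res$coord$pairing == pairing]
    if (length(v)) v[1] else NA_real_
  }
  rows <- lapply(pairs, function(pp) {
    pre <- one(pp$pre); post <- one(pp$post)
    data.frame(
      animal_id = pp$pre$animal_id,
      cycle_duration = grab(post, "Sol-L", "cycle_duration") /
        grab(pre, "Sol-L", "cycle_duration"),
      sol_burst_duration = grab(post, "Sol-L", "burst_duration") /
        grab(pre, "Sol-L", "burst_duration"),
      ta_burst_duration = grab(post, "TA-L", "burst_duration") /
        grab(pre, "TA-L", "burst_duration"),
      sol_peak_amplitude = grab(post, "Sol-L", "peak_amplitude") /
        grab(pre, "Sol-L", "peak_amplitude"),
      ta_peak_amplitude = grab(post, "TA-L", "peak_amplitude") /
        grab(pre, "TA-L", "peak_amplitude"),
      interlimb_r = grab_r(post, "interlimb") / grab_r(pre, "interlimb"),
      intralimb_r = grab_r(post, "intralimb") / grab_r(pre, "intralimb"))
  })
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  tests <- list()
  for (par in setdiff(names(ratios), "animal_id")) {
    v <- ratios[[par]]
    v <- v[is.finite(v)]
    if (length(v) >= 2)
      tests[[length(tests) + 1L]] <-
        cbind(data.frame(parameter = par), as.data.frame(ratio_vs_unity(v)))
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(ratios = ratios, tests = tests)
}
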