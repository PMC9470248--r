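FACTOR_LEVELS <- list(
  trial_type = c("standard", "oddball", "deviant"),
  reward = c("low", "high"),
  response_mode = c("manual", "counting")
)

# coerce analysis factors to sum-to-zero coding with canonical level order
sum_coded <- function(measures, factors) {
  df <- as.data.frame(measures)
  for (f in factors) {
    lev <- intersect(FACTOR_LEVELS[[f]] %||% unique(df[[f]]), unique(df[[f]]))
    df[[f]] <- factor(df[[f]], levels = lev)
    stats::contrasts(df[[f]]) <- stats::contr.sum(length(lev))
  }
  df$participant <- factor(df$participant)
  df
}

random_formula <- function(random, fixed) {
  switch(random,
    full = paste0("(1 + ", paste(fixed, collapse = " + "), " | participant)"),
    slopes_trial_type = "(1 + trial_type | participant)",
    intercept = "(1 | participant)",
    abort(paste0("unknown random structure '", random, "'."))
  )
}

#' Fit the linear mixed model for trial-by-trial pupil measures
#'
#' Fits, by REML (default), a linear mixed-effects model of a per-trial
#' response on the design factors under sum-to-zero contrast coding, with a
#' participant random effect whose structure is one of `"full"` (intercept
#' plus slopes on every fixed factor), `"slopes_trial_type"`, `"intercept"`,
#' or `"auto"` (AIC selection via [select_random_structure()]). A singular
#' random-effects fit triggers an automatic refit with the next simpler
#' structure; the fallback is recorded on the returned object.
#'
#' @param measures Per-trial measures table (see [compute_measures()]).
#' @param response Response column: `"change"`, `"baseline_mean"` or
#'   `"rt_ms"`.
#' @param fixed Character vector of fixed factors, e.g.
#'   `c("trial_type", "reward")`.
#' @param interactions Include all interactions between fixed factors?
#' @param random Random-effect structure (see above).
#' @param reml Fit by REML (`TRUE`) or ML?
#' @return An `oddball_lmm`: list with the `lme4` fit, the coded data, and
#'   bookkeeping (`random`, `fallback`, `aic_table` when auto-selected).
#' @export
fit_lmm <- function(measures, response = "change",
                    fixed = c("trial_type"), interactions = TRUE,
                    random = "slopes_trial_type", reml = TRUE) {
  if (length(unique(measures$participant)) < 2) {
    abort("fit_lmm needs at least 2 participants.")
  }
  df <- sum_coded(measures, fixed)
  if (random == "auto") {
    sel <- select_random_structure(measures, response = response,
                                   fixed = fixed,
                                   interactions = interactions, reml = reml)
    out <- sel$fits[[sel$choice]]
    out$aic_table <- sel$aic
    return(out)
  }
  ladder <- c("full", "slopes_trial_type", "intercept")
  ladder <- ladder[match(random, ladder):length(ladder)]
  if (!"trial_type" %in% fixed) {
    ladder <- setdiff(ladder, "slopes_trial_type")
  }
  fallback <- NULL
  fit <- NULL
  for (r in ladder) {
    fml <- stats::as.formula(paste(
      response, "~",
      paste(fixed, collapse = if (interactions) " * " else " + "),
      "+", random_formula(r, fixed)
    ))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE))
    ))
    if (!lme4::isSingular(fit, tol = 1e-5) || r == "intercept") {
      if (r != random) fallback <- r
      random <- r
      break
    }
  }
  structure(
    list(fit = fit, data = df, response = response, fixed = fixed,
         interactions = interactions, random = random, reml = reml,
         fallback = fallback),
    class = "oddball_lmm"
  )
}

#' @export
print.oddball_lmm <- function(x, ...) {
  cat(sprintf(
    "<oddball_lmm> %s ~ %s; random: %s%s; AIC %.1f\n",
    x$response, paste(x$fixed, collapse = " * "), x$random,
    if (!is.null(x$fallback)) paste0(" (fallback from singular fit)") else "",
    stats::AIC(x$fit)
  ))
  invisible(x)
}

#' Choose the participant random-effect structure by AIC
#'
#' Fits the candidate ladder -- intercept plus slopes on all fixed factors,
#' intercept plus slopes on trial type only, intercept only -- at matched
#' fixed structure and scores each by AIC; the lowest AIC wins and ties go
#' to the simpler model. (AIC is compared across REML fits with identical
#' fixed effects; an ML refit is available via `reml = FALSE`.)
#'
#' @inheritParams fit_lmm
#' @return List: `choice`, `aic` (named vector, ladder order complex to
#'   simple), `fits` (named list of `oddball_lmm`).
#' @export
select_random_structure <- function(measures, response = "change",
                                    fixed = c("trial_type"),
                                    interactions = TRUE, reml = TRUE) {
  ladder <- c("full", "slopes_trial_type", "intercept")
  if (!"trial_type" %in% fixed) ladder <- c("full", "intercept")
  if (identical(fixed, "trial_type") || identical(fixed, c("trial_type"))) {
    ladder <- c("slopes_trial_type", "intercept")
  }
  fits <- list()
  aic <- numeric(0)
  for (r in ladder) {
    fits[[r]] <- fit_lmm(measures, response = response, fixed = fixed,
                         interactions = interactions, random = r, reml = reml)
    aic[r] <- stats::AIC(fits[[r]]$fit)
  }
  best <- pick_simplest_best(aic)
  list(choice = ladder[best], aic = aic, fits = fits)
}

# candidates are ordered complex -> simple; the lowest AIC wins and exact
# ties go to the later (simpler) entry
pick_simplest_best <- function(aic) {
  max(which(aic <= min(aic) + 1e-9))
}

#' Estimated marginal means with 95% confidence intervals
#'
#' Model-based cell means for the requested factors, averaged with equal
#' weights over the levels of all non-focal fixed factors, with z-based 95%
#' confidence intervals (estimate +/- 1.96 SE from the fixed-effect
#' covariance; degrees of freedom are taken as infinite, matching the
#' z statistics reported for the contrasts).
#'
#' @param model An `oddball_lmm`.
#' @param factors Character vector of focal factors.
#' @return Tibble with the factor level columns plus `estimate`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
estimated_marginal_means <- function(model, factors = model$fixed) {
  emm <- emm_grid(model, factors)
  s <- as.data.frame(summary(emm, infer = c(TRUE, FALSE)))
  out <- tibble::as_tibble(s[, factors, drop = FALSE])
  out[] <- lapply(out, as.character)
  out$estimate <- s$emmean
  out$se <- s$SE
  out$ci_low <- s$asymp.LCL
  out$ci_high <- s$asymp.UCL
  out
}

emm_grid <- function(model, factors) {
  spec <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  emmeans::emmeans(model$fit, spec, lmer.df = "asymptotic",
                   data = model$data)
}

#' Test a family of linear contrasts with Holm-Bonferroni correction
#'
#' Each contrast is a named weight vector over the cells of the factor grid
#' (cells labelled by their factor levels joined with `:`); its estimate is
#' the corresponding linear combination of estimated marginal means, tested
#' with `z = estimate / SE` against the two-sided normal reference. Raw p
#' values are then step-down Holm-adjusted within the declared family.
#'
#' @param model An `oddball_lmm`.
#' @param contrasts Named list of named weight vectors, e.g.
#'   `list("oddball - standard" = c("oddball" = 1, "standard" = -1))`.
#' @param factors Factors spanning the grid the weights refer to.
#' @return Tibble: `label`, `estimate`, `se`, `z`, `p_raw`, `p_adjusted`.
#' @export
contrast_tests <- function(model, contrasts, factors = model$fixed) {
  emm <- emm_grid(model, factors)
  s <- as.data.frame(summary(emm))
  labels <- do.call(paste, c(s[, factors, drop = FALSE], sep = ":"))
  method <- lapply(contrasts, function(w) {
    miss <- setdiff(names(w), labels)
    if (length(miss) > 0) {
      abort(paste0("contrast names not in grid: ",
                   paste(miss, collapse = ", "), " (grid: ",
                   paste(labels, collapse = ", "), ")."))
    }
    v <- numeric(nrow(s))
    v[match(names(w), labels)] <- w
    v
  })
  ct <- as.data.frame(summary(emmeans::contrast(emm, method = method),
                              adjust = "none"))
  z <- ct$z.ratio
  p <- ct$p.value
  # a null contrast (e.g. a level against itself) has estimate 0, SE 0:
  # report z = 0, p = 1 rather than 0/0
  degenerate <- ct$SE == 0 & abs(ct$estimate) < 1e-12
  z[degenerate] <- 0
  p[degenerate] <- 1
  tibble::tibble(
    label = names(contrasts),
    estimate = ct$estimate,
    se = ct$SE,
    z = z,
    p_raw = p,
    p_adjusted = p.adjust(p, method = "holm")
  )
}

#' Tonic (pre-stimulus baseline) analysis of reward condition
#'
#' Fits a separate linear mixed model of the per-trial pre-stimulus baseline
#' mean with reward condition as the nominal fixed effect and a participant
#' random intercept, and tests the high-minus-low difference.
#'
#' @param measures Per-trial measures restricted to the reward conditions of
#'   interest (rows with reward `low`/`high`).
#' @return List: `emm` (EMM table per reward level), `contrast` (one-row
#'   contrast tibble), `model`.
#' @export
baseline_tonic_analysis <- function(measures) {
  measures <- measures[measures$reward %in% c("low", "high"), , drop = FALSE]
  model <- fit_lmm(measures, response = "baseline_mean", fixed = "reward",
                   random = "intercept")
  emm <- estimated_marginal_means(model, "reward")
  ct <- contrast_tests(model,
                       list("high - low" = c(high = 1, low = -1)),
                       factors = "reward")
  list(emm = emm, contrast = ct, model = model)
}

#' Repeated-measures ANOVA on oddball response times
#'
#' One-way repeated-measures ANOVA on participant-mean response times to
#' correctly answered oddballs, by reward condition, with partial eta
#' squared `SS_effect / (SS_effect + SS_error)`.
#'
#' @param measures Per-trial measures (only correct oddball trials with a
#'   recorded RT are used).
#' @return List: `F`, `df1`, `df2`, `p`, `partial_eta2`, `cell_means`
#'   (tibble of condition means, ms).
#' @export
rt_anova <- function(measures) {
  rt <- measures |>
    dplyr::filter(.data$trial_type == "oddball", .data$outcome == "correct",
                  !is.na(.data$rt_ms)) |>
    dplyr::group_by(.data$participant, .data$reward) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop")
  k <- length(unique(rt$reward))
  if (k < 2) abort("rt_anova needs at least two reward conditions.")
  rt$participant <- factor(rt$participant)
  rt$reward <- factor(rt$reward)
  a <- aov(rt ~ reward + Error(participant), data = rt)
  within <- summary(a)[["Error: Within"]][[1]]
  ss_eff <- within["reward", "Sum Sq"]
  ss_err <- within["Residuals", "Sum Sq"]
  f_val <- within["reward", "F value"]
  p_val <- within["reward", "Pr(>F)"]
  eta <- ss_eff / (ss_eff + ss_err)
  # degenerate case: no effect variance beyond rounding dust
  tot <- sum((rt$rt - mean(rt$rt))^2)
  if (ss_eff <= 1e-12 * max(tot, 1)) {
    f_val <- 0; p_val <- 1; eta <- 0
  }
  list(
    F = f_val,
    df1 = within["reward", "Df"],
    df2 = within["Residuals", "Df"],
    p = p_val,
    partial_eta2 = eta,
    cell_means = rt |>
      dplyr::group_by(.data$reward) |>
      dplyr::summarise(mean_rt_ms = mean(.data$rt), .groups = "drop")
  )
}

#' Full condition-effect analysis for one experiment design
#'
#' Runs the experiment's declared statistical analysis on a measures table:
#' the change-score mixed model with its contrast family, and for the reward
#' design additionally the tonic baseline model and the response-time
#' ANOVA.
#'
#' * `exp1` — change ~ trial type; EMMs per trial type; Holm family
#'   {oddball - standard, deviant - standard}.
#' * `exp2` — change ~ trial type x response mode; EMMs per response mode
#'   (equal-weight over trial types) and per cell; family
#'   {manual - counting}.
#' * `exp3` — change ~ trial type x reward; EMMs per (trial type, reward)
#'   cell; Holm family of the two difference-of-differences contrasts
#'   {(oddball-standard): high - low, (deviant-standard): high - low};
#'   plus the tonic baseline contrast (its own family) and the RT ANOVA.
#'
#' @param measures Per-trial measures after exclusions (correct trials).
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param random Random-effect structure passed to [fit_lmm()]; the default
#'   `"auto"` selects by AIC.
#' @return An `oddball_report` list: `experiment`, `model` (fit summary
#'   info), `emm` tables, `contrasts`, and for exp3 `tonic` and `rt`.
#' @export
analyze_experiment <- function(measures, experiment = c("exp1", "exp2", "exp3"),
                               random = "auto") {
  experiment <- match.arg(experiment)
  report <- list(experiment = experiment)
  if (experiment == "exp1") {
    model <- fit_lmm(measures, fixed = "trial_type", random = random)
    report$emm <- list(trial_type = estimated_marginal_means(model, "trial_type"))
    report$contrasts <- contrast_tests(model, list(
      "oddball - standard" = c(oddball = 1, standard = -1),
      "deviant - standard" = c(deviant = 1, standard = -1)
    ), factors = "trial_type")
  } else if (experiment == "exp2") {
    model <- fit_lmm(measures, fixed = c("trial_type", "response_mode"),
                     random = random)
    report$emm <- list(
      response_mode = estimated_marginal_means(model, "response_mode"),
      cells = estimated_marginal_means(model, c("trial_type", "response_mode"))
    )
    report$contrasts <- contrast_tests(model, list(
      "manual - counting" = c(manual = 1, counting = -1)
    ), factors = "response_mode")
  } else {
    model <- fit_lmm(measures, fixed = c("trial_type", "reward"),
                     random = random)
    report$emm <- list(
      cells = estimated_marginal_means(model, c("trial_type", "reward")),
      reward = estimated_marginal_means(model, "reward")
    )
    report$contrasts <- contrast_tests(model, list(
      "(oddball - standard): high - low" = c(
        "oddball:high" = 1, "standard:high" = -1,
        "oddball:low" = -1, "standard:low" = 1
      ),
      "(deviant - standard): high - low" = c(
        "deviant:high" = 1, "standard:high" = -1,
        "deviant:low" = -1, "standard:low" = 1
      )
    ), factors = c("trial_type", "reward"))
    report$tonic <- baseline_tonic_analysis(measures)
    report$rt <- rt_anova(measures)
  }
  report$model <- list(
    random = model$random,
    fallback = model$fallback,
    aic = stats::AIC(model$fit),
    logLik = as.numeric(stats::logLik(model$fit)),
    converged = is.null(model$fit@optinfo$conv$lme4$messages)
  )
  report$fit <- model
  structure(report, class = "oddball_report")
}

#' @export
print.oddball_report <- function(x, ...) {
  cat(sprintf("<oddball_report> %s (random: %s)\n", x$experiment,
              x$model$random))
  for (nm in names(x$emm)) {
    cat("EMMs by", nm, ":\n")
    print(as.data.frame(x$emm[[nm]]), digits = 4)
  }
  cat("contrasts:\n")
  print(as.data.frame(x$contrasts), digits = 4)
  if (!is.null(x$tonic)) {
    cat("tonic baseline (mm^2):\n")
    print(as.data.frame(x$tonic$emm), digits = 5)
    print(as.data.frame(x$tonic$contrast), digits = 4)
  }
  if (!is.null(x$rt)) {
    cat(sprintf("RT ANOVA: F(%d,%d) = %.3g, p = %.3g, partial eta^2 = %.3g\n",
                x$rt$df1, x$rt$df2, x$rt$F, x$rt$p, x$rt$partial_eta2))
  }
  invisible(x)
}
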