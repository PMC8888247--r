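#' Cycle-level biovolume averages
#'
#' Averages total biovolume per replicate over each experiment period:
#' the pristine baseline (before the first pulse) and one period per pulse
#' cycle (pulse day, exclusive, to the next pulse day, inclusive, matching
#' morning sampling before the pulse). With the full study layout
#' (3 treatments x 6 replicates x 4 periods) this yields 72 averaged
#' values.
#'
#' @param timeseries long-format table with `day`, `treatment`,
#'   `replicate` and `biovolume`.
#' @param pulse_days pulse days or an [experiment_design()].
#' @return data.frame with `treatment`, `replicate`, `period`
#'   (Baseline/P1/P2/...), `mean_biovolume`, `n_samples`.
#' @export
cycle_average_biovolume <- function(timeseries, pulse_days) {
  if (inherits(pulse_days, "pp_design")) pulse_days <- pulse_days$pulse_days
  validate_timeseries(timeseries, required = c("day", "treatment",
                                               "replicate", "biovolume"))
  if (!length(pulse_days) || any(diff(pulse_days) <= 0))
    pp_stop_invalid("`pulse_days` must be non-empty and strictly increasing")

  labels <- c("Baseline", paste0("P", seq_along(pulse_days)))
  period <- cut(timeseries$day, breaks = c(-Inf, pulse_days, Inf),
                labels = labels, right = TRUE)
  # replicates are nested in treatments: aggregate over replicate x period,
  # then re-attach each replicate's treatment
  agg <- aggregate(timeseries$biovolume,
                   by = list(replicate = timeseries$replicate,
                             period = period),
                   FUN = mean, drop = FALSE)
  names(agg)[3] <- "mean_biovolume"
  if (any(is.na(agg$mean_biovolume)))
    pp_stop_invalid("empty period: every period needs at least one sample")
  cnt <- aggregate(timeseries$biovolume,
                   by = list(replicate = timeseries$replicate,
                             period = period),
                   FUN = length, drop = FALSE)
  agg$n_samples <- cnt$x
  agg$treatment <- timeseries$treatment[match(agg$replicate,
                                              timeseries$replicate)]
  agg <- agg[order(agg$treatment, agg$replicate, agg$period),
             c("treatment", "replicate", "period", "mean_biovolume",
               "n_samples")]
  rownames(agg) <- NULL
  agg
}

#' Total biovolume from particle-counter size bins
#'
#' Averages replicate technical counts, then sums the per-bin biovolumes.
#'
#' @param bin_volumes numeric vector of per-bin biovolumes (one count), or
#'   a matrix with one technical count per row (e.g. 3 x 300 bins).
#' @return Total biovolume (um^3/ml).
#' @examples
#' total_biovolume(matrix(1:6, nrow = 3))  # mean of counts, then summed
#' @export
total_biovolume <- function(bin_volumes) {
  if (is.matrix(bin_volumes)) {
    if (any(!is.finite(bin_volumes)) || any(bin_volumes < 0))
      pp_stop_invalid("bin biovolumes must be finite and non-negative")
    return(sum(colMeans(bin_volumes)))
  }
  if (!is.numeric(bin_volumes) || any(!is.finite(bin_volumes)) ||
      any(bin_volumes < 0))
    pp_stop_invalid("bin biovolumes must be finite and non-negative")
  sum(bin_volumes)
}

#' Regress chlorophyll-a on biovolume with a treatment interaction
#'
#' Linear model of total chlorophyll-a on total biovolume, treatment and
#' their interaction, quantifying whether enrichment changes the amount of
#' chlorophyll per unit biovolume. Optionally log10-transforms both
#' variables; with `"auto"` the transform is applied when a Shapiro-Wilk
#' screen on the untransformed residuals fails at `alpha`.
#'
#' @param data data.frame with `chl_total`, `biovolume`, `treatment`.
#' @param log10_transform `"auto"`, `"never"` or `"always"`.
#' @param alpha significance level of the residual-normality screen.
#' @return Object of class `pp_chl_fit`: the `lm` fit plus per-treatment
#'   slopes, interaction contrasts vs the reference treatment, the
#'   interaction F test and R^2.
#' @export
fit_chl_biovolume <- function(data, log10_transform = c("auto", "never",
                                                        "always"),
                              alpha = 0.05) {
  log10_transform <- match.arg(log10_transform)
  req <- c("chl_total", "biovolume", "treatment")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    pp_stop_schema(paste0("`data` is missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
  data$treatment <- factor(data$treatment)
  counts <- table(data$treatment)
  if (any(counts < 3))
    pp_stop_invalid("need at least 3 observations per treatment")

  fit_once <- function(d) lm(chl_total ~ biovolume * treatment, data = d)
  fit <- fit_once(data)
  transformed <- FALSE
  if (log10_transform == "always" ||
      (log10_transform == "auto" && {
        n <- length(residuals(fit))
        sh <- shapiro.test(residuals(fit)[seq_len(min(n, 5000))])
        sh$p.value < alpha
      })) {
    if (any(data$chl_total <= 0) || any(data$biovolume <= 0))
      pp_stop_invalid("log10 transform requires positive values")
    data$chl_total <- log10(data$chl_total)
    data$biovolume <- log10(data$biovolume)
    fit <- fit_once(data)
    transformed <- TRUE
  }
  if (fit$rank < length(coef(fit)))
    pp_stop_invalid("rank-deficient fit: slopes are not identifiable")

  cf <- coef(fit)
  lv <- levels(data$treatment)
  slopes <- setNames(rep(cf[["biovolume"]], length(lv)), lv)
  for (l in lv[-1]) {
    nm <- paste0("biovolume:treatment", l)
    if (nm %in% names(cf)) slopes[l] <- slopes[l] + cf[[nm]]
  }
  an <- anova(fit)
  inter <- an["biovolume:treatment", , drop = FALSE]

  structure(list(
    model = fit,
    transformed = transformed,
    reference = lv[1],
    slopes = slopes,
    interaction_f = inter[["F value"]],
    interaction_p = inter[["Pr(>F)"]],
    r_squared = summary(fit)$r.squared
  ), class = "pp_chl_fit")
}

#' @export
print.pp_chl_fit <- function(x, ...) {
  cat("Chlorophyll-a ~ biovolume * treatment",
      if (x$transformed) "(log10 scale)" else "", "\n")
  cat(sprintf("  R^2 = %.3f; interaction F = %.3g, p = %.3g\n",
              x$r_squared, x$interaction_f, x$interaction_p))
  cat("  slopes:", paste(sprintf("%s %.4g", names(x$slopes), x$slopes),
                         collapse = ", "), "\n")
  invisible(x)
}

# fit one metric with the random-effects fallback cascade; returns the fit
# and a label of the structure retained
fit_trend_one <- function(df, interaction) {
  fixed <- if (interaction) "value ~ n_pulses * treatment"
           else "value ~ n_pulses + treatment"
  use_intensity <- length(unique(df$pulse_intensity)) > 1L &&
    !anyNA(df$pulse_intensity)
  forms <- c(
    if (use_intensity)
      paste(fixed, "+ (1 + n_pulses | replicate) + (1 | pulse_intensity)"),
    if (use_intensity) paste(fixed, "+ (1 | replicate) + (1 | pulse_intensity)"),
    paste(fixed, "+ (1 + n_pulses | replicate)"),
    paste(fixed, "+ (1 | replicate)")
  )
  last <- NULL
  for (f in forms) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(as.formula(f), data = df,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                                                   check.conv.singular =
                                                     lme4::.makeCC("ignore",
                                                                   1e-4)))
      )),
      error = function(e) NULL)
    if (is.null(fit)) next
    last <- list(fit = fit, formula = f)
    if (!lme4::isSingular(fit, tol = 1e-4)) return(last)
  }
  if (is.null(last))
    pp_stop_invalid("mixed model could not be fitted for a metric")
  attr(last, "singular") <- TRUE
  last
}

# empirical (Nakagawa-style) variance-explained decomposition
variance_explained <- function(fit) {
  fix <- as.numeric(model.matrix(fit) %*% lme4::fixef(fit))
  full <- fitted(fit)
  v_fix <- stats::var(fix)
  v_re <- stats::var(full - fix)
  v_res <- stats::sigma(fit)^2
  tot <- v_fix + v_re + v_res
  c(marginal = v_fix / tot, conditional = (v_fix + v_re) / tot)
}

# permutation p-values: treatment labels permuted across replicates,
# cycle order permuted within replicates for the trend term
permutation_pvalues <- function(df, interaction, n_permutations, observed_f) {
  terms <- names(observed_f)
  reps <- unique(df$replicate)
  rep_tr <- df$treatment[match(reps, df$replicate)]
  count <- setNames(numeric(length(terms)), terms)
  for (b in seq_len(n_permutations)) {
    perm <- df
    new_tr <- sample(rep_tr)
    perm$treatment <- new_tr[match(perm$replicate, reps)]
    perm$n_pulses <- unsplit(lapply(split(perm$n_pulses, perm$replicate),
                                    sample), perm$replicate)
    pf <- tryCatch({
      ft <- fit_trend_one(perm, interaction)
      av <- suppressWarnings(stats::anova(ft$fit))
      setNames(av[["F value"]], rownames(av))
    }, error = function(e) NULL)
    if (is.null(pf)) next
    for (tm in terms)
      if (tm %in% names(pf) && pf[[tm]] >= observed_f[[tm]])
        count[tm] <- count[tm] + 1
  }
  (count + 1) / (n_permutations + 1)
}

#' Estimate eutrophication and sequential-perturbation effects
#'
#' Fits, for each perturbation metric, a linear mixed-effects model with
#' the number of pulse perturbations (as a numeric trend) and the
#' treatment (reference = first/control level) as fixed effects, a random
#' intercept (and, when the data support it, a random perturbation slope)
#' per replicate, and the pulse intensity as an additional random
#' blocking term. Because each cycle has a single intensity, the intensity
#' term is often inestimable; singular or failed fits fall back
#' automatically through simpler random structures down to a random
#' intercept per replicate. F statistics and p-values use Satterthwaite
#' denominator degrees of freedom; a permutation-based alternative is
#' available for small designs.
#'
#' @param metrics output of [compute_metrics()]; must contain `replicate`,
#'   `treatment`, `cycle` and the metric columns.
#' @param metric_cols metrics to model.
#' @param interaction also estimate the perturbation-count x treatment
#'   interaction.
#' @param pvalues `"satterthwaite"` (default) or `"permutation"`.
#' @param n_permutations permutations for the permutation option.
#' @param seed optional seed used for the permutation option.
#' @return Object of class `pp_trends`: `effects` (one row per metric x
#'   term with estimate, F, p and the variance explained by the fixed
#'   effects alone and by the full model) and `fits` (the underlying
#'   models and formulas retained).
#' @export
fit_metric_trends <- function(metrics,
                              metric_cols = c("c0", "d0", "rs_scaled",
                                              "rc_scaled"),
                              interaction = FALSE,
                              pvalues = c("satterthwaite", "permutation"),
                              n_permutations = 5000,
                              seed = NULL) {
  pvalues <- match.arg(pvalues)
  req <- c("replicate", "treatment", "cycle", metric_cols)
  missing_cols <- setdiff(req, names(metrics))
  if (length(missing_cols))
    pp_stop_schema(paste0("`metrics` is missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
  if (length(unique(metrics$cycle)) < 2L)
    pp_stop_invalid("need at least 2 perturbation cycles to estimate trends")
  if (!is.null(seed)) set.seed(seed)

  lv <- unique(as.character(metrics$treatment))
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))

  effects <- list()
  fits <- list()
  for (m in metric_cols) {
    df <- data.frame(
      value = metrics[[m]],
      n_pulses = as.numeric(metrics$cycle),
      treatment = factor(metrics$treatment, levels = lv),
      replicate = factor(metrics$replicate),
      pulse_intensity = factor(metrics$pulse_intensity)
    )
    df <- df[is.finite(df$value), ]
    ft <- fit_trend_one(df, interaction)
    fit <- ft$fit
    av <- suppressWarnings(stats::anova(fit))  # Satterthwaite type III
    fvals <- setNames(av[["F value"]], rownames(av))
    pvals <- setNames(av[["Pr(>F)"]], rownames(av))
    if (pvalues == "permutation")
      pvals <- permutation_pvalues(df, interaction, n_permutations, fvals)
    ve <- variance_explained(fit)

    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    term_label <- function(tm) {
      switch(tm, n_pulses = "n_perturbations",
             treatment = "eutrophication",
             `n_pulses:treatment` = "interaction", tm)
    }
    for (tm in rownames(av)) {
      idx <- if (tm == "n_pulses") "n_pulses" else NA
      est <- if (!is.na(idx) && idx %in% names(cf)) cf[[idx]] else NA_real_
      est_se <- if (!is.na(idx) && idx %in% names(cf)) se[[idx]] else NA_real_
      effects[[length(effects) + 1L]] <- data.frame(
        metric = m,
        term = term_label(tm),
        estimate = est,
        se = est_se,
        f_value = fvals[[tm]],
        p_value = pvals[[tm]],
        marginal_r2 = ve[["marginal"]],
        conditional_r2 = ve[["conditional"]],
        formula = ft$formula,
        singular = isTRUE(attr(ft, "singular"))
      )
    }
    # treatment level contrasts vs the reference
    tr_terms <- grep("^treatment", names(cf), value = TRUE)
    contrasts <- data.frame(
      level = sub("^treatment", "", tr_terms),
      estimate = unname(cf[tr_terms]),
      se = unname(se[tr_terms])
    )
    fits[[m]] <- list(fit = fit, formula = ft$formula, contrasts = contrasts)
  }
  structure(list(
    effects = do.call(rbind, effects),
    fits = fits,
    reference = lv[1]
  ), class = "pp_trends")
}

#' @export
print.pp_trends <- function(x, ...) {
  cat(sprintf("Perturbation-metric trend estimates (reference: %s)\n",
              x$reference))
  eff <- x$effects
  eff$f_value <- signif(eff$f_value, 4)
  eff$p_value <- signif(eff$p_value, 3)
  eff$marginal_r2 <- round(eff$marginal_r2, 3)
  eff$conditional_r2 <- round(eff$conditional_r2, 3)
  print(eff[, c("metric", "term", "f_value", "p_value",
                "marginal_r2", "conditional_r2")], row.names = FALSE)
  invisible(x)
}

#' Enriched-to-control displacement ratio
#'
#' Ratio of the mean maximum displacement in the enriched treatments
#' (pooled) to the mean in the control treatment: the fold-change in the
#' absolute chlorophyll-a response attributable to eutrophication.
#'
#' @param metrics output of [compute_metrics()].
#' @param control label of the unenriched treatment.
#' @return A single ratio.
#' @export
estimate_displacement_ratio <- function(metrics, control = "control") {
  if (!all(c("treatment", "d0") %in% names(metrics)))
    pp_stop_schema("`metrics` must contain `treatment` and `d0`")
  if (!control %in% metrics$treatment)
    pp_stop_invalid(sprintf("control treatment '%s' not present", control))
  ctrl <- mean(metrics$d0[metrics$treatment == control])
  enr <- mean(metrics$d0[metrics$treatment != control])
  enr / ctrl
}
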