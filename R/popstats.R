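#' Moment skewness
#'
#' `b1 = m3 / m2^(3/2)` with `mk` the k-th central sample moment (1/n
#' normalisation). Zero for a normal distribution; positive values indicate
#' a right tail.
#'
#' @param values numeric vector, `n >= 3`, non-zero variance.
#' @return dimensionless skewness.
#' @export
moment_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stopf("skewness needs n >= 3")
  m2 <- central_moment(values, 2)
  if (m2 <= 0) stopf("skewness is undefined for zero-variance data")
  central_moment(values, 3) / m2^1.5
}

#' Moment kurtosis (raw, not excess)
#'
#' `b2 = m4 / m2^2`; equals 3 for a normal distribution, values above 3
#' indicate heavy tails. The minimum attainable value is 1 (a symmetric
#' two-point distribution).
#'
#' @param values numeric vector, `n >= 4`, non-zero variance.
#' @return dimensionless kurtosis.
#' @export
moment_kurtosis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) stopf("kurtosis needs n >= 4")
  m2 <- central_moment(values, 2)
  if (m2 <= 0) stopf("kurtosis is undefined for zero-variance data")
  central_moment(values, 4) / m2^2
}

#' Fit the IQR baseline criterion on a control population
#'
#' `I = Q75 + 1.5 * IQR` computed on the pooled control values, with the
#' linear-interpolation quantile convention (R type 7). The control is the
#' no-inducer medium at the matching timepoint for liquid-culture data, or
#' the time-zero population for leaf data.
#'
#' @param control numeric vector of control fluorescence values, or a
#'   population tibble with a `value` column (rows are pooled).
#' @param source free-text description of the control recorded on the
#'   model.
#' @return object of class `baseline_model`: `source`, `q75`, `iqr`,
#'   `threshold_I`.
#' @export
fit_baseline <- function(control, source = "control") {
  if (is.data.frame(control)) control <- control$value
  control <- as.numeric(control)
  if (length(control) == 0L || all(is.na(control)))
    stopf("empty control population")
  q <- stats::quantile(control, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  iqr <- q[2] - q[1]
  structure(list(source = source, q75 = q[2], iqr = iqr,
                 threshold_I = q[2] + 1.5 * iqr),
            class = "baseline_model")
}

#' @exportS3Method base::print
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model (%s): Q75 = %.4g, IQR = %.4g, I = %.4g>\n",
              x$source, x$q75, x$iqr, x$threshold_I))
  invisible(x)
}

#' Express fluorescence relative to the baseline threshold
#'
#' Divides every corrected fluorescence value by the baseline threshold
#' `I`, so that a value of 1 sits exactly at baseline and a cell is
#' "high-fluorescence" iff its relative value is strictly greater than 1.
#'
#' @param pop population tibble with a `value` column (or numeric vector).
#' @param baseline a [fit_baseline()] model with `threshold_I > 0`.
#' @return same shape as the input with `rel_value` (and `high`) added;
#'   for a numeric vector input, the numeric relative values.
#' @export
relative_fluorescence <- function(pop, baseline) {
  stopifnot(inherits(baseline, "baseline_model"))
  if (baseline$threshold_I <= 0)
    stopf("degenerate control: baseline threshold I = %.4g <= 0",
          baseline$threshold_I)
  if (is.numeric(pop)) return(pop / baseline$threshold_I)
  pop$rel_value <- pop$value / baseline$threshold_I
  pop$high <- pop$rel_value > 1
  pop
}

#' Exclude replicates with insufficient cell counts
#'
#' @param pop population tibble with `condition`, `timepoint`, `replicate`.
#' @param min_cells minimum cells per replicate (default 20); smaller
#'   replicates are dropped with a warning.
#' @return filtered tibble.
#' @export
exclude_small_replicates <- function(pop, min_cells = 20L) {
  counts <- dplyr::count(pop, .data$condition, .data$timepoint, .data$replicate)
  small <- counts[counts$n < min_cells, ]
  if (nrow(small) > 0) {
    warnf("excluding %d replicate(s) with fewer than %d cells: %s",
          nrow(small), min_cells,
          paste(sprintf("%s/t%s/%s (n=%d)", small$condition, small$timepoint,
                        small$replicate, small$n), collapse = "; "))
    pop <- dplyr::anti_join(pop, small[c("condition", "timepoint", "replicate")],
                            by = c("condition", "timepoint", "replicate"))
  }
  pop
}

#' Summarise population heterogeneity per condition and timepoint
#'
#' Produces one summary row per condition x timepoint from the pooled
#' (across replicates) relative fluorescence values: replicate and cell
#' counts, median and IQR of relative fluorescence, the percentage of
#' cells strictly above baseline, the maximum, and moment skewness and
#' kurtosis.
#'
#' @param pop population tibble carrying `rel_value` (from
#'   [relative_fluorescence()]); replicate exclusion should already have
#'   been applied via [exclude_small_replicates()].
#' @return tibble with columns `condition`, `timepoint`, `n_replicates`,
#'   `n_cells`, `median_rel_fluor`, `iqr_rel_fluor`, `proportion_high`
#'   (percent), `max_rel_fluor`, `skewness`, `kurtosis`.
#' @export
summarize_population <- function(pop) {
  if (!"rel_value" %in% names(pop))
    stopf("`pop` must carry `rel_value`; call relative_fluorescence() first")
  pop |>
    dplyr::group_by(.data$condition, .data$timepoint) |>
    dplyr::summarise(
      n_replicates = dplyr::n_distinct(.data$replicate),
      n_cells = dplyr::n(),
      median_rel_fluor = stats::median(.data$rel_value),
      iqr_rel_fluor = stats::quantile(.data$rel_value, 0.75, names = FALSE) -
        stats::quantile(.data$rel_value, 0.25, names = FALSE),
      proportion_high = 100 * mean(.data$rel_value > 1),
      max_rel_fluor = max(.data$rel_value),
      # zero-variance groups have no defined shape statistics
      skewness = tryCatch(moment_skewness(.data$rel_value),
                          error = function(e) NA_real_),
      kurtosis = tryCatch(moment_kurtosis(.data$rel_value),
                          error = function(e) NA_real_),
      .groups = "drop")
}

#' Top-quantile subpopulation fold change
#'
#' For each replicate, selects the cells at or above the `1 - q` quantile
#' of that replicate's relative fluorescence and records the median of
#' their relative values (fold change versus baseline; 1 = baseline). Per
#' timepoint, a one-sample t-test compares the replicate fold changes
#' against 1; across timepoints the replicate fold changes are compared by
#' ANOVA + Tukey HSD when the normality/homoscedasticity gate passes
#' (Shapiro-Wilk p > 0.05 in every group and Levene p > 0.05) and by
#' Kruskal-Wallis + Dunn with Holm-Bonferroni adjustment otherwise.
#'
#' @param pop population tibble carrying `rel_value`, single condition.
#' @param q upper-tail fraction: 0.01 (top 1%) for liquid-culture data,
#'   0.10 (top 10%) for leaf data.
#' @return list of class `subpopulation_result`: `quantile_q`,
#'   `replicate_foldchanges` (tibble), `per_timepoint_tests` (one-sample
#'   t-tests vs 1), `across_timepoints` ([hypothesis_tests()] output, NULL
#'   if fewer than two timepoints).
#' @export
top_quantile_foldchange <- function(pop, q) {
  assert_number(q, "q", 1e-6, 1 - 1e-6)
  min_n <- ceiling(1 / q)
  counts <- dplyr::count(pop, .data$condition, .data$timepoint, .data$replicate)
  small <- counts[counts$n < min_n, ]
  if (nrow(small) > 0) {
    warnf("excluding %d replicate(s) with fewer than %d cells from the top-%g%% analysis",
          nrow(small), min_n, 100 * q)
    pop <- dplyr::anti_join(pop, small[c("condition", "timepoint", "replicate")],
                            by = c("condition", "timepoint", "replicate"))
  }
  if (nrow(pop) == 0L) stopf("all replicates excluded from the top-quantile analysis")

  fc <- pop |>
    dplyr::group_by(.data$condition, .data$timepoint, .data$replicate) |>
    dplyr::summarise(fold_change = {
      cut <- stats::quantile(.data$rel_value, 1 - q, names = FALSE, type = 7)
      stats::median(.data$rel_value[.data$rel_value >= cut])
    }, n_cells = dplyr::n(), .groups = "drop")

  per_tp <- fc |>
    dplyr::group_by(.data$condition, .data$timepoint) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2 || stats::sd(d$fold_change) == 0) {
        tibble::tibble(n = nrow(d), statistic = NA_real_, df = NA_real_,
                       p_value = NA_real_)
      } else {
        tt <- stats::t.test(d$fold_change, mu = 1)
        tibble::tibble(n = nrow(d), statistic = unname(tt$statistic),
                       df = unname(tt$parameter), p_value = tt$p.value)
      }
    }) |>
    dplyr::ungroup()

  across <- NULL
  if (dplyr::n_distinct(fc$timepoint) >= 2) {
    grp <- fc |> dplyr::count(.data$timepoint)
    if (all(grp$n >= 2)) {
      # degenerate (e.g. zero-variance) groups leave the comparison empty
      across <- tryCatch(hypothesis_tests(fc$fold_change, factor(fc$timepoint)),
                         error = function(e) NULL)
    }
  }
  structure(list(quantile_q = q, replicate_foldchanges = fc,
                 per_timepoint_tests = per_tp, across_timepoints = across),
            class = "subpopulation_result")
}

#' Group comparison with a normality/homoscedasticity gate
#'
#' Runs Shapiro-Wilk on every group and Levene's test across groups at
#' alpha = 0.05. If all pass, compares groups by one-way ANOVA with Tukey
#' HSD post hocs; otherwise by Kruskal-Wallis with Dunn's pairwise tests
#' under Holm-Bonferroni adjustment.
#'
#' @param values numeric response.
#' @param groups factor of group membership (>= 2 groups, each with >= 2
#'   observations).
#' @param alpha significance level (default 0.05).
#' @return list: `gate` (per-group Shapiro p, Levene p, chosen `branch`),
#'   `omnibus` (statistic, df, p, decision), `posthoc` tibble (pair,
#'   estimate or z, p, adjusted p, significance).
#' @export
hypothesis_tests <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stopf("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stopf("Levene's test needs >= 2 observations per group; group(s) %s too small",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  shapiro_p <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (stats::sd(v) == 0) stopf("Shapiro-Wilk is undefined for the constant group '%s'", g)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  lev <- car::leveneTest(values ~ groups)
  levene_p <- lev[["Pr(>F)"]][1]
  parametric <- all(shapiro_p > alpha) && levene_p > alpha

  if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    omnibus <- list(test = "anova", statistic = an[["F value"]][1],
                    df = c(an[["Df"]][1], an[["Df"]][2]),
                    p_value = an[["Pr(>F)"]][1])
    tk <- stats::TukeyHSD(fit)$groups
    posthoc <- tibble::tibble(
      pair = rownames(tk), estimate = tk[, "diff"],
      p_value = tk[, "p adj"], p_adjusted = tk[, "p adj"],
      method = "tukey_hsd")
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus <- list(test = "kruskal_wallis",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
    posthoc <- dunn_test(values, groups, p_adjust = "holm")
  }
  omnibus$significant <- omnibus$p_value < alpha
  posthoc$significant <- posthoc$p_adjusted < alpha
  list(gate = list(shapiro_p = shapiro_p, levene_p = levene_p,
                   branch = if (parametric) "parametric" else "nonparametric"),
       omnibus = omnibus, posthoc = posthoc)
}

#' Dunn's post-hoc test
#'
#' Pairwise rank-sum z-tests on the joint ranking (with tie correction)
#' following a Kruskal-Wallis test; two-sided p-values with the requested
#' multiplicity adjustment (default Holm-Bonferroni).
#'
#' @param values numeric response.
#' @param groups factor of group membership.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return tibble: `pair`, `estimate` (z statistic), `p_value`,
#'   `p_adjusted`, `method`.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- droplevels(as.factor(groups))
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  res <- apply(combs, 2, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    ni <- sum(i); nj <- sum(j)
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  tibble::tibble(pair = paste(combs[1, ], combs[2, ], sep = "-"),
                 estimate = unname(res["z", ]), p_value = unname(res["p", ]),
                 p_adjusted = stats::p.adjust(res["p", ], method = p_adjust),
                 method = paste0("dunn_", p_adjust))
}

#' Normal probability plot coordinates
#'
#' Pairs the ordered sample with standard-normal quantiles at the plotting
#' positions `(i - 0.5) / n`; the pairs fall on a straight line iff the
#' data are normal, and a convex right tail above the line signals positive
#' skewness.
#'
#' @param values numeric vector, `n >= 2`.
#' @return tibble with `theoretical` (normal quantiles) and `ordered`
#'   (sorted sample values).
#' @export
normal_probability_data <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stopf("need n >= 2")
  tibble::tibble(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                 ordered = sort(values))
}

#' Colony-forming units per gram of fresh weight
#'
#' `CFU gFW^-1 = colonies * dilution * (wash_volume / plated_volume) /
#' fresh_weight`: the plated aliquot is scaled back to the full leaf wash
#' and normalised by plant fresh weight.
#'
#' @param colony_count colonies counted on the plate (>= 0).
#' @param dilution_factor fold dilution of the plated aliquot (> 0).
#' @param plated_volume volume plated, same units as `wash_volume` (> 0).
#' @param wash_volume total leaf-wash volume (> 0).
#' @param leaf_fresh_weight plant fresh weight in grams (> 0).
#' @return CFU per gram fresh weight.
#' @export
cfu_per_gram <- function(colony_count, dilution_factor, plated_volume,
                         wash_volume, leaf_fresh_weight) {
  if (any(colony_count < 0)) stopf("`colony_count` must be >= 0")
  for (v in list(dilution_factor, plated_volume, wash_volume, leaf_fresh_weight))
    if (any(!is.finite(v)) || any(v <= 0))
      stopf("dilution, volumes and fresh weight must all be > 0")
  colony_count * dilution_factor * (wash_volume / plated_volume) /
    leaf_fresh_weight
}
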