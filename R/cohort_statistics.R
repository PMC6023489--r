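#' Label subjects as PAH or normal from catheterization pressures
#'
#' PAH is defined hemodynamically: mean pulmonary artery pressure
#' `mPAp >= 25` mmHg together with a pulmonary artery wedge (or left
#' atrial) pressure `PAWp <= 15` mmHg at rest. Subjects with `mPAp < 25`
#' are labelled normal. The remaining combination (`mPAp >= 25` with
#' `PAWp > 15`, i.e. post-capillary hypertension) falls outside the
#' definition and is returned as `NA` with a warning.
#'
#' @param mPAp Mean pulmonary artery pressure, mmHg.
#' @param PAWp Pulmonary artery wedge (or left atrial) pressure, mmHg.
#' @return Factor with levels `c("normal", "pah")`; `NA` for excluded
#'   subjects.
#' @export
pah_group <- function(mPAp, PAWp) {
  out <- rep(NA_character_, length(mPAp))
  out[mPAp < 25] <- "normal"
  out[mPAp >= 25 & PAWp <= 15] <- "pah"
  if (anyNA(out))
    warning(sum(is.na(out)), " subject(s) with mPAp >= 25 and PAWp > 15 ",
            "fall outside the PAH definition and were excluded")
  factor(out, levels = c("normal", "pah"))
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-sided test with the pooled variance estimate and
#' `df = n1 + n2 - 2` (Welch's unpooled variant is available via
#' `var_equal = FALSE`).
#'
#' @param xs,ys Numeric samples, each with >= 2 values.
#' @param var_equal Use the pooled variance (default TRUE).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(xs, ys, var_equal = TRUE) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  if (length(xs) < 2L) stop("first group has fewer than 2 values")
  if (length(ys) < 2L) stop("second group has fewer than 2 values")
  if (var_equal) {
    res <- ttest_from_summary(mean(xs), stats::sd(xs), length(xs),
                              mean(ys), stats::sd(ys), length(ys))
  } else {
    ht <- stats::t.test(xs, ys, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  res
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' The same test as [two_sample_ttest()] computed from group means,
#' standard deviations, and sizes only — enough to reproduce printed
#' clinical-table p-values.
#'
#' @param m1,s1,n1 Mean, sd, size of group 1.
#' @param m2,s2,n2 Mean, sd, size of group 2.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) stop("pooled variance is zero: t-test undefined")
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Holm-Bonferroni step-down correction
#'
#' Step-down family-wise error control, uniformly more powerful than plain
#' Bonferroni: sort p-values ascending, multiply the i-th smallest by
#' `m - i + 1`, enforce a monotone running maximum, cap at 1, and return in
#' the original order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Corrected p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[ord]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Rank recording sites and formants by group separation
#'
#' Runs a pooled two-sample t-test (normal vs PAH) on every
#' (site, formant) feature cell and ranks the results by raw p-value
#' ascending; the top row identifies the most informative site and formant.
#' Holm-Bonferroni correction across the 16 cells is reported alongside.
#'
#' @param features Data frame with columns `subject_id`, `group` (factor
#'   with levels `normal`, `pah`), `site`, `formant`, `value`; one row per
#'   (subject, site, formant) cell.
#' @param alpha Significance level, echoed into the attributes.
#' @param var_equal Pooled-variance test (default TRUE).
#' @return Data frame with one row per (site, formant): `site`, `formant`,
#'   `t`, `df`, `p_raw`, `p_corrected`, sorted by `p_raw`.
#' @export
rank_sites_formants <- function(features, alpha = 0.05, var_equal = TRUE) {
  need <- c("subject_id", "group", "site", "formant", "value")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  cells <- expand.grid(site = unique(features$site),
                       formant = sort(unique(features$formant)),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$site, cells$formant), ]
  incomplete <- character(0)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- features$site == cells$site[i] & features$formant == cells$formant[i]
    xs <- features$value[sel & features$group == "normal"]
    ys <- features$value[sel & features$group == "pah"]
    if (length(xs) < 2L || length(ys) < 2L || anyNA(c(xs, ys))) {
      incomplete <<- c(incomplete,
                       sprintf("%s/formant %s", cells$site[i], cells$formant[i]))
      return(NULL)
    }
    tt <- two_sample_ttest(xs, ys, var_equal = var_equal)
    data.frame(site = cells$site[i], formant = cells$formant[i],
               t = tt$t, df = tt$df, p_raw = tt$p)
  })
  if (length(incomplete))
    stop("missing or incomplete feature cells: ",
         paste(incomplete, collapse = "; "))
  out <- do.call(rbind, res)
  out$p_corrected <- holm_bonferroni(out$p_raw)
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Sweep window lengths at a fixed site and formant
#'
#' For each candidate segment length `L`, tests normal vs PAH on the
#' length-`L` windowed feature, then applies Holm-Bonferroni across the
#' whole sweep (the multiple-testing family is the set of window lengths).
#' The optimal length is the `argmin` of the corrected p-value.
#'
#' @param features Data frame with columns `subject_id`, `group`,
#'   `window_length_s`, `value` (already restricted to one site/formant).
#' @param lengths Window lengths to test (default `1:20` seconds).
#' @param var_equal Pooled-variance test (default TRUE).
#' @return Data frame with one row per length: `window_length_s`, `t`,
#'   `df`, `p_raw`, `p_corrected`; attribute `optimal_length`.
#' @export
sweep_window_lengths <- function(features, lengths = 1:20, var_equal = TRUE) {
  need <- c("group", "window_length_s", "value")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  res <- lapply(lengths, function(L) {
    sel <- abs(features$window_length_s - L) < 1e-9
    xs <- features$value[sel & features$group == "normal"]
    ys <- features$value[sel & features$group == "pah"]
    tt <- two_sample_ttest(xs, ys, var_equal = var_equal)
    data.frame(window_length_s = L, t = tt$t, df = tt$df, p_raw = tt$p)
  })
  out <- do.call(rbind, res)
  out$p_corrected <- holm_bonferroni(out$p_raw)
  rownames(out) <- NULL
  attr(out, "optimal_length") <- out$window_length_s[which.min(out$p_corrected)]
  out
}

#' Per-group sample size for a two-sided two-sample t-test
#'
#' Post-hoc power analysis. The default `"normal"` method uses the
#' normal-approximation formula
#' `n = 2 (z_{1-alpha/2} + z_{power})^2 sigma^2 / delta^2`, rounded up and
#' floored at 2. `"t"` inverts the noncentral-t power function
#' ([stats::power.t.test()]); it is typically one subject more
#' conservative. The alternative group's sd defaults to the null sd.
#'
#' @param mean_null,sd_null Mean and sd under the null (control group).
#' @param mean_alt Mean under the alternative.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.90).
#' @param method `"normal"` (default) or `"t"`.
#' @return Integer sample size per group (>= 2).
#' @export
required_sample_size <- function(mean_null, mean_alt, sd_null,
                                 alpha = 0.05, power = 0.90,
                                 method = c("normal", "t")) {
  method <- match.arg(method)
  if (sd_null <= 0) stop("sd_null must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie strictly in (0, 1)")
  delta <- abs(mean_alt - mean_null)
  if (delta == 0) stop("zero effect size: required sample size is infinite")
  n <- if (method == "normal") {
    2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 *
      sd_null^2 / delta^2
  } else {
    stats::power.t.test(delta = delta, sd = sd_null, sig.level = alpha,
                        power = power, type = "two.sample",
                        alternative = "two.sided")$n
  }
  max(2L, as.integer(ceiling(n - 1e-9)))
}
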