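test_that("group labels are a pure function of mPAp and PAWp", {
  g <- pah_group(c(10, 24.9, 25, 93), c(10, 14, 10, 14))
  expect_equal(as.character(g), c("normal", "normal", "pah", "pah"))
  expect_warning(g2 <- pah_group(c(30, 20), c(20, 10)), "excluded")
  expect_true(is.na(g2[1]))
  expect_equal(as.character(g2[2]), "normal")
})

test_that("pooled t-test matches its summary-statistic twin exactly", {
  set.seed(401)
  xs <- rnorm(35, 0, 1.3)
  ys <- rnorm(25, 0.7, 1.1)
  raw <- two_sample_ttest(xs, ys)
  summ <- ttest_from_summary(mean(xs), sd(xs), 35, mean(ys), sd(ys), 25)
  expect_equal(raw$t, summ$t)
  expect_equal(raw$p, summ$p)
  expect_equal(raw$df, 58)
  # and both agree with stats::t.test(var.equal = TRUE) as oracle
  ht <- stats::t.test(xs, ys, var.equal = TRUE)
  expect_equal(raw$t, unname(ht$statistic))
  expect_equal(raw$p, ht$p.value)
})

test_that("t-test degenerate and identity cases", {
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(c(1, 1, 1), c(2, 2, 2)), "pooled variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "fewer than 2")
  eqm <- ttest_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(eqm$t, 0)
  expect_equal(eqm$p, 1)
})

test_that("a clear shift is detected, consistent with a permutation oracle", {
  xs <- c(1, 2, 3)
  ys <- xs + 10
  res <- two_sample_ttest(xs, ys)
  expect_lt(res$p, 0.001)
  # exact permutation oracle on all 20 splits of the 6 values
  pool <- c(xs, ys)
  stats_all <- apply(utils::combn(6, 3), 2, function(idx)
    abs(mean(pool[idx]) - mean(pool[-idx])))
  obs <- abs(mean(xs) - mean(ys))
  p_perm <- mean(stats_all >= obs - 1e-12)
  expect_equal(p_perm, 2 / 20)      # the observed split is the most extreme
})

test_that("printed clinical-table p-values are reproduced", {
  expect_equal(round(ttest_from_summary(14.1, 18.0, 35, 11.9, 17.4, 25)$p, 2),
               0.64)
  expect_equal(round(ttest_from_summary(95.4, 23.3, 35, 87.6, 24.3, 25)$p, 2),
               0.21)
  expect_equal(round(ttest_from_summary(4.4, 2.5, 35, 3.4, 1.0, 25)$p, 2),
               0.06)
})

test_that("Holm step-down matches hand-derived and library oracles", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.30)), c(0.03, 0.04, 0.30))
  # all permutations of small p-vectors against two oracles
  set.seed(402)
  base_sets <- list(c(0.001, 0.02, 0.04, 0.2, 0.9),
                    c(0.05, 0.05, 0.05), runif(4))
  for (ps in base_sets) {
    perms <- if (length(ps) <= 4) {
      do.call(rbind, lapply(seq_len(factorial(length(ps))), function(i) ps))
    } else NULL
    for (i in 1:20) {
      p <- sample(ps)
      got <- holm_bonferroni(p)
      expect_equal(got, holm_oracle(p))
      expect_equal(got, stats::p.adjust(p, method = "holm"))
      expect_true(all(got >= p))                      # >= raw
      expect_true(all(got <= pmin(1, length(p) * p))) # <= Bonferroni
    }
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site/formant ranking finds the planted cell", {
  set.seed(403)
  sites <- c("apex", "2LICS", "2RICS", "4LICS")
  mk <- function(effects) {
    do.call(rbind, lapply(sites, function(s) do.call(rbind, lapply(1:4,
      function(f) {
        eff <- effects[[paste(s, f)]] %||% 0
        data.frame(
          subject_id = sprintf("S%02d", 1:20), site = s, formant = f,
          group = factor(rep(c("normal", "pah"), each = 10),
                         levels = c("normal", "pah")),
          value = rnorm(20) - c(rep(0, 10), rep(eff, 10)))
      }))))
  }
  tests <- rank_sites_formants(mk(list("2LICS 1" = 3)))
  expect_equal(nrow(tests), 16)
  expect_equal(tests$site[1], "2LICS")
  expect_equal(tests$formant[1], 1)
  expect_true(all(diff(tests$p_raw) >= 0))
  expect_true(all(tests$p_corrected >= tests$p_raw))

  # larger planted effect outranks the smaller one
  two <- rank_sites_formants(mk(list("2LICS 1" = 4, "apex 2" = 1.5)))
  expect_equal(two$site[1], "2LICS")
  expect_lt(which(two$site == "2LICS" & two$formant == 1),
            which(two$site == "apex" & two$formant == 2))

  full <- mk(list())
  incomplete <- full[!(full$site == "apex" & full$formant == 1), ]
  expect_error(rank_sites_formants(incomplete), "apex/formant 1")
})

test_that("null feature tables stay null after correction", {
  set.seed(404)
  n_sig <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    feats <- data.frame(
      subject_id = sprintf("S%02d", 1:20), site = "2LICS", formant = 1,
      group = factor(rep(c("normal", "pah"), each = 10)),
      value = rnorm(20))
    tt <- rank_sites_formants(feats)
    n_sig <- n_sig + any(tt$p_corrected <= 0.05)
  }
  # single-cell family: corrected = raw; rejection rate ~ alpha
  expect_lte(n_sig, qbinom(0.999, n_rep, 0.05) + 1)
})

test_that("window sweep applies Holm across lengths and reports the argmin", {
  set.seed(405)
  lengths <- 1:20
  subj <- sprintf("S%02d", 1:24)
  grp <- factor(rep(c("normal", "pah"), each = 12))
  base <- rnorm(24)
  feats <- do.call(rbind, lapply(lengths, function(L) {
    eff <- if (L == 10) 2.5 else 0.3
    data.frame(subject_id = subj, group = grp, window_length_s = L,
               value = base + rnorm(24, 0, 0.8) -
                 ifelse(grp == "pah", eff, 0))
  }))
  sw <- sweep_window_lengths(feats, lengths = lengths)
  expect_equal(nrow(sw), 20)
  expect_true(all(sw$p_corrected >= sw$p_raw))
  expect_equal(attr(sw, "optimal_length"),
               sw$window_length_s[which.min(sw$p_corrected)])
  expect_equal(attr(sw, "optimal_length"), 10)
})

test_that("required sample size reproduces closed-form cases", {
  expect_equal(required_sample_size(4.75e5, 4.56e5, 9.85e3), 6)
  # effect equal to one sd: 2 * (1.95996 + 1.28155)^2 = 21.01 -> 22
  expect_equal(required_sample_size(0, 1, 1), 22)
  expect_equal(required_sample_size(4.75e5, 4.56e5, 9.85e3, method = "t"), 7)
  expect_error(required_sample_size(5, 5, 1), "zero effect")
  expect_error(required_sample_size(0, 1, 0), "sd_null")
})

test_that("Monte-Carlo power at the returned n meets the target", {
  set.seed(406)
  n <- required_sample_size(0, 1, 1, alpha = 0.05, power = 0.90)
  rej <- replicate(600, {
    two_sample_ttest(rnorm(n, 0), rnorm(n, 1))$p <= 0.05
  })
  expect_gte(mean(rej), 0.90 - 0.04)
})
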