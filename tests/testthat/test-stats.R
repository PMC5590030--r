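# group statistics: BH-FDR, Pearson, sample size, contrasts, ANOVA

test_that("fdr_adjust reproduces the hand-computed BH step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)                  # m = 1 identity
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("fdr_adjust matches the brute-force oracle and p.adjust on random vectors", {
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
})

test_that("pearson_correlation handles perfect linearity and rejects degenerates", {
  x <- 1:5
  res <- pearson_correlation(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_error(pearson_correlation(x, rep(3, 5)), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
  # agrees with the base oracle on a generic sample
  set.seed(5)
  a <- rnorm(12); b <- a + rnorm(12)
  ct <- cor.test(a, b)
  mine <- pearson_correlation(a, b)
  expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(mine$p, ct$p.value, tolerance = 1e-10)
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)
})

test_that("r = 0.73 at n = 5 reproduces the reported p and CI within rounding", {
  # construct a 5-point sample with r exactly 0.73 via Gram-Schmidt
  x <- c(-2, -1, 0, 1, 2)
  e <- c(1, -1, 0, -1, 1)
  e <- e - mean(e) - sum(e * x) / sum(x * x) * x     # orthogonal to x
  r_target <- 0.73
  y <- r_target * x / sqrt(sum(x^2)) +
    sqrt(1 - r_target^2) * e / sqrt(sum(e^2))
  res <- pearson_correlation(x, y)
  expect_equal(res$r, 0.73, tolerance = 1e-10)
  expect_lt(abs(res$p - 0.17), 0.015)
  expect_lt(abs(res$ci_high - 0.98), 0.015)
  expect_lt(abs(res$ci_low - (-0.44)), 0.015)
  # the printed two-decimal values are attainable for some r rounding to 0.73
  rs <- seq(0.725, 0.7349, by = 5e-4)
  cis <- vapply(rs, function(r) tanh(atanh(r) - qnorm(0.975) / sqrt(2)),
                numeric(1))
  ps <- vapply(rs, function(r) 2 * pt(-abs(r * sqrt(3) / sqrt(1 - r^2)), 3),
               numeric(1))
  expect_true(any(round(cis, 2) == -0.44 & round(ps, 2) == 0.17))
})

test_that("pearson p-values are uniform under independence at n = 5", {
  set.seed(101)
  p <- replicate(2000, pearson_correlation(rnorm(5), rnorm(5))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("required_sample_size matches the noncentral-t oracle", {
  # frozen oracle: power(n=5, d=2, a=.05) = 0.7905 < 0.8 <= power(n=6)
  res <- required_sample_size(40, 20, alpha = 0.05, power = 0.8)
  expect_equal(res$n, 6L)
  expect_equal(res$d, 2)
  res3 <- required_sample_size(40, 20, alpha = 0.05, power = 0.8,
                               n_pairwise = 3)
  expect_equal(res3$n, 7L)
  expect_equal(res3$alpha_adjusted, 0.05 / 3)
  # floor contract: vanishing power still requires n = 2 for SD estimation
  expect_equal(required_sample_size(40, 20, power = 1e-12)$n, 2L)
  expect_error(required_sample_size(0, 20), "positive")
  # monotone: non-increasing in the effect, non-decreasing in the family size
  ns <- vapply(c(20, 40, 60, 80), function(red)
    required_sample_size(red, 20)$n, integer(1))
  expect_true(all(diff(ns) <= 0))
  np <- vapply(1:4, function(k)
    required_sample_size(40, 20, n_pairwise = k)$n, integer(1))
  expect_true(all(diff(np) >= 0))
})

test_that("the analytic power function agrees with simulation", {
  n <- 6; d <- 2
  set.seed(202)
  rej <- replicate(20000, {
    g1 <- rnorm(n, 0, 1); g2 <- rnorm(n, d, 1)
    abs(mean(g1) - mean(g2)) /
      sqrt((var(g1) + var(g2)) / n) > qt(0.975, 2 * n - 2)
  })
  analytic <- required_sample_size(40, 20)$achieved_power
  expect_equal(mean(rej), analytic, tolerance = 0.02)
})

test_that("compare_cells handles identical groups and small cells", {
  tab <- null_group_table(n_per_cell = 4)
  # identical data in both agents -> estimate 0, p = 1
  tab2 <- tab
  vals <- ave(tab2$eq3_ce_volume_percent,
              tab2$roi, tab2$day, FUN = function(v) v[1])
  tab2$eq3_ce_volume_percent <- vals
  res <- compare_cells(tab2, model = "welch")
  expect_true(all(res$estimate == 0))
  expect_true(all(res$p == 1))
  # a 1-subject cell is skipped with a reason
  tab3 <- tab[!(tab$agent == "control" & tab$roi == "core" & tab$day == 1 &
                  seq_len(nrow(tab)) %in% which(tab$agent == "control" &
                                                  tab$roi == "core" &
                                                  tab$day == 1)[-1]), ]
  res3 <- compare_cells(tab3, model = "welch")
  skipped <- res3[res3$roi == "core" & res3$day == 1, ]
  expect_true(skipped$skipped)
  expect_match(skipped$reason, "fewer than 2")
  # adjusted p never below raw p
  ok <- !res3$skipped
  expect_true(all(res3$p_adj[ok] >= res3$p[ok] - 1e-15))
})

test_that("welch and mixed backends agree in sign on a balanced table", {
  set.seed(303)
  tab <- null_group_table(n_per_cell = 5)
  # deterministic structure: subject offsets + cell effects
  eff <- c(core = 3, borderzone = -2, contralesional = 0.5)
  tab$eq3_ce_volume_percent <- ifelse(tab$agent == "targeted",
                                      eff[tab$roi], 0) +
    as.numeric(factor(tab$subject)) * 0.01
  rw <- compare_cells(tab, model = "welch")
  rm_ <- compare_cells(tab, model = "mixed")
  key <- paste(rw$roi, rw$day)
  expect_equal(key, paste(rm_$roi, rm_$day))
  expect_true(all(sign(rw$estimate) == sign(rm_$estimate)))
  expect_equal(rw$estimate, rm_$estimate, tolerance = 0.2)
})

test_that("a strong single-cell effect is detected and nulls stay calibrated", {
  set.seed(404)
  n_rep <- 60
  hit <- logical(n_rep)
  null_sig <- 0L; null_n <- 0L
  for (i in seq_len(n_rep)) {
    tab <- null_group_table(n_per_cell = 5)
    sel <- tab$agent == "targeted" & tab$roi == "core" & tab$day == 2
    tab$eq3_ce_volume_percent[sel] <- tab$eq3_ce_volume_percent[sel] + 5
    res <- compare_cells(tab, model = "welch")
    tgt <- res$roi == "core" & res$day == 2
    hit[i] <- res$p_adj[tgt] < 0.05
    null_sig <- null_sig + sum(res$p_adj[!tgt] < 0.05)
    null_n <- null_n + sum(!tgt)
  }
  expect_gte(mean(hit), 0.9)          # the seeded cell is found
  expect_lte(null_sig / null_n, 0.05) # null cells rarely adjusted-significant
})

test_that("treatment_effect runs the one-way ANOVA on lesion-fraction change", {
  # degenerate: zero within-group variance and equal means -> F = 0
  tab0 <- data.frame(subject = paste0("s", 1:9),
                     agent = rep(c("saline", "control", "targeted"), each = 3),
                     change = rep(5, 9))
  r0 <- treatment_effect(tab0, change_col = "change")
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)
  # long-format day-1/day-3 input: matches an aov oracle
  set.seed(505)
  subj <- paste0("m", 1:18)
  agent <- rep(c("saline", "control", "targeted"), each = 6)
  f1 <- runif(18, 15, 25)
  f3 <- f1 * (1 + rnorm(18, -0.05, 0.2))
  tab <- rbind(data.frame(subject = subj, agent = agent, day = 1,
                          hemispheric_lesion_fraction = f1),
               data.frame(subject = subj, agent = agent, day = 3,
                          hemispheric_lesion_fraction = f3))
  res <- treatment_effect(tab)
  change <- 100 * (f3 - f1) / f1
  oracle <- summary(aov(change ~ agent))[[1]]
  expect_equal(res$f, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(treatment_effect(tab0[1:3, ], change_col = "change"),
               ">= 2 groups")
})

test_that("treatment_effect is calibrated under the null and powered for 3-SD shifts", {
  set.seed(606)
  p_null <- replicate(300, {
    tab <- data.frame(subject = paste0("s", 1:18),
                      agent = rep(c("saline", "control", "targeted"),
                                  each = 6),
                      change = rnorm(18))
    treatment_effect(tab, change_col = "change")$p
  })
  expect_gt(suppressWarnings(ks.test(p_null, "punif"))$p.value, 0.01)
  hit <- replicate(100, {
    ch <- rnorm(18)
    ch[13:18] <- ch[13:18] - 3          # targeted group shifted by 3 SD
    tab <- data.frame(subject = paste0("s", 1:18),
                      agent = rep(c("saline", "control", "targeted"),
                                  each = 6),
                      change = ch)
    treatment_effect(tab, change_col = "change")$p < 0.05
  })
  expect_gte(mean(hit), 0.95)
})

test_that("apply_exclusions filters with per-row reasons", {
  tab <- data.frame(subject = paste0("s", 1:5),
                    died_before_mri = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                    lesion_volume_mm3 = c(3, 0, 4, 5, 6),
                    injection_failed = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  res <- apply_exclusions(tab)
  expect_equal(res$kept$subject, c("s4", "s5"))
  expect_equal(res$excluded$reason,
               c("mortality before MRI", "no lesion on T2 map",
                 "inadequate contrast agent delivery"))
})
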