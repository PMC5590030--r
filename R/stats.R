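# Group-level statistics: per-cell agent contrasts with FDR control, the
# lesion-volume/CE-fraction correlation, the treatment-effect ANOVA on lesion
# fraction change, and the noncentral-t sample-size calculation.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply p_(i) by m/i, enforce
#' monotonicity from the largest rank down, cap at 1. Output order matches
#' the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order; each adjusted value is
#'   >= its raw value.
#' @export
fdr_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pearson product-moment correlation with Fisher confidence interval
#'
#' Two-sided p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df; 95%
#' CI via the Fisher z transform with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @param conf_level confidence level (default 0.95).
#' @return list with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * q * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n)
}

# exact power of the two-sided two-sample t-test at per-group size n,
# standardized effect d, significance level alpha (noncentral t)
two_sample_t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}

#' Per-group sample size for a pairwise two-sample t-test
#'
#' Smallest integer n per group at which the two-sided two-sample t-test at
#' level `alpha / n_pairwise` (Bonferroni over the pairwise family) reaches
#' the requested power for the standardized effect
#' `d = reduction_percent / sd_percent`, using the exact noncentral-t power
#' function. The reduction and its SD are interpreted on the same percent
#' scale, so d is their ratio. The floor is n = 2 (minimum for SD
#' estimation).
#'
#' @param reduction_percent expected group difference, in percent units
#'   (e.g. 40 for a 40% lesion reduction).
#' @param sd_percent between-animal SD on the same percent scale (e.g. 20).
#' @param alpha familywise two-sided significance level (default 0.05).
#' @param power target power (default 0.8).
#' @param n_pairwise number of pairwise comparisons Bonferroni-corrected for
#'   (default 1 = no correction).
#' @param n_max search cap.
#' @return list with `n` (per group), `d`, `alpha_adjusted`, and
#'   `achieved_power`.
#' @export
required_sample_size <- function(reduction_percent, sd_percent, alpha = 0.05,
                                 power = 0.8, n_pairwise = 1L, n_max = 1000L) {
  if (reduction_percent <= 0 || sd_percent <= 0)
    stop("reduction_percent and sd_percent must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power < 0 || power >= 1) stop("power must lie in [0, 1)")
  if (n_pairwise < 1) stop("n_pairwise must be >= 1")
  d <- reduction_percent / sd_percent
  a <- alpha / n_pairwise
  for (n in 2:n_max) {
    pw <- two_sample_t_power(n, d, a)
    if (pw >= power)
      return(list(n = n, d = d, alpha_adjusted = a, achieved_power = pw))
  }
  stop("requested power not reachable within n_max = ", n_max)
}

check_group_table <- function(table, value) {
  need <- c("subject", "agent", "day", "roi", value)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("group table lacks column(s): ", paste(missing_cols, collapse = ", "))
  invisible(table)
}

#' Per-cell contrasts between the two contrast agents
#'
#' For every ROI x day cell, tests the targeted-vs-control agent difference
#' of a quantification endpoint (default the CE volume percentage), then
#' FDR-adjusts the family of cell p-values with [fdr_adjust()].
#'
#' Two backends:
#' \describe{
#'   \item{`welch`}{independent two-sample Welch t-test per cell. Simple,
#'     assumption-light, and used for the calibration simulations.}
#'   \item{`mixed`}{one linear mixed model on the full table
#'     (`value ~ roi * agent * day + (1 | subject)`, fitted with lme4), then
#'     Wald-z per-cell contrasts from the fixed effects. A reconstruction:
#'     the factor structure is known but the original random-effects /
#'     covariance specification is not.}
#' }
#'
#' Cells with fewer than 2 subjects per agent are skipped; the returned table
#' records the reason.
#'
#' @param table data.frame with columns `subject`, `agent`, `day`, `roi` and
#'   the `value` column.
#' @param model `"welch"` or `"mixed"`.
#' @param value name of the endpoint column (default
#'   `"eq3_ce_volume_percent"`).
#' @param agents length-2 character vector, contrast = first minus second
#'   (default targeted minus control).
#' @return data.frame of test results: `contrast`, `roi`, `day`, `estimate`,
#'   `p`, `p_adj`, `n_1`, `n_2`, `skipped`, `reason`.
#' @export
compare_cells <- function(table, model = c("welch", "mixed"),
                          value = "eq3_ce_volume_percent",
                          agents = c("targeted", "control")) {
  model <- match.arg(model)
  check_group_table(table, value)
  if (length(agents) != 2L) stop("agents must name exactly 2 levels")
  tab <- table[table$agent %in% agents, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for the requested agents")
  cells <- unique(tab[, c("roi", "day")])
  cells <- cells[order(cells$roi, cells$day), , drop = FALSE]

  fit <- NULL
  if (model == "mixed") {
    mtab <- tab
    mtab$roi <- factor(mtab$roi)
    mtab$agent <- factor(mtab$agent, levels = agents)
    mtab$day <- factor(mtab$day)
    form <- stats::as.formula(paste(value, "~ roi * agent * day + (1 | subject)"))
    # desk-scale tables often have negligible between-subject variance, so
    # singular / boundary fits are expected; Wald contrasts stay well-defined
    fit <- lme4::lmer(form, data = mtab,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        check.conv.grad = "ignore",
                        check.conv.hess = "ignore"))
    fe <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    tt <- stats::delete.response(stats::terms(fit))
  }

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    roi_i <- cells$roi[i]; day_i <- cells$day[i]
    sub <- tab[tab$roi == roi_i & tab$day == day_i, ]
    v1 <- sub[[value]][sub$agent == agents[1]]
    v2 <- sub[[value]][sub$agent == agents[2]]
    base <- data.frame(contrast = paste(agents[1], "-", agents[2]),
                       roi = roi_i, day = day_i,
                       estimate = NA_real_, p = NA_real_, p_adj = NA_real_,
                       n_1 = length(v1), n_2 = length(v2),
                       skipped = FALSE, reason = "")
    if (length(v1) < 2L || length(v2) < 2L) {
      base$skipped <- TRUE
      base$reason <- "fewer than 2 subjects in a compared cell"
      return(base)
    }
    if (model == "welch") {
      if (stats::sd(c(v1, v2)) == 0) {
        base$estimate <- 0; base$p <- 1
      } else {
        ht <- tryCatch(stats::t.test(v1, v2), error = function(e) NULL)
        if (is.null(ht)) {   # zero variance within both groups
          base$estimate <- mean(v1) - mean(v2)
          base$p <- if (base$estimate == 0) 1 else 0
        } else {
          base$estimate <- unname(ht$estimate[1] - ht$estimate[2])
          base$p <- ht$p.value
        }
      }
    } else {
      lv <- lapply(fit@frame[c("roi", "agent", "day")], levels)
      nd <- data.frame(roi = factor(c(roi_i, roi_i), levels = lv$roi),
                       agent = factor(agents, levels = lv$agent),
                       day = factor(c(day_i, day_i), levels = lv$day))
      mf <- stats::model.frame(tt, nd, xlev = lv)
      X <- stats::model.matrix(tt, mf)
      L <- X[1, ] - X[2, ]
      est <- sum(L * fe)
      se <- sqrt(drop(t(L) %*% vc %*% L))
      base$estimate <- est
      base$p <- 2 * stats::pnorm(-abs(est / se))
    }
    base
  })
  out <- do.call(rbind, rows)
  tested <- !out$skipped
  if (any(tested)) out$p_adj[tested] <- fdr_adjust(out$p[tested])
  out
}

#' One-way ANOVA for a treatment effect on lesion growth
#'
#' Tests whether the day-1 to day-3 change in hemispheric lesion fraction
#' differs between treatment groups (saline, control agent, targeted agent).
#' The change score is the relative change in percent,
#' `100 * (f_day3 - f_day1) / f_day1`, per subject.
#'
#' @param table data.frame with columns `subject`, `agent`, `day`,
#'   `hemispheric_lesion_fraction` containing both days for each subject,
#'   or precomputed changes via `change_col`.
#' @param days length-2 vector of the baseline and follow-up day (default
#'   `c(1, 3)`).
#' @param change_col optional name of a precomputed change column; when given,
#'   `table` needs one row per subject.
#' @return list with `f`, `p`, `df`, `group_means`, `n_per_group`.
#' @export
treatment_effect <- function(table, days = c(1, 3), change_col = NULL) {
  if (is.null(change_col)) {
    need <- c("subject", "agent", "day", "hemispheric_lesion_fraction")
    if (!all(need %in% names(table)))
      stop("table lacks column(s): ",
           paste(setdiff(need, names(table)), collapse = ", "))
    base <- table[table$day == days[1], ]
    fup <- table[table$day == days[2], ]
    m <- merge(base[, c("subject", "agent", "hemispheric_lesion_fraction")],
               fup[, c("subject", "hemispheric_lesion_fraction")],
               by = "subject", suffixes = c("_base", "_fup"))
    if (!nrow(m)) stop("no subject has both time points")
    m$change <- 100 * (m$hemispheric_lesion_fraction_fup -
                         m$hemispheric_lesion_fraction_base) /
      m$hemispheric_lesion_fraction_base
    dat <- data.frame(agent = m$agent, change = m$change)
  } else {
    dat <- data.frame(agent = table$agent, change = table[[change_col]])
  }
  groups <- split(dat$change, dat$agent)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (length(groups) < 2L) stop("need >= 2 groups with >= 2 subjects")
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  gm <- vapply(groups, mean, 1)
  grand <- sum(n * gm) / sum(n)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1
  df2 <- sum(n) - k
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  if (ssw == 0 && ssb == 0) p <- 1
  list(f = f, p = p, df = c(df1, df2), group_means = gm, n_per_group = n)
}

#' Declarative subject exclusion filter
#'
#' Applies the protocol exclusion rules as row filters with per-row reasons
#' rather than hard-coded drops: death before MRI, absence of a lesion on the
#' T2 map, inadequate contrast-agent delivery.
#'
#' @param table data.frame with a `subject` column; optional logical columns
#'   `died_before_mri` and `injection_failed`, and a numeric
#'   `lesion_volume_mm3`.
#' @param min_lesion_volume subjects below this lesion volume (mm^3) are
#'   excluded as "no lesion" (default: strictly positive volume required).
#' @return list with `kept` (filtered table) and `excluded` (data.frame of
#'   `subject`, `reason`).
#' @export
apply_exclusions <- function(table, min_lesion_volume = 0) {
  stopifnot("subject" %in% names(table))
  reason <- rep(NA_character_, nrow(table))
  if ("died_before_mri" %in% names(table))
    reason[is.na(reason) & table$died_before_mri %in% TRUE] <-
      "mortality before MRI"
  if ("lesion_volume_mm3" %in% names(table))
    reason[is.na(reason) & table$lesion_volume_mm3 <= min_lesion_volume] <-
      "no lesion on T2 map"
  if ("injection_failed" %in% names(table))
    reason[is.na(reason) & table$injection_failed %in% TRUE] <-
      "inadequate contrast agent delivery"
  drop <- !is.na(reason)
  list(kept = table[!drop, , drop = FALSE],
       excluded = data.frame(subject = table$subject[drop],
                             reason = reason[drop]))
}
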