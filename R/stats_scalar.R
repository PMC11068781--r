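#' Cohen's d from group summary statistics
#'
#' Effect size between two conditions computed from their means and
#' standard deviations with the equal-weight pooled SD:
#' \deqn{d = \frac{|m_1 - m_2|}{\sqrt{(s_1^2 + s_2^2)/2}}.}
#' This is the convention that reproduces published dive-kinematics effect
#' sizes from their group tables.
#'
#' @param mean1,sd1 mean and SD of the first condition.
#' @param mean2,sd2 mean and SD of the second condition.
#' @return Cohen's d (non-negative scalar).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (!(sd1 > 0 && sd2 > 0)) stop("standard deviations must be positive")
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Paired Student's t test with effect size
#'
#' Classical two-sided paired t test, reported together with Cohen's d
#' computed from the two samples' means and SDs (see [cohens_d()]).
#'
#' @param x,y paired numeric samples of equal length (n >= 2).
#' @param label optional comparison label carried into the result.
#' @return object of class `scalar_test`: list with `statistic`, `df`,
#'   `p_value`, `effect_size_d`, `label`.
#' @export
paired_t <- function(x, y, label = "paired") {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("paired t test needs n >= 2")
  d <- x - y
  if (stats::sd(d) < 1e-14)
    stop_divekin("zero-variance paired differences: t test degenerate",
                 "divekin_degenerate_test")
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 effect_size_d = cohens_d(mean(x), stats::sd(x),
                                          mean(y), stats::sd(y)),
                 label = label),
            class = "scalar_test")
}

#' @export
print.scalar_test <- function(x, ...) {
  cat(sprintf("<scalar_test> %s: t(%g) = %.3f, p = %.4g, d = %.2f\n",
              x$label, x$df, x$statistic, x$p_value, x$effect_size_d))
  invisible(x)
}

#' Mixed two-way repeated-measures ANOVA with Bonferroni contrasts
#'
#' Mixed-design ANOVA with one between-subject factor (`group`, e.g.
#' control vs video-instruction) and one within-subject factor (`time`,
#' pre vs post), on one scalar value per subject and time level. F tests
#' come from the standard balanced mixed-design sums of squares (between
#' stratum: group; within stratum: time and group:time). The four cell
#' contrasts conventionally reported for this design are returned with
#' Bonferroni-adjusted p values: pre vs post within each group (paired t)
#' and between groups at each time (two-sample pooled t).
#'
#' @param values numeric response, one entry per subject x time.
#' @param group between-subject factor (2 levels).
#' @param time within-subject factor (2 levels).
#' @param subject subject identifier.
#' @param alpha significance level carried into the report. Default 0.05.
#' @return object of class `mixed_anova`: list with `anova_table`
#'   (effect, df1, df2, F, p) and `contrasts` (comparison, estimate, t,
#'   df, p, p_bonferroni).
#' @export
mixed_anova <- function(values, group, time, subject, alpha = 0.05) {
  dat <- data.frame(y = as.numeric(values), group = factor(group),
                    time = factor(time), subject = factor(subject))
  if (nlevels(dat$group) != 2L || nlevels(dat$time) != 2L)
    stop("mixed_anova expects exactly 2 group levels and 2 time levels")
  tab <- table(dat$subject, dat$time)
  if (any(tab != 1L))
    stop_divekin("unbalanced within-subject data: every subject needs exactly one value per time level",
                 "divekin_unbalanced_design")
  subj_group <- unique(dat[, c("subject", "group")])
  if (any(table(subj_group$group) < 2L))
    stop_divekin("each group needs >= 2 subjects", "divekin_unbalanced_design")
  if (nrow(subj_group) != nlevels(dat$subject))
    stop("a subject appears in more than one group")

  fit <- stats::aov(y ~ group * time + Error(subject), data = dat)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1L]]
  within <- sm[["Error: Within"]][[1L]]
  rn <- function(x) trimws(rownames(x))
  pick <- function(strat, eff) {
    i <- match(eff, rn(strat))
    res <- match("Residuals", rn(strat))
    data.frame(effect = eff, df1 = strat$Df[i], df2 = strat$Df[res],
               F = strat$`F value`[i], p = strat$`Pr(>F)`[i])
  }
  anova_table <- rbind(pick(between, "group"),
                       pick(within, "time"),
                       pick(within, "group:time"))
  # all-equal data: aov reports NaN F on zero SS; the null convention is F = 0, p = 1
  degen <- is.nan(anova_table$F)
  anova_table$F[degen] <- 0
  anova_table$p[degen] <- 1

  g <- levels(dat$group); tl <- levels(dat$time)
  cell <- function(gi, ti) {
    d <- dat[dat$group == g[gi] & dat$time == tl[ti], ]
    d$y[order(d$subject)]
  }
  ct <- function(label, x, y, paired) {
    spread <- if (paired) stats::sd(x - y) else stats::sd(c(x - mean(x), y - mean(y)))
    if (spread < 1e-14) {  # zero-variance cell pair: t.test would abort
      delta <- mean(x) - mean(y)
      return(data.frame(comparison = label, estimate = delta,
                        t = if (abs(delta) < 1e-14) 0 else sign(delta) * Inf,
                        df = length(x) - 1,
                        p = if (abs(delta) < 1e-14) 1 else 0))
    }
    tt <- if (paired) stats::t.test(x, y, paired = TRUE)
          else stats::t.test(x, y, var.equal = TRUE)
    data.frame(comparison = label, estimate = mean(x) - mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  contrasts <- rbind(
    ct(sprintf("%s_%s x %s_%s", g[1], tl[1], g[1], tl[2]), cell(1, 1), cell(1, 2), TRUE),
    ct(sprintf("%s_%s x %s_%s", g[1], tl[1], g[2], tl[1]), cell(1, 1), cell(2, 1), FALSE),
    ct(sprintf("%s_%s x %s_%s", g[2], tl[1], g[2], tl[2]), cell(2, 1), cell(2, 2), TRUE),
    ct(sprintf("%s_%s x %s_%s", g[1], tl[2], g[2], tl[2]), cell(1, 2), cell(2, 2), FALSE))
  contrasts$p_bonferroni <- pmin(1, contrasts$p * nrow(contrasts))

  structure(list(anova_table = anova_table, contrasts = contrasts,
                 alpha = alpha),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("<mixed_anova>\n")
  print(x$anova_table, row.names = FALSE)
  cat("Bonferroni-adjusted cell contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
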