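test_that("cohens_d implements the equal-weight pooled-SD convention", {
  expect_equal(cohens_d(1, 1, 1, 2), 0)
  expect_equal(cohens_d(0, 1, 1, 1), 1)
  # symmetry and scale invariance
  expect_equal(cohens_d(3, 0.4, 2, 0.9), cohens_d(2, 0.9, 3, 0.4))
  expect_equal(cohens_d(30, 4, 20, 9), cohens_d(3, 0.4, 2, 0.9))
  expect_error(cohens_d(1, 0, 2, 1), "positive")
})

test_that("published group tables reproduce their printed effect sizes", {
  stats_path <- system.file("extdata", "study_summary_stats.csv",
                            package = "divekin")
  tab <- read.csv(stats_path)
  printed <- tab[!is.na(tab$printed_d), ]
  expect_equal(nrow(printed), 4L)
  for (i in seq_len(nrow(printed))) {
    d <- cohens_d(printed$mean1[i], printed$sd1[i],
                  printed$mean2[i], printed$sd2[i])
    expect_equal(round(d, 2), printed$printed_d[i])
  }
})

test_that("paired t reduces to the closed-form hand calculation", {
  x <- c(12.1, 14.3, 11.8, 13.5, 12.9)
  y <- c(11.4, 13.1, 12.0, 12.2, 12.5)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  r <- paired_t(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_error(paired_t(x, x + 1), class = "divekin_degenerate_test")
  expect_error(paired_t(x, y[1:3]), "equal length")
})

test_that("paired-t p values are uniform under the null", {
  set.seed(17)
  p <- replicate(4000, {
    x <- rnorm(8); y <- rnorm(8)
    paired_t(x, y)$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("SPM paired t on identical curve sets yields no clusters", {
  set.seed(1)
  a <- matrix(rnorm(5 * 101), 5, 101)
  r <- spm_paired_t(a, a, n_perm = 500)
  expect_true(all(r$t_curve == 0))
  expect_equal(nrow(r$clusters), 0L)
})

test_that("SPM node-wise t equals the scalar paired t at each node", {
  set.seed(2)
  a <- matrix(rnorm(8 * 101), 8, 101)
  b <- matrix(rnorm(8 * 101), 8, 101)
  r <- spm_paired_t(a, b, n_perm = 300)
  node_t <- vapply(1:101, function(j) paired_t(a[, j], b[, j])$statistic, 0)
  expect_equal(r$t_curve, node_t, tolerance = 1e-10)
})

test_that("a localized offset is detected as a cluster matching the exhaustive oracle", {
  set.seed(42)
  n <- 8
  a <- matrix(rnorm(n * 101), n, 101)
  b <- a
  b[, 41:61] <- b[, 41:61] + 2.5
  b <- b + matrix(rnorm(n * 101, 0, 0.2), n, 101)
  r <- spm_paired_t(a, b, n_perm = 10000)
  expect_identical(r$method, "exhaustive")
  expect_equal(r$n_perm, 256L)
  expect_gte(nrow(r$clusters), 1L)
  # the widest cluster overlaps the 40-60% window
  k <- which.max(r$clusters$extent_nodes)
  expect_lt(r$clusters$start_pct[k], 60)
  expect_gt(r$clusters$end_pct[k], 40)
  expect_lt(r$clusters$p_value[k], 0.05)

  # independent oracle: explicit enumeration of all 2^8 sign flips
  D <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  tmat <- apply(signs, 1, function(s) {
    Ds <- D * s
    apply(Ds, 2, function(col) mean(col) / (sd(col) / sqrt(n)))
  })                                   # 101 x 256
  maxT <- apply(abs(tmat), 2, max)
  t_crit_oracle <- sort(maxT)[ceiling(0.95 * 256)]
  expect_equal(r$t_crit, t_crit_oracle, tolerance = 1e-12)
  obs_supra <- abs(tmat[, which(rowSums(signs == 1) == n)[1]]) > t_crit_oracle
  rl <- rle(as.vector(obs_supra))
  obs_ext <- max(rl$lengths[rl$values])
  perm_ext <- apply(abs(tmat) > t_crit_oracle, 2, function(z) {
    if (!any(z)) return(0L)
    rz <- rle(z); max(rz$lengths[rz$values])
  })
  expect_equal(r$clusters$p_value[k], mean(perm_ext >= obs_ext),
               tolerance = 1e-12)
})

test_that("SPM permutation inference is reproducible and relabeling-invariant", {
  set.seed(3)
  a <- matrix(rnorm(12 * 101), 12, 101)
  b <- matrix(rnorm(12 * 101), 12, 101) + 0.8
  r1 <- spm_paired_t(a, b, n_perm = 800, seed = 10)
  r2 <- spm_paired_t(a, b, n_perm = 800, seed = 10)
  expect_identical(r1$method, "random")
  expect_equal(r1$t_crit, r2$t_crit)
  expect_equal(r1$clusters, r2$clusters)
  # relabeling pairs: shuffle rows jointly; exhaustive enumeration makes
  # the permutation set itself relabeling-invariant
  perm <- sample(12)
  rownames(a) <- rownames(b) <- sprintf("s%02d", 1:12)
  r3 <- spm_paired_t(a, b, n_perm = 5000, seed = 10)
  r4 <- spm_paired_t(a[perm, ], b[perm, ], n_perm = 5000, seed = 10)
  expect_identical(r3$method, "exhaustive")
  expect_equal(r3$t_crit, r4$t_crit)
  expect_error(spm_paired_t(a, b[1:11, ]), "identical dimensions")
  bb <- b; rownames(bb)[1] <- "zz"
  expect_error(spm_paired_t(a, bb), class = "divekin_pairing_error")
})

test_that("mixed ANOVA matches an independent sums-of-squares oracle", {
  set.seed(5)
  ns <- 4
  dat <- expand.grid(subject = 1:(2 * ns), time = c("pre", "post"))
  dat$group <- ifelse(dat$subject <= ns, "CG", "VG")
  dat$y <- rnorm(nrow(dat)) + ifelse(dat$group == "VG" & dat$time == "post", 1.5, 0)
  m <- mixed_anova(dat$y, dat$group, dat$time, dat$subject)

  y <- dat$y; g <- factor(dat$group); tm <- factor(dat$time); s <- factor(dat$subject)
  gm <- mean(y)
  m_g <- tapply(y, g, mean); m_t <- tapply(y, tm, mean)
  m_gt <- tapply(y, list(g, tm), mean); m_s <- tapply(y, s, mean)
  subj_group <- tapply(as.character(g), s, function(z) z[1])
  ss_g <- 2 * ns * sum((m_g - gm)^2)
  ss_sw <- 2 * sum((m_s - m_g[subj_group])^2)
  ss_t <- 2 * ns * sum((m_t - gm)^2)
  ss_gt <- ns * sum((sweep(sweep(m_gt, 1, m_g - gm), 2, m_t - gm) - gm)^2)
  ss_err <- sum((y - gm)^2) - ss_g - ss_sw - ss_t - ss_gt
  F_oracle <- c(ss_g / (ss_sw / (2 * ns - 2)),
                ss_t / (ss_err / (2 * ns - 2)),
                ss_gt / (ss_err / (2 * ns - 2)))
  expect_equal(m$anova_table$F, F_oracle, tolerance = 1e-8)
  expect_equal(m$anova_table$df1, rep(1L, 3))
  expect_equal(m$anova_table$df2, rep(2L * ns - 2L, 3))
})

test_that("all-equal data gives F = 0 and p = 1 throughout", {
  dat <- expand.grid(subject = 1:8, time = c("pre", "post"))
  dat$group <- ifelse(dat$subject <= 4, "CG", "VG")
  m <- mixed_anova(rep(3.2, 16), dat$group, dat$time, dat$subject)
  expect_equal(m$anova_table$F, rep(0, 3))
  expect_equal(m$anova_table$p, rep(1, 3))
  expect_equal(m$contrasts$t, rep(0, 4))
  expect_equal(m$contrasts$p_bonferroni, rep(1, 4))
})

test_that("a pure interaction is flagged as interaction, not main effects", {
  # group effects of opposite sign pre vs post, with disturbance patterns
  # constructed orthogonal to both main effects: the interaction F must
  # fire while both main-effect sums of squares are exactly zero
  dat <- expand.grid(subject = 1:8, time = c("pre", "post"))
  dat$group <- ifelse(dat$subject <= 4, "CG", "VG")
  delta <- ifelse(dat$group == "CG", 1, -1) * ifelse(dat$time == "pre", 1, -1)
  subj_wiggle <- c(0.3, -0.3, 0.2, -0.2)[((dat$subject - 1) %% 4) + 1]
  within_wiggle <- ifelse(dat$subject %% 2 == 0, 0.15, -0.15) *
    ifelse(dat$time == "pre", 1, -1)
  dat$y <- delta + subj_wiggle + within_wiggle
  m <- mixed_anova(dat$y, dat$group, dat$time, dat$subject)
  at <- m$anova_table
  expect_lt(at$p[at$effect == "group:time"], 0.05)
  expect_gt(at$p[at$effect == "group"], 0.5)
  expect_gt(at$p[at$effect == "time"], 0.5)
})

test_that("unbalanced designs are rejected", {
  dat <- expand.grid(subject = 1:8, time = c("pre", "post"))
  dat$group <- ifelse(dat$subject <= 4, "CG", "VG")
  expect_error(mixed_anova(rnorm(15), dat$group[-1], dat$time[-1],
                           dat$subject[-1]),
               class = "divekin_unbalanced_design")
})
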