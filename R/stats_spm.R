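#' One-dimensional SPM paired t test with permutation inference
#'
#' Node-wise paired t statistic along time-normalized curves, with
#' family-wise inference by the maximum-statistic permutation method:
#' the paired differences are sign-flipped (exhaustively when `2^n <=
#' n_perm`, otherwise by `n_perm` random flips that always include the
#' identity), the critical threshold `t_crit` is the `1 - alpha` quantile
#' of the permutation distribution of `max |t|` over nodes, and each
#' maximal suprathreshold run (cluster) of the observed `|t|` curve gets a
#' p value equal to the proportion of permutations whose largest
#' suprathreshold cluster extent reaches the observed extent.
#'
#' @param a,b matrices of paired curves, units x nodes (e.g. subjects x
#'   101); rows are pairing units, matched by rowname when present,
#'   otherwise by position.
#' @param alpha family-wise significance level. Default 0.05.
#' @param n_perm permutation budget. Default 10000.
#' @param seed RNG seed for the random-flip branch (exhaustive enumeration
#'   is deterministic regardless).
#' @return object of class `spm_result`: list with `t_curve`, `t_crit`,
#'   `clusters` (data.frame: start_pct, end_pct, extent_nodes, p_value),
#'   `alpha`, `n_perm`, `method` (`"exhaustive"` or `"random"`).
#' @export
spm_paired_t <- function(a, b, alpha = 0.05, n_perm = 10000L, seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("curve sets must have identical dimensions")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b)))
      stop_divekin("curve sets are not paired: unit ids differ", "divekin_pairing_error")
    b <- b[rownames(a), , drop = FALSE]
  }
  n <- nrow(a); q <- ncol(a)
  if (n < 2L) stop("SPM paired t needs >= 2 pairing units")
  if (n_perm < 2L) stop("n_perm must be >= 2")
  D <- a - b

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    S <- matrix(sample(c(1, -1), (n_perm - 1L) * n, replace = TRUE),
                n_perm - 1L, n)
    S <- rbind(rep(1, n), S)               # identity permutation included
  }
  m_perm <- nrow(S)

  ss <- colSums(D^2)                        # invariant under sign flips
  M <- S %*% D / n
  Vn <- sweep(-n * M^2, 2L, ss, "+") / (n - 1L) / n   # var(d)/n per node
  Tm <- M / sqrt(pmax(Vn, 0))
  Tm[!is.finite(Tm)] <- 0                   # zero-difference nodes: t := 0
  id_row <- if (exhaustive) which(rowSums(S == 1) == n)[1L] else 1L
  t_obs <- as.vector(Tm[id_row, ])
  maxT <- apply(abs(Tm), 1L, max)
  t_crit <- sort(maxT)[ceiling((1 - alpha) * m_perm)]

  supra <- abs(t_obs) > t_crit
  clusters <- data.frame(start_pct = numeric(0), end_pct = numeric(0),
                         extent_nodes = integer(0), p_value = numeric(0))
  if (any(supra)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cs <- starts[r$values]; ce <- ends[r$values]
    # permutation distribution of the largest suprathreshold cluster extent
    perm_ext <- apply(abs(Tm) > t_crit, 1L, function(z) {
      if (!any(z)) return(0L)
      rz <- rle(z); max(rz$lengths[rz$values])
    })
    pct <- seq(0, 100, length.out = q)
    clusters <- data.frame(
      start_pct = pct[cs], end_pct = pct[ce],
      extent_nodes = ce - cs + 1L,
      p_value = vapply(ce - cs + 1L,
                       function(e) mean(perm_ext >= e), 0))
  }
  structure(list(t_curve = t_obs, t_crit = t_crit, clusters = clusters,
                 alpha = alpha, n_perm = m_perm,
                 method = if (exhaustive) "exhaustive" else "random"),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> %s permutation SPM paired t: t_crit = %.3f (alpha = %g, %d perms)\n",
              x$method, x$t_crit, x$alpha, x$n_perm))
  if (nrow(x$clusters) == 0L) {
    cat("no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("cluster %d: %.1f-%.1f%% of cycle, p = %.4g\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$p_value[i]))
  }
  invisible(x)
}

#' Plot an SPM result as the conventional two-panel figure
#'
#' Top panel: group mean curves with an SD ribbon; bottom panel: the
#' SPM t curve with the critical threshold and shaded suprathreshold
#' clusters.
#'
#' @param x an `spm_result`.
#' @param a,b the two curve sets (units x nodes) that produced it.
#' @param labels legend labels for the two conditions.
#' @param ylab y label of the top panel.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.spm_result <- function(x, a, b, labels = c("A", "B"), ylab = "value", ...) {
  q <- length(x$t_curve)
  pct <- seq(0, 100, length.out = q)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  ma <- colMeans(a); mb <- colMeans(b)
  sa <- apply(a, 2, stats::sd); sb <- apply(b, 2, stats::sd)
  graphics::plot(pct, ma, type = "n", xlab = "", ylab = ylab,
                 ylim = range(ma + sa, ma - sa, mb + sb, mb - sb))
  graphics::polygon(c(pct, rev(pct)), c(ma + sa, rev(ma - sa)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::polygon(c(pct, rev(pct)), c(mb + sb, rev(mb - sb)),
                    col = grDevices::adjustcolor("firebrick", 0.25), border = NA)
  graphics::lines(pct, ma, col = "steelblue", lwd = 2)
  graphics::lines(pct, mb, col = "firebrick", lwd = 2)
  graphics::legend("topleft", legend = labels, col = c("steelblue", "firebrick"),
                   lwd = 2, bty = "n")
  graphics::plot(pct, x$t_curve, type = "l", xlab = "dive cycle (%)",
                 ylab = "SPM{t}",
                 ylim = range(x$t_curve, x$t_crit, -x$t_crit))
  graphics::abline(h = c(-x$t_crit, x$t_crit), lty = 2)
  if (nrow(x$clusters) > 0L)
    for (i in seq_len(nrow(x$clusters)))
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3L],
                     x$clusters$end_pct[i], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("grey40", 0.2), border = NA)
  invisible(x)
}
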