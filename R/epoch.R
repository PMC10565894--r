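#' Phylogenetically stratified epoch scan
#'
#' Dates admixture by exploiting tree structure: the four-taxon test only
#' detects gene flow that post-dates the (P1, P2) split, so re-running the
#' windowed `f_d` scan with successively deeper P1 taxa tracks introgression
#' further back in time. Each P1 yields a mean `f_d` over non-missing windows
#' with a normal 95% CI, paired with the mean net divergence `d_a(P1, P2)`
#' (a proxy for split time); a mean `f_d` rising with `d_a` indicates
#' admixture older than the shallower splits.
#'
#' @param gm A [geno_matrix()].
#' @param popmap Population map.
#' @param p1_list Two or more P1 taxa, disjoint from the other roles.
#' @param p2,p3,outgroup Fixed roles of the scan.
#' @param windows Window tibble.
#' @param min_sites Passed to [scan_windows()].
#' @param boot_ci Also compute a contig-block bootstrap CI (`n` resamples of
#'   whole windows) that acknowledges window autocorrelation? Default off,
#'   mirroring the plain normal-CI presentation.
#' @param n_boot Bootstrap resamples when `boot_ci = TRUE`.
#' @return An `epoch_scan` tibble: one row per P1 with `mean_fd`, `ci_lo`,
#'   `ci_hi`, `n_windows`, `n_missing_fd`, `mean_da`, ordered by increasing
#'   `mean_da`. The window-level table is in `attr(, "windows")`.
#' @export
stratified_scan <- function(gm, popmap, p1_list, p2, p3, outgroup, windows,
                            min_sites = NULL, boot_ci = FALSE, n_boot = 200) {
  if (length(p1_list) < 2) stop("need at least two P1 taxa")
  if (any(p1_list %in% c(p2, p3, outgroup))) {
    stop("P1 taxa must be disjoint from P2/P3/outgroup")
  }
  win_level <- purrr::map_dfr(p1_list, function(p1) {
    sc <- scan_windows(
      gm, popmap, windows, p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
      dxy_pairs = list(c(p1, p2)), min_sites = min_sites
    )
    da <- sc[[paste0("da_", p1, "_", p2)]]
    tibble::tibble(
      p1 = p1, contig = sc$contig, start = sc$start, end = sc$end,
      fd = sc$fd, D = sc$D, da = da
    )
  })
  summ <- purrr::map_dfr(split(win_level, win_level$p1)[unique(win_level$p1)],
                         function(d) {
    fd <- d$fd[!is.na(d$fd)]
    if (length(fd) == 0) stop("P1 '", d$p1[1], "' yields zero usable windows")
    se <- stats::sd(fd) / sqrt(length(fd))
    out <- tibble::tibble(
      p1 = d$p1[1], mean_fd = mean(fd),
      ci_lo = mean(fd) - 1.96 * se, ci_hi = mean(fd) + 1.96 * se,
      n_windows = length(fd), n_missing_fd = sum(is.na(d$fd)),
      mean_da = mean(d$da, na.rm = TRUE)
    )
    if (boot_ci) {
      bm <- vapply(seq_len(n_boot), function(b) {
        mean(sample(fd, length(fd), replace = TRUE))
      }, numeric(1))
      q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      out$boot_lo <- q[1]
      out$boot_hi <- q[2]
    }
    out
  })
  summ <- dplyr::arrange(summ, .data$mean_da)
  class(summ) <- c("epoch_scan", class(summ))
  attr(summ, "windows") <- win_level
  attr(summ, "roles") <- c(P2 = p2, P3 = p3, outgroup = outgroup)
  summ
}

#' Linear-model contrasts of window-level f_d across groups
#'
#' Fits the one-way fixed-effects model `fd ~ group`, reports group marginal
#' means and all pairwise t contrasts with the pooled residual variance, both
#' unadjusted and Tukey-adjusted, plus (when an epoch scan is supplied) the
#' sign and value of the slope of group mean `f_d` on mean `d_a` -- the
#' headline "does admixture increase with divergence" check.
#'
#' @param windows_long Tibble with one row per (group, window); missing
#'   values are dropped.
#' @param group,value Column names of the grouping factor and response.
#' @param epoch_scan Optional `epoch_scan` from [stratified_scan()] giving
#'   `mean_da` per group.
#' @return An object of class `fd_trend` with elements `fit` (the `lm`),
#'   `means`, `contrasts` (estimate, t, df, `p_unadj`, `p_tukey`) and
#'   `slope_da`. Supports [generics::tidy()] and [generics::glance()].
#' @export
trend_test <- function(windows_long, group = "p1", value = "fd",
                       epoch_scan = NULL) {
  d <- tibble::tibble(
    group = as.character(windows_long[[group]]),
    y = windows_long[[value]]
  )
  d <- d[!is.na(d$y) & !is.na(d$group), , drop = FALSE]
  counts <- table(d$group)
  if (length(counts) < 2) stop("singular design: need at least two groups")
  if (any(counts < 2)) stop("every group needs at least two windows")
  d$group <- factor(d$group, levels = unique(d$group))

  fit <- stats::lm(y ~ group, data = d)
  g <- nlevels(d$group)
  N <- nrow(d)
  df_res <- N - g
  s2 <- sum(stats::residuals(fit)^2) / df_res
  # clamp numerical noise so groups with literally constant values report
  # exact degenerate contrasts
  if (s2 < (1e-10 * (max(abs(d$y)) + 1))^2) s2 <- 0
  if (s2 == 0) warning("zero residual variance: contrast p-values degenerate")
  means <- tibble::tibble(
    group = levels(d$group),
    mean = as.numeric(tapply(d$y, d$group, mean)),
    n = as.integer(counts[levels(d$group)])
  )

  pairs <- utils::combn(levels(d$group), 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(pairs, function(pr) {
    m1 <- means$mean[means$group == pr[1]]
    m2 <- means$mean[means$group == pr[2]]
    n1 <- means$n[means$group == pr[1]]
    n2 <- means$n[means$group == pr[2]]
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    est <- m1 - m2
    t <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
    tibble::tibble(
      group1 = pr[1], group2 = pr[2], estimate = est,
      se = se, t = t, df = df_res,
      p_unadj = if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df_res),
      p_tukey = if (is.infinite(t)) 0 else {
        stats::ptukey(abs(t) * sqrt(2), g, df_res, lower.tail = FALSE)
      }
    )
  })

  slope_da <- NULL
  if (!is.null(epoch_scan)) {
    m <- match(means$group, epoch_scan$p1)
    if (!any(is.na(m))) {
      sl <- stats::coef(stats::lm(means$mean ~ epoch_scan$mean_da[m]))[[2]]
      slope_da <- sl
    }
  }
  structure(
    list(fit = fit, means = means, contrasts = contrasts,
         slope_da = slope_da, sigma2 = s2, df_residual = df_res),
    class = "fd_trend"
  )
}

#' @export
print.fd_trend <- function(x, ...) {
  cat("<fd_trend> one-way f_d model:", nrow(x$means), "groups,",
      x$df_residual, "residual df\n")
  print(x$means)
  if (!is.null(x$slope_da)) {
    cat(sprintf("slope of group means on d_a: %.4g\n", x$slope_da))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn trend_test Pairwise contrasts as a tibble.
#' @param x An `fd_trend` object.
#' @param ... Unused.
#' @export
tidy.fd_trend <- function(x, ...) x$contrasts

#' @describeIn trend_test One-row model summary (groups, residual df and
#'   variance, d_a slope).
#' @export
glance.fd_trend <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$means),
    n_obs = sum(x$means$n),
    df_residual = x$df_residual,
    sigma2 = x$sigma2,
    slope_da = if (is.null(x$slope_da)) NA_real_ else x$slope_da
  )
}

#' Spearman rank correlation between two window statistics
#'
#' Ranks with average-tie handling, rho as Pearson's correlation of the
#' ranks, and a p-value from the t approximation
#' `t = rho sqrt((n-2) / (1-rho^2))`. Window pairs where either value is
#' missing are dropped (and counted).
#'
#' @param x,y Numeric vectors of per-window statistics.
#' @return A one-row tibble: `rho`, `p`, `n_pairs`, `n_dropped`.
#' @export
correlate_windows <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  xs <- x[ok]
  ys <- y[ok]
  if (length(xs) < 3) stop("need at least 3 complete window pairs")
  if (length(unique(xs)) == 1 || length(unique(ys)) == 1) {
    stop("undefined correlation: a variable is constant over windows")
  }
  rho <- stats::cor(rank(xs), rank(ys))
  n <- length(xs)
  p <- if (abs(rho) == 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  tibble::tibble(rho = rho, p = p, n_pairs = n, n_dropped = sum(!ok))
}

#' Mean f_d in recombination-rate quantile bins
#'
#' Sorts windows into `n_bins` quantile bins of recombination rate (edges at
#' the `1/n ... (n-1)/n` sample quantiles, linear-interpolation type 7) and
#' summarizes `f_d` per bin with normal 95% CIs; pairwise bin contrasts reuse
#' the pooled-variance machinery of [trend_test()]. A positive trend across
#' bins is the classic signature of selection against gene flow: introgressed
#' ancestry survives where recombination decouples it from deleterious
#' backgrounds.
#'
#' @param windows Tibble with `fd` and `rate` columns (e.g. from
#'   [scan_windows()] + [annotate_recombination()]).
#' @param n_bins Number of quantile bins (default 5).
#' @return A `recomb_bins` tibble: `bin`, `rate_lo`, `rate_hi`, `mean_fd`,
#'   `ci_lo`, `ci_hi`, `n_windows`; contrasts in `attr(, "trend")`.
#' @export
recombination_quantile_bins <- function(windows, n_bins = 5) {
  d <- windows[!is.na(windows$fd) & !is.na(windows$rate), , drop = FALSE]
  if (nrow(d) < n_bins) stop("fewer windows with f_d and rate than bins")
  edges <- stats::quantile(d$rate, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7, names = FALSE)
  if (anyDuplicated(edges)) {
    dup <- which(duplicated(edges))[1] - 1
    stop("rate ties leave bin ", dup, " empty (duplicated quantile edge)")
  }
  d$bin <- cut(d$rate, breaks = edges, include.lowest = TRUE,
               labels = seq_len(n_bins))
  n_by <- table(d$bin)
  if (any(n_by == 0)) {
    stop("bin ", names(n_by)[which(n_by == 0)[1]], " is empty")
  }
  summ <- purrr::map_dfr(seq_len(n_bins), function(b) {
    fd <- d$fd[d$bin == b]
    se <- stats::sd(fd) / sqrt(length(fd))
    tibble::tibble(
      bin = b, rate_lo = edges[b], rate_hi = edges[b + 1],
      mean_fd = mean(fd), ci_lo = mean(fd) - 1.96 * se,
      ci_hi = mean(fd) + 1.96 * se, n_windows = length(fd)
    )
  })
  trend <- if (all(n_by >= 2)) {
    trend_test(tibble::tibble(p1 = as.character(d$bin), fd = d$fd))
  } else {
    NULL
  }
  class(summ) <- c("recomb_bins", class(summ))
  attr(summ, "trend") <- trend
  attr(summ, "edges") <- edges
  summ
}
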