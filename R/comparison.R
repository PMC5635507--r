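#' Wilcoxon signed rank test for paired series
#'
#' Paired-difference test used to compare two assessment methods net by
#' net.  Zero differences are dropped by default (`zero_method = "pratt"`
#' ranks them first and then discards them); tied absolute differences get
#' mid-ranks.  With at most `exact_limit` nonzero pairs the two-sided
#' p-value is exact, from the full distribution of the positive-rank sum
#' over all sign assignments (computed by convolution, valid under ties);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y equal-length numeric series (>= 2 pairs).
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_limit switch to the normal approximation above this many
#'   nonzero pairs.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return List: `statistic` (positive-rank sum V), `p`, `n` (nonzero
#'   pairs), `method` ("exact" or "normal"), `zero_method`, `degenerate`
#'   (`TRUE` when all differences are zero, in which case `p = 1`).
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("drop", "pratt"),
                                 exact_limit = 15,
                                 alternative = c("two.sided", "greater", "less")) {
  zero_method <- match.arg(zero_method)
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  nz <- d != 0
  n <- sum(nz)
  if (n == 0)
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate",
                zero_method = zero_method, degenerate = TRUE))
  r <- if (zero_method == "drop") rank(abs(d[nz])) else rank(abs(d))[nz]
  v <- sum(r[d[nz] > 0])

  if (n <= exact_limit) {
    # exact distribution of V by convolution over doubled ranks
    # (mid-ranks are half-integers, so 2r is integral)
    w <- as.integer(round(2 * r))
    f <- c(1, numeric(sum(w)))   # f[s+1] = #assignments with doubled sum s
    for (wi in w) {
      g <- f
      g[(wi + 1):length(f)] <- g[(wi + 1):length(f)] + f[1:(length(f) - wi)]
      f <- g
    }
    tot <- 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[1:(v2 + 1)]) / tot
    p_ge <- sum(f[(v2 + 1):length(f)]) / tot
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le)
    method <- "exact"
  } else {
    if (zero_method == "drop") {
      mu <- n * (n + 1) / 4
      sig2 <- n * (n + 1) * (2 * n + 1) / 24
    } else {
      nn <- length(d); n0 <- nn - n
      mu <- (nn * (nn + 1) - n0 * (n0 + 1)) / 4
      sig2 <- (nn * (nn + 1) * (2 * nn + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
    }
    ties <- table(r)
    sig2 <- sig2 - sum(ties^3 - ties) / 48
    cc <- switch(alternative, two.sided = sign(v - mu) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (v - mu - cc) / sqrt(sig2)
    p <- switch(alternative,
      two.sided = 2 * pnorm(-abs(z)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z))
    p <- min(1, p)
    method <- "normal"
  }
  list(statistic = v, p = p, n = as.integer(n), method = method,
       zero_method = zero_method, degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-safe), with a two-sided p-value
#' from the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric series (>= 3 pairs).
#' @return List: `rho`, `p`, `n`, `degenerate` (`TRUE`, with `NA` results,
#'   when either series has zero rank variance).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0
       else 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Simple linear regression fit
#'
#' Ordinary least squares of `y` on `x`, as used for the dashed fitted
#' line on method-versus-method scatterplots.
#'
#' @param x,y equal-length numeric series (>= 2 points, `x` not constant).
#' @return List: `slope`, `intercept`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  if (var(x) == 0) stop("x is constant: fit undefined")
  co <- coef(lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]), n = length(x))
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric comparison of a measurement across two or more groups
#' (e.g. aspect ratio across WHOPES size classes), with tie-corrected H
#' and a chi-square p-value on `k - 1` degrees of freedom.  Delegates to
#' [stats::kruskal.test()].
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return List: `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least 2 series")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference (bias) and 95% limits of agreement
#' `bias +/- 1.96 * sd(d)` for paired measurements, optionally on the log
#' scale when differences of raw values are skewed.
#'
#' @param x,y equal-length numeric series (>= 2 pairs).
#' @param log_transform analyse `log(x) - log(y)`; requires all values > 0.
#' @return List: `bias`, `loa_low`, `loa_high`, `sd`, `log_transformed`,
#'   `n`.
#' @export
bland_altman <- function(x, y, log_transform = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop("log_transform requires all values > 0")
    x <- log(x); y <- log(y)
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, log_transformed = log_transform, n = length(x))
}

#' Paired comparison of two assessment methods
#'
#' Joins two per-net assessment tables on `net_id` and computes the full
#' paired-comparison battery on the chosen metric: Wilcoxon signed rank,
#' Spearman correlation, simple linear regression (`a` on `b`), and
#' Bland-Altman agreement.  No multiple-testing adjustment is applied.
#'
#' @param a,b assessment data frames from [assess_nets()].
#' @param metric `"total_area_cm2"` or `"hole_count"`.
#' @param log_ba use log-transformed values in the Bland-Altman analysis.
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return Object of class `paired_comparison`.
#' @export
compare_methods <- function(a, b, metric = c("total_area_cm2", "hole_count"),
                            log_ba = FALSE, ...) {
  metric <- match.arg(metric)
  m <- merge(a[, c("net_id", metric)], b[, c("net_id", metric)],
             by = "net_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 2) stop("need at least 2 paired nets")
  va <- m[[paste0(metric, "_a")]]
  vb <- m[[paste0(metric, "_b")]]
  # degenerate series (constant x, zero rank variance) yield NA components
  # rather than aborting the whole comparison
  na_fit <- list(slope = NA_real_, intercept = NA_real_, n = nrow(m))
  na_rho <- list(rho = NA_real_, p = NA_real_, n = nrow(m), degenerate = TRUE)
  structure(list(
    method_a = if (nrow(a)) a$method[1] else NA_character_,
    method_b = if (nrow(b)) b$method[1] else NA_character_,
    metric = metric, pairs = m,
    wilcoxon = wilcoxon_signed_rank(va, vb, ...),
    spearman = if (nrow(m) >= 3 && sd(rank(va)) > 0 && sd(rank(vb)) > 0)
      spearman_rho(va, vb) else na_rho,
    regression = tryCatch(linear_fit(vb, va), error = function(e) na_fit),
    bland_altman = bland_altman(va, vb, log_transform = log_ba)),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s vs %s on %s (n = %d nets)\n",
              x$method_a, x$method_b, x$metric, nrow(x$pairs)))
  cat(sprintf("  Wilcoxon signed rank: V = %.1f, p = %.4g (%s, zeros: %s)\n",
              x$wilcoxon$statistic, x$wilcoxon$p, x$wilcoxon$method,
              x$wilcoxon$zero_method))
  cat(sprintf("  Spearman: rho = %.3f, p = %.4g\n", x$spearman$rho, x$spearman$p))
  cat(sprintf("  Regression (a on b): slope = %.3f, intercept = %.3f\n",
              x$regression$slope, x$regression$intercept))
  cat(sprintf("  Bland-Altman%s: bias = %.3f [%.3f, %.3f]\n",
              if (x$bland_altman$log_transformed) " (log)" else "",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}
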