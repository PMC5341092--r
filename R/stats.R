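#' Statistical results container
#'
#' Light-weight record for a single test result, mirroring the layout of the
#' result tables: statistic, degrees of freedom where defined, raw and
#' (optionally) family-wise adjusted p-value, the adjustment-family label and
#' the sample size(s) involved.
#'
#' @param name test label.
#' @param statistic numeric test statistic.
#' @param df degrees of freedom, or `NA` where not defined.
#' @param p_raw raw two-tailed p-value in `[0, 1]`.
#' @param p_adjusted adjusted p-value, or `NA` before adjustment.
#' @param family adjustment-family label.
#' @param n sample size(s) used.
#' @return an object of class `stat_result`.
#' @export
stat_result <- function(name, statistic, df = NA_real_, p_raw,
                        p_adjusted = NA_real_, family = NA_character_, n = NA) {
  stopifnot(is.numeric(p_raw), p_raw >= 0, p_raw <= 1 + 1e-12)
  structure(
    list(name = name, statistic = statistic, df = df,
         p_raw = min(p_raw, 1), p_adjusted = p_adjusted,
         family = family, n = n),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$name, x$statistic))
  if (!is.na(x$df[1])) cat(sprintf(", df = %s", paste(x$df, collapse = ",")))
  cat(sprintf(", p = %.4g", x$p_raw))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p(adj) = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

rank_avg <- function(x) rank(x, ties.method = "average")

# Pearson correlation written out explicitly; errors on zero variance.
pearson_r <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("correlation undefined: zero variance")
  sum(xc * yc) / (sx * sy)
}

# Two-tailed p from the t approximation used for rank correlations,
# on the stated degrees of freedom.
p_from_t_rho <- function(rho, df) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tval), df)
}

#' Spearman rank correlation (two-tailed)
#'
#' Average ranks for ties; the coefficient is the Pearson correlation of the
#' rank vectors, with a two-tailed p-value from
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 3, finite.
#' @param name test label.
#' @return a [stat_result] with `statistic` = rho.
#' @export
spearman <- function(x, y, name = "spearman") {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  rho <- pearson_r(rank_avg(x), rank_avg(y))
  stat_result(name, rho, df = n - 2, p_raw = p_from_t_rho(rho, n - 2), n = n)
}

#' Partial Spearman rank correlation (two-tailed)
#'
#' All variables are rank-transformed (average ranks); the partial correlation
#' between `x` and `y` given the k control variables is obtained from the
#' inverse \eqn{\Omega} of the Pearson correlation matrix of the ranks as
#' \eqn{\rho_{xy\cdot z} = -\Omega_{12}/\sqrt{\Omega_{11}\Omega_{22}}}, with a
#' two-tailed p-value from the t approximation on \eqn{n-2-k} degrees of
#' freedom. With no controls this reduces to [spearman()].
#'
#' @param x,y paired numeric vectors.
#' @param controls numeric matrix/data.frame of control variables (may be
#'   `NULL` or zero columns).
#' @param name test label.
#' @return a [stat_result].
#' @export
partial_spearman <- function(x, y, controls = NULL, name = "partial_spearman") {
  if (is.null(controls)) controls <- matrix(numeric(0), nrow = length(x), ncol = 0)
  controls <- as.matrix(controls)
  k <- ncol(controls)
  if (k == 0) {
    res <- spearman(x, y, name = name)
    return(res)
  }
  n <- length(x)
  stopifnot(length(y) == n, nrow(controls) == n, n > k + 2,
            all(is.finite(x)), all(is.finite(y)), all(is.finite(controls)))
  m <- cbind(x, y, controls)
  r <- apply(m, 2, rank_avg)
  if (any(apply(r, 2, stats::var) == 0)) stop("rank-degenerate variable")
  cmat <- stats::cor(r)  # Pearson correlation of ranks
  omega <- tryCatch(solve(cmat), error = function(e)
    stop("singular rank correlation matrix"))
  rho <- -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
  stat_result(name, rho, df = n - 2 - k,
              p_raw = p_from_t_rho(rho, n - 2 - k), n = n)
}

#' Kruskal-Wallis test with tie correction
#'
#' Pooled average ranks; \eqn{H = \frac{12}{N(N+1)}\sum n_i(\bar R_i -
#' \frac{N+1}{2})^2}, divided by the tie-correction factor
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; p from \eqn{\chi^2} on g-1 df.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @param name test label.
#' @return a [stat_result] with `statistic` = H.
#' @export
kruskal_wallis <- function(groups, name = "kruskal_wallis") {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  stopifnot(all(is.finite(pooled)))
  n_tot <- length(pooled)
  if (n_tot < 3) stop("total N must be >= 3")
  if (length(unique(pooled)) == 1) stop("H undefined: all values identical")
  r <- rank_avg(pooled)
  sizes <- vapply(groups, length, 1L)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(sizes * (rbar - (n_tot + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  h <- h / corr
  df <- length(groups) - 1
  stat_result(name, h, df = df,
              p_raw = stats::pchisq(h, df, lower.tail = FALSE), n = sizes)
}

# Exact null distribution of the Mann-Whitney U count for (n1, n2) without
# ties: counts[u+1] = number of arrangements with U = u, via the standard
# recurrence N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
mwu_exact_counts <- function(n1, n2) {
  umax <- n1 * n2
  a <- array(0, dim = c(n1 + 1, n2 + 1, umax + 1))
  a[1, , 1] <- 1
  a[, 1, 1] <- 1
  for (m in seq_len(n1)) {
    for (n in seq_len(n2)) {
      v <- a[m + 1, n, ]
      shifted <- c(rep(0, n), a[m, n + 1, seq_len(umax + 1 - n)])
      a[m + 1, n + 1, ] <- v + shifted
    }
  }
  a[n1 + 1, n2 + 1, ]
}

#' Mann-Whitney U test (two-tailed)
#'
#' U counts, for each value of the first sample, the second-sample values it
#' exceeds (ties counting one half). `mode = "auto"` uses the exact
#' no-ties enumeration when \eqn{n_1 n_2 \le 400} and there are no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction. `mode = "exact"` forces an exact permutation computation (with
#' ties, by complete enumeration of group assignments; guarded by a size
#' limit); `mode = "normal"` forces the approximation.
#'
#' @param a,b nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param name test label.
#' @return a [stat_result] with `statistic` = U (for `a`).
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal"),
                           name = "mwu") {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank_avg(pooled)
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2  # U for a
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(mode,
    auto = (!has_ties && n1 * n2 <= 400),
    exact = TRUE,
    normal = FALSE)
  if (use_exact && !has_ties) {
    counts <- mwu_exact_counts(n1, n2)
    tot <- sum(counts)
    lo <- sum(counts[seq_len(u + 1)]) / tot
    hi <- sum(counts[seq(u + 1, n1 * n2 + 1)]) / tot
    p <- min(1, 2 * min(lo, hi))
    return(stat_result(name, u, p_raw = p, n = c(n1, n2)))
  }
  if (use_exact && has_ties) {
    n_comb <- choose(n1 + n2, n1)
    if (n_comb > 2e5)
      stop("exact mode with ties infeasible at this sample size")
    combs <- utils::combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(stat_result(name, u, p_raw = p, n = c(n1, n2)))
  }
  # tie-corrected normal approximation with continuity correction
  n_tot <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sig2 <- n1 * n2 / 12 * ((n_tot + 1) - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
  if (sig2 <= 0) return(stat_result(name, u, p_raw = 1, n = c(n1, n2)))
  num <- u - mu
  num <- num - sign(num) * 0.5
  if (abs(u - mu) < 0.5) num <- 0
  z <- num / sqrt(sig2)
  stat_result(name, u, p_raw = min(1, 2 * stats::pnorm(-abs(z))), n = c(n1, n2))
}

# z statistic of the tie-corrected normal-approximation MWU without
# continuity correction (used for the algebraic link to Kruskal-Wallis).
mwu_z_no_cc <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n_tot <- n1 + n2
  pooled <- c(a, b)
  r <- rank_avg(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  sig2 <- n1 * n2 / 12 * ((n_tot + 1) - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
  (u - n1 * n2 / 2) / sqrt(sig2)
}

table_margins <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  list(r = rowSums(tab), c = colSums(tab), n = sum(tab))
}

#' Pearson chi-squared test of independence
#'
#' \eqn{\sum (O-E)^2/E} with expected counts from the margins, no Yates
#' correction; p from \eqn{\chi^2} on (r-1)(c-1) df.
#'
#' @param tab r x c matrix of non-negative integer counts, r,c >= 2.
#' @param name test label.
#' @return a [stat_result].
#' @export
pearson_chi2 <- function(tab, name = "chi2") {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2)
  m <- table_margins(tab)
  if (any(m$r == 0) || any(m$c == 0)) stop("zero row or column margin")
  e <- outer(m$r, m$c) / m$n
  x2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stat_result(name, x2, df = df,
              p_raw = stats::pchisq(x2, df, lower.tail = FALSE), n = m$n)
}

expected_counts <- function(tab) {
  m <- table_margins(tab)
  outer(m$r, m$c) / m$n
}

# log probability of a 2 x c table under the fixed-margins
# (multivariate hypergeometric) null.
log_table_prob <- function(tab) {
  m <- table_margins(tab)
  sum(lfactorial(m$r)) + sum(lfactorial(m$c)) - lfactorial(m$n) -
    sum(lfactorial(tab))
}

#' Fisher's exact test (2 x 2) and Freeman-Halton extension (2 x 3)
#'
#' Enumerates every table with the observed margins; the two-sided p-value is
#' the total probability of tables whose probability under the fixed-margins
#' null does not exceed that of the observed table (probability-mass method).
#'
#' @param tab 2 x 2 or 2 x 3 matrix of non-negative integer counts.
#' @param name test label.
#' @return a [stat_result] with `statistic` = probability of the observed
#'   table.
#' @export
fisher_exact <- function(tab, name = "fisher") {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) %in% c(2, 3))
  m <- table_margins(tab)
  if (any(m$r == 0) || any(m$c == 0)) stop("degenerate margins: zero row or column total")
  lp_obs <- log_table_prob(tab)
  r1 <- m$r[1]
  cs <- m$c
  p <- 0
  tol <- 1e-7
  if (ncol(tab) == 2) {
    for (a in max(0, r1 - cs[2]):min(r1, cs[1])) {
      t2 <- rbind(c(a, r1 - a), cs - c(a, r1 - a))
      lp <- log_table_prob(t2)
      if (lp <= lp_obs + tol) p <- p + exp(lp)
    }
  } else {
    for (a in 0:min(r1, cs[1])) {
      for (b in 0:min(r1 - a, cs[2])) {
        cc <- r1 - a - b
        if (cc > cs[3]) next
        row1 <- c(a, b, cc)
        t2 <- rbind(row1, cs - row1)
        lp <- log_table_prob(t2)
        if (lp <= lp_obs + tol) p <- p + exp(lp)
      }
    }
  }
  stat_result(name, exp(lp_obs), p_raw = min(1, p), n = m$n)
}

#' Select chi-squared or Fisher's exact test for a contingency table
#'
#' Fisher's exact test whenever any expected count under independence is
#' below 5, otherwise Pearson's chi-squared.
#'
#' @param tab contingency table of counts.
#' @return `"fisher"` or `"chi2"`.
#' @export
choose_test <- function(tab) {
  if (any(expected_counts(tab) < 5)) "fisher" else "chi2"
}

#' Run the test selected by [choose_test()] on a contingency table
#' @param tab contingency table of counts.
#' @param name test label.
#' @return a [stat_result]; its `name` records which test ran.
#' @export
contingency_test <- function(tab, name = "contingency") {
  which <- choose_test(tab)
  if (which == "fisher") fisher_exact(tab, name = paste0(name, "_fisher"))
  else pearson_chi2(tab, name = paste0(name, "_chi2"))
}

#' Holm step-down adjustment
#'
#' Step-down family-wise error-rate control: with p-values sorted ascending,
#' the i-th adjusted value is \eqn{\min(1, \max_{j\le i}(m-j+1)\,p_{(j)})}.
#' The family size `m` may exceed the number of supplied p-values, for
#' families that include tests run in analysis variants.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m family size, `m >= length(p)`.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  if (m < length(p)) stop("family size m smaller than number of p-values")
  if (length(p) == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_along(p) + 1) * p[o]))
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Percentile bootstrap confidence interval of the median
#'
#' Draws `B` resamples with replacement, records each resample's median, and
#' returns the nearest-rank order statistics of the B medians at probabilities
#' alpha/2 and 1 - alpha/2.
#'
#' @param x nonempty numeric sample.
#' @param B number of pseudo-replicates (default 100,000, the analysis-wide
#'   setting).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(x, B = 100000L, level = 0.95, seed = NULL) {
  stopifnot(length(x) >= 1, B >= 1, level > 0, level < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- length(x)
  meds <- vapply(seq_len(B), function(i) stats::median(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  s <- sort(meds)
  alpha <- 1 - level
  lo <- s[max(1L, ceiling(alpha / 2 * B))]
  hi <- s[min(B, ceiling((1 - alpha / 2) * B))]
  c(lo, hi)
}
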