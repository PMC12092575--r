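#' Two-tailed Mann-Whitney U test with rank-biserial effect size
#'
#' The statistic counts pairs with `x > y` (ties contribute one half); the
#' rank-biserial correlation is `r_rb = 2*U_x/(n_x*n_y) - 1`, the difference
#' between the proportions of favourable and unfavourable pairs. The p-value
#' uses exhaustive enumeration of all group assignments (exact under ties)
#' when `choose(n, n_x) <= 20000`, otherwise the normal approximation with
#' tie and continuity correction.
#'
#' @param x,y Numeric samples for the two groups.
#' @return One-row tibble: `u`, `p_value`, `r_rb`, group sizes, medians and
#'   IQRs, and the `method` used for the p-value.
#' @export
mann_whitney_rrb <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1,
              "both groups must be non-empty",
              class = "odynr_validation_error")
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  u_of <- function(idx_x) {
    r <- midrank(comb)
    sum(r[idx_x]) - length(idx_x) * (length(idx_x) + 1) / 2
  }
  u <- u_of(seq_len(nx))
  r_rb <- 2 * u / (nx * ny) - 1
  mu <- nx * ny / 2

  if (choose(n, nx) <= 20000) {
    idx_sets <- combn(n, nx)
    us <- apply(idx_sets, 2, function(ii) {
      r <- midrank(comb)
      sum(r[ii]) - nx * (nx + 1) / 2
    })
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(comb)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  tibble::tibble(
    u = u, p_value = p, r_rb = r_rb, n_x = nx, n_y = ny,
    median_x = stats::median(x), iqr_x_lo = unname(quantile(x, 0.25)),
    iqr_x_hi = unname(quantile(x, 0.75)),
    median_y = stats::median(y), iqr_y_lo = unname(quantile(y, 0.25)),
    iqr_y_hi = unname(quantile(y, 0.75)),
    method = method
  )
}

#' Spearman correlation with a permutation p-value
#'
#' Spearman's rho on midranks; the two-sided p-value is
#' `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)` over random permutations of `y`.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return One-row tibble: `rho`, `p_value`, `n`, `n_perm`.
#' @export
spearman_perm <- function(x, y, n_perm = 1000L, seed = 1L) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3",
              class = "odynr_validation_error")
  assert_that(stats::var(x) > 0 && stats::var(y) > 0,
              "constant vector: Spearman's rho undefined",
              class = "odynr_validation_error")
  rx <- midrank(x); ry <- midrank(y)
  rho <- stats::cor(rx, ry)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(rx, ry[sample(length(ry))])) >= abs(rho) - 1e-12
    }, logical(1)))
  })
  tibble::tibble(rho = rho, p_value = (1 + exceed) / (n_perm + 1),
                 n = length(x), n_perm = n_perm)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard routine (`stats::shapiro.test`), used as a
#' normality gate before the non-parametric comparisons.
#'
#' @param x Numeric sample, `3 <= n <= 5000`, not constant.
#' @return One-row tibble: `w`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  assert_that(length(x) >= 3 && length(x) <= 5000,
              "Shapiro-Wilk requires 3 <= n <= 5000",
              class = "odynr_validation_error")
  assert_that(stats::var(x) > 0, "constant vector",
              class = "odynr_validation_error")
  t <- stats::shapiro.test(x)
  tibble::tibble(w = unname(t$statistic), p_value = t$p.value, n = length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the output preserves
#' the input order.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]",
              class = "odynr_validation_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Conservative p-value over repeated experiments
#'
#' Twice the median p-value across repeats, clamped at 1: a conservative
#' summary of repeated log-rank tests.
#'
#' @param p_values Per-repeat p-values (>= 1 value).
#' @return Single p-value in `[0, 1]`.
#' @export
conservative_p <- function(p_values) {
  assert_that(length(p_values) >= 1, "need at least one p-value",
              class = "odynr_validation_error")
  min(1, 2 * stats::median(p_values))
}
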