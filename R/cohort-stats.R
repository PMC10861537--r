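# Inferential tests used on the paired cohorts, with exact small-sample
# nulls by full enumeration and documented large-sample approximations.

.test_result <- function(statistic, p_value, method, exact, n) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 exact = exact, n = n), class = "stromashift_test")
}

#' @export
print.stromashift_test <- function(x, ...) {
  cat(x$method, if (x$exact) "(exact)" else "(approximate)", "\n")
  cat("  statistic =", format(x$statistic), "  p =", format(x$p_value),
      "  n =", x$n, "\n")
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Enumerates every table compatible with the observed margins and sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (the convention of standard statistical software, so printed
#' p-values are directly comparable).
#'
#' @param table 2x2 matrix of nonnegative integer counts `[[a, b], [c, d]]`,
#'   or the vector `c(a, b, c, d)` in row-major order.
#' @return a test result with `statistic` the observed top-left count.
#' @examples
#' fisher_exact_2x2(matrix(c(26, 9, 15, 20), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.vector(t(table))
  if (length(x) != 4L) stop("need a 2x2 table", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0L) stop("empty table", call. = FALSE)
  klo <- max(0, r1 + c1 - n); khi <- min(r1, c1)
  k <- klo:khi
  pk <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  # relative tolerance guards against ties lost to floating point
  p <- min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  .test_result(statistic = a, p_value = p,
               method = "Fisher's exact test (two-sided)",
               exact = TRUE, n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are mid-ranked. For
#' `m <= exact_limit` nonzero differences the null is computed exactly by
#' enumerating all `2^m` sign assignments (symmetric around the null mean,
#' so the two-sided p is the probability of a statistic at least as far from
#' `m(m+1)/4` as observed). Beyond that the exact classical signed-rank
#' null is still used when the absolute differences are untied; tied larger
#' samples fall back to a normal approximation with tie and continuity
#' corrections.
#'
#' @param x first sample, or the paired differences if `y` is `NULL`.
#' @param y optional second sample (differences are `x - y`).
#' @param exact_limit largest m for which the exact null is enumerated
#'   (default 12; enumeration is instantaneous there).
#' @return a test result with `statistic` V, the sum of ranks of positive
#'   differences.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12L) {
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) stop("missing values in differences", call. = FALSE)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all differences are zero; p = 1")
    return(.test_result(NA_real_, 1, "Wilcoxon signed-rank (paired, two-sided)",
                        TRUE, 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  tied <- anyDuplicated(r) > 0L
  if (m <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    vs <- as.vector(signs %*% r)
    p <- mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
    exact <- TRUE
  } else if (!tied) {
    # untied ranks: the null is the classical signed-rank distribution,
    # available exactly at any m (two-sided by symmetry around mu)
    vmin <- min(v, 2 * mu - v)
    p <- min(1, 2 * stats::psignrank(vmin, m))
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  .test_result(v, p, "Wilcoxon signed-rank (paired, two-sided)", exact, m)
}

#' Mann-Whitney U test (two independent samples)
#'
#' Pooled values are mid-ranked; U counts, for sample `x`, the pairs it wins
#' (plus half-ties). For `length(x) + length(y) <= exact_limit` the null is
#' enumerated over all assignments of the pooled ranks to the two groups;
#' beyond that the classical exact U null is used for untied data, and a
#' normal approximation with tie and continuity corrections for tied data.
#' Two-sided p is symmetric around the null mean `n_x n_y / 2`.
#'
#' @param x,y numeric samples.
#' @param exact_limit largest pooled size for exact enumeration (default 12).
#' @return a test result with `statistic` U for `x`.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tied <- anyDuplicated(r) > 0L
  if (n <= exact_limit) {
    picks <- utils::combn(n, nx)
    w <- colSums(matrix(r[picks], nrow = nx))
    us <- w - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    exact <- TRUE
  } else if (!tied) {
    # untied pooled ranks: exact U null at any size, symmetric around mu
    umin <- min(u, 2 * mu - u)
    p <- min(1, 2 * stats::pwilcox(umin, nx, ny))
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  .test_result(u, p, "Mann-Whitney U (two-sided)", exact, n)
}

#' Spearman rank correlation with exact small-sample p
#'
#' rho is the Pearson correlation of the mid-ranks. For `n <= exact_limit`
#' the two-sided p enumerates all `n!` permutations of one rank vector
#' (probability of `|rho|` at least as large as observed); otherwise the
#' t-distribution approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom is used.
#'
#' @param x,y numeric vectors, `length >= 3`.
#' @param exact_limit largest n for exact enumeration (default 8; 8! =
#'   40320 permutations).
#' @return a test result with `statistic` rho.
#' @export
spearman_test <- function(x, y, exact_limit = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: rho undefined")
    return(.test_result(NaN, NA_real_, "Spearman correlation (two-sided)",
                        FALSE, n))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- .permutations(n)
    m <- matrix(ry[t(perms)], nrow = n)
    rhos <- (colSums(rx * m) / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    exact <- TRUE
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), n - 2))
    exact <- FALSE
  }
  .test_result(rho, p, "Spearman correlation (two-sided)", exact, n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in the input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, monotone in the sorted-p order and `<= 1`.
#' @export
bh_adjust <- function(p) {
  .check_range(p, 0, 1, "p")
  stats::p.adjust(p, method = "BH")
}
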