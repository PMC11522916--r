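#' Hill number of order q
#'
#' Effective number of species of a relative-abundance vector: `q = 0` is
#' species richness, `q = 1` the exponential of Shannon entropy (taken as the
#' analytic limit, not a numerical one), `q = 2` the inverse Simpson
#' concentration. Hill numbers weakly decrease in `q`.
#'
#' @param p Numeric vector of relative abundances summing to 1 (tolerance
#'   1e-9); zeros allowed.
#' @param q Non-negative order.
#' @return The Hill diversity (scalar >= 1).
#' @export
hill_number <- function(p, q) {
  if (length(p) == 0 || all(p == 0)) rs_abort("empty or all-zero abundance vector")
  if (any(p < 0)) rs_abort("relative abundances must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) {
    rs_abort(sprintf("relative abundances sum to %.6f, not 1", sum(p)))
  }
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# Internal: singleton/doubleton bookkeeping for integer count vectors.
count_stats <- function(counts) {
  if (length(counts) == 0) rs_abort("empty count vector")
  if (any(counts < 0)) rs_abort("counts must be >= 0")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    rs_abort("sample coverage and rarefaction are defined on integer counts",
             class = "reefsucc_noninteger_counts")
  }
  counts <- round(counts[counts > 0])
  n <- sum(counts)
  if (n < 1) rs_abort("at least one positive count required")
  list(x = counts, n = n, S = length(counts),
       f1 = sum(counts == 1), f2 = sum(counts == 2))
}

#' Estimated sample coverage
#'
#' Estimates the fraction of the community's total abundance that belongs to
#' species detected in the sample, from the singleton and doubleton
#' frequencies: `C = 1 - (f1/n) * (n-1)f1 / ((n-1)f1 + 2 f2)`. Equals 1 when
#' the sample has no singletons.
#'
#' @param counts Non-negative integer abundance vector.
#' @return Coverage estimate in \[0, 1\].
#' @export
sample_coverage <- function(counts) {
  s <- count_stats(counts)
  if (s$f1 == 0) return(1)
  denom <- (s$n - 1) * s$f1 + 2 * s$f2
  fac <- if (denom > 0) (s$n - 1) * s$f1 / denom else 1
  1 - (s$f1 / s$n) * fac
}

# Internal: expected coverage of a rarefied/extrapolated sample of size m.
coverage_at_m <- function(s, m) {
  if (m == s$n) return(sample_coverage(s$x))
  if (m < s$n) {
    keep <- s$x <= s$n - m
    if (!any(keep)) return(1)
    term <- exp(lchoose(s$n - s$x[keep], m) - lchoose(s$n - 1, m))
    return(1 - sum(s$x[keep] / s$n * term))
  }
  if (s$f1 == 0) return(1)
  denom <- (s$n - 1) * s$f1 + 2 * s$f2
  a <- if (denom > 0) (s$n - 1) * s$f1 / denom else 1
  1 - (s$f1 / s$n) * a^(m - s$n + 1)
}

# Internal: Chao1-style estimate of the number of undetected species.
f0_hat <- function(s) {
  if (s$f1 == 0) return(0)
  if (s$f2 > 0) (s$n - 1) / s$n * s$f1^2 / (2 * s$f2)
  else (s$n - 1) / s$n * s$f1 * (s$f1 - 1) / 2
}

# Internal: asymptotic Shannon entropy (Chao-Wang-Jost estimator).
entropy_asymptotic <- function(s) {
  x <- s$x; n <- s$n
  sub <- x[x <= n - 1]
  h1 <- if (length(sub)) sum(sub / n * (digamma(n) - digamma(sub))) else 0
  f1 <- s$f1; f2 <- s$f2
  a <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 0) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  h2 <- 0
  if (f1 > 0 && a < 1) {
    r <- seq_len(n - 1)
    h2 <- (f1 / n) * (1 - a)^(1 - n) * (-log(a) - sum((1 - a)^r / r))
  }
  h1 + h2
}

# Internal: Hill-number estimate at sample size m (interpolation for m < n,
# analytic continuation/extrapolation for m > n, observed at m = n).
hill_at_m <- function(s, q, m) {
  x <- s$x; n <- s$n
  if (q == 2) {
    simpson <- sum(x * (x - 1)) / (n * (n - 1))
    return(1 / (1 / m + (1 - 1 / m) * simpson))
  }
  if (q == 0) {
    if (m == n) return(s$S)
    if (m < n) {
      keep <- x <= n - m
      drop <- if (any(keep)) sum(exp(lchoose(n - x[keep], m) - lchoose(n, m))) else 0
      return(s$S - drop)
    }
    f0 <- f0_hat(s)
    if (f0 == 0) return(s$S)
    return(s$S + f0 * (1 - (1 - s$f1 / (n * f0 + s$f1))^(m - n)))
  }
  if (q == 1) {
    if (m <= n) {
      h <- 0
      for (xi in x) {
        k <- seq_len(min(xi, m))
        pk <- stats::dhyper(k, xi, n - xi, m)
        h <- h + sum(-(k / m) * log(k / m) * pk)
      }
      return(exp(h))
    }
    h_obs <- -sum((x / n) * log(x / n))
    h_asy <- max(entropy_asymptotic(s), h_obs)
    mstar <- m - n
    return(exp(n / (n + mstar) * h_obs + mstar / (n + mstar) * h_asy))
  }
  rs_abort("rarefaction supports q in {0, 1, 2}")
}

#' Rarefaction and extrapolation of Hill numbers
#'
#' Computes the expected Hill diversity of orders `q` at a grid of sample
#' sizes: exact (hypergeometric) interpolation below the reference sample
#' size, the observed value at `m = n`, and extrapolation up to `2n` based on
#' the Chao1 estimate of undetected species (`q = 0`), an asymptotic-entropy
#' blend (`q = 1`), and the unbiased Simpson continuation (`q = 2`). Each
#' estimate is paired with the expected sample coverage at that size.
#'
#' @param counts Non-negative integer abundance vector (named or not).
#' @param q Orders, subset of `c(0, 1, 2)`.
#' @param grid Integer sample sizes; defaults to about `knots` sizes spanning
#'   1 to `2n`. Sizes above `2n` are rejected.
#' @param knots Number of grid points when `grid` is NULL.
#' @return Tibble with columns `q`, `m`, `method` (`interpolated`,
#'   `observed`, `extrapolated`), `estimate`, `coverage`.
#' @export
rarefaction_curve <- function(counts, q = c(0, 1, 2), grid = NULL, knots = 40) {
  s <- count_stats(counts)
  if (is.null(grid)) {
    grid <- unique(sort(c(1, round(seq(1, 2 * s$n, length.out = knots)), s$n)))
  }
  grid <- unique(sort(round(grid)))
  if (any(grid <= 0)) rs_abort("rarefaction grid sizes must be positive")
  if (any(grid > 2 * s$n)) {
    rs_abort(sprintf("extrapolation is capped at 2n = %d", 2 * s$n))
  }
  out <- tidyr::expand_grid(q = q, m = grid)
  out$method <- dplyr::case_when(
    out$m < s$n ~ "interpolated",
    out$m == s$n ~ "observed",
    TRUE ~ "extrapolated"
  )
  out$estimate <- purrr::map2_dbl(out$q, out$m, function(qi, mi) hill_at_m(s, qi, mi))
  cov_by_m <- vapply(grid, function(mi) coverage_at_m(s, mi), 0)
  out$coverage <- cov_by_m[match(out$m, grid)]
  tibble::as_tibble(out)
}

#' Convert percent cover to pseudo-counts
#'
#' Line-intercept "abundance" is percent cover, not individuals, while sample
#' coverage and rarefaction are defined on counts. Cover is converted to
#' pseudo-counts by discretising the intercepted tape at a declared
#' resolution (default 1 cm): `count = round(cover/100 * tape_m * 100 /
#' resolution_cm)`.
#'
#' @param cover Percent cover vector (one entry per taxon).
#' @param tape_m Total tape length (metres) behind the cover estimates.
#' @param resolution_cm Discretisation resolution in centimetres.
#' @return Integer pseudo-count vector, same names as `cover`.
#' @export
cover_to_counts <- function(cover, tape_m, resolution_cm = 1) {
  if (any(cover < 0)) rs_abort("cover must be >= 0")
  if (tape_m <= 0 || resolution_cm <= 0) rs_abort("tape length and resolution must be > 0")
  counts <- round(cover / 100 * tape_m * 100 / resolution_cm)
  stats::setNames(as.integer(counts), names(cover))
}
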