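test_that("zero between-group variance reproduces OLS at the boundary", {
  # identical (x, y) pattern in every group forces the variance component to 0
  base <- tibble::tibble(x = c(-2, -1, 0, 1, 2), y = c(0.8, 1.1, 2.2, 2.8, 4.1))
  df <- purrr::map_dfr(1:4, function(g) dplyr::mutate(base, g = paste0("g", g)))
  fit <- fit_lmm(df, y ~ x + (1 | g))
  ols <- stats::lm(y ~ x, data = df)
  tab <- tidy(fit)
  expect_true(glance(fit)$singular)
  expect_equal(tab$estimate, unname(stats::coef(ols)), tolerance = 1e-6)

  # Satterthwaite df approaches the OLS residual df and p matches OLS
  ols_p <- summary(ols)$coefficients["x", "Pr(>|t|)"]
  sw <- satterthwaite_test(fit, "x")
  expect_equal(sw$df, nrow(df) - 2, tolerance = 0.5)
  expect_equal(sw$p, ols_p, tolerance = 1e-3)
})

test_that("balanced one-way REML matches the method-of-moments closed form", {
  set.seed(20)
  n_g <- 8; n_per <- 6
  g <- factor(rep(seq_len(n_g), each = n_per))
  y <- rnorm(n_g, 0, 2)[g] + rnorm(n_g * n_per, 0, 1)
  df <- tibble::tibble(y = y, g = g)
  fit <- fit_lmm(df, y ~ 1 + (1 | g))
  an <- stats::anova(stats::lm(y ~ g))
  msb <- an["g", "Mean Sq"]; msw <- an["Residuals", "Mean Sq"]
  tau2 <- max((msb - msw) / n_per, 0)
  gl <- glance(fit)
  expect_equal(gl$sigma^2, msw, tolerance = 1e-6)
  expect_equal(gl$sd_g^2, tau2, tolerance = 1e-6)

  # group-constant covariate: Satterthwaite df close to n_groups - 2
  x_g <- rnorm(n_g)
  df$x <- x_g[g]
  df$y2 <- 1 + 2 * df$x + rnorm(n_g, 0, 1)[g] + rnorm(nrow(df), 0, 0.3)
  fit2 <- fit_lmm(df, y2 ~ x + (1 | g))
  sw <- satterthwaite_test(fit2, "x")
  expect_equal(sw$df, n_g - 2, tolerance = 0.5)
  expect_lte(sw$df, nrow(df) - 2)
})

test_that("known variance ratio reproduces the GLS closed form", {
  set.seed(30)
  n_g <- 10; n_per <- 5
  g <- factor(rep(seq_len(n_g), each = n_per))
  x <- rnorm(n_g * n_per)
  y <- 2 + 1.5 * x + rnorm(n_g, 0, 1.3)[g] + rnorm(n_g * n_per, 0, 0.9)
  fit <- fit_lmm(tibble::tibble(y = y, x = x, g = g), y ~ x + (1 | g))
  gl <- glance(fit)
  # GLS with the REML-estimated covariance equals the reported fixed effects
  v <- diag(gl$sigma^2, n_g * n_per)
  z <- stats::model.matrix(~ g - 1)
  v <- v + gl$sd_g^2 * (z %*% t(z))
  xmat <- cbind(1, x)
  vi <- solve(v)
  beta <- solve(t(xmat) %*% vi %*% xmat, t(xmat) %*% vi %*% y)
  expect_equal(tidy(fit)$estimate, as.numeric(beta), tolerance = 1e-8)
})

test_that("model validation catches unsupported structures", {
  df <- tibble::tibble(y = rnorm(20), x = rnorm(20),
                       g = factor(rep(1:4, 5)))
  expect_error(fit_lmm(df, y ~ x + (x | g)), class = "reefsucc_random_slope")
  df$x2 <- df$x * 2
  expect_error(fit_lmm(df, y ~ x + x2 + (1 | g)),
               class = "reefsucc_aliased_design")
  df$one <- factor("a")
  expect_error(fit_lmm(df, y ~ x + (1 | one)), "fewer than 2 levels")
  expect_error(satterthwaite_test(fit_lmm(df, y ~ x + (1 | g)), "nope"),
               "no coefficient")
})

test_that("two crossed random intercepts are supported", {
  set.seed(40)
  site <- factor(rep(1:5, times = 3))
  year <- factor(rep(1:3, each = 5))
  y <- rnorm(5, 0, 1)[site] + rnorm(3, 0, 1)[year] + rnorm(15, 0, 0.5)
  fit <- fit_lmm(tibble::tibble(y = y, site = site, year = year),
                 y ~ 1 + (1 | site) + (1 | year))
  gl <- glance(fit)
  expect_true(all(c("sd_site", "sd_year") %in% names(gl)))
})

test_that("ANOVA + LSD letters encode exactly the pairwise significance graph", {
  # identical groups: F = 0, p = 1, one shared letter
  df0 <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                        g = rep(c("a", "b", "c"), each = 3))
  r0 <- anova_lsd(df0, "v", "g")
  expect_equal(glance(r0)$f, 0, tolerance = 1e-12)
  expect_equal(glance(r0)$p, 1, tolerance = 1e-12)
  expect_true(all(tidy(r0)$letters == tidy(r0)$letters[1]))

  # clearly separated groups get distinct letters
  df1 <- tibble::tibble(v = c(0, 0, 0.1, 10, 10, 10.1),
                        g = rep(c("lo", "hi"), each = 3))
  r1 <- anova_lsd(df1, "v", "g")
  expect_lt(glance(r1)$p, 1e-6)
  expect_equal(sort(tidy(r1)$letters), c("a", "b"))

  # two-group F equals the squared pooled t
  tt <- stats::t.test(v ~ g, data = df1, var.equal = TRUE)
  expect_equal(glance(r1)$f, unname(tt$statistic)^2, tolerance = 1e-9)

  # letters match the brute-force significance graph on random instances
  set.seed(50)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    df <- tibble::tibble(
      g = rep(letters[1:k], each = 4),
      v = rnorm(4 * k, mean = sample(0:3, k, replace = TRUE)[rep(1:k, each = 4)])
    )
    r <- anova_lsd(df, "v", "g")
    tab <- tidy(r)
    if (is.null(r$pairwise)) {
      expect_true(all(tab$letters == tab$letters[1]))
      next
    }
    for (j in seq_len(nrow(r$pairwise))) {
      l1 <- tab$letters[tab$group == r$pairwise$group1[j]]
      l2 <- tab$letters[tab$group == r$pairwise$group2[j]]
      share <- length(intersect(strsplit(l1, "")[[1]],
                                strsplit(l2, "")[[1]])) > 0
      if (r$pairwise$p[j] < r$alpha) {
        expect_false(share)
      } else {
        expect_true(share)
      }
    }
  }

  const <- tibble::tibble(v = rep(c(1, 2), each = 3),
                          g = rep(c("a", "b"), each = 3))
  expect_error(suppressWarnings(anova_lsd(const, "v", "g")),
               "zero within-group")
})
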