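test_that("Bray-Curtis matches hand evaluation and flags empty units", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  withzero <- rbind(u1 = c(1, 2), u2 = c(0, 0))
  expect_error(bray_curtis(withzero), class = "reefsucc_zero_unit")
})

test_that("PCoA recovers classical-scaling geometry", {
  # collinear points: one positive axis, coordinates (-1, 0, 1) up to sign
  d_line <- as.dist(rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
  ord <- pcoa(d_line)
  expect_equal(ncol(ord$coordinates), 1)
  expect_equal(unname(sort(ord$coordinates[, 1])), c(-1, 0, 1),
               tolerance = 1e-9)

  # unit square: two positive eigenvalues each explaining 50%
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ord_sq <- pcoa(stats::dist(sq))
  expect_equal(ord_sq$explained[1:2], c(0.5, 0.5), tolerance = 1e-9)

  # duplicated unit lands on coincident coordinates
  dup <- rbind(c(0, 0), c(0, 0), c(3, 4), c(1, 5))
  ord_dup <- pcoa(stats::dist(dup))
  expect_equal(ord_dup$coordinates[1, ], ord_dup$coordinates[2, ],
               tolerance = 1e-9)

  expect_error(pcoa(stats::dist(rbind(c(0, 0), c(1, 1)))), "at least 3")
})

test_that("PCoA reconstructs Euclidean-embeddable distances and inertia", {
  set.seed(3)
  x <- matrix(rnorm(10 * 5), 10, 5)
  d <- stats::dist(x)
  ord <- pcoa(d)
  expect_equal(as.numeric(stats::dist(ord$coordinates)), as.numeric(d),
               tolerance = 1e-9)
  eig <- ord$eigenvalues
  expect_equal(sum(eig[eig > 1e-9]), sum(d^2) / 10, tolerance = 1e-9)
  expect_true(all(diff(eig) <= 1e-12))
})

test_that("PERMANOVA partitions R2 to one and matches a brute-force pseudo-F", {
  set.seed(21)
  x <- matrix(rnorm(18 * 4), 18, 4)
  x[1:9, 1] <- x[1:9, 1] + 1.5
  g <- factor(rep(c("u", "v"), each = 9))
  d <- stats::dist(x)
  res <- permanova(d, data.frame(g = g), ~ g, n_perm = 99, seed = 5)
  tab <- tidy(res)
  expect_equal(sum(tab$r2[tab$term != "Total"], na.rm = TRUE), 1,
               tolerance = 1e-9)

  # classical one-factor construction from squared distances
  dm2 <- as.matrix(d)^2
  n <- 18
  ss_t <- sum(dm2[upper.tri(dm2)]) / n
  ss_w <- sum(vapply(levels(g), function(l) {
    idx <- which(g == l)
    sum(dm2[idx, idx][upper.tri(dm2[idx, idx])]) / length(idx)
  }, 0))
  f_manual <- ((ss_t - ss_w) / 1) / (ss_w / (n - 2))
  expect_equal(tab$f[tab$term == "g"], f_manual, tolerance = 1e-9)
})

test_that("clearly separated clusters hit the permutation floor", {
  set.seed(77)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 50, 0.1), 10, 2))
  g <- factor(rep(1:2, each = 10))
  res <- permanova(stats::dist(x), data.frame(g = g), ~ g,
                   n_perm = 999, seed = 1)
  expect_equal(tidy(res)$p[1], 1 / 1000, tolerance = 1e-12)

  # distance-preserving relabelling leaves the partition unchanged
  perm <- sample(20)
  res2 <- permanova(stats::dist(x[perm, ]), data.frame(g = g[perm]), ~ g,
                    n_perm = 999, seed = 1)
  expect_equal(tidy(res2)$f[1], tidy(res)$f[1], tolerance = 1e-9)
  expect_equal(tidy(res2)$p[1], tidy(res)$p[1], tolerance = 1e-12)
})

test_that("degenerate and aliased PERMANOVA designs are handled", {
  d0 <- stats::as.dist(matrix(0, 6, 6))
  res <- permanova(d0, data.frame(g = factor(rep(1:2, 3))), ~ g,
                   n_perm = 99, seed = 1)
  tab <- tidy(res)
  expect_equal(tab$r2[tab$term == "Residual"], 1)
  expect_equal(tab$r2[tab$term == "g"], 0)

  design <- data.frame(year = factor(rep(1:2, each = 3)),
                       protected = factor(rep(c("a", "b"), each = 3)))
  x <- matrix(rnorm(12), 6, 2)
  expect_error(
    permanova(stats::dist(x), design, ~ year + protected, n_perm = 99, seed = 1),
    class = "reefsucc_aliased_design"
  )
})

test_that("db-RDA forward selection finds a planted driver and stays null on constants", {
  set.seed(9)
  n <- 24
  driver <- rnorm(n)
  y <- cbind(driver * 2 + rnorm(n, 0, 0.5), rnorm(n), rnorm(n))
  d <- stats::dist(y)
  cand <- data.frame(driver = driver)
  for (j in 1:11) cand[[paste0("noise", j)]] <- rnorm(n)
  fit <- dbrda_forward_select(d, cand)
  expect_equal(fit$selected[1], "driver")
  expect_lte(fit$constrained_inertia, fit$total_inertia + 1e-9)
  expect_equal(fit$constrained_inertia + fit$unconstrained_inertia,
               fit$total_inertia, tolerance = 1e-9)

  # identical response across units: zero inertia, empty selection
  d_id <- stats::dist(matrix(1, 6, 3))
  fit_id <- dbrda_forward_select(d_id, cand[1:6, ])
  expect_length(fit_id$selected, 0)
  expect_equal(fit_id$total_inertia, 0, tolerance = 1e-9)

  # of two perfectly collinear candidates, exactly one is selected and the
  # other is skipped with a log note
  cand2 <- cand
  cand2$dup <- cand2$driver * 3
  fit2 <- dbrda_forward_select(d, cand2[c("driver", "dup")])
  expect_true("skipped_collinear" %in% fit2$steps$action)
  expect_length(intersect(c("driver", "dup"), fit2$selected), 1)
})

test_that("db-RDA constrained inertia agrees with vegan on a selected model", {
  set.seed(13)
  n <- 20
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- cbind(2 * x1 + rnorm(n, 0, 0.4), -x2 + rnorm(n, 0, 0.4), rnorm(n))
  d <- stats::dist(y)
  fit <- dbrda_forward_select(d, data.frame(x1 = x1, x2 = x2))
  vfit <- vegan::dbrda(d ~ x1 + x2, data = data.frame(x1 = x1, x2 = x2))
  # vegan scales ordination inertia by 1/(n - 1)
  expect_equal(fit$total_inertia / (n - 1), vfit$tot.chi, tolerance = 1e-6)
  if (setequal(fit$selected, c("x1", "x2"))) {
    expect_equal(fit$constrained_inertia / (n - 1), vfit$CCA$tot.chi,
                 tolerance = 1e-6)
  }
})
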