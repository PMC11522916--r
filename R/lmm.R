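#' Random-intercept linear mixed model with Satterthwaite tests
#'
#' REML fit of a linear mixed model with one or two crossed random-intercept
#' grouping factors (the only random structure the package's analyses use),
#' e.g. `cover ~ protected * year + (1 | site)` or
#' `abundance ~ coral_cover + (1 | site) + (1 | year)`. Fixed-effect Wald
#' t-tests use Satterthwaite's degrees-of-freedom approximation. Boundary
#' variance estimates (a variance component at 0) are allowed and flagged via
#' `glance()`.
#'
#' @param data Data frame containing all model variables.
#' @param formula An lme4-style formula; every random term must be a plain
#'   random intercept `(1 | g)`.
#' @return Object of class `reef_lmm` wrapping the fit; see
#'   [tidy.reef_lmm()], [glance.reef_lmm()] and [satterthwaite_test()].
#' @export
fit_lmm <- function(data, formula) {
  bars <- lme4::findbars(formula)
  if (length(bars) == 0) rs_abort("formula has no random term; use lm() instead")
  for (b in bars) {
    if (!identical(b[[2]], 1)) {
      rs_abort("only random intercepts (1 | group) are supported",
               class = "reefsucc_random_slope")
    }
    g <- all.vars(b[[3]])
    for (gv in g) {
      if (dplyr::n_distinct(data[[gv]]) < 2) {
        rs_abort(sprintf("random factor %s has fewer than 2 levels", gv))
      }
    }
  }
  fixed <- lme4::nobars(formula)
  mm <- stats::model.matrix(fixed, stats::model.frame(fixed, data))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    rs_abort(sprintf("singular fixed design; aliased columns: %s",
                     paste(aliased, collapse = ", ")),
             class = "reefsucc_aliased_design")
  }
  if (nrow(mm) <= ncol(mm)) rs_abort("need more observations than fixed parameters")
  # boundary (singular) fits are legitimate here and flagged below
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE))
  structure(list(
    fit = fit,
    formula = formula,
    n = nrow(mm),
    p = ncol(mm),
    singular = lme4::isSingular(fit)
  ), class = "reef_lmm")
}

#' @export
print.reef_lmm <- function(x, ...) {
  cat("linear mixed model (REML", if (x$singular) ", boundary fit" else "", ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a reef_lmm fit
#'
#' @param x A `reef_lmm` object.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std_error`, `t`, `df` (Satterthwaite),
#'   `p`.
#' @export
tidy.reef_lmm <- function(x, ...) {
  ct <- stats::coef(summary(x$fit, ddf = "Satterthwaite"))
  tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    t = unname(ct[, "t value"]),
    df = unname(ct[, "df"]),
    p = unname(ct[, "Pr(>|t|)"])
  )
}

#' Glance at a reef_lmm fit
#'
#' @param x A `reef_lmm` object.
#' @param ... Unused.
#' @return One-row tibble with REML log-likelihood, residual SD, one
#'   `sd_<group>` column per random intercept, and the boundary flag.
#' @export
glance.reef_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  out <- tibble::tibble(
    logLik_reml = as.numeric(stats::logLik(x$fit)),
    sigma = stats::sigma(x$fit),
    n = x$n,
    singular = x$singular
  )
  for (i in seq_len(nrow(vc))) {
    if (vc$grp[i] != "Residual") {
      out[[paste0("sd_", vc$grp[i])]] <- vc$sdcor[i]
    }
  }
  out
}

#' Satterthwaite Wald test for one fixed-effect coefficient
#'
#' @param x A `reef_lmm` object.
#' @param coefficient Name of the fixed-effect term.
#' @return One-row tibble: `term`, `estimate`, `t`, `df`, `p`.
#' @export
satterthwaite_test <- function(x, coefficient) {
  tab <- tidy(x)
  row <- tab[tab$term == coefficient, ]
  if (nrow(row) == 0) {
    rs_abort(sprintf("no coefficient named '%s'; available: %s",
                     coefficient, paste(tab$term, collapse = ", ")))
  }
  if (!is.finite(row$df) || row$df <= 0) {
    rs_abort("Satterthwaite df is non-positive; numerical failure",
             class = "reefsucc_bad_df")
  }
  row[c("term", "estimate", "t", "df", "p")]
}

# Internal: maximal cliques of an undirected adjacency matrix (Bron-Kerbosch,
# fine for the handful of groups LSD letters deal with).
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      cliques[[length(cliques) + 1]] <<- sort(r)
      return()
    }
    for (v in p) {
      nb <- setdiff(which(adj[v, ] == 1), v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

#' One-way ANOVA with Fisher's LSD letters
#'
#' One-way F test followed (when significant at `alpha`) by Fisher's least
#' significant difference: all pairwise t-tests on the pooled residual mean
#' square with no multiplicity correction, which is what the LSD procedure
#' means. Groups are labelled with compact letters so that groups sharing a
#' letter are pairwise non-significant; letters are assigned to the maximal
#' cliques of the non-significance graph in descending-mean order, so the
#' labelling is deterministic.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `reef_anova_lsd` with `anova` (F, df, p),
#'   `groups` (tibble: group, n, mean, letters) and `pairwise` (tibble of all
#'   pairs with t, p; NULL when the omnibus test is not significant).
#' @export
anova_lsd <- function(data, value, group, alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) rs_abort("need at least 2 groups")
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  if (df_res < 1) rs_abort("no residual degrees of freedom")
  if (mse <= .Machine$double.eps^0.75 * max(stats::var(y), 1)) {
    rs_abort("zero within-group variance everywhere; LSD undefined")
  }
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ord <- order(-means)
  levs <- levels(g)[ord]
  k <- length(levs)

  pairwise <- NULL
  adj <- matrix(1, k, k)
  omnibus_p <- an["g", "Pr(>F)"]
  if (omnibus_p < alpha) {
    pw <- utils::combn(k, 2)
    rows <- purrr::map_dfr(seq_len(ncol(pw)), function(j) {
      a <- levs[pw[1, j]]; b <- levs[pw[2, j]]
      se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
      tval <- (means[[a]] - means[[b]]) / se
      tibble::tibble(group1 = a, group2 = b, t = tval,
                     p = 2 * stats::pt(-abs(tval), df_res))
    })
    pairwise <- rows
    for (j in seq_len(ncol(pw))) {
      if (rows$p[j] < alpha) {
        adj[pw[1, j], pw[2, j]] <- 0
        adj[pw[2, j], pw[1, j]] <- 0
      }
    }
  }
  diag(adj) <- 1
  cliques <- maximal_cliques(adj)
  cliques <- cliques[order(vapply(cliques, min, 0L))]
  letter_of <- stats::setNames(rep("", k), levs)
  for (ci in seq_along(cliques)) {
    for (m in cliques[[ci]]) {
      letter_of[m] <- paste0(letter_of[m], letters[ci])
    }
  }
  groups <- tibble::tibble(
    group = levs,
    n = as.integer(ns[levs]),
    mean = as.numeric(means[levs]),
    letters = unname(letter_of)
  )
  structure(list(
    anova = tibble::tibble(f = an["g", "F value"], df1 = an["g", "Df"],
                           df2 = df_res, p = omnibus_p),
    groups = groups,
    pairwise = pairwise,
    alpha = alpha
  ), class = "reef_anova_lsd")
}

#' @export
print.reef_anova_lsd <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.reef_anova_lsd <- function(x, ...) x$groups

#' @export
glance.reef_anova_lsd <- function(x, ...) x$anova
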