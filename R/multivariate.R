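#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between assemblage rows of a
#' wide abundance tibble (or plain numeric matrix). Entries lie in \[0, 1\];
#' rows with no positive abundance are rejected because the dissimilarity is
#' undefined for them.
#'
#' @param abundance Wide tibble from [coral_abundance_matrix()] (metadata
#'   columns are detected and dropped) or a numeric matrix with units as rows.
#' @return A `dist` object labelled by unit.
#' @export
bray_curtis <- function(abundance) {
  m <- if (is.matrix(abundance)) abundance else abundance_parts(abundance)$matrix
  if (any(m < 0)) rs_abort("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    rs_abort(sprintf(
      "unit(s) with all-zero abundance: %s",
      paste(rownames(m)[zero], collapse = ", ")
    ), class = "reefsucc_zero_unit")
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double-centering
#' of `-d^2/2` followed by eigendecomposition; coordinates are eigenvectors
#' scaled by the square root of their eigenvalues. Axes with non-positive
#' eigenvalues are dropped and explained variance is computed over positive
#' eigenvalues only; a Cailliez constant-shift correction is available for
#' strongly non-Euclidean dissimilarities.
#'
#' @param d A `dist` object or symmetric matrix.
#' @param n_axes Number of axes to retain (default all positive axes).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return An object of class `reef_pcoa`: list with `coordinates` (units x
#'   axes), `eigenvalues` (all, descending), `explained` (fraction per
#'   retained axis), `correction`, `labels`.
#' @export
pcoa <- function(d, n_axes = NULL, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) rs_abort("PCoA needs at least 3 units")
  fit <- suppressWarnings(
    stats::cmdscale(d, k = n - 1, eig = TRUE, add = (correction == "cailliez"))
  )
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- 1e-9 * max(abs(eig), 1)
  pos <- which(fit$eig > tol)
  coords <- fit$points[, pos, drop = FALSE]
  keep <- min(length(pos), n_axes %||% length(pos))
  coords <- coords[, seq_len(keep), drop = FALSE]
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (keep > 0) {
    colnames(coords) <- paste0("PCoA", seq_len(keep))
    rownames(coords) <- labels
  }
  pos_eig <- fit$eig[pos]
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    explained = (pos_eig / sum(pos_eig))[seq_len(keep)],
    correction = correction,
    labels = labels
  ), class = "reef_pcoa")
}

#' @export
print.reef_pcoa <- function(x, ...) {
  cat(sprintf(
    "PCoA: %d units, %d retained axes (%s correction)\n",
    nrow(x$coordinates), ncol(x$coordinates), x$correction
  ))
  cat("explained:", paste0(sprintf("%.1f%%", 100 * x$explained), collapse = " "), "\n")
  invisible(x)
}

#' PERMANOVA with crossed fixed factors
#'
#' Permutational multivariate analysis of variance on a dissimilarity matrix,
#' partitioning squared dissimilarities among terms entered sequentially
#' (Type-I sums of squares) in the order given by `formula`; significance by
#' free permutation of units with the `(b + 1) / (B + 1)` p-value estimator.
#' Delegates the partition and permutation machinery to [vegan::adonis2()].
#'
#' @param d A `dist` object over units.
#' @param design Data frame of factors, rows aligned with the units of `d`.
#' @param formula Right-hand-sided formula over columns of `design`; default
#'   `~ year + protected + year:protected`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; required, every p-value depends on it.
#' @return Tibble of class `reef_permanova`: one row per term plus Residual
#'   and Total with `df`, `ss`, `r2`, `f`, `p`; attributes `n_perm`, `seed`.
#' @export
permanova <- function(d, design,
                      formula = ~ year + protected + year:protected,
                      n_perm = 999, seed) {
  if (missing(seed)) rs_abort("permanova() requires an explicit seed")
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (nrow(design) != n) rs_abort("design rows must align with distance units")
  vars <- all.vars(formula)
  check_columns(design, vars, "design")
  design <- as.data.frame(design)
  for (v in vars) {
    if (!is.factor(design[[v]])) design[[v]] <- factor(design[[v]])
  }
  mm <- stats::model.matrix(formula, design)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    rs_abort(sprintf(
      "aliased (fully confounded) design columns: %s",
      paste(aliased, collapse = ", ")
    ), class = "reefsucc_aliased_design")
  }
  total_ss <- sum(d^2) / n
  term_labels <- attr(stats::terms(formula), "term.labels")
  if (total_ss < 1e-12) {
    tab <- tibble::tibble(
      term = c(term_labels, "Residual", "Total"),
      df = c(rep(NA_integer_, length(term_labels)), NA_integer_, n - 1L),
      ss = 0, r2 = c(rep(0, length(term_labels)), 1, 1),
      f = NA_real_, p = NA_real_
    )
    return(structure(tab, class = c("reef_permanova", class(tab)),
                     n_perm = n_perm, seed = seed))
  }
  # adonis2 resolves the formula response in its caller's frame, so the call
  # is evaluated inside a frame that carries the distance object
  env <- new.env(parent = asNamespace("vegan"))
  env$..d <- d
  env$..design <- design
  env$..np <- n_perm
  fo <- stats::as.formula(
    paste("..d ~", paste(term_labels, collapse = " + ")), env = env
  )
  set.seed(seed)
  fit <- eval(bquote(
    vegan::adonis2(.(fo), data = ..design, permutations = ..np, by = "terms")
  ), env)
  tab <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    ss = fit$SumOfSqs,
    r2 = fit$R2,
    f = fit$F,
    p = fit$`Pr(>F)`
  )
  structure(tab, class = c("reef_permanova", class(tab)),
            n_perm = n_perm, seed = seed)
}

#' Distance-based RDA with AIC forward selection
#'
#' Constrained ordination of a dissimilarity matrix on environmental
#' predictors, built on the positive-eigenvalue principal-coordinate
#' representation. Starting from the null (unconstrained) model, the
#' candidate whose addition most lowers `AIC = n * log(residual inertia / n)
#' + 2 (k + 1)` (k = number of selected predictors) is added at each step;
#' selection stops when no candidate lowers the AIC. Candidates collinear
#' with the selected set are skipped and logged.
#'
#' @param d A `dist` object over units.
#' @param candidates Data frame of numeric candidate predictors, rows aligned
#'   with units.
#' @return Object of class `reef_dbrda`: `selected`, `steps` (per-step AIC
#'   log), `total_inertia`, `constrained_inertia`, `unconstrained_inertia`,
#'   `site_scores`, `predictor_scores`, `eig_constrained`, `aic`.
#' @export
dbrda_forward_select <- function(d, candidates) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) != n) rs_abort("candidate rows must align with distance units")
  if (anyNA(candidates)) rs_abort("candidates must not contain missing values")
  if (!all(vapply(candidates, is.numeric, TRUE))) {
    rs_abort("candidates must be numeric columns")
  }
  ord <- pcoa(d)
  y <- ord$coordinates          # centered by construction
  total <- sum(y^2)
  aic_of <- function(resid, k) n * log(max(resid, 1e-12) / n) + 2 * (k + 1)

  selected <- character(0)
  current_resid <- total
  current_aic <- aic_of(total, 0)
  steps <- list()
  step_i <- 0
  if (total > 1e-10) repeat {
    step_i <- step_i + 1
    pool <- setdiff(names(candidates), selected)
    if (length(pool) == 0) break
    best <- NULL
    for (cand in pool) {
      x <- as.matrix(cbind(1, candidates[c(selected, cand)]))
      qx <- qr(x)
      if (qx$rank < ncol(x)) {
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = step_i, candidate = cand, aic = NA_real_,
          action = "skipped_collinear"
        )
        next
      }
      fitted <- qr.fitted(qx, y)
      resid <- total - sum(fitted^2)
      aic <- aic_of(resid, length(selected) + 1)
      steps[[length(steps) + 1]] <- tibble::tibble(
        step = step_i, candidate = cand, aic = aic, action = "evaluated"
      )
      if (is.null(best) || aic < best$aic) {
        best <- list(candidate = cand, aic = aic, resid = resid)
      }
    }
    if (is.null(best) || best$aic >= current_aic) break
    selected <- c(selected, best$candidate)
    current_aic <- best$aic
    current_resid <- best$resid
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = step_i, candidate = best$candidate, aic = best$aic,
      action = "added"
    )
  }

  site_scores <- NULL
  predictor_scores <- NULL
  eig_constrained <- numeric(0)
  if (length(selected) > 0) {
    x <- as.matrix(cbind(1, candidates[selected]))
    fitted <- qr.fitted(qr(x), y)
    sv <- svd(fitted)
    keep <- sv$d^2 > 1e-9 * max(sv$d^2, 1)
    eig_constrained <- sv$d[keep]^2
    site_scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
    colnames(site_scores) <- paste0("dbRDA", seq_len(sum(keep)))
    rownames(site_scores) <- ord$labels
    predictor_scores <- stats::cor(candidates[selected], site_scores)
  }
  structure(list(
    selected = selected,
    steps = dplyr::bind_rows(steps),
    total_inertia = total,
    constrained_inertia = total - current_resid,
    unconstrained_inertia = current_resid,
    site_scores = site_scores,
    predictor_scores = predictor_scores,
    eig_constrained = eig_constrained,
    aic = current_aic
  ), class = "reef_dbrda")
}

#' @export
print.reef_dbrda <- function(x, ...) {
  cat("db-RDA forward selection\n")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(null model)", "\n")
  cat(sprintf("constrained inertia: %.4f of %.4f (%.1f%%)\n",
              x$constrained_inertia, x$total_inertia,
              100 * x$constrained_inertia / max(x$total_inertia, 1e-12)))
  invisible(x)
}
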