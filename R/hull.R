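# General-dimension convex hull by the incremental beneath-beyond method.
# Points at most `tol` outside a facet are treated as on/inside it, so
# duplicated and boundary points are absorbed without degenerate facets.

# Internal: hyperplane through d affinely independent points (rows of pts).
# Returns NULL when the points are (numerically) affinely dependent.
facet_plane <- function(pts, tol) {
  d <- ncol(pts)
  a <- t(pts[-1, , drop = FALSE]) - pts[1, ]
  qa <- qr(a)
  if (qa$rank < d - 1) return(NULL)
  qf <- qr.Q(qa, complete = TRUE)
  normal <- qf[, d]
  list(normal = normal, offset = sum(normal * pts[1, ]))
}

# Internal: full hull structure (facets as global row indices).
convex_hull <- function(x, tol = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (d < 1) rs_abort("need at least one coordinate dimension")
  scale <- max(apply(x, 2, function(col) diff(range(col))), 1)
  tol <- tol %||% (1e-9 * scale)
  if (d == 1) {
    lo <- which.min(x[, 1]); hi <- which.max(x[, 1])
    deg <- (x[hi, 1] - x[lo, 1]) < tol
    return(list(dim = 1, degenerate = deg, volume = max(0, x[hi, 1] - x[lo, 1]),
                vertex_idx = if (deg) lo else c(lo, hi)))
  }
  if (n < d + 1) return(list(dim = d, degenerate = TRUE, volume = 0,
                             vertex_idx = integer(0)))

  # initial affine basis: greedy farthest-point selection
  i0 <- which.min(x[, 1])
  basis <- i0
  qmat <- matrix(0, d, 0)
  for (k in seq_len(d)) {
    v <- t(x) - x[i0, ]
    if (ncol(qmat) > 0) v <- v - qmat %*% (t(qmat) %*% v)
    norms <- sqrt(colSums(v^2))
    j <- which.max(norms)
    if (norms[j] < tol) {
      return(list(dim = d, degenerate = TRUE, volume = 0, vertex_idx = integer(0)))
    }
    basis <- c(basis, j)
    qmat <- cbind(qmat, v[, j] / norms[j])
  }
  centre <- colMeans(x[basis, , drop = FALSE])

  orient <- function(f) {
    if (is.null(f)) return(NULL)
    if (sum(f$normal * centre) > f$offset) {
      f$normal <- -f$normal
      f$offset <- -f$offset
    }
    f
  }
  facets <- list()
  for (drop_i in seq_along(basis)) {
    idx <- basis[-drop_i]
    f <- orient(facet_plane(x[idx, , drop = FALSE], tol))
    if (is.null(f)) next
    f$idx <- sort(idx)
    facets[[length(facets) + 1]] <- f
  }

  rest <- setdiff(seq_len(n), basis)
  if (length(rest) > 0) {
    ord <- rest[order(-rowSums((x[rest, , drop = FALSE] -
                                  matrix(centre, length(rest), d, byrow = TRUE))^2))]
    for (ip in ord) {
      p <- x[ip, ]
      above <- vapply(facets, function(f) sum(f$normal * p) - f$offset, 0)
      vis <- which(above > tol)
      if (length(vis) == 0) next
      ridge_keys <- character(0)
      ridge_list <- list()
      ridge_count <- integer(0)
      for (fi in vis) {
        idx <- facets[[fi]]$idx
        for (v in idx) {
          r <- setdiff(idx, v)
          key <- paste(r, collapse = "-")
          pos <- match(key, ridge_keys)
          if (is.na(pos)) {
            ridge_keys <- c(ridge_keys, key)
            ridge_list[[length(ridge_list) + 1]] <- r
            ridge_count <- c(ridge_count, 1L)
          } else {
            ridge_count[pos] <- ridge_count[pos] + 1L
          }
        }
      }
      horizon <- ridge_list[ridge_count == 1L]
      new_facets <- list()
      ok <- TRUE
      for (r in horizon) {
        verts <- sort(c(as.integer(r), ip))
        f <- orient(facet_plane(x[verts, , drop = FALSE], tol))
        if (is.null(f)) { ok <- FALSE; break }
        f$idx <- verts
        new_facets[[length(new_facets) + 1]] <- f
      }
      if (!ok) next   # numerically flat cone; point is effectively on the hull
      facets <- c(facets[-vis], new_facets)
    }
  }

  vol <- 0
  for (f in facets) {
    m <- t(x[f$idx, , drop = FALSE]) - centre
    vol <- vol + abs(det(m)) / factorial(d)
  }
  list(dim = d, degenerate = FALSE, volume = vol,
       vertex_idx = sort(unique(unlist(lapply(facets, `[[`, "idx")))))
}

#' Convex-hull volume in arbitrary dimension
#'
#' Exact volume of the convex hull of a point cloud (area in 2-D,
#' 4-dimensional content in the trait-space application). A cloud with fewer
#' than `d + 1` affinely independent points is degenerate and returns 0.
#'
#' @param x Numeric matrix, points as rows.
#' @param tol Geometric tolerance; default `1e-9` times the coordinate range.
#' @return Volume (scalar >= 0) with attribute `degenerate` (logical).
#' @export
convex_hull_volume <- function(x, tol = NULL) {
  h <- convex_hull(x, tol)
  structure(h$volume, degenerate = h$degenerate)
}

#' Convex-hull vertex indices
#'
#' Row indices of the points that are vertices of the convex hull of `x`.
#' For coincident points only one representative is reported.
#'
#' @inheritParams convex_hull_volume
#' @return Sorted integer vector of row indices (empty when degenerate).
#' @export
convex_hull_vertices <- function(x, tol = NULL) {
  convex_hull(x, tol)$vertex_idx
}
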