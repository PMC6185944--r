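#' Principal angles between two manifolds
#'
#' Computes the m principal angles between two m-dimensional subspaces of
#' n-dimensional space from the singular value decomposition of the m x m
#' inner-product matrix of their orthonormal bases
#' (`t(W_A) %*% W_B = P_A C t(P_B)`, with `C` the diagonal matrix of ranked
#' cosines). Angles are ascending by construction; 0 means a shared
#' direction, 90 an orthogonal one.
#'
#' @param W_a,W_b n x m matrices with orthonormal columns (e.g. `$W` of a
#'   [fit_pca()] manifold), or `manifold` objects.
#' @return class `principal_angles`: `angles` (degrees, ascending),
#'   `cosines`, and the aligned direction matrices `P_a`, `P_b` (m x m
#'   orthogonal).
#' @export
principal_angles <- function(W_a, W_b) {
  if (inherits(W_a, "manifold")) W_a <- W_a$W
  if (inherits(W_b, "manifold")) W_b <- W_b$W
  stopifnot(nrow(W_a) == nrow(W_b), ncol(W_a) == ncol(W_b))
  if (!is_orthonormal(W_a) || !is_orthonormal(W_b))
    stop("contract violation: bases must be orthonormal (within 1e-8)",
         call. = FALSE)
  s <- svd(crossprod(W_a, W_b))
  cosines <- pmin(pmax(s$d, 0), 1)
  structure(list(angles = acos(cosines) * 180 / pi, cosines = cosines,
                 P_a = s$u, P_b = s$v),
            class = "principal_angles")
}

#' @export
print.principal_angles <- function(x, ...) {
  cat("<principal_angles> degrees:",
      paste(sprintf("%.1f", x$angles), collapse = ", "), "\n")
  invisible(x)
}

# Angles (degrees, ascending) between two orthonormal bases, vector only.
angles_between <- function(W_a, W_b) {
  s <- svd(crossprod(W_a, W_b), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, 0), 1)) * 180 / pi
}

#' Significance of principal angles against a surrogate ensemble
#'
#' Per-rank thresholds are the `alpha` quantile of each rank's surrogate
#' angle distribution (angles smaller than almost all surrogate angles are
#' "significantly small"). Reports the largest k such that the leading k
#' observed angles are all below threshold.
#'
#' @param result a [principal_angles()] result (or a plain angle vector in
#'   degrees, ascending).
#' @param ensemble a [tme_surrogates()] ensemble computed at matching m.
#' @param alpha significance level (default 0.001).
#' @return list with `thresholds` (degrees per rank), `significant` (logical
#'   per rank), and `k` (count of leading significantly small angles).
#' @export
angle_significance <- function(result, ensemble, alpha = 0.001) {
  angles <- if (inherits(result, "principal_angles")) result$angles
            else result
  m <- length(angles)
  surr <- surrogate_angles(ensemble, m)
  if (nrow(surr) * alpha < 1)
    stop("resolution error: n_surrogates x alpha < 1", call. = FALSE)
  thresholds <- apply(surr, 2, stats::quantile, probs = alpha,
                      names = FALSE)
  significant <- angles < thresholds
  k <- if (!significant[1]) 0L else {
    first_fail <- match(FALSE, significant)
    if (is.na(first_fail)) m else first_fail - 1L
  }
  list(thresholds = thresholds, significant = significant, k = k)
}

# Extract the n_surrogates x m angle matrix for dimensionality m from an
# ensemble (computed from stored surrogate manifold bases).
surrogate_angles <- function(ensemble, m) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  key <- as.character(m)
  if (!is.null(ensemble$angles[[key]])) return(ensemble$angles[[key]])
  if (m > ensemble$m_max)
    stop("ensemble holds bases only up to m = ", ensemble$m_max,
         call. = FALSE)
  t(vapply(seq_along(ensemble$bases_a), function(i) {
    angles_between(ensemble$bases_a[[i]][, seq_len(m), drop = FALSE],
                   ensemble$bases_b[[i]][, seq_len(m), drop = FALSE])
  }, numeric(m)))
}
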