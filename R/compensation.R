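# The compensation index: the core statistic of the package.

#' Compensation index of a group of sites
#'
#' For a group G of sites with branch-wise signed property-change vectors
#' X_i, the compensation index is
#' \deqn{C(G) = 1 - \frac{\lVert \sum_i X_i \rVert}{\sum_i \lVert X_i \rVert},}
#' with Euclidean norms over branches. C = 1 when changes perfectly oppose
#' each other (the summed vector vanishes), C = 0 when all sites change in
#' the same direction. On a single branch the norm reduces to the absolute
#' value and C becomes [branch_compensation()].
#'
#' C is invariant under jointly permuting branch indices across sites and
#' under multiplying all vectors by a positive scalar; C(\{X, -X\}) = 1 and
#' C(\{X, X\}) = 0 exactly.
#'
#' @param vectors Numeric matrix (rows = sites, columns = branches) or list
#'   of equal-length numeric vectors, at least two.
#' @return Compensation index in [0, 1] (clipped against rounding).
#' @export
compensation_index <- function(vectors) {
  if (is.list(vectors)) {
    if (length(unique(lengths(vectors))) != 1L) {
      stop("site change vectors must have equal length")
    }
    vectors <- do.call(rbind, vectors)
  }
  stopifnot(is.matrix(vectors))
  if (nrow(vectors) < 2L) stop("a group needs at least 2 sites")
  if (anyNA(vectors)) stop("change vectors contain NA (non-analyzable site?)")
  norms <- sqrt(rowSums(vectors^2))
  if (all(norms == 0)) {
    stop("all change vectors are zero; compensation is undefined ",
         "(no change signal at these sites)")
  }
  val <- 1 - sqrt(sum(colSums(vectors)^2)) / sum(norms)
  min(max(val, 0), 1)
}

#' Branch-level compensation index
#'
#' The compensation index restricted to a single branch j:
#' \deqn{C_j(G) = 1 - |\sum_i x_{ij}| / \sum_i |x_{ij}|.}
#'
#' @param changes Numeric vector of per-site signed property changes on one
#'   branch (length >= 2).
#' @param zero_tol Branches where every |change| is below `zero_tol` times
#'   the maximum absolute change observed (or absolutely, if all are tiny)
#'   have an undefined index and return `NA` (flagged, never imputed).
#' @return C_j in [0, 1], or `NA` if undefined.
#' @export
branch_compensation <- function(changes, zero_tol = 1e-9) {
  stopifnot(is.numeric(changes))
  if (length(changes) < 2L) stop("a group needs at least 2 sites")
  if (anyNA(changes)) stop("changes contain NA")
  tot <- sum(abs(changes))
  if (tot <= zero_tol) return(NA_real_)
  min(max(1 - abs(sum(changes)) / tot, 0), 1)
}

# Pairwise compensation matrix for clustering: C for every pair of rows of X.
.pairwise_compensation <- function(X) {
  norms <- sqrt(rowSums(X^2))
  ip <- tcrossprod(X)
  sum_norm <- sqrt(pmax(outer(norms^2, norms^2, "+") + 2 * ip, 0))
  C <- 1 - sum_norm / outer(norms, norms, "+")
  pmin(pmax(C, 0), 1)
}
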