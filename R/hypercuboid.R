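#' Per-class value intervals of a feature
#'
#' For each class, the closed interval \eqn{[L_i, U_i]} spanned by the
#' feature's values over the samples of that class. These intervals are the
#' one-dimensional class hypercuboids from which the dependency (relevance)
#' measure is built.
#'
#' @param values Numeric vector of feature values, one per sample.
#' @param labels Class label per sample (any atomic type; coerced to factor).
#' @return A matrix with one row per class and columns \code{L} and \code{U};
#'   row names are the class levels.
#' @examples
#' class_intervals(c(1, 2, 5, 6), c("A", "A", "B", "B"))
#' @export
class_intervals <- function(values, labels) {
  stopifnot(is.numeric(values))
  if (length(values) != length(labels))
    stop("values and labels must have equal length")
  f <- if (is.factor(labels)) labels else factor(labels)
  if (any(tabulate(f, nbins = nlevels(f)) == 0L))
    stop("degenerate class partition: empty class")
  L <- tapply(values, f, min)
  U <- tapply(values, f, max)
  out <- cbind(L = as.numeric(L), U = as.numeric(U))
  rownames(out) <- levels(f)
  out
}

# Class-hypercuboid membership matrix H (c x n) for a set of features.
# x: numeric matrix, features in rows, samples in columns. h_ij = 1 iff
# sample j lies inside class i's axis-aligned box in every feature dimension.
# Closed intervals: boundary samples (class min/max) are inside.
.hypercuboid_membership <- function(x, f) {
  n <- ncol(x)
  lev <- levels(f)
  H <- matrix(0L, nrow = length(lev), ncol = n,
              dimnames = list(lev, colnames(x)))
  for (i in seq_along(lev)) {
    idx <- which(f == lev[i])
    lo <- apply(x[, idx, drop = FALSE], 1L, min)
    hi <- apply(x[, idx, drop = FALSE], 1L, max)
    inside <- colSums(x >= lo & x <= hi) == nrow(x)
    H[i, ] <- as.integer(inside)
  }
  H
}

#' Rough-hypercuboid relevance (dependency) of a feature set
#'
#' Builds one axis-aligned hypercuboid per class, spanning the class-wise
#' min--max range of every supplied feature, and counts the samples that fall
#' into more than one class box ("confused" samples). The relevance is
#' \deqn{\gamma = 1 - \frac{1}{n}\sum_j v_j, \qquad
#'       v_j = \min\{1, \sum_i h_{ij} - 1\},}
#' where \eqn{h_{ij}} indicates that sample \eqn{j} lies inside class
#' \eqn{i}'s box. \eqn{\gamma \in [0, 1]}; it is 1 iff the class boxes are
#' pairwise disjoint over the samples and 0 for a constant feature with at
#' least two classes. Adding a feature can only shrink the boxes, so
#' \eqn{\gamma} is monotone non-decreasing under feature addition.
#'
#' @param x Numeric vector (one feature) or matrix with features in rows and
#'   samples in columns.
#' @param labels Class label per sample.
#' @param detail If \code{TRUE}, also return the membership matrix \code{H}
#'   and confusion vector \code{V}.
#' @return The relevance \eqn{\gamma} (a number in \eqn{[0,1]}), or, with
#'   \code{detail = TRUE}, a list with elements \code{gamma}, \code{H},
#'   \code{V}.
#' @examples
#' rh_relevance(c(1, 2, 5, 6), c("A", "A", "B", "B"))  # disjoint: 1
#' rh_relevance(c(1, 4, 2, 3), c("A", "A", "B", "B"))  # overlapping: 0.5
#' @export
rh_relevance <- function(x, labels, detail = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.numeric(x)) stop("x must be numeric")
  if (ncol(x) != length(labels))
    stop("number of samples and labels differ")
  f <- if (is.factor(labels)) labels else factor(labels)
  if (any(tabulate(f, nbins = nlevels(f)) == 0L))
    stop("degenerate class partition: empty class")
  H <- .hypercuboid_membership(x, f)
  V <- pmin(1L, colSums(H) - 1L)
  gamma <- 1 - sum(V) / ncol(x)
  if (detail) list(gamma = gamma, H = H, V = V) else gamma
}

#' Supervised similarity between two features
#'
#' Similarity used by the clustering algorithm to grow coarse clusters
#' around a seed. With \eqn{\gamma_1, \gamma_2} the single-feature
#' relevances and \eqn{\gamma_{12}} the joint (two-dimensional) relevance,
#' the shared (redundant) dependency \eqn{\gamma_1 + \gamma_2 -
#' \gamma_{12}} is normalized in the Sørensen--Dice form, by the mean of
#' the two single-feature dependencies:
#' \deqn{S = \max\left\{0, \frac{2\,(\gamma_1 + \gamma_2 - \gamma_{12})}
#'   {\gamma_1 + \gamma_2}\right\},}
#' with \eqn{S = 0} when either relevance is 0. Because
#' \eqn{\gamma_{12} \ge \max(\gamma_1, \gamma_2)}, \eqn{S \le 1}; \eqn{S =
#' 1} requires the two features to carry identical dependency
#' (\eqn{\gamma_1 = \gamma_2 = \gamma_{12}}, e.g. a duplicated feature)
#' and \eqn{S = 0} marks fully complementary features. Normalizing by the
#' \emph{smaller} relevance instead would rate any feature maximally
#' similar to a fully discriminating seed (\eqn{\gamma_1 = 1} forces
#' \eqn{\gamma_{12} = 1}, so the ratio is identically 1), collapsing the
#' clustering into one cluster whenever some feature separates the
#' classes; the Dice normalization stays discriminating there, reducing
#' to \eqn{S = 2\gamma_2 / (1 + \gamma_2)} against a \eqn{\gamma_1 = 1}
#' seed.
#'
#' @param v1,v2 Numeric vectors of equal length (two features over the same
#'   samples).
#' @param labels Class label per sample (shared by both features).
#' @return Similarity in \eqn{[0, 1]}.
#' @examples
#' lab <- c("A", "A", "B", "B")
#' rh_similarity(c(1, 4, 2, 3), c(2, 3, 1, 4), lab)  # complementary: 0
#' @export
rh_similarity <- function(v1, v2, labels) {
  if (length(v1) != length(v2))
    stop("features must have equal length")
  g1 <- rh_relevance(v1, labels)
  g2 <- rh_relevance(v2, labels)
  if (min(g1, g2) == 0) return(0)
  g12 <- rh_relevance(rbind(v1, v2), labels)
  max(0, 2 * (g1 + g2 - g12) / (g1 + g2))
}
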