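#' Madsen-Browning weighted-sum statistic for a continuous trait
#'
#' Each individual gets the weighted count S_i = sum_j g_ij /
#' sqrt(n q_j (1 - q_j)) with q_j the sample MAF, so rare alleles carry
#' large weights. For a continuous phenotype the statistic is the absolute
#' Pearson correlation between y and S (the original rank-sum form applies
#' to case-control data only); a zero-variance score gives 0.
#'
#' @param G a \code{\link{genotype_matrix}} with no missing entries.
#' @param y numeric phenotype.
#' @return Scalar statistic, larger = stronger association.
#' @export
we_statistic <- function(G, y) {
  stopifnot(inherits(G, "genotype_matrix"))
  w <- we_weights(G)
  S <- drop(G$values %*% w)
  if (stats::sd(S) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(y, S))
}

we_weights <- function(G) {
  q <- G$maf
  n <- G$n_individuals
  w <- numeric(length(q))
  poly <- q > 0
  w[poly] <- 1 / sqrt(n * q[poly] * (1 - q[poly]))
  w
}

#' Variable-threshold burden statistic
#'
#' For every threshold t in the rarity lattice (t_max plus every observed
#' MAF below it) the pooled count C_t(i) = sum over variants with
#' MAF <= t of g_ij is scored as
#' z(t) = |sum_i (y_i - ybar) C_t(i)| / sqrt(sum_i C_t(i)^2); the statistic
#' is the maximum of z(t) over the lattice. The full raw lattice is used
#' (duplicated pooled columns cannot change a maximum).
#'
#' @param G a \code{\link{genotype_matrix}} with no missing entries.
#' @param y numeric phenotype.
#' @param t_max upper rarity threshold; default 0.05.
#' @return Scalar statistic (0 when every pooled count is zero).
#' @export
vt_statistic <- function(G, y, t_max = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  C <- vt_pooled_counts(G, t_max)
  if (ncol(C) == 0L) return(0)
  vt_max_z(C, y)
}

vt_pooled_counts <- function(G, t_max = 0.05) {
  thresholds <- sort(unique(c(t_max, G$maf[G$maf < t_max & G$maf > 0])),
                     decreasing = TRUE)
  cols <- lapply(thresholds, function(t) {
    m <- which(G$maf <= t & G$maf > 0)
    if (length(m) == 0L) return(NULL)
    rowSums(G$values[, m, drop = FALSE])
  })
  keep <- !vapply(cols, is.null, logical(1))
  C <- do.call(cbind, cols[keep])
  if (is.null(C)) C <- matrix(0, G$n_individuals, 0)
  colnames(C) <- sprintf("t%.6g", thresholds[keep])
  C
}

vt_max_z <- function(C, y) {
  denom <- sqrt(colSums(C^2))
  ok <- denom > 0
  if (!any(ok)) return(0)
  num <- abs(drop(crossprod(C[, ok, drop = FALSE], y - mean(y))))
  max(num / denom[ok])
}

#' Sequence kernel association (SKAT) statistic
#'
#' Variance-component score statistic Q = r' G W^2 G' r with r = y - ybar
#' (intercept-only null model for a continuous trait) and W the diagonal
#' matrix of Beta-density weights w_j = dbeta(q_j; a1, a2) evaluated at the
#' sample MAF. Default Beta(1, 25) weights up-weight rare variants.
#' Significance is assessed by permutation, like every other statistic in
#' the package, so no asymptotic mixture-of-chi-square approximation is
#' involved.
#'
#' @param G a \code{\link{genotype_matrix}} with no missing entries.
#' @param y numeric phenotype.
#' @param a1,a2 Beta-density weight parameters; defaults 1 and 25.
#' @return Scalar Q >= 0.
#' @export
skat_statistic <- function(G, y, a1 = 1, a2 = 25) {
  stopifnot(inherits(G, "genotype_matrix"))
  w <- stats::dbeta(G$maf, a1, a2)
  r <- y - mean(y)
  sum((drop(crossprod(G$values, r)) * w)^2)
}
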