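#' Fit one regularized multiple-regression association model
#'
#' Fits a single gene-level multiple regression of a continuous trait on a
#' genotype design (optionally augmented with pooled rare-variant counts,
#' see \code{\link{build_pooled_variables}}) using one of five
#' regularization methods:
#' \describe{
#'   \item{RR}{ridge regression; fitted values via the singular value
#'     decomposition with shrinkage d^2/(d^2 + lambda) per singular
#'     direction. \code{lambda = 0} is ordinary least squares (through the
#'     pseudoinverse when the design is rank deficient).}
#'   \item{PCR}{principal components regression on the top k left singular
#'     vectors of the column-centered design.}
#'   \item{PLS}{partial least squares with orthogonal scores; the first
#'     weight vector is proportional to X'y.}
#'   \item{LASSO}{L1-penalized regression over a descending lambda path,
#'     the path position chosen by an information criterion
#'     (\code{\link{information_criterion}}).}
#'   \item{SPLS}{sparse PLS: per component, direction entries with
#'     magnitude below eta times the largest magnitude are zeroed; the
#'     union of surviving variables is refit by PLS, and (K, eta) is chosen
#'     over a two-way grid by the information criterion.}
#' }
#'
#' The scalar \code{fit_statistic} (orientation: larger = stronger
#' association) is the Pearson correlation between \code{y} and the fitted
#' values for RR/PCR/PLS, and -log10 of the post-selection F-test p-value
#' (\code{\link{post_selection_f_pvalue}}) for LASSO/SPLS. A degenerate fit
#' (zero-variance fitted values, empty selected set) has statistic 0.
#'
#' Design columns are mean-centered but, by default, not variance-scaled:
#' unit-variance scaling would inflate rare-variant columns, and the fixed
#' ridge penalties are calibrated on raw genotype counts. Set
#' \code{standardize = TRUE} for unit-variance scaling.
#'
#' @param x design: an \code{augmented_design}, a
#'   \code{\link{genotype_matrix}}, or a plain numeric matrix.
#' @param y numeric response, one value per row of the design.
#' @param method one of \code{"RR"}, \code{"PCR"}, \code{"PLS"},
#'   \code{"SPLS"}, \code{"LASSO"}.
#' @param k number of components for PCR/PLS; overrides \code{k_rule}.
#' @param k_rule \code{"one"} (a single component) or \code{"compk"}
#'   (smallest k whose response R-squared reaches \code{theta} times the
#'   full-rank R-squared); used when \code{k} is \code{NULL}.
#' @param theta variance-explained fraction for \code{k_rule = "compk"};
#'   default 0.8.
#' @param lambda ridge penalty (RR only), >= 0; default 0.
#' @param criterion information criterion for LASSO/SPLS: \code{"AIC"},
#'   \code{"BIC"} or \code{"GIC"}.
#' @param K_max largest number of SPLS components searched; default
#'   \code{min(10, rank)}.
#' @param eta_grid SPLS thresholding grid in [0, 1); default 0.1..0.9.
#' @param standardize scale design columns to unit variance before fitting.
#'
#' @return An object of class \code{"rvfit"}.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200 * 12, 2, 0.05), 200, 12)
#' y <- 1.5 * X[, 3] + rnorm(200)
#' fit <- rvfit(X, y, method = "LASSO", criterion = "BIC")
#' print(fit)
#' @export
rvfit <- function(x, y, method = c("RR", "PCR", "PLS", "SPLS", "LASSO"),
                  k = NULL, k_rule = c("compk", "one"), theta = 0.8,
                  lambda = 0, criterion = c("AIC", "BIC", "GIC"),
                  K_max = NULL, eta_grid = seq(0.1, 0.9, by = 0.1),
                  standardize = FALSE) {
  method <- match.arg(method)
  k_rule <- match.arg(k_rule)
  criterion <- match.arg(criterion)
  d <- .as_design(x)
  X <- d$matrix
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n)
    stop("length(y) must equal the number of design rows")
  if (anyNA(X) || anyNA(y))
    stop("design and response must not contain missing values")

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale_sd <- rep(1, ncol(X))
  if (standardize) {
    scale_sd <- apply(Xc, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    Xc <- sweep(Xc, 2, scale_sd, "/")
  }
  ybar <- mean(y)
  yc <- y - ybar

  eng <- switch(method,
    RR    = .fit_ridge(Xc, yc, lambda),
    PCR   = .fit_pcr(Xc, yc, k = k, k_rule = k_rule, theta = theta),
    PLS   = .fit_pls_top(Xc, yc, k = k, k_rule = k_rule, theta = theta),
    LASSO = .fit_lasso(Xc, yc, criterion = criterion),
    SPLS  = .fit_spls(Xc, yc, K_max = K_max, eta_grid = eta_grid,
                      criterion = criterion))

  fitted <- ybar + eng$fitted_c
  beta <- eng$beta / scale_sd
  names(beta) <- colnames(X)
  selected <- eng$selected
  if (is.null(selected)) selected <- seq_len(ncol(X))
  names(selected) <- colnames(X)[selected]

  if (is.null(eng$statistic)) {
    s <- if (stats::sd(fitted) == 0 || stats::sd(y) == 0) 0
         else stats::cor(y, fitted)
    stat_type <- "correlation"
  } else {
    s <- eng$statistic
    stat_type <- eng$statistic_type
  }

  structure(list(
    method = method,
    hyperparams = eng$hyperparams,
    mu = ybar,
    coefficients = beta,
    fitted = fitted,
    selected = selected,
    fit_statistic = s,
    statistic_type = stat_type,
    degenerate = isTRUE(eng$degenerate),
    y = y,
    center = center,
    scale = scale_sd,
    origin = d$origin,
    n = n, p = ncol(X),
    call = match.call()),
    class = "rvfit")
}

.as_design <- function(x) {
  if (inherits(x, "augmented_design"))
    return(list(matrix = x$matrix, origin = x$origin))
  if (is.list(x) && !is.data.frame(x) &&
      all(c("matrix", "origin") %in% names(x)))
    return(x)
  if (inherits(x, "genotype_matrix")) {
    if (anyNA(x$values))
      stop("impute missing genotypes before model fitting")
    return(list(matrix = x$values,
                origin = rep("original", ncol(x$values))))
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  list(matrix = x, origin = rep("original", ncol(x)))
}

# ---- SVD-based engines ------------------------------------------------------

.svd_rank <- function(sv) {
  tol <- max(sv$d) * max(dim(sv$u)) * .Machine$double.eps
  sum(sv$d > tol)
}

.fit_ridge <- function(Xc, yc, lambda) {
  stopifnot(lambda >= 0)
  sv <- svd(Xc)
  r <- .svd_rank(sv)
  if (r == 0L)
    return(list(fitted_c = rep(0, nrow(Xc)), beta = rep(0, ncol(Xc)),
                hyperparams = list(lambda = lambda), selected = NULL))
  d <- sv$d[seq_len(r)]
  uy <- crossprod(sv$u[, seq_len(r), drop = FALSE], yc)
  shrink <- d^2 / (d^2 + lambda)           # lambda = 0: pseudoinverse limit
  fitted_c <- sv$u[, seq_len(r), drop = FALSE] %*% (shrink * uy)
  beta <- sv$v[, seq_len(r), drop = FALSE] %*% ((d / (d^2 + lambda)) * uy)
  list(fitted_c = drop(fitted_c), beta = drop(beta),
       hyperparams = list(lambda = lambda), selected = NULL)
}

.fit_pcr <- function(Xc, yc, k = NULL, k_rule = "compk", theta = 0.8) {
  sv <- svd(Xc)
  r <- .svd_rank(sv)
  if (r == 0L)
    return(list(fitted_c = rep(0, nrow(Xc)), beta = rep(0, ncol(Xc)),
                hyperparams = list(k = 0), selected = NULL))
  if (is.null(k))
    k <- .choose_k_pcr(sv, yc, r, k_rule, theta)
  if (k < 1 || k > r)
    stop("k must lie in 1..rank(X) = 1..", r)
  uy <- crossprod(sv$u[, seq_len(k), drop = FALSE], yc)
  fitted_c <- sv$u[, seq_len(k), drop = FALSE] %*% uy
  beta <- sv$v[, seq_len(k), drop = FALSE] %*% (uy / sv$d[seq_len(k)])
  list(fitted_c = drop(fitted_c), beta = drop(beta),
       hyperparams = list(k = k), selected = NULL)
}

.choose_k_pcr <- function(sv, yc, r, k_rule, theta) {
  if (k_rule == "one") return(1L)
  uy2 <- drop(crossprod(sv$u[, seq_len(r), drop = FALSE], yc))^2
  ess <- cumsum(uy2)                       # explained SS after k components
  if (ess[r] == 0) return(1L)
  as.integer(which(ess >= theta * ess[r])[1])
}

# Orthogonal-scores PLS recursion. Returns scores, per-score response
# projections and the weight/loading matrices needed for coefficients.
.pls_core <- function(Xc, yc, k_max) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0)
  Z <- matrix(0, n, 0); b <- numeric(0)
  X1 <- Xc
  tol <- .Machine$double.eps^0.75 * max(1, sum(Xc^2)) * max(1, sum(yc^2))
  for (m in seq_len(k_max)) {
    w <- drop(crossprod(X1, yc))
    if (sum(w^2) <= tol) break
    z <- drop(X1 %*% w)
    zz <- sum(z^2)
    if (zz <= tol) break
    pm <- drop(crossprod(X1, z)) / zz
    W <- cbind(W, w); P <- cbind(P, pm); Z <- cbind(Z, z)
    b <- c(b, sum(z * yc) / zz)
    X1 <- X1 - tcrossprod(z, pm)
  }
  list(W = W, P = P, Z = Z, b = b, k = length(b))
}

.pls_beta <- function(core, k) {
  if (k == 0L) return(NULL)
  W <- core$W[, seq_len(k), drop = FALSE]
  P <- core$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), core$b[seq_len(k)]))
}

.fit_pls_top <- function(Xc, yc, k = NULL, k_rule = "compk", theta = 0.8) {
  sv_rank <- .svd_rank(svd(Xc))
  core <- .pls_core(Xc, yc, k_max = if (is.null(k)) sv_rank else k)
  if (core$k == 0L)                        # X'y = 0: null fit, statistic 0
    return(list(fitted_c = rep(0, nrow(Xc)), beta = rep(0, ncol(Xc)),
                hyperparams = list(k = 0), selected = NULL,
                statistic = 0, statistic_type = "correlation",
                degenerate = TRUE))
  if (is.null(k)) {
    if (k_rule == "one") k <- 1L
    else {
      ess <- cumsum(core$b^2 * colSums(core$Z^2))
      k <- as.integer(which(ess >= theta * ess[core$k])[1])
    }
  } else if (k > core$k) {
    stop("k must lie in 1..rank(X) = 1..", core$k)
  }
  fitted_c <- drop(core$Z[, seq_len(k), drop = FALSE] %*% core$b[seq_len(k)])
  list(fitted_c = fitted_c, beta = .pls_beta(core, k),
       hyperparams = list(k = k), selected = NULL)
}

#' Choose the number of PCR/PLS components
#'
#' Implements the two component-count rules used in the association tests:
#' \code{"one"} always returns a single component; \code{"compk"} returns
#' the smallest k for which the model's response R-squared reaches
#' \code{theta} times the R-squared of the full-rank (ordinary least
#' squares) fit.
#'
#' @param x design matrix (will be column-centered).
#' @param y numeric response.
#' @param rule \code{"compk"} or \code{"one"}.
#' @param theta fraction of the full-rank R-squared; default 0.8.
#' @param method \code{"PCR"} or \code{"PLS"} (the component basis).
#' @return Integer component count.
#' @export
choose_k <- function(x, y, rule = c("compk", "one"), theta = 0.8,
                     method = c("PCR", "PLS")) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  stopifnot(theta > 0, theta <= 1)
  X <- as.matrix(x)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- as.numeric(y) - mean(y)
  if (rule == "one") return(1L)
  if (method == "PCR") {
    sv <- svd(Xc)
    .choose_k_pcr(sv, yc, .svd_rank(sv), rule, theta)
  } else {
    core <- .pls_core(Xc, yc, k_max = .svd_rank(svd(Xc)))
    if (core$k == 0L) return(1L)
    ess <- cumsum(core$b^2 * colSums(core$Z^2))
    as.integer(which(ess >= theta * ess[core$k])[1])
  }
}

# ---- information criteria and post-selection F ------------------------------

#' Information criterion for model-size selection
#'
#' IC = n * log(rss / n) + multiplier * df, with multiplier 2 for AIC,
#' log(n) for BIC and (log log n) * (log p) for GIC (a standard
#' high-dimensional choice; override through \code{multiplier}). Smaller is
#' better. \code{rss = 0} yields \code{-Inf}, which callers treat as an
#' immediate, degenerate winner.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of observations.
#' @param df model degrees of freedom (number of selected variables).
#' @param criterion \code{"AIC"}, \code{"BIC"} or \code{"GIC"}.
#' @param p number of candidate predictors (needed for GIC).
#' @param multiplier optional explicit penalty multiplier overriding
#'   \code{criterion}.
#' @return Scalar criterion value.
#' @export
information_criterion <- function(rss, n, df,
                                  criterion = c("AIC", "BIC", "GIC"),
                                  p = NULL, multiplier = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(rss >= 0, df >= 0, n > 0)
  if (is.null(multiplier)) {
    multiplier <- switch(criterion,
      AIC = 2,
      BIC = log(n),
      GIC = {
        if (is.null(p)) stop("GIC needs p, the number of candidate predictors")
        log(log(n)) * log(p)
      })
  }
  stopifnot(multiplier > 0)
  if (rss == 0) return(-Inf)
  n * log(rss / n) + multiplier * df
}

#' Post-selection F-test p-value
#'
#' Refits ordinary least squares of y on the selected design columns plus
#' an intercept and returns the upper-tail p-value of the global F
#' statistic F = ((TSS - RSS)/s) / (RSS/(n - s - 1)) on (s, n - s - 1)
#' degrees of freedom, where s is the number of selected columns. Used as
#' the model-performance score of the sparse methods (as -log10 p).
#'
#' An empty selection gives p = 1. A saturated selection (s >= n - 1) or an
#' exact fit (RSS = 0) gives the smallest positive double and sets the
#' \code{"degenerate"} attribute.
#'
#' @param x design matrix.
#' @param y numeric response.
#' @param selected integer indices of selected columns.
#' @return p-value in (0, 1], with attribute \code{degenerate}.
#' @export
post_selection_f_pvalue <- function(x, y, selected) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  s <- length(selected)
  if (s == 0L)
    return(structure(1, degenerate = FALSE))
  if (s >= n - 1L)
    return(structure(.Machine$double.xmin, degenerate = TRUE))
  Xs <- cbind(1, X[, selected, drop = FALSE])
  qx <- qr(Xs)
  rss <- sum((y - qr.fitted(qx, y))^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0)
    return(structure(1, degenerate = TRUE))
  if (rss <= tss * .Machine$double.eps * n)
    return(structure(.Machine$double.xmin, degenerate = TRUE))
  f <- ((tss - rss) / s) / (rss / (n - s - 1))
  structure(stats::pf(f, s, n - s - 1, lower.tail = FALSE),
            degenerate = FALSE)
}

# ---- L1 engines -------------------------------------------------------------

# Descending lambda path from lambda_max = max_j |x_j' y_c| / n, 100
# log-spaced values down to eps * lambda_max (eps = 0.001 when n > p, 0.01
# otherwise), mirroring the usual coordinate-descent path convention.
.lasso_path <- function(Xc, yc, nlambda = 100) {
  n <- nrow(Xc); p <- ncol(Xc)
  lmax <- max(abs(crossprod(Xc, yc))) / n
  eps <- if (n > p) 1e-3 else 1e-2
  if (lmax <= 0) return(NULL)
  exp(seq(log(lmax), log(eps * lmax), length.out = nlambda))
}

.fit_lasso <- function(Xc, yc, criterion = "BIC") {
  n <- nrow(Xc); p <- ncol(Xc)
  path <- .lasso_path(Xc, yc)
  null_fit <- list(fitted_c = rep(0, n), beta = rep(0, p),
                   hyperparams = list(criterion = criterion, lambda = NA_real_),
                   selected = integer(0), statistic = 0,
                   statistic_type = "neglog10p", degenerate = FALSE)
  if (is.null(path)) return(null_fit)
  if (p >= 2L) {
    gfit <- glmnet::glmnet(Xc, yc, family = "gaussian", lambda = path,
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-16)
    B <- as.matrix(gfit$beta)
    path <- gfit$lambda
  } else {
    # single predictor: exact soft-threshold solution
    xx <- sum(Xc^2); xy <- sum(Xc * yc)
    B <- matrix(vapply(path, function(l) {
      sign(xy) * max(0, abs(xy) - n * l) / xx
    }, numeric(1)), nrow = 1)
  }
  resid <- yc - Xc %*% B
  rss <- colSums(resid^2)
  df <- colSums(B != 0)
  ic <- vapply(seq_along(path), function(i)
    information_criterion(rss[i], n, df[i], criterion, p = p), numeric(1))
  best <- which.min(ic)                    # first minimum = largest lambda
  beta <- B[, best]
  sel <- which(beta != 0)
  if (length(sel) == 0L) return(null_fit)
  pv <- post_selection_f_pvalue(Xc, yc, sel)
  list(fitted_c = drop(Xc %*% beta), beta = beta,
       hyperparams = list(criterion = criterion, lambda = path[best],
                          ic = ic[best]),
       selected = sel,
       statistic = -log10(pv), statistic_type = "neglog10p",
       degenerate = attr(pv, "degenerate"))
}

# Sparse PLS: per component the direction vector (on the deflated design)
# is hard-thresholded at eta * max |entry|; survivors accumulate into the
# active set, and the final coefficients come from a PLS refit on the
# active set with K components.
.spls_active_sets <- function(Xc, yc, K_max, eta) {
  p <- ncol(Xc)
  X1 <- Xc
  active <- integer(0)
  sets <- vector("list", K_max)
  tol <- .Machine$double.eps^0.75 * max(1, sum(Xc^2)) * max(1, sum(yc^2))
  for (m in seq_len(K_max)) {
    w <- drop(crossprod(X1, yc))
    if (sum(w^2) <= tol) { sets[seq(m, K_max)] <- list(NULL); break }
    w[abs(w) < eta * max(abs(w))] <- 0
    z <- drop(X1 %*% w)
    zz <- sum(z^2)
    if (zz <= tol) { sets[seq(m, K_max)] <- list(NULL); break }
    active <- union(active, which(w != 0))
    sets[[m]] <- sort(active)
    X1 <- X1 - tcrossprod(z, drop(crossprod(X1, z)) / zz)
  }
  sets
}

.fit_spls <- function(Xc, yc, K_max = NULL, eta_grid = seq(0.1, 0.9, 0.1),
                      criterion = "BIC") {
  n <- nrow(Xc); p <- ncol(Xc)
  stopifnot(all(eta_grid >= 0), all(eta_grid < 1))
  r <- .svd_rank(svd(Xc))
  if (is.null(K_max)) K_max <- min(10L, r)
  K_max <- max(1L, min(K_max, r))
  null_fit <- list(fitted_c = rep(0, n), beta = rep(0, p),
                   hyperparams = list(criterion = criterion,
                                      K = 0L, eta = NA_real_),
                   selected = integer(0), statistic = 0,
                   statistic_type = "neglog10p", degenerate = FALSE)
  best <- NULL
  seen <- new.env(parent = emptyenv())   # (K, A) pairs recur across etas
  for (eta in eta_grid) {
    sets <- .spls_active_sets(Xc, yc, K_max, eta)
    for (K in seq_len(K_max)) {
      A <- sets[[K]]
      if (is.null(A) || length(A) == 0L) next
      key <- paste(K, paste(A, collapse = ","))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      sub <- .pls_core(Xc[, A, drop = FALSE], yc, k_max = K)
      if (sub$k == 0L) next
      kk <- min(K, sub$k)
      fitted_c <- drop(sub$Z[, seq_len(kk), drop = FALSE] %*% sub$b[seq_len(kk)])
      rss <- sum((yc - fitted_c)^2)
      ic <- information_criterion(rss, n, df = length(A), criterion, p = p)
      if (is.null(best) || ic < best$ic)
        best <- list(ic = ic, K = K, eta = eta, A = A, kk = kk,
                     fitted_c = fitted_c, core = sub)
    }
  }
  if (is.null(best)) return(null_fit)
  beta <- rep(0, p)
  beta[best$A] <- .pls_beta(best$core, best$kk)
  pv <- post_selection_f_pvalue(Xc, yc, best$A)
  list(fitted_c = best$fitted_c, beta = beta,
       hyperparams = list(criterion = criterion, K = best$K, eta = best$eta,
                          ic = best$ic),
       selected = best$A,
       statistic = -log10(pv), statistic_type = "neglog10p",
       degenerate = attr(pv, "degenerate"))
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.rvfit <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, function(v) format(v, digits = 4),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("rvfit: %s (%s)\n", x$method, hp))
  cat(sprintf("  n = %d, design columns = %d, selected = %d\n",
              x$n, x$p, length(x$selected)))
  cat(sprintf("  fit statistic (%s) = %.4g%s\n", x$statistic_type,
              x$fit_statistic, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.rvfit <- function(object, ...) {
  c("(Intercept)" = unname(object$mu -
      sum(object$coefficients * object$center)),
    object$coefficients)
}

#' @export
fitted.rvfit <- function(object, ...) object$fitted

#' @export
residuals.rvfit <- function(object, ...) object$y - object$fitted

#' @export
predict.rvfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- if (inherits(newdata, "augmented_design")) newdata$matrix
       else if (inherits(newdata, "genotype_matrix")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != object$p)
    stop("newdata must have ", object$p, " columns")
  Xc <- sweep(X, 2, object$center)
  drop(object$mu + Xc %*% object$coefficients)
}

#' @export
summary.rvfit <- function(object, ...) {
  r2 <- if (stats::sd(object$fitted) == 0) 0
        else stats::cor(object$y, object$fitted)^2
  sel <- object$selected
  structure(list(fit = object, r_squared = r2,
                 n_selected = length(sel),
                 n_pooled_selected = sum(object$origin[sel] == "pooled"),
                 selected_names = names(sel)),
            class = "summary.rvfit")
}

#' @export
print.summary.rvfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training R-squared = %.4f\n", x$r_squared))
  cat(sprintf("  selected columns: %d (%d pooled)\n",
              x$n_selected, x$n_pooled_selected))
  if (x$n_selected > 0 && x$n_selected <= 25)
    cat("   ", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
simulate.rvfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  sigma <- stats::sd(object$y - object$fitted)
  out <- as.data.frame(replicate(nsim, object$fitted + stats::rnorm(n, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.rvfit <- function(x, ...) {
  beta <- x$coefficients
  col <- ifelse(x$origin == "pooled", "tomato", "grey40")
  graphics::barplot(beta, col = col, border = NA, las = 2,
                    cex.names = 0.5,
                    ylab = "coefficient",
                    main = sprintf("%s coefficients", x$method), ...)
  invisible(x)
}
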