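#' Permutation p-value for an association statistic
#'
#' Computes an empirical p-value by permuting the phenotype relative to all
#' genotype rows. The statistic procedure must encapsulate the full
#' analysis — including any model-size or penalty selection by information
#' criterion — so that selection is redone independently inside every
#' permutation. The genotype design is unchanged by a phenotype
#' permutation, so pooled columns are built once, outside the loop.
#'
#' The p-value is (1 + number of permutation statistics >= observed) /
#' (B + 1); ties count as extreme, and the smallest achievable p is
#' 1/(B + 1). A statistic procedure that fails on a permuted dataset
#' contributes -Inf (never extreme) with a warning.
#'
#' Optional sequential early stopping: when the exceedance count reaches
#' \code{r_max} the loop stops and the p-value uses the permutations run so
#' far. Off by default.
#'
#' @param statistic function of the phenotype vector returning a scalar
#'   with orientation larger = more extreme.
#' @param y numeric phenotype.
#' @param B number of permutations (>= 1).
#' @param seed optional integer master seed (R's Mersenne-Twister RNG).
#' @param early_stop enable sequential stopping.
#' @param r_max exceedance count triggering the stop; default 50.
#' @param label optional method label carried into the result.
#' @return An object of class \code{"rvperm"}: \code{observed},
#'   \code{perm_stats}, \code{p_value}, \code{B} (permutations actually
#'   run), \code{seed}, \code{label}.
#' @export
permutation_pvalue <- function(statistic, y, B, seed = NULL,
                               early_stop = FALSE, r_max = 50,
                               label = NULL) {
  stopifnot(is.function(statistic), B >= 1)
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic(y)
  n <- length(y)
  perm_stats <- numeric(B)
  r <- 0L
  used <- 0L
  for (b in seq_len(B)) {
    yp <- y[sample.int(n)]
    s <- tryCatch(statistic(yp), error = function(e) {
      warning("statistic failed on permutation ", b, ": ",
              conditionMessage(e), call. = FALSE)
      -Inf
    })
    perm_stats[b] <- s
    used <- b
    if (s >= observed) r <- r + 1L
    if (early_stop && r >= r_max) break
  }
  perm_stats <- perm_stats[seq_len(used)]
  structure(list(observed = observed,
                 perm_stats = perm_stats,
                 p_value = (1 + r) / (used + 1),
                 B = used,
                 seed = seed,
                 rng = RNGkind()[1],
                 label = label),
            class = "rvperm")
}

#' @export
print.rvperm <- function(x, ...) {
  cat(sprintf("rvperm%s: observed = %.4g, B = %d, p = %.4g\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$observed, x$B, x$p_value))
  invisible(x)
}

# Build the per-permutation statistic closure for one method, with the
# genotype-dependent pieces (SVD, pooled counts, weighted scores)
# precomputed once: they are invariant under phenotype permutation.
.statistic_factory <- function(method, G, design, k_rule = "compk",
                               theta = 0.8, lambda = 0, criterion = "AIC",
                               K_max = NULL, eta_grid = seq(0.1, 0.9, 0.1),
                               t_max = 0.05, standardize = FALSE) {
  if (method %in% c("RR", "PCR", "PLS", "SPLS", "LASSO")) {
    X <- design$matrix
    center <- colMeans(X)
    Xc <- sweep(X, 2, center)
    if (standardize) {
      sds <- apply(Xc, 2, stats::sd)
      sds[sds == 0] <- 1
      Xc <- sweep(Xc, 2, sds, "/")
    }
  }
  switch(method,
    RR = {
      sv <- svd(Xc)
      r <- .svd_rank(sv)
      U <- sv$u[, seq_len(r), drop = FALSE]
      shrink <- sv$d[seq_len(r)]^2 / (sv$d[seq_len(r)]^2 + lambda)
      function(y) {
        yc <- y - mean(y)
        fitted <- drop(U %*% (shrink * crossprod(U, yc)))
        if (stats::sd(fitted) == 0) return(0)
        stats::cor(y, fitted)
      }
    },
    PCR = {
      sv <- svd(Xc)
      r <- .svd_rank(sv)
      U <- sv$u[, seq_len(r), drop = FALSE]
      function(y) {
        yc <- y - mean(y)
        uy <- drop(crossprod(U, yc))
        k <- if (k_rule == "one") 1L else {
          ess <- cumsum(uy^2)
          if (ess[r] == 0) 1L else which(ess >= theta * ess[r])[1]
        }
        fitted <- drop(U[, seq_len(k), drop = FALSE] %*% uy[seq_len(k)])
        if (stats::sd(fitted) == 0) return(0)
        stats::cor(y, fitted)
      }
    },
    PLS = {
      r <- .svd_rank(svd(Xc))
      function(y) {
        yc <- y - mean(y)
        core <- .pls_core(Xc, yc, k_max = if (k_rule == "one") 1L else r)
        if (core$k == 0L) return(0)
        k <- if (k_rule == "one") 1L else {
          ess <- cumsum(core$b^2 * colSums(core$Z^2))
          which(ess >= theta * ess[core$k])[1]
        }
        fitted <- drop(core$Z[, seq_len(k), drop = FALSE] %*%
                         core$b[seq_len(k)])
        if (stats::sd(fitted) == 0) return(0)
        stats::cor(y, fitted)
      }
    },
    LASSO = function(y) {
      .fit_lasso(Xc, y - mean(y), criterion = criterion)$statistic
    },
    SPLS = function(y) {
      .fit_spls(Xc, y - mean(y), K_max = K_max, eta_grid = eta_grid,
                criterion = criterion)$statistic
    },
    WE = {
      S <- drop(G$values %*% we_weights(G))
      s_ok <- stats::sd(S) > 0
      function(y) {
        if (!s_ok || stats::sd(y) == 0) return(0)
        abs(stats::cor(y, S))
      }
    },
    VT = {
      C <- vt_pooled_counts(G, t_max)
      if (ncol(C) == 0L) function(y) 0
      else function(y) vt_max_z(C, y)
    },
    SKAT = {
      GW <- sweep(G$values, 2, stats::dbeta(G$maf, 1, 25), "*")
      function(y) sum(drop(crossprod(GW, y - mean(y)))^2)
    },
    stop("unknown method: ", method))
}

#' Run one association test under the permutation null
#'
#' Dispatch over the eight tests (five regularized regressions and the
#' WE/VT/SKAT comparators), assembling the design with or without pooled
#' rare-variant columns, binding the statistic procedure (with all
#' selection steps inside it) and running
#' \code{\link{permutation_pvalue}}. Results carry the conventional label,
#' e.g. \code{"PCR.Comp1.p"} (one component, pooled predictors included),
#' \code{"RR.lambda10"}, \code{"LASSO.BIC"}.
#'
#' @param method one of \code{"RR"}, \code{"PCR"}, \code{"PLS"},
#'   \code{"SPLS"}, \code{"LASSO"}, \code{"WE"}, \code{"VT"},
#'   \code{"SKAT"}.
#' @param G a \code{\link{genotype_matrix}} with no missing entries.
#' @param y numeric phenotype aligned to the rows of \code{G}.
#' @param pooled add pooled rare-variant columns to the regression design
#'   (ignored by WE/VT/SKAT, which define their own pooling).
#' @param B number of permutations; default 1000.
#' @param seed integer master seed.
#' @param k_rule,theta,lambda,criterion,K_max,eta_grid,standardize passed
#'   to the regression engines (see \code{\link{rvfit}}).
#' @param t_max rarity threshold for pooling and VT; default 0.05.
#' @param early_stop,r_max sequential stopping controls, see
#'   \code{\link{permutation_pvalue}}.
#' @return An \code{"rvperm"} object with additional fields
#'   \code{method}, \code{options}, \code{selected_variants} (labels of
#'   design columns selected on the observed data; all columns for
#'   non-sparse methods) and \code{fit} (the observed-data
#'   \code{\link{rvfit}} for regression methods).
#' @export
run_test <- function(method = c("RR", "PCR", "PLS", "SPLS", "LASSO",
                                "WE", "VT", "SKAT"),
                     G, y, pooled = FALSE, B = 1000, seed = NULL,
                     k_rule = c("compk", "one"), theta = 0.8, lambda = 0,
                     criterion = c("AIC", "BIC", "GIC"), K_max = NULL,
                     eta_grid = seq(0.1, 0.9, by = 0.1), t_max = 0.05,
                     standardize = FALSE, early_stop = FALSE, r_max = 50) {
  method <- match.arg(method)
  k_rule <- match.arg(k_rule)
  criterion <- match.arg(criterion)
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$values))
    stop("impute missing genotypes before testing (impute_missing)")
  y <- as.numeric(y)
  if (length(y) != G$n_individuals)
    stop("phenotype length does not match the genotype matrix")

  regression <- method %in% c("RR", "PCR", "PLS", "SPLS", "LASSO")
  design <- if (regression && pooled) build_pooled_variables(G, t_max)
            else if (regression) .as_design(G)
            else NULL

  stat <- .statistic_factory(method, G, design, k_rule = k_rule,
                             theta = theta, lambda = lambda,
                             criterion = criterion, K_max = K_max,
                             eta_grid = eta_grid, t_max = t_max,
                             standardize = standardize)

  label <- switch(method,
    RR = sprintf("RR.lambda%g", lambda),
    PCR = paste0("PCR.", if (k_rule == "one") "Comp1" else "Compk"),
    PLS = paste0("PLS.", if (k_rule == "one") "Comp1" else "Compk"),
    LASSO = paste0("LASSO.", criterion),
    SPLS = paste0("SPLS.", criterion),
    method)
  if (regression && pooled) label <- paste0(label, ".p")

  res <- permutation_pvalue(stat, y, B = B, seed = seed,
                            early_stop = early_stop, r_max = r_max,
                            label = label)
  res$method <- method
  res$options <- list(pooled = regression && pooled, k_rule = k_rule,
                      theta = theta, lambda = lambda, criterion = criterion,
                      K_max = K_max, eta_grid = eta_grid, t_max = t_max,
                      standardize = standardize)
  if (regression) {
    fit <- rvfit(design, y, method = method,
                 k = NULL, k_rule = k_rule, theta = theta, lambda = lambda,
                 criterion = criterion, K_max = K_max, eta_grid = eta_grid,
                 standardize = standardize)
    res$fit <- fit
    res$selected_variants <- names(fit$selected)
  } else {
    res$selected_variants <- G$variant_ids
  }
  res
}

#' Write a permutation result as a JSON record
#'
#' @param result an \code{"rvperm"} object from \code{\link{run_test}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "rvperm"))
  rec <- list(method = result$method,
              label = result$label,
              options = result$options,
              observed = result$observed,
              p_value = result$p_value,
              B = result$B,
              seed = result$seed,
              rng = result$rng,
              selected_variants = as.list(result$selected_variants))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
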