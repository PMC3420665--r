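# Parse a method label like "RR.lambda10", "PCR.Comp1.p", "LASSO.BIC"
# into run_test() arguments. The grammar mirrors the labels run_test()
# emits, so power tables and single tests use the same nomenclature.
.parse_method_label <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  method <- parts[1]
  opts <- list(method = method, pooled = FALSE, k_rule = "compk",
               lambda = 0, criterion = "AIC")
  if (!method %in% c("RR", "PCR", "PLS", "SPLS", "LASSO",
                     "WE", "VT", "SKAT"))
    stop("unknown method in label: ", label)
  for (tok in parts[-1]) {
    if (tok == "p") opts$pooled <- TRUE
    else if (tok == "Comp1") opts$k_rule <- "one"
    else if (tok == "Compk") opts$k_rule <- "compk"
    else if (tok %in% c("AIC", "BIC", "GIC")) opts$criterion <- tok
    else if (grepl("^lambda[0-9.]+$", tok))
      opts$lambda <- as.numeric(sub("^lambda", "", tok))
    else stop("unknown option '", tok, "' in label: ", label)
  }
  opts
}

#' Estimate empirical power (or type-I error) by simulation
#'
#' Simulates \code{S} datasets from a scenario and genotype profile (with
#' a fresh causal-variant draw per dataset), runs each requested test with
#' \code{B} permutations, and reports the fraction of datasets with
#' empirical p-value at or below \code{alpha} together with its binomial
#' Monte-Carlo standard error sqrt(power (1 - power) / S). Under the
#' \code{"null"} scenario the same quantity is the empirical type-I error.
#'
#' Methods are named by label: \code{"RR.lambda0"}, \code{"RR.lambda10"},
#' \code{"PCR.Comp1"}, \code{"PCR.Compk"}, \code{"PLS.Comp1"},
#' \code{"PLS.Compk"}, \code{"LASSO.AIC"} (or BIC/GIC),
#' \code{"SPLS.AIC"} (or BIC/GIC), \code{"WE"}, \code{"VT"},
#' \code{"SKAT"}; append \code{".p"} to a regression label to add pooled
#' rare-variant columns to its design.
#'
#' All per-dataset and per-test seeds derive from the master seed, so a
#' run replays exactly, independent of the order of \code{methods}.
#'
#' @param scenario a \code{\link{scenario_config}} or scenario id string.
#' @param profile a \code{\link{genotype_profile}}.
#' @param methods character vector of method labels.
#' @param S number of simulated datasets.
#' @param B permutations per test.
#' @param alpha significance level; default 0.05.
#' @param seed master seed.
#' @param K_max,eta_grid,theta,t_max tuning controls passed through to
#'   \code{\link{run_test}}.
#' @return An object of class \code{"rvpower"}: a list with \code{table}
#'   (data frame: method, power, mc_se, S, B, alpha), \code{p_values}
#'   (S x methods matrix), \code{selection} (per sparse method the mean
#'   total / causal / pooled columns selected on the observed data) and
#'   the call settings.
#' @export
estimate_power <- function(scenario, profile, methods, S, B,
                           alpha = 0.05, seed = NULL,
                           K_max = NULL, eta_grid = seq(0.1, 0.9, by = 0.1),
                           theta = 0.8, t_max = 0.05) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(profile, "genotype_profile"),
            S >= 1, B >= 1, alpha > 0, alpha < 1)
  parsed <- lapply(methods, .parse_method_label)
  if (!is.null(seed)) set.seed(seed)
  ds_seeds <- sample.int(2^28, S)
  # per-test seeds depend on the dataset seed and the method label (not its
  # position), so results are invariant to the ordering of `methods`
  label_hash <- vapply(methods, function(l)
    sum(utf8ToInt(l) * seq_along(utf8ToInt(l))) %% 8191L, numeric(1))
  pm_seeds <- outer(ds_seeds, label_hash,
                    function(a, b) (a * 8191 + b) %% (2^31 - 1) + 1)

  pvals <- matrix(NA_real_, S, length(methods),
                  dimnames = list(NULL, methods))
  sel_tot <- sel_caus <- sel_pool <- pvals
  for (s in seq_len(S)) {
    dat <- simulate_dataset(profile, scenario, seed = ds_seeds[s])
    for (m in seq_along(methods)) {
      o <- parsed[[m]]
      res <- run_test(o$method, dat$G, dat$y, pooled = o$pooled,
                      B = B, seed = pm_seeds[s, m],
                      k_rule = o$k_rule, theta = theta,
                      lambda = o$lambda, criterion = o$criterion,
                      K_max = K_max, eta_grid = eta_grid, t_max = t_max)
      pvals[s, m] <- res$p_value
      if (o$method %in% c("LASSO", "SPLS")) {
        fit <- res$fit
        sel <- fit$selected
        sel_tot[s, m] <- length(sel)
        sel_pool[s, m] <- sum(fit$origin[sel] == "pooled")
        orig_sel <- sel[fit$origin[sel] == "original"]
        sel_caus[s, m] <- sum(orig_sel %in% dat$causal$index)
      }
    }
  }
  power <- colMeans(pvals <= alpha)
  tab <- data.frame(method = methods,
                    power = unname(power),
                    mc_se = unname(sqrt(power * (1 - power) / S)),
                    S = S, B = B, alpha = alpha,
                    row.names = NULL)
  sparse <- vapply(parsed, function(o)
    o$method %in% c("LASSO", "SPLS"), logical(1))
  selection <- if (any(sparse))
    data.frame(method = methods[sparse],
               mean_selected = colMeans(sel_tot[, sparse, drop = FALSE]),
               mean_causal_selected = colMeans(sel_caus[, sparse, drop = FALSE]),
               mean_pooled_selected = colMeans(sel_pool[, sparse, drop = FALSE]),
               row.names = NULL)
  else NULL
  structure(list(table = tab, p_values = pvals, selection = selection,
                 scenario = scenario$id, seed = seed),
            class = "rvpower")
}

#' @export
print.rvpower <- function(x, ...) {
  cat(sprintf("rvpower: scenario %s, S = %d datasets, B = %d permutations\n",
              x$scenario, x$table$S[1], x$table$B[1]))
  print(x$table, digits = 3)
  if (!is.null(x$selection)) {
    cat("selection summary (sparse methods):\n")
    print(x$selection, digits = 3)
  }
  invisible(x)
}

#' Summarize variable selection against the causal truth
#'
#' For sparse fits (LASSO or SPLS only) reports the mean number of design
#' columns selected, the mean number of truly causal genotype columns
#' among them, and the mean number of pooled columns selected.
#'
#' @param fits list of \code{\link{rvfit}} objects with method LASSO or
#'   SPLS.
#' @param truth list (same length) of integer vectors of causal variant
#'   indices (original-column indices).
#' @return Data frame with one row: \code{mean_selected},
#'   \code{mean_causal_selected}, \code{mean_pooled_selected}.
#' @export
selection_report <- function(fits, truth) {
  stopifnot(length(fits) == length(truth), length(fits) >= 1)
  ok <- vapply(fits, function(f)
    inherits(f, "rvfit") && f$method %in% c("LASSO", "SPLS"), logical(1))
  if (!all(ok))
    stop("selection_report applies to sparse fits (LASSO/SPLS) only")
  stats_one <- function(f, tr) {
    sel <- f$selected
    orig <- sel[f$origin[sel] == "original"]
    c(total = length(sel),
      causal = sum(orig %in% tr),
      pooled = sum(f$origin[sel] == "pooled"))
  }
  m <- t(mapply(stats_one, fits, truth))
  data.frame(mean_selected = mean(m[, "total"]),
             mean_causal_selected = mean(m[, "causal"]),
             mean_pooled_selected = mean(m[, "pooled"]))
}

#' Write an rvpower table as TSV
#'
#' @param x an \code{"rvpower"} object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_power_tsv <- function(x, path) {
  stopifnot(inherits(x, "rvpower"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
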