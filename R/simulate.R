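#' Genotype profile for the synthetic gene generator
#'
#' Describes the marginal structure of a Sanger-sequenced gene region:
#' number of individuals, number of polymorphic variant sites and how many
#' of them are rare (MAF below 1\%). Rare target MAFs are drawn with
#' density proportional to 1/x (a neutral-spectrum-like shape) on
#' \code{rare_maf_range}; common MAFs uniformly on
#' \code{common_maf_range}. \code{ld_rho} > 0 induces AR(1) linkage
#' disequilibrium between adjacent variants through a latent Gaussian
#' copula; the default 0 gives independent variants.
#'
#' @param n_individuals sample size.
#' @param n_variants polymorphic variant count.
#' @param n_rare number of variants with MAF < 0.01.
#' @param rare_maf_range,common_maf_range target-MAF ranges.
#' @param ld_rho AR(1) latent correlation in [0, 1).
#' @return An object of class \code{"genotype_profile"}.
#' @export
genotype_profile <- function(n_individuals, n_variants, n_rare,
                             rare_maf_range = c(1 / (2 * n_individuals), 0.01),
                             common_maf_range = c(0.01, 0.5),
                             ld_rho = 0) {
  stopifnot(n_rare <= n_variants, n_rare >= 0,
            n_individuals >= 2, n_variants >= 1,
            ld_rho >= 0, ld_rho < 1,
            rare_maf_range[1] > 0, rare_maf_range[2] <= 0.5,
            common_maf_range[1] > 0, common_maf_range[2] <= 0.5)
  structure(list(n_individuals = n_individuals,
                 n_variants = n_variants,
                 n_rare = n_rare,
                 rare_maf_range = rare_maf_range,
                 common_maf_range = common_maf_range,
                 ld_rho = ld_rho),
            class = "genotype_profile")
}

#' Preset gene profiles
#'
#' Profiles emulating the marginal structure of three Sanger-sequenced
#' genes in 1998 individuals: gene A with 98 polymorphic sites (85 rare at
#' MAF < 1\%), gene B with 28 (26 rare) and gene C with 122 (99 rare).
#' \code{n} rescales the sample size, keeping the variant counts.
#'
#' @param name \code{"geneA"}, \code{"geneB"} or \code{"geneC"}.
#' @param n sample size; default 1998.
#' @return A \code{\link{genotype_profile}}.
#' @export
gene_profile <- function(name = c("geneA", "geneB", "geneC"), n = 1998) {
  name <- match.arg(name)
  counts <- switch(name,
    geneA = c(98L, 85L),
    geneB = c(28L, 26L),
    geneC = c(122L, 99L))
  genotype_profile(n_individuals = n, n_variants = counts[1],
                   n_rare = counts[2])
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf(
    "genotype_profile: n = %d, %d variants (%d rare MAF < %.3g), ld_rho = %g\n",
    x$n_individuals, x$n_variants, x$n_rare, x$rare_maf_range[2], x$ld_rho))
  invisible(x)
}

# 1/x density on [a, b): inverse-CDF draw a * (b/a)^u
.rmaf_rare <- function(m, range) {
  range[1] * (range[2] / range[1])^stats::runif(m)
}

#' Simulate a genotype matrix from a profile
#'
#' Each variant gets a target MAF from its rarity class and genotypes
#' Binomial(2, MAF) per individual (independent variants), or allele
#' indicators thresholded from a latent AR(1) Gaussian copula when
#' \code{ld_rho > 0}. Columns are redrawn (with a fresh target MAF) until
#' the realized sample MAF is polymorphic and falls in the variant's
#' rarity class, so a \code{gene_profile("geneA")} draw always has exactly
#' 98 polymorphic sites of which 85 have realized MAF below 1\%. Rare and
#' common variants are placed in random column order.
#'
#' @param profile a \code{\link{genotype_profile}}.
#' @param seed optional integer seed.
#' @return A \code{\link{genotype_matrix}}.
#' @export
simulate_genotypes <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "genotype_profile"))
  if (!is.null(seed)) set.seed(seed)
  n <- profile$n_individuals
  p <- profile$n_variants
  is_rare <- sample(rep(c(TRUE, FALSE),
                        c(profile$n_rare, p - profile$n_rare)))
  rho <- profile$ld_rho
  Z <- NULL
  if (rho > 0) {
    # two latent haplotype layers with AR(1) correlation across variants
    Z <- lapply(1:2, function(h) {
      E <- matrix(stats::rnorm(n * p), n, p)
      for (j in 2:p) E[, j] <- rho * E[, j - 1] + sqrt(1 - rho^2) * E[, j]
      E
    })
  }
  draw_col <- function(j) {
    for (attempt in seq_len(1000L)) {
      q <- if (is_rare[j]) .rmaf_rare(1, profile$rare_maf_range)
           else stats::runif(1, profile$common_maf_range[1],
                             profile$common_maf_range[2])
      g <- if (rho > 0 && attempt == 1L) {
        (Z[[1]][, j] < stats::qnorm(q)) + (Z[[2]][, j] < stats::qnorm(q))
      } else {
        stats::rbinom(n, 2, q)
      }
      f <- sum(g) / (2 * n)
      f <- min(f, 1 - f)
      if (f > 0 && (f < 0.01) == is_rare[j]) return(c(q, g))
    }
    stop("could not realize a variant in the requested MAF class")
  }
  draws <- vapply(seq_len(p), draw_col, numeric(n + 1))
  G <- genotype_matrix(draws[-1, , drop = FALSE],
                       variant_ids = paste0("V", seq_len(p)))
  G$target_maf <- draws[1, ]
  G
}

#' Phenotype simulation scenarios
#'
#' Presets for the twelve simulation scenarios (two scenario sets of six)
#' plus a \code{"null"} scenario with no causal variants. In set I the
#' causal effect size is constant across MAF; in set II the per-variant
#' effect is proportional to a weight function of the MAF (default
#' 1/sqrt(q)), with the proportionality constant calibrated so the mean
#' effect over the causal set equals the target. Effects are in phenotype
#' standard deviations (baseline trait is Normal(0, 1)).
#'
#' \tabular{llll}{
#'   id \tab causal threshold \tab causal set \tab mean effect (SD) \cr
#'   I.1/II.1 Large10 \tab MAF < 0.01 \tab 10\% of rare \tab 1.64 \cr
#'   I.2/II.2 Rare/Common \tab MAF < 0.01 \tab 4 rare + 4 common \tab
#'     1.64 (rare), 0.07 (common) \cr
#'   I.3/II.3 Modest10 \tab MAF < 0.01 \tab 10\% of rare \tab 1 \cr
#'   I.4/II.4 Modest20 \tab MAF < 0.01 \tab 20\% of rare \tab 1 \cr
#'   I.5/II.5 Bidirectional \tab MAF < 0.01 \tab 7.5\% deleterious +
#'     7.5\% protective \tab 1.64 \cr
#'   I.6/II.6 VeryRare \tab MAF < 0.001 \tab 20\% of rare \tab 1.64 \cr
#' }
#'
#' @param id scenario id, e.g. \code{"I.1"}, \code{"II.5"}, \code{"null"}.
#' @param weight_fn MAF weight function for set II; default
#'   \code{function(q) 1 / sqrt(q)}.
#' @return An object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(id, weight_fn = function(q) 1 / sqrt(q)) {
  id <- as.character(id)
  if (id == "null")
    return(structure(list(id = "null", causal_maf_threshold = 0.01,
                          direction = "deleterious", causal_fraction = 0,
                          fixed_counts = NULL, effect = 0,
                          common_effect = 0, maf_dependent = FALSE,
                          weight_fn = weight_fn),
                     class = "scenario_config"))
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("I", "II") ||
      !parts[2] %in% as.character(1:6))
    stop("unknown scenario id: ", id,
         " (use I.1..I.6, II.1..II.6 or 'null')")
  num <- as.integer(parts[2])
  cfg <- switch(num,
    list(threshold = 0.01, direction = "deleterious",
         fraction = 0.10, fixed = NULL, effect = 1.64),            # Large10
    list(threshold = 0.01, direction = "deleterious",
         fraction = NULL, fixed = c(rare = 4L, common = 4L),
         effect = 1.64),                                           # Rare/Common
    list(threshold = 0.01, direction = "deleterious",
         fraction = 0.10, fixed = NULL, effect = 1),               # Modest10
    list(threshold = 0.01, direction = "deleterious",
         fraction = 0.20, fixed = NULL, effect = 1),               # Modest20
    list(threshold = 0.01, direction = "bidirectional",
         fraction = 0.15, fixed = NULL, effect = 1.64),            # Bidirect.
    list(threshold = 0.001, direction = "deleterious",
         fraction = 0.20, fixed = NULL, effect = 1.64))            # VeryRare
  structure(list(id = id,
                 causal_maf_threshold = cfg$threshold,
                 direction = cfg$direction,
                 causal_fraction = cfg$fraction,
                 fixed_counts = cfg$fixed,
                 effect = cfg$effect,
                 common_effect = 0.07,
                 maf_dependent = parts[1] == "II",
                 weight_fn = weight_fn),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  set <- if (x$id == "null") "null" else if (x$maf_dependent)
    "effect ~ 1/weight(MAF)" else "constant effect"
  cz <- if (!is.null(x$fixed_counts))
    sprintf("%d rare + %d common", x$fixed_counts["rare"],
            x$fixed_counts["common"])
  else sprintf("%.3g%% of rare", 100 * x$causal_fraction)
  cat(sprintf(
    "scenario %s: causal MAF < %g, %s, %s, mean effect %g SD (%s)\n",
    x$id, x$causal_maf_threshold, x$direction, cz, x$effect, set))
  invisible(x)
}

#' Select causal variants and effect directions for one simulated dataset
#'
#' The causal set is drawn uniformly without replacement from the variants
#' with MAF below the scenario threshold (the Rare/Common scenario
#' additionally samples from the variants with MAF >= 0.01). Percentages
#' convert to counts by round-half-to-even with a minimum of one variant.
#' In the bidirectional scenario the causal count m splits into
#' ceiling(m/2) deleterious and floor(m/2) protective variants.
#'
#' @param maf numeric vector of sample MAFs.
#' @param scenario a \code{\link{scenario_config}}.
#' @return Data frame with columns \code{index}, \code{maf}, \code{sign}
#'   (+1 deleterious, -1 protective) and \code{group} (\code{"rare"} /
#'   \code{"common"}); zero rows for the null scenario.
#' @export
select_causal <- function(maf, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  empty <- data.frame(index = integer(0), maf = numeric(0),
                      sign = numeric(0), group = character(0))
  if (scenario$id == "null") return(empty)
  eligible <- which(maf < scenario$causal_maf_threshold & maf > 0)
  if (length(eligible) == 0L)
    stop("no variant with MAF below the causal threshold ",
         scenario$causal_maf_threshold)
  if (!is.null(scenario$fixed_counts)) {
    common <- which(maf >= 0.01)
    if (length(common) < scenario$fixed_counts["common"])
      stop("fewer than ", scenario$fixed_counts["common"],
           " common variants available")
    if (length(eligible) < scenario$fixed_counts["rare"])
      stop("fewer than ", scenario$fixed_counts["rare"],
           " rare variants available")
    idx_r <- sample(eligible, scenario$fixed_counts["rare"])
    idx_c <- sample(common, scenario$fixed_counts["common"])
    return(data.frame(index = c(idx_r, idx_c),
                      maf = maf[c(idx_r, idx_c)],
                      sign = 1,
                      group = rep(c("rare", "common"),
                                  scenario$fixed_counts)))
  }
  m <- max(1L, round(scenario$causal_fraction * length(eligible)))
  m <- min(m, length(eligible))
  idx <- if (length(eligible) == 1L) eligible else sample(eligible, m)
  sign <- rep(1, m)
  if (scenario$direction == "bidirectional") {
    n_del <- ceiling(m / 2)
    sign <- sample(rep(c(1, -1), c(n_del, m - n_del)))
  }
  data.frame(index = idx, maf = maf[idx], sign = sign, group = "rare")
}

#' Per-variant causal effect magnitudes
#'
#' Scenario set I assigns the target mean effect to every causal variant
#' (common causal variants get the common-variant target). Scenario set II
#' sets delta_j = c * w(q_j) with w the scenario weight function (default
#' 1/sqrt(q)) and c solved, within each group, so that the mean of the
#' delta_j equals the group target — an exact calibration identity.
#'
#' @param causal data frame from \code{\link{select_causal}}.
#' @param scenario a \code{\link{scenario_config}}.
#' @return \code{causal} with a \code{delta} column of signed effects in
#'   phenotype SD units.
#' @export
effect_sizes <- function(causal, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (nrow(causal) == 0L) {
    causal$delta <- numeric(0)
    return(causal)
  }
  target <- ifelse(causal$group == "common", scenario$common_effect,
                   scenario$effect)
  mag <- if (!scenario$maf_dependent) target
  else {
    w <- scenario$weight_fn(causal$maf)
    out <- numeric(nrow(causal))
    for (g in unique(causal$group)) {
      i <- causal$group == g
      out[i] <- target[i][1] * sum(i) * w[i] / sum(w[i])
    }
    out
  }
  causal$delta <- causal$sign * mag
  causal
}

#' Simulate a phenotype given genotypes and causal effects
#'
#' Individuals carrying no causal minor allele draw from Normal(0, 1).
#' Carriers draw from Normal(delta_j*, 1), where j* is the rarest causal
#' variant the individual carries (smallest MAF; signed delta). Carriers
#' of exactly one causal variant therefore use that variant's effect.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param effects data frame from \code{\link{effect_sizes}} (columns
#'   \code{index}, \code{maf}, \code{delta}).
#' @param seed optional integer seed.
#' @return Numeric phenotype vector of length n.
#' @export
simulate_phenotype <- function(G, effects, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- G$n_individuals
  mu <- rep(0, n)
  if (nrow(effects) > 0L) {
    o <- order(effects$maf)             # rarest first
    M <- G$values[, effects$index[o], drop = FALSE] > 0
    delta <- effects$delta[o]
    first <- apply(M, 1, function(r) which(r)[1])
    carrier <- !is.na(first)
    mu[carrier] <- delta[first[carrier]]
  }
  stats::rnorm(n, mean = mu, sd = 1)
}

#' Simulate one full dataset for a scenario
#'
#' Draws genotypes from the profile, selects causal variants and effects
#' for the scenario (a fresh causal draw per dataset) and simulates the
#' phenotype. Everything derives from one seeded RNG stream, so the full
#' dataset replays identically under the same seed.
#'
#' @param profile a \code{\link{genotype_profile}}.
#' @param scenario a \code{\link{scenario_config}}.
#' @param seed optional integer seed.
#' @return List with \code{G} (genotype matrix), \code{y} (phenotype) and
#'   \code{causal} (effects data frame).
#' @export
simulate_dataset <- function(profile, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- simulate_genotypes(profile)
  causal <- effect_sizes(select_causal(G$maf, scenario), scenario)
  y <- simulate_phenotype(G, causal)
  list(G = G, y = y, causal = causal)
}
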