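#' Genotype matrix for one gene or region
#'
#' Container for additive-coded genotypes (counts of the minor allele,
#' 0/1/2, \code{NA} for missing) on \code{n} individuals at \code{p} variant
#' sites, together with per-variant sample minor-allele frequencies (MAF).
#' The constructor validates the coding and orients every column to the
#' minor allele (see \code{\link{compute_maf}}).
#'
#' @param values numeric matrix, \code{n x p}; entries 0, 1, 2 or \code{NA}.
#' @param variant_ids character vector of \code{p} variant labels; defaults
#'   to \code{colnames(values)} or \code{V1..Vp}.
#' @param sample_ids optional character vector of \code{n} individual ids.
#'
#' @return An object of class \code{"genotype_matrix"}: a list with
#'   \code{values} (reoriented matrix), \code{variant_ids}, \code{maf}
#'   (frequencies in \code{[0, 0.5]}) and \code{n_individuals}.
#' @export
genotype_matrix <- function(values, variant_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("need at least 2 individuals")
  if (ncol(values) < 1L)
    stop("need at least 1 variant")
  ok <- values %in% c(0, 1, 2) | is.na(values)
  if (!all(ok))
    stop("genotype entries must be 0, 1, 2 or NA")
  if (is.null(variant_ids)) variant_ids <- colnames(values)
  if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(variant_ids))
    stop("duplicated variant ids: ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "))
  if (length(variant_ids) != ncol(values))
    stop("variant_ids length does not match number of columns")
  colnames(values) <- variant_ids
  if (!is.null(sample_ids)) {
    if (anyDuplicated(sample_ids))
      stop("duplicated sample ids: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
    if (length(sample_ids) != nrow(values))
      stop("sample_ids length does not match number of rows")
    rownames(values) <- sample_ids
  }
  G <- structure(list(values = values,
                      variant_ids = variant_ids,
                      maf = rep(NA_real_, ncol(values)),
                      n_individuals = nrow(values)),
                 class = "genotype_matrix")
  compute_maf(G)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              x$n_individuals, length(x$variant_ids)))
  cat(sprintf("  MAF range [%.4g, %.4g]; %d variants with MAF < 0.01; %d monomorphic\n",
              min(x$maf), max(x$maf), sum(x$maf < 0.01 & x$maf > 0),
              sum(x$maf == 0)))
  nm <- sum(is.na(x$values))
  if (nm > 0) cat(sprintf("  %d missing genotypes\n", nm))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Compute minor-allele frequencies with minor-allele orientation
#'
#' The sample frequency at variant j is
#' (sum of non-missing allele counts) / (2 x number of non-missing
#' genotypes). A frequency above 0.5 means the column is coded on the major
#' allele; the column is then recoded g -> 2 - g and the frequency replaced
#' by its complement, so every stored MAF lies in \code{[0, 0.5]}. The
#' operation is idempotent.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return \code{G} with \code{maf} filled in and columns minor-allele
#'   oriented.
#' @export
compute_maf <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$values
  nobs <- colSums(!is.na(v))
  if (any(nobs == 0L))
    stop("variant(s) with all genotypes missing: ",
         paste(G$variant_ids[nobs == 0L], collapse = ", "))
  f <- colSums(v, na.rm = TRUE) / (2 * nobs)
  flip <- f > 0.5
  if (any(flip)) {
    v[, flip] <- 2 - v[, flip]
    # recompute (not complement) so a second pass reproduces f exactly
    f[flip] <- colSums(v[, flip, drop = FALSE], na.rm = TRUE) /
      (2 * nobs[flip])
  }
  G$values <- v
  G$maf <- unname(f)
  G
}

#' Impute missing genotypes under Hardy-Weinberg equilibrium
#'
#' Each missing entry at a variant with MAF q is drawn independently from
#' the Hardy-Weinberg genotype distribution
#' \{(1-q)^2, 2q(1-q), q^2\} on \{0, 1, 2\}. Observed entries are
#' unchanged. Imputation is done once per dataset, before any analysis or
#' permutation.
#'
#' @param G a \code{\link{genotype_matrix}} (MAFs already computed from the
#'   non-missing entries).
#' @param seed optional integer seed for reproducibility.
#' @return \code{G} without missing entries.
#' @export
impute_missing <- function(G, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  v <- G$values
  for (j in seq_len(ncol(v))) {
    miss <- which(is.na(v[, j]))
    if (length(miss) == 0L) next
    q <- G$maf[j]
    v[miss, j] <- sample(0:2, length(miss), replace = TRUE,
                         prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }
  G$values <- v
  G
}

#' Drop monomorphic variants
#'
#' Removes every variant whose sample MAF is exactly zero; the order of the
#' remaining variants is preserved. A region in which all variants are
#' monomorphic is untestable and raises an error.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return A \code{genotype_matrix} containing only polymorphic variants.
#' @export
filter_monomorphic <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  keep <- G$maf > 0
  if (!any(keep))
    stop("all variants are monomorphic; no testable region")
  G$values <- G$values[, keep, drop = FALSE]
  G$variant_ids <- G$variant_ids[keep]
  G$maf <- G$maf[keep]
  G
}

#' Augment a genotype design with pooled rare-variant counts
#'
#' Builds the variable-threshold pooling lattice: the threshold set is
#' \code{t_max} (default 5\%) together with every observed MAF value below
#' \code{t_max}. For each threshold t the pooled predictor is the
#' per-individual unweighted count of minor alleles over all variants with
#' MAF <= t. Pooled columns that duplicate one another are collapsed to a
#' single column labelled with the largest threshold, and a pooled column
#' identical to a single original genotype column is dropped; both rules
#' avoid exactly collinear predictors. Original genotype columns are always
#' retained.
#'
#' @param G a \code{\link{genotype_matrix}} without missing entries.
#' @param t_max upper rarity threshold in (0, 0.5]; default 0.05.
#' @return An object of class \code{"augmented_design"}: list with
#'   \code{matrix} (n x (p + m) design), \code{pooled_thresholds} (m
#'   frequencies), \code{pooled_members} (list of m integer vectors of
#'   member variant indices) and \code{origin} (per-column
#'   \code{"original"} / \code{"pooled"} tags). With no variant at or below
#'   \code{t_max} the design simply has zero pooled columns.
#' @export
build_pooled_variables <- function(G, t_max = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  stopifnot(t_max > 0, t_max <= 0.5)
  if (anyNA(G$values))
    stop("impute or remove missing genotypes before pooling")
  thresholds <- sort(unique(c(t_max, G$maf[G$maf < t_max & G$maf > 0])),
                     decreasing = TRUE)
  members <- lapply(thresholds, function(t) which(G$maf <= t & G$maf > 0))
  nonempty <- lengths(members) > 0L
  thresholds <- thresholds[nonempty]
  members <- members[nonempty]

  if (length(thresholds)) {
    # collapse duplicate member sets, keeping the largest threshold's label
    key <- vapply(members, paste, character(1), collapse = ",")
    keep <- !duplicated(key)
    thresholds <- thresholds[keep]
    members <- members[keep]
    # a pooled column identical to one original column adds nothing
    single <- vapply(seq_along(members), function(i) {
      ci <- rowSums(G$values[, members[[i]], drop = FALSE])
      any(vapply(seq_len(ncol(G$values)),
                 function(j) all(ci == G$values[, j]), logical(1)))
    }, logical(1))
    thresholds <- thresholds[!single]
    members <- members[!single]
  }

  pooled <- if (length(members))
    vapply(members, function(m) rowSums(G$values[, m, drop = FALSE]),
           numeric(nrow(G$values)))
  else
    matrix(0, nrow(G$values), 0)
  pooled <- as.matrix(pooled)
  if (length(thresholds))
    colnames(pooled) <- sprintf("pooled_t%.6g", thresholds)
  X <- cbind(G$values, pooled)
  structure(list(matrix = X,
                 pooled_thresholds = thresholds,
                 pooled_members = members,
                 origin = c(rep("original", ncol(G$values)),
                            rep("pooled", length(thresholds)))),
            class = "augmented_design")
}

#' @export
print.augmented_design <- function(x, ...) {
  cat(sprintf("augmented_design: %d x %d (%d original + %d pooled columns)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$origin == "original"), sum(x$origin == "pooled")))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read genotypes from a delimited matrix or a VCF file
#'
#' The matrix format is a delimited text file with a header row of variant
#' ids, an `id` first column of individual ids, and entries 0/1/2/NA. VCF
#' files are parsed through the GT field of biallelic records (multiallelic
#' records raise an error unless \code{drop_multiallelic = TRUE}); `./.` is
#' treated as missing.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"matrix"} or
#'   \code{"vcf"}.
#' @param drop_multiallelic drop multiallelic VCF records instead of
#'   raising an error.
#' @return A \code{\link{genotype_matrix}}.
#' @export
load_genotypes <- function(path, format = c("auto", "matrix", "vcf"),
                           drop_multiallelic = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "matrix"
  if (format == "vcf")
    return(.load_vcf(path, drop_multiallelic))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L || tolower(names(tab)[1]) != "id")
    stop("matrix format requires an 'id' first column plus variant columns")
  ids <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  vals <- raw
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(is.na(vals) & !(is.na(raw) | raw %in% c("NA", ""))))
    stop("non-numeric genotype entries in ", path)
  genotype_matrix(vals, variant_ids = colnames(vals), sample_ids = ids)
}

.load_vcf <- function(path, drop_multiallelic) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt)
  if (any(multi)) {
    if (!drop_multiallelic)
      stop("multiallelic records found (set drop_multiallelic = TRUE to skip): ",
           paste(utils::head(vcfR::getID(vcf)[multi]), collapse = ", "))
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- vcfR::getID(vcf)
  if (all(is.na(ids)) || anyDuplicated(stats::na.omit(ids)))
    ids <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))
  genotype_matrix(t(counts), variant_ids = ids, sample_ids = colnames(gt))
}

#' Read a phenotype file
#'
#' Tab-delimited with columns \code{id} and \code{value}; one continuous
#' trait value per individual.
#'
#' @param path file path.
#' @return Named numeric vector (names are individual ids).
#' @export
load_phenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("id", "value") %in% tolower(names(tab))))
    stop("phenotype file needs columns 'id' and 'value'")
  names(tab) <- tolower(names(tab))
  if (anyDuplicated(tab$id))
    stop("duplicated phenotype ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  y <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(y))
    stop("non-numeric phenotype value for id(s): ",
         paste(tab$id[is.na(y)], collapse = ", "))
  names(y) <- tab$id
  y
}

#' Align a phenotype vector with a genotype matrix by individual id
#'
#' @param G a \code{\link{genotype_matrix}} with sample ids.
#' @param y named phenotype vector from \code{\link{load_phenotype}}.
#' @return \code{y} reordered to the rows of \code{G}.
#' @export
align_phenotype <- function(G, y) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- rownames(G$values)
  if (is.null(ids))
    stop("genotype matrix has no sample ids to align on")
  missing_ids <- setdiff(names(y), ids)
  absent_ids <- setdiff(ids, names(y))
  if (length(missing_ids) || length(absent_ids))
    stop("id mismatch between phenotype and genotypes; ",
         if (length(missing_ids))
           paste0("phenotype ids not in genotypes: ",
                  paste(missing_ids, collapse = ", "), "; ") else "",
         if (length(absent_ids))
           paste0("genotype ids without phenotype: ",
                  paste(absent_ids, collapse = ", ")) else "")
  y[ids]
}

#' Write a genotype matrix in the delimited matrix format
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @export
write_genotype_matrix <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- rownames(G$values)
  if (is.null(ids)) ids <- paste0("ind", seq_len(G$n_individuals))
  tab <- data.frame(id = ids, G$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype vector in the two-column phenotype format
#'
#' @param y named numeric vector.
#' @param path output file path.
#' @export
write_phenotype <- function(y, path) {
  ids <- names(y)
  if (is.null(ids)) ids <- paste0("ind", seq_along(y))
  utils::write.table(data.frame(id = ids, value = unname(y)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
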