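# Whole-proteome analysis chain: consistency filtering -> optional
# normalization -> left-censored imputation -> PCA / clustering -> Welch-test
# differential abundance with BH correction and volcano classification.

#' Proteomics workflow configuration
#'
#' Defaults follow common practice for label-free data: keep proteins seen in
#' at least two thirds of the samples of at least one group, no normalization
#' (search engines typically emit MaxLFQ-normalized intensities already),
#' QRILC-style left-censored imputation, log2 fold-change cutoffs of -1 and 1,
#' and a Benjamini-Hochberg adjusted-p threshold of 0.01.
#'
#' `vsn` and random-forest imputation are recognised names but deliberately
#' not implemented; requesting them raises a clear error rather than silently
#' substituting another method.
#'
#' @param min_group_fraction Consistency threshold in (0, 1\].
#' @param normalization `"none"`, `"median"` or `"quantile"`.
#' @param imputation `"qrilc"`, `"min_downshift"` or `"group_mean"`.
#' @param fc_cutoffs Length-2 numeric, lower and upper log2 fold-change cutoff.
#' @param alpha Adjusted-p threshold in (0, 1).
#' @param seed Integer seed for stochastic steps (imputation).
#' @return List of class `proteomics_config`.
#' @export
proteomics_config <- function(min_group_fraction = 2 / 3,
                              normalization = "none",
                              imputation = "qrilc",
                              fc_cutoffs = c(-1, 1),
                              alpha = 0.01,
                              seed = 42L) {
  if (normalization %in% c("vsn")) {
    stop("normalization method 'vsn' is not implemented; use 'none', 'median' or 'quantile'")
  }
  normalization <- match.arg(normalization, c("none", "median", "quantile"))
  if (imputation %in% c("rf", "random_forest")) {
    stop("imputation method '", imputation,
         "' is not implemented; use 'qrilc', 'min_downshift' or 'group_mean'")
  }
  imputation <- match.arg(imputation, c("qrilc", "min_downshift", "group_mean"))
  stopifnot(min_group_fraction > 0, min_group_fraction <= 1,
            length(fc_cutoffs) == 2L, fc_cutoffs[1L] < fc_cutoffs[2L],
            alpha > 0, alpha < 1)
  structure(list(min_group_fraction = min_group_fraction,
                 normalization = normalization, imputation = imputation,
                 log_base = 2, fc_cutoffs = as.numeric(fc_cutoffs),
                 alpha = alpha, seed = as.integer(seed)),
            class = "proteomics_config")
}

group_columns <- function(samples) split(samples$sample_id, samples$sample_group)

#' Filter proteins by identification consistency
#'
#' A protein is retained iff there is at least one sample group in which it
#' was observed in at least `min_group_fraction` of that group's samples
#' (threshold `ceil(fraction * group size)`; with the default two-thirds rule
#' 2 of 3 passes and 1 of 3 fails).
#'
#' @param am An [abundance_matrix()].
#' @param samples Sample table covering the matrix columns.
#' @param min_group_fraction Fraction in (0, 1\].
#' @return List with `matrix` (retained rows) and `dropped_ids`.
#' @export
filter_by_consistency <- function(am, samples, min_group_fraction = 2 / 3) {
  stopifnot(min_group_fraction > 0, min_group_fraction <= 1)
  v <- am_values(am)
  groups <- group_columns(samples)
  keep <- rep(FALSE, nrow(v))
  for (ids in groups) {
    ids <- intersect(ids, colnames(v))
    if (!length(ids)) next
    need <- ceiling(min_group_fraction * length(ids) - 1e-9)
    keep <- keep | rowSums(!is.na(v[, ids, drop = FALSE])) >= need
  }
  list(matrix = am_replace(am, v[keep, , drop = FALSE]),
       dropped_ids = rownames(v)[!keep])
}

#' Median normalization
#'
#' Rescales each sample's observed values so that every sample median equals
#' the global median of all observed values. Missing cells are untouched.
#'
#' @inheritParams filter_by_consistency
#' @return Normalized `abundance_matrix`.
#' @export
normalize_median <- function(am) {
  v <- am_values(am)
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  if (any(is.na(med))) {
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[is.na(med)], collapse = ", "))
  }
  global <- stats::median(v[!is.na(v)])
  am_replace(am, sweep(v, 2L, global / med, "*"))
}

#' Quantile normalization
#'
#' Classic quantile normalization of the observed values: within each sample,
#' values are replaced by the mean across samples of the values at the same
#' rank; ties receive the mean of their rank-values and samples with unequal
#' observed counts use interpolated reference quantiles (as implemented by
#' \pkg{limma}). Missing cells are untouched.
#'
#' @inheritParams filter_by_consistency
#' @return Normalized `abundance_matrix`.
#' @export
normalize_quantile <- function(am) {
  v <- am_values(am)
  nobs <- colSums(!is.na(v))
  if (any(nobs == 0L)) {
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[nobs == 0L], collapse = ", "))
  }
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  am_replace(am, out)
}

# -- imputation ---------------------------------------------------------------

check_imputable <- function(v) {
  nobs <- colSums(!is.na(v))
  if (any(nobs < 4L)) {
    stop("sample(s) with fewer than 4 observed values: ",
         paste(colnames(v)[nobs < 4L], collapse = ", "),
         "; apply stronger consistency filtering before imputation")
  }
}

#' QRILC-style left-censored imputation
#'
#' Assumes the missing values of a sample are the low tail of a normal
#' distribution of log2 intensities. Per sample with missing fraction `m`,
#' the sorted observed log2 values are regressed on standard-normal quantiles
#' at plotting positions `m + (1 - m) * (i - 0.5) / n_obs` using the lower
#' half of the observed points; the intercept and slope estimate the mean and
#' standard deviation of the uncensored distribution, and each missing cell
#' is drawn from that normal truncated above at its `m`-quantile. The draw is
#' deterministic given `seed`.
#'
#' Input on the linear scale is log2-transformed first; the result is always
#' on the log2 scale.
#'
#' @inheritParams filter_by_consistency
#' @param seed Integer seed.
#' @return List with `matrix` (log2-scale, complete for every cell that could
#'   be imputed) and `mask` (logical matrix marking imputed cells).
#' @export
impute_qrilc <- function(am, seed = 42L) {
  am <- am_log2(am)
  v <- am_values(am)
  mask <- is.na(v)
  if (!any(mask)) return(list(matrix = am, mask = mask))
  check_imputable(v)
  withr::with_seed(as.integer(seed), {
    for (s in colnames(v)) {
      x <- v[, s]
      miss <- which(is.na(x))
      if (!length(miss)) next
      obs <- sort(x[!is.na(x)])
      n_obs <- length(obs)
      m <- length(miss) / length(x)
      p <- m + (1 - m) * (seq_len(n_obs) - 0.5) / n_obs
      z <- stats::qnorm(p)
      lower <- seq_len(max(2L, ceiling(n_obs / 2)))
      fit <- stats::lm.fit(cbind(1, z[lower]), obs[lower])
      mu <- fit$coefficients[1L]
      sigma <- max(fit$coefficients[2L], 1e-6)
      u <- stats::runif(length(miss), min = 0, max = m)
      v[miss, s] <- mu + sigma * stats::qnorm(u)
    }
  })
  list(matrix = am_replace(am, v), mask = mask)
}

#' Downshifted-normal imputation
#'
#' Draws each missing cell from `Normal(mean - shift * sd, width * sd)` of the
#' sample's observed log2 values (the "Perseus-style" left-shifted normal).
#'
#' @inheritParams impute_qrilc
#' @param shift Downshift in sample standard deviations.
#' @param width Width of the imputation distribution in sample sds;
#'   `width = 0` gives a deterministic constant fill.
#' @return As [impute_qrilc()].
#' @export
impute_min_downshift <- function(am, shift = 1.8, width = 0.3, seed = 42L) {
  am <- am_log2(am)
  v <- am_values(am)
  mask <- is.na(v)
  if (!any(mask)) return(list(matrix = am, mask = mask))
  check_imputable(v)
  withr::with_seed(as.integer(seed), {
    for (s in colnames(v)) {
      miss <- which(is.na(v[, s]))
      if (!length(miss)) next
      obs <- v[!is.na(v[, s]), s]
      v[miss, s] <- stats::rnorm(length(miss),
                                 mean = mean(obs) - shift * stats::sd(obs),
                                 sd = width * stats::sd(obs))
    }
  })
  list(matrix = am_replace(am, v), mask = mask)
}

#' Group-mean imputation
#'
#' Fills each missing cell with the mean of the observed log2 values of the
#' same protein within the sample's group. Cells in groups with no observed
#' value stay missing and the protein is flagged.
#'
#' @inheritParams filter_by_consistency
#' @return List with `matrix`, `mask`, and `unimputable` (protein ids with at
#'   least one cell left missing).
#' @export
impute_group_mean <- function(am, samples) {
  am <- am_log2(am)
  v <- am_values(am)
  mask <- is.na(v)
  for (ids in group_columns(samples)) {
    ids <- intersect(ids, colnames(v))
    if (!length(ids)) next
    sub <- v[, ids, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    for (s in ids) {
      miss <- is.na(v[, s]) & !is.nan(mu)
      v[miss, s] <- mu[miss]
    }
  }
  unimputable <- rownames(v)[rowSums(is.na(v)) > 0L]
  list(matrix = am_replace(am, v), mask = mask, unimputable = unimputable)
}

# -- multivariate overviews ---------------------------------------------------

#' Principal component analysis of samples
#'
#' Samples are observations and proteins variables; variables are
#' mean-centered but not scaled, and scores come from the singular-value
#' decomposition. Requires a complete (imputed) matrix.
#'
#' @inheritParams filter_by_consistency
#' @return Object of class `protflow_pca` with `scores` (tibble, one row per
#'   sample) and `var_explained` (fractions, nonincreasing, summing to 1 over
#'   the retained components).
#' @export
pca_samples <- function(am) {
  v <- am_values(am)
  if (anyNA(v)) stop("matrix has missing values; impute before PCA")
  if (ncol(v) < 2L) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  scores <- tibble::as_tibble(p$x, rownames = "sample_id")
  structure(list(scores = scores, var_explained = ve, prcomp = p),
            class = "protflow_pca")
}

#' @export
print.protflow_pca <- function(x, ...) {
  cat(sprintf("<protflow_pca> %d samples; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), 100 * x$var_explained[1L],
              100 * x$var_explained[min(2L, length(x$var_explained))]))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Average-linkage agglomeration on the distance `1 - Pearson correlation`
#' between samples. A zero-variance sample would make the correlation
#' undefined; such pairs get correlation 0 with a warning.
#'
#' @inheritParams filter_by_consistency
#' @return Object of class `protflow_hclust` with the `stats::hclust` fit,
#'   a `merges` tibble (merge indices and heights) and the distance used.
#' @export
cluster_samples <- function(am) {
  v <- am_values(am)
  if (anyNA(v)) stop("matrix has missing values; impute before clustering")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant sample(s): ", paste(colnames(v)[sds == 0], collapse = ", "),
            "; their correlations are set to 0")
  }
  cc <- suppressWarnings(stats::cor(v))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  structure(list(
    hclust = hc,
    merges = tibble::tibble(step = seq_len(nrow(hc$merge)),
                            left = hc$merge[, 1L], right = hc$merge[, 2L],
                            height = hc$height),
    distance = "1 - Pearson correlation", linkage = "average"
  ), class = "protflow_hclust")
}

#' @export
print.protflow_hclust <- function(x, ...) {
  cat(sprintf("<protflow_hclust> %d samples, %s linkage on %s\n",
              length(x$hclust$labels), x$linkage, x$distance))
  invisible(x)
}

#' Export a sample dendrogram as Newick
#' @param clustering A [cluster_samples()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

# -- differential abundance ---------------------------------------------------

#' Read a comparison file
#'
#' Delimited text with columns `test_group` and `control_group`, one row per
#' comparison.
#' @param path File path.
#' @return Tibble with `test_group`, `control_group`.
#' @export
read_comparisons <- function(path) {
  tab <- read_delim_chr(path)
  i_test <- match_col(names(tab), c("test_group", "test", "group"))
  i_ctrl <- match_col(names(tab), c("control_group", "control"))
  if (is.na(i_test) || is.na(i_ctrl)) {
    stop("comparison file needs test_group and control_group columns")
  }
  tibble::tibble(test_group = as.character(tab[[i_test]]),
                 control_group = as.character(tab[[i_ctrl]]))
}

#' Differential abundance between sample groups
#'
#' Per protein and comparison: log2 fold change as the difference of group
#' means of log2 values, raw p from Welch's unequal-variance two-sample test,
#' and Benjamini-Hochberg adjustment within each comparison. Zero-variance
#' groups receive a variance floor of `1e-9` so the statistic stays defined;
#' affected proteins are flagged in `var_floored`.
#'
#' @param am A complete (imputed) [abundance_matrix()]; linear-scale input is
#'   log2-transformed first.
#' @param samples Sample table covering the matrix columns.
#' @param comparisons Tibble with `test_group`, `control_group` (or a list of
#'   2-vectors `c(test, control)`).
#' @param var_floor Variance floor for degenerate groups.
#' @return Tibble of class `protflow_da` with `comparison`, `protein_id`,
#'   `log2fc`, `p_raw`, `p_adj`, `n_test`, `n_control`, `var_floored`.
#' @export
differential_abundance <- function(am, samples, comparisons, var_floor = 1e-9) {
  am <- am_log2(am)
  v <- am_values(am)
  if (anyNA(v)) stop("matrix has missing values; impute before testing")
  if (is.list(comparisons) && !is.data.frame(comparisons)) {
    comparisons <- tibble::tibble(
      test_group = vapply(comparisons, `[[`, character(1L), 1L),
      control_group = vapply(comparisons, `[[`, character(1L), 2L)
    )
  }
  groups <- group_columns(samples)
  res <- purrr::pmap_dfr(comparisons, function(test_group, control_group, ...) {
    for (g in c(test_group, control_group)) {
      if (!g %in% names(groups)) stop("unknown group name: '", g, "'")
      if (length(intersect(groups[[g]], colnames(v))) < 2L) {
        stop("group '", g, "' has fewer than 2 samples")
      }
    }
    a <- v[, intersect(groups[[test_group]], colnames(v)), drop = FALSE]
    b <- v[, intersect(groups[[control_group]], colnames(v)), drop = FALSE]
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
    floored <- v1 < var_floor | v2 < var_floor
    v1 <- pmax(v1, var_floor); v2 <- pmax(v2, var_floor)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    tibble::tibble(
      comparison = paste(test_group, "vs", control_group),
      test_group = test_group, control_group = control_group,
      protein_id = rownames(v),
      log2fc = unname(m1 - m2), p_raw = unname(p),
      p_adj = unname(stats::p.adjust(p, method = "BH")),
      n_test = n1, n_control = n2, var_floored = unname(floored)
    )
  })
  class(res) <- c("protflow_da", class(res))
  res
}

#' Classify differential results for a volcano plot
#'
#' `up` iff `log2fc >= fc_cutoffs[2]` and `p_adj <= alpha`; `down` iff
#' `log2fc <= fc_cutoffs[1]` and `p_adj <= alpha` (both boundaries
#' inclusive); otherwise `not_significant`.
#'
#' @param results A [differential_abundance()] tibble.
#' @param fc_cutoffs Length-2 numeric log2 fold-change cutoffs.
#' @param alpha Adjusted-p threshold.
#' @return `results` with a `volcano_class` factor column; class counts are
#'   attached as attribute `class_counts`.
#' @export
classify_volcano <- function(results, fc_cutoffs = c(-1, 1), alpha = 0.01) {
  stopifnot(length(fc_cutoffs) == 2L, fc_cutoffs[1L] < fc_cutoffs[2L])
  cls <- dplyr::case_when(
    results$p_adj <= alpha & results$log2fc >= fc_cutoffs[2L] ~ "up",
    results$p_adj <= alpha & results$log2fc <= fc_cutoffs[1L] ~ "down",
    TRUE ~ "not_significant"
  )
  results$volcano_class <- factor(cls, levels = c("down", "not_significant", "up"))
  attr(results, "class_counts") <- as.list(table(results$volcano_class))
  if (!inherits(results, "protflow_da")) class(results) <- c("protflow_da", class(results))
  results
}
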