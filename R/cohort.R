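# Cohort-level analytics: projection of tumor spectra onto exposure
# signatures, PCA, age regression, cohort contrasts, SV class proportions,
# and region-restricted spectra.

#' Exposure spectrum from treated replicates
#'
#' The exposure profile is the mean of the replicate catalogs' frequency
#' vectors (each replicate weighted equally); `method = "pooled"` instead
#' sums counts before normalizing, which weights replicates by burden.
#'
#' @param catalogs list of [mutation_catalog] (the treated replicates).
#' @param name profile name (e.g. `"BPA"`, `"SO"`).
#' @param method `"mean"` (default) or `"pooled"`.
#' @return object of class `exposure_profile` with `name` and `spectrum`
#'   (frequency vector summing to 1).
#' @export
exposure_profile <- function(catalogs, name, method = c("mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(catalogs) > 0)
  scheme <- catalogs[[1]]$scheme
  if (method == "mean") {
    fmat <- vapply(catalogs, catalog_frequency, numeric(scheme$size))
    spectrum <- rowMeans(fmat)
  } else {
    total <- Reduce(`+`, lapply(catalogs, `[[`, "counts"))
    spectrum <- total / sum(total)
  }
  structure(list(name = name, scheme = scheme, spectrum = spectrum),
            class = "exposure_profile")
}

#' Cosine similarity of each sample's spectrum to an exposure profile
#'
#' Empty catalogs are skipped with a warning and listed in the `skipped`
#' attribute. When sample metadata is supplied, per-cohort summaries
#' (median and quartiles) are attached for boxplot-style reporting.
#'
#' @param catalogs named list of [mutation_catalog].
#' @param profile an [exposure_profile] on the same scheme.
#' @param meta optional data.frame with columns `sample_id`, `cohort` and
#'   optionally `age`.
#' @return data.frame with `sample_id`, `similarity` (and `cohort`, `age`
#'   when `meta` given); attributes `skipped` and, with metadata,
#'   `cohort_summary`.
#' @export
similarity_to_exposure <- function(catalogs, profile, meta = NULL) {
  stopifnot(inherits(profile, "exposure_profile"))
  skipped <- character(0)
  rows <- list()
  for (ct in catalogs) {
    if (ct$n_total == 0) {
      warning("similarity_to_exposure: skipping empty catalog for sample ",
              ct$sample_id)
      skipped <- c(skipped, ct$sample_id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = ct$sample_id,
      similarity = cosine_similarity(catalog_frequency(ct),
                                     profile$spectrum),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), similarity = numeric(0))
  if (!is.null(meta)) {
    out <- merge(out, meta, by = "sample_id", all.x = TRUE, sort = FALSE)
    summ <- do.call(rbind, lapply(split(out, out$cohort), function(g) {
      q <- stats::quantile(g$similarity, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(cohort = g$cohort[1], n = nrow(g), q1 = q[1],
                 median = q[2], q3 = q[3], stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    attr(out, "cohort_summary") <- summ
  }
  attr(out, "skipped") <- skipped
  out
}

#' PCA of sample spectra
#'
#' Centered (not scaled) principal component analysis of a samples-by-
#' categories frequency matrix; the 96 trinucleotide frequencies share
#' units, so correlation-mode scaling is not applied. The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param freq_matrix numeric matrix, samples in rows, categories in
#'   columns; at least 3 rows.
#' @return list with `scores`, `loadings`, `explained` (variance fractions
#'   summing to 1).
#' @export
pca_spectra <- function(freq_matrix) {
  freq_matrix <- as.matrix(freq_matrix)
  if (nrow(freq_matrix) < 3) {
    stop("pca_spectra: need at least 3 samples")
  }
  centered <- scale(freq_matrix, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    stop("pca_spectra: all samples are identical (zero total variance)")
  }
  p <- stats::prcomp(freq_matrix, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2))
}

#' Regression of exposure similarity on patient age
#'
#' Ordinary least squares of per-sample cosine similarity on age within one
#' cohort, with a two-sided t-test on the slope.
#'
#' @param scores data.frame with `sample_id` and `similarity` (as from
#'   [similarity_to_exposure]).
#' @param meta data.frame with `sample_id`, `cohort`, `age`.
#' @param cohort cohort label to analyze.
#' @return list with `slope`, `intercept`, `p_value` (two-sided, on the
#'   slope), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
age_regression <- function(scores, meta, cohort) {
  df <- if (all(c("cohort", "age") %in% names(scores))) scores else
    merge(scores, meta, by = "sample_id")
  df <- df[df$cohort == cohort & !is.na(df$age), , drop = FALSE]
  if (nrow(df) < 3) {
    stop("age_regression: fewer than 3 aged samples in cohort ", cohort)
  }
  if (stats::sd(df$age) == 0) {
    stop("age_regression: age is constant in cohort ", cohort)
  }
  fit <- stats::lm(similarity ~ age, data = df)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = s$coefficients["age", "Pr(>|t|)"],
       r_squared = s$r.squared,
       n = nrow(df), fit = fit)
}

# exact two-sided Mann-Whitney p by enumeration of all C(m+n, m) group
# assignments of the pooled values (ties handled naturally)
mw_exact <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n_tot <- length(pooled)
  u_stat <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(vapply(xx, function(v) sum(v > yy) + 0.5 * sum(v == yy), numeric(1)))
  }
  u_obs <- u_stat(seq_len(m))
  mu <- m * (n_tot - m) / 2
  combos <- utils::combn(n_tot, m)
  u_all <- apply(combos, 2, u_stat)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U comparison of two cohorts
#'
#' Two-sided test that one cohort's similarity scores are stochastically
#' larger. Exact p-values are computed by exhaustive enumeration of group
#' assignments when `m + n <= exact_limit` (default 12); larger samples use
#' the normal approximation with tie correction.
#'
#' @param scores_a,scores_b numeric score vectors (each length >= 2).
#' @param exact_limit switch point between exact and approximate p.
#' @return list with `U` (statistic for the first group), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
compare_cohorts <- function(scores_a, scores_b, exact_limit = 12) {
  m <- length(scores_a)
  n <- length(scores_b)
  if (m < 2 || n < 2) {
    stop("compare_cohorts: each group needs at least 2 samples")
  }
  u <- sum(vapply(scores_a, function(v) {
    sum(v > scores_b) + 0.5 * sum(v == scores_b)
  }, numeric(1)))
  if (m + n <= exact_limit) {
    return(list(U = u, p_value = mw_exact(scores_a, scores_b),
                method = "exact"))
  }
  # normal approximation with tie correction
  pooled <- c(scores_a, scores_b)
  nt <- table(pooled)
  tie_term <- sum(nt^3 - nt) / ((m + n) * (m + n - 1))
  mu <- m * n / 2
  sigma <- sqrt(m * n / 12 * (m + n + 1 - tie_term))
  if (sigma == 0) {
    return(list(U = u, p_value = 1, method = "normal"))
  }
  z <- (u - mu) / sigma
  list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Per-cohort structural-variant class proportions
#'
#' @param sv data.frame as from [read_sv_table], with a `cohort` column (or
#'   `sample_id` used as cohort when absent).
#' @return data.frame with `cohort`, `class`, `count`, `proportion`
#'   (summing to 1 within each cohort); cohorts with no SVs are omitted.
#' @export
sv_class_proportions <- function(sv) {
  if (!"cohort" %in% names(sv)) sv$cohort <- sv$sample_id
  if (nrow(sv) == 0) {
    warning("sv_class_proportions: no SV records")
    return(data.frame(cohort = character(0), class = character(0),
                      count = numeric(0), proportion = numeric(0)))
  }
  rows <- lapply(split(sv, sv$cohort), function(g) {
    counts <- table(factor(g$class, levels = SV_CLASSES))
    data.frame(cohort = g$cohort[1], class = SV_CLASSES,
               count = as.numeric(counts),
               proportion = as.numeric(counts) / nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spectrum of mutations restricted to a region set
#'
#' Builds the SBS96 catalog of records falling inside `regions` (e.g. cancer
#' gene footprints) and reports, for the subset and genome-wide, the
#' fraction of mutations in each of the six substitution classes and in any
#' named single categories.
#'
#' @param records `mutation_records` for one sample/cohort.
#' @param regions a [labeled_intervals] region set (non-empty).
#' @param genome reference genome as in [build_catalog].
#' @param categories optional SBS96 labels to report individually (e.g.
#'   `"G[T>G]G"`).
#' @return list with `catalog` (in-region catalog; `empty` flag attribute),
#'   `class_fractions` (data.frame: class, in-region and genome-wide
#'   fraction), `category_fractions` (same for requested single
#'   categories).
#' @export
region_subset_spectrum <- function(records, regions, genome,
                                   categories = character(0)) {
  stopifnot(inherits(regions, "labeled_intervals"))
  if (length(regions$gr) == 0) {
    stop("region_subset_spectrum: empty region set")
  }
  inside <- suppressWarnings(
    IRanges::overlapsAny(records_granges(records), regions$gr,
                         ignore.strand = TRUE))
  sub <- records[inside, , drop = FALSE]
  class(sub) <- c("mutation_records", "data.frame")
  ct_sub <- build_catalog(sub, genome, "SBS96")
  ct_all <- build_catalog(records, genome, "SBS96")
  attr(ct_sub, "empty") <- ct_sub$n_total == 0

  class_of <- sub("^.\\[(.>.)\\].$", "\\1", names(ct_all$counts))
  frac_by_class <- function(ct) {
    if (ct$n_total == 0) return(stats::setNames(rep(NA_real_, 6), SBS_CLASSES))
    tapply(ct$counts, class_of, sum)[SBS_CLASSES] / ct$n_total
  }
  class_fractions <- data.frame(
    class = SBS_CLASSES,
    in_region = as.numeric(frac_by_class(ct_sub)),
    genome_wide = as.numeric(frac_by_class(ct_all)),
    stringsAsFactors = FALSE
  )
  category_fractions <- NULL
  if (length(categories)) {
    bad <- setdiff(categories, ct_all$scheme$labels)
    if (length(bad)) {
      stop("region_subset_spectrum: unknown categories: ",
           paste(bad, collapse = ", "))
    }
    category_fractions <- data.frame(
      category = categories,
      in_region = if (ct_sub$n_total > 0)
        as.numeric(ct_sub$counts[categories] / ct_sub$n_total)
      else NA_real_,
      genome_wide = as.numeric(ct_all$counts[categories] / ct_all$n_total),
      stringsAsFactors = FALSE
    )
  }
  list(catalog = ct_sub, class_fractions = class_fractions,
       category_fractions = category_fractions)
}
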