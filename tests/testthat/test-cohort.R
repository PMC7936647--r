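sigs5c <- synthetic_signatures()
labs96c <- category_scheme("SBS96")$labels

mk_catalog <- function(counts, id) {
  mutation_catalog(id, "SBS96", stats::setNames(counts, labs96c))
}

test_that("similarity to an exposure profile is 1 for proportional spectra", {
  prof <- exposure_profile(list(mk_catalog(
    round(sigs5c$profiles[, 3] * 1e5), "r1")), "EXPO")
  ct <- mk_catalog(round(sigs5c$profiles[, 3] * 1e5) * 3, "s1")
  out <- similarity_to_exposure(list(ct), prof)
  expect_equal(out$similarity, 1, tolerance = 1e-9)
})

test_that("similarity is invariant to scaling and consistent category permutation", {
  set.seed(2)
  counts <- stats::rmultinom(1, 3000, sigs5c$profiles %*% rep(0.2, 5))[, 1]
  a <- counts / sum(counts)
  b <- as.numeric(sigs5c$profiles[, 2])
  perm <- sample(96)
  expect_equal(cosine_similarity(a, b), cosine_similarity(7 * a, b))
  expect_equal(cosine_similarity(a, b), cosine_similarity(a[perm], b[perm]))
})

test_that("3-sample micro-example matches hand-computed cosines", {
  # 4-category toy vectors embedded in SBS96 (zeros elsewhere)
  embed <- function(v, id) {
    counts <- rep(0, 96)
    counts[1:4] <- v
    mk_catalog(counts, id)
  }
  prof_ct <- embed(c(1, 1, 0, 0), "p")
  prof <- exposure_profile(list(prof_ct), "toy")
  cts <- list(embed(c(1, 1, 0, 0), "s1"), embed(c(1, 0, 1, 0), "s2"),
              embed(c(0, 0, 1, 1), "s3"))
  out <- similarity_to_exposure(cts, prof)
  expect_equal(out$similarity, c(1, 0.5, 0), tolerance = 1e-12)
})

test_that("empty catalogs are skipped with a warning and listed", {
  prof <- exposure_profile(list(mk_catalog(rep(1, 96), "r")), "E")
  cts <- list(mk_catalog(rep(0, 96), "empty1"), mk_catalog(rep(1, 96), "ok"))
  expect_warning(out <- similarity_to_exposure(cts, prof), "empty1")
  expect_equal(attr(out, "skipped"), "empty1")
  expect_equal(out$sample_id, "ok")
})

test_that("exposure profile is the mean of replicate frequencies by default", {
  c1 <- mk_catalog(c(rep(10, 48), rep(0, 48)), "r1")   # n = 480
  c2 <- mk_catalog(c(rep(0, 48), rep(30, 48)), "r2")   # n = 1440
  mean_prof <- exposure_profile(list(c1, c2), "E")$spectrum
  pool_prof <- exposure_profile(list(c1, c2), "E", method = "pooled")$spectrum
  expect_equal(unname(mean_prof[1]), 0.5 * (10 / 480))
  expect_equal(sum(mean_prof), 1)
  expect_equal(unname(pool_prof[1]), 10 / 1920)
})

test_that("PCA is centered, lossless, and errors on degenerate input", {
  x <- matrix(c(1, 2, 3, 4, 2, 1, 0, 7, 5, 5, 5, 5), nrow = 4)
  p <- pca_spectra(x)
  centered <- scale(x, center = TRUE, scale = FALSE)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, centered, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(p$explained), 1)
  # translation invariance of scores
  p2 <- pca_spectra(x + matrix(5, 4, 3))
  expect_equal(p$scores, p2$scores, tolerance = 1e-10)
  dup <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  expect_error(pca_spectra(dup), "identical")
  expect_error(pca_spectra(x[1:2, ]), "at least 3")
})

test_that("PC1 separates high- and zero-admixture clusters", {
  set.seed(71)
  mk <- function(adm, id) {
    w <- (1 - adm) * c(0.6, 0.4, 0, 0, 0) + adm * c(0, 0, 1, 0, 0)
    mk_catalog(stats::rmultinom(1, 800, sigs5c$profiles %*% w)[, 1], id)
  }
  cts <- c(lapply(1:10, function(i) mk(0.6, paste0("hi", i))),
           lapply(1:10, function(i) mk(0, paste0("lo", i))))
  fm <- t(vapply(cts, catalog_frequency, numeric(96)))
  p <- pca_spectra(fm)
  pc1 <- p$scores[, 1]
  lab <- rep(c("hi", "lo"), each = 10)
  # silhouette of the two groups on PC1 must be positive
  sil <- vapply(seq_along(pc1), function(i) {
    a <- mean(abs(pc1[i] - pc1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    a <- mean(abs(pc1[i] - setdiff(pc1[lab == lab[i]], pc1[i])))
    b <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_true(all(range(pc1[lab == "hi"]) < min(pc1[lab == "lo"])) ||
                all(range(pc1[lab == "hi"]) > max(pc1[lab == "lo"])))
})

test_that("age regression recovers noiseless linear similarity exactly", {
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     cohort = "C1", age = seq(30, 75, by = 5))
  scores <- data.frame(sample_id = meta$sample_id,
                       similarity = 0.001 * meta$age + 0.2)
  fit <- suppressWarnings(age_regression(scores, meta, "C1"))
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  meta$age <- 50
  expect_error(age_regression(scores, meta, "C1"), "constant")
})

test_that("Mann-Whitney exact p matches hand enumeration and symmetry", {
  res <- compare_cohorts(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 0.1)   # 2/20 orderings as extreme
  same <- compare_cohorts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("exact Mann-Whitney matches enumeration for all m+n <= 10", {
  set.seed(15)
  for (m in 2:5) {
    for (n in 2:(10 - m)) {
      x <- round(stats::runif(m, 0, 10), 1)
      y <- round(stats::runif(n, 0, 10), 1)
      res <- compare_cohorts(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, oracle_mw_p(x, y),
                   info = sprintf("m=%d n=%d", m, n))
    }
  }
  # tie-free cases also agree with the distribution-based exact test
  for (rep in 1:10) {
    x <- stats::rnorm(4)
    y <- stats::rnorm(5)
    res <- compare_cohorts(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(res$p_value, ref, tolerance = 1e-9)
  }
})

test_that("large-sample Mann-Whitney approximation is calibrated and powerful", {
  set.seed(19)
  # agreement with R's tie-corrected normal approximation, no continuity
  for (rep in 1:5) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(25)
    res <- compare_cohorts(x, y)
    expect_equal(res$method, "normal")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(res$p_value, ref, tolerance = 1e-9)
  }
  # power: shift of 1 SD at n = 50/50 rejected at alpha 0.05 in > 90%
  rej <- 0
  for (rep in 1:200) {
    x <- stats::rnorm(50)
    y <- stats::rnorm(50, mean = 1)
    if (compare_cohorts(x, y)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 200, 0.9)
})

test_that("SV class proportions sum to one per cohort and match tallies", {
  set.seed(10)
  sv <- data.frame(
    sample_id = "s", cohort = rep(c("A", "B"), c(10, 40)),
    class = c(rep("TRA", 5), rep("DEL", 5),
              sample(c("DEL", "DUP", "INV", "TRA"), 40, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  out <- sv_class_proportions(sv)
  expect_equal(out$proportion[out$cohort == "A" & out$class == "TRA"], 0.5)
  for (coh in c("A", "B")) {
    expect_equal(sum(out$proportion[out$cohort == coh]), 1)
    brute <- table(factor(sv$class[sv$cohort == coh],
                          levels = c("DEL", "DUP", "INV", "TRA")))
    expect_equal(out$count[out$cohort == coh], as.numeric(brute))
  }
  solo <- sv_class_proportions(data.frame(sample_id = "s", cohort = "C",
                                          class = rep("INV", 7)))
  expect_equal(solo$proportion, c(0, 0, 1, 0)[match(solo$class,
                                                    c("DEL", "DUP", "INV", "TRA"))])
})

test_that("region-restricted spectra report class fractions vs genome-wide", {
  cfg <- simulation_config(seed = 91, genome_length = 5e4)
  gr <- generate_reference(cfg)
  s <- simulate_sample(gr, "s", treated_weights(cfg), 400, cfg)
  all_regions <- labeled_intervals("all", GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(1, 5e4)))
  res_all <- region_subset_spectrum(s$records, all_regions, gr$genome,
                                    categories = "G[T>G]G")
  expect_equal(res_all$catalog$counts,
               build_catalog(s$records, gr$genome, "SBS96")$counts)
  expect_equal(res_all$class_fractions$in_region,
               res_all$class_fractions$genome_wide)
  expect_equal(sum(res_all$class_fractions$in_region), 1)
  none <- labeled_intervals("none", GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(49990, 49999)))
  res_none <- region_subset_spectrum(s$records, none, gr$genome)
  expect_true(attr(res_none$catalog, "empty"))
  expect_equal(res_none$catalog$n_total, 0)
})
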