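sigs5 <- synthetic_signatures()
labs96 <- category_scheme("SBS96")$labels

catalog_from_freq <- function(f, n = 1e6, id = "x") {
  mutation_catalog(id, "SBS96", stats::setNames(f * n, labs96))
}

test_that("signature matrices validate column stochasticity and round-trip as TSV", {
  expect_true(all(abs(colSums(sigs5$profiles) - 1) < 1e-8))
  bad <- sigs5$profiles
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(signature_matrix(bad, "SBS96"), "sum to 1")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(sigs5, p)
  back <- read_signature_matrix(p, "SBS96")
  expect_equal(back$names, sigs5$names)
  expect_equal(back$profiles, sigs5$profiles, tolerance = 1e-8)
})

test_that("bundled synthetic signatures are well separated", {
  P <- sigs5$profiles
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(cosine_similarity(P[, i], P[, j]), 0.3)
  }
})

test_that("refit recovers a pure signature exactly", {
  ct <- catalog_from_freq(sigs5$profiles[, "SYN2"])
  fit <- refit(ct, sigs5)
  expect_equal(unname(fit$weights["SYN2"]), 1, tolerance = 1e-6)
  expect_equal(sum(fit$weights) - fit$weights[["SYN2"]], 0)
  expect_lt(fit$residual_error, 1e-10)
})

test_that("refit recovers an exact two-signature mixture to 1e-4", {
  f <- 0.6 * sigs5$profiles[, "SYN1"] + 0.4 * sigs5$profiles[, "SYN4"]
  fit <- refit(catalog_from_freq(f), sigs5)
  expect_equal(unname(fit$weights["SYN1"]), 0.6, tolerance = 1e-4)
  expect_equal(unname(fit$weights["SYN4"]), 0.4, tolerance = 1e-4)
  expect_equal(unname(sum(fit$weights[c("SYN2", "SYN3", "SYN5")])), 0)
  # agreement with an independent constrained least-squares oracle on the
  # final active set
  o <- pracma::lsqnonneg(sigs5$profiles[, c("SYN1", "SYN4")], as.numeric(f))
  err_oracle <- sum((f - sigs5$profiles[, c("SYN1", "SYN4")] %*% o$x)^2)
  expect_lt(abs(fit$residual_error - err_oracle), 1e-4)
})

test_that("refit agrees with the projected-gradient oracle on noisy catalogs", {
  set.seed(12)
  for (rep in 1:10) {
    w <- c(SYN1 = 0.5, SYN3 = 0.3, SYN5 = 0.2)
    counts <- stats::rmultinom(1, 5000,
                               sigs5$profiles[, names(w)] %*% w)[, 1]
    ct <- mutation_catalog("m", "SBS96", stats::setNames(counts, labs96))
    fit <- refit(ct, sigs5)
    act <- names(fit$weights)[fit$weights > 0]
    f <- catalog_frequency(ct)
    o <- pracma::lsqnonneg(sigs5$profiles[, act, drop = FALSE],
                           as.numeric(f))
    err_oracle <- sum((f - sigs5$profiles[, act, drop = FALSE] %*% o$x)^2)
    expect_lt(abs(fit$residual_error - err_oracle), 1e-4)
  }
})

test_that("refit residual is monotone in the signature library", {
  set.seed(77)
  counts <- stats::rmultinom(
    1, 3000, sigs5$profiles %*% rep(0.2, 5))[, 1]
  ct <- mutation_catalog("m", "SBS96", stats::setNames(counts, labs96))
  err3 <- refit(ct, signature_matrix(sigs5$profiles[, 1:3], "SBS96"))$residual_error
  err5 <- refit(ct, sigs5)$residual_error
  expect_lte(err5, err3 + 1e-12)
})

test_that("refit weights are invariant to catalog scaling", {
  set.seed(5)
  counts <- stats::rmultinom(1, 2000,
                             0.7 * sigs5$profiles[, 1] +
                               0.3 * sigs5$profiles[, 2])[, 1]
  ct1 <- mutation_catalog("a", "SBS96", stats::setNames(counts, labs96))
  ct2 <- mutation_catalog("b", "SBS96", stats::setNames(counts * 17, labs96))
  expect_equal(refit(ct1, sigs5)$weights, refit(ct2, sigs5)$weights,
               tolerance = 1e-10)
})

test_that("weights stay non-negative, sum to at most 1, and honor the cutoff", {
  set.seed(9)
  for (rep in 1:20) {
    w_true <- as.numeric(stats::rmultinom(1, 20, rep(1, 5))[, 1]) / 20
    counts <- stats::rmultinom(1, 1000, sigs5$profiles %*% w_true)[, 1]
    fit <- refit(mutation_catalog("m", "SBS96",
                                  stats::setNames(counts, labs96)), sigs5)
    expect_true(all(fit$weights >= 0))
    expect_lte(sum(fit$weights), 1 + 1e-8)
    expect_true(all(fit$weights[fit$weights > 0] >= 0.06 - 1e-9))
    expect_equal(fit$unattributed, 1 - sum(fit$weights))
  }
})

test_that("MAP attribution posterior is a proper distribution and honors zeros", {
  # two-signature toy on SBS96: B has zero mass at category 1
  P <- sigs5$profiles[, c("SYN1", "SYN2")]
  P[1, ] <- c(0.05, 0)
  P <- sweep(P, 2, colSums(P), `/`)
  sig2 <- signature_matrix(P, "SBS96")
  f <- 0.5 * P[, 1] + 0.5 * P[, 2]
  ct <- catalog_from_freq(f, n = 1e4)
  att <- attribute_and_subtract(ct, sig2, baseline_names = "SYN2")
  post <- att$posterior
  rs <- rowSums(post)
  expect_true(all(abs(rs[!is.na(rs)] - 1) < 1e-9))
  expect_equal(unname(post[1, "SYN1"]), 1)   # zero-likelihood exclusion
  expect_equal(unname(att$map_signature[1]), "SYN1")
  expect_true(all(att$adjusted_counts <= ct$counts + 1e-9))
  expect_true(all(att$adjusted_counts >= 0))
})

test_that("posterior ties are broken by name order and flagged", {
  # equal weights and equal profile values on the overlap categories
  P <- matrix(0, 96, 2, dimnames = list(NULL, c("Zb", "Aa")))
  P[1:64, "Zb"] <- 1 / 64
  P[33:96, "Aa"] <- 1 / 64
  sig2 <- signature_matrix(P, "SBS96")
  ct <- catalog_from_freq(as.numeric(0.5 * P[, 1] + 0.5 * P[, 2]), n = 1e4)
  att <- attribute_and_subtract(ct, sig2, baseline_names = character(0),
                                cutoff = 0)
  overlap <- labs96[33:64]
  expect_setequal(att$ties, overlap)
  expect_true(all(att$map_signature[overlap] == "Aa"))
})

test_that("undefined-posterior categories pass through unadjusted and are flagged", {
  P <- matrix(0, 96, 2, dimnames = list(NULL, c("A", "B")))
  P[1:48, 1] <- 1 / 48
  P[1:48, 2] <- rev(seq_len(48)) / sum(seq_len(48))
  sig2 <- signature_matrix(P, "SBS96")
  counts <- stats::setNames(rep(0, 96), labs96)
  counts[1:48] <- 10
  counts[60] <- 5  # category with zero probability under both signatures
  ct <- mutation_catalog("x", "SBS96", counts)
  att <- attribute_and_subtract(ct, sig2, baseline_names = "A", cutoff = 0)
  expect_true(labs96[60] %in% att$undefined)
  expect_equal(unname(att$adjusted_counts[60]), 5)
})

test_that("baseline subtraction moves spectra toward the exposure signature", {
  set.seed(444)
  for (rep in 1:25) {
    base <- 0.6 * sigs5$profiles[, 1] + 0.4 * sigs5$profiles[, 2]
    mix <- 0.5 * base + 0.5 * sigs5$profiles[, 3]
    counts <- stats::rmultinom(1, 2000, mix)[, 1]
    ct <- mutation_catalog("t", "SBS96", stats::setNames(counts, labs96))
    att <- attribute_and_subtract(ct, sigs5,
                                  baseline_names = c("SYN1", "SYN2"))
    expo <- sigs5$profiles[, 3]
    expect_gt(
      cosine_similarity(catalog_frequency(att$adjusted_catalog), expo),
      cosine_similarity(catalog_frequency(ct), expo)
    )
  }
})

test_that("soft subtraction removes at most the original counts", {
  set.seed(11)
  mix <- 0.5 * sigs5$profiles[, 1] + 0.5 * sigs5$profiles[, 3]
  counts <- stats::rmultinom(1, 3000, mix)[, 1]
  ct <- mutation_catalog("t", "SBS96", stats::setNames(counts, labs96))
  att <- attribute_and_subtract(ct, sigs5, baseline_names = "SYN1",
                                mode = "soft")
  expect_true(all(att$adjusted_counts >= 0))
  expect_true(all(att$adjusted_counts <= ct$counts + 1e-9))
  expect_lt(att$adjusted_catalog$n_total, ct$n_total)
})

test_that("Pearson comparison matches the textbook formula and flags degeneracy", {
  ct <- catalog_from_freq(sigs5$profiles[, "SYN4"])
  rho <- compare_to_published(ct, sigs5)
  expect_equal(unname(rho["SYN4"]), 1, tolerance = 1e-9)

  # 4-category toy check against a direct formula evaluation
  f <- c(0.4, 0.3, 0.2, 0.1)
  s <- c(0.1, 0.2, 0.3, 0.4)
  hand <- sum((f - mean(f)) * (s - mean(s))) /
    sqrt(sum((f - mean(f))^2) * sum((s - mean(s))^2))
  expect_equal(stats::cor(f, s), hand)

  # uniform catalog vs uniform signature: undefined, reported as NA
  uni <- matrix(1 / 96, 96, 1, dimnames = list(NULL, "FLAT"))
  sig_flat <- signature_matrix(uni, "SBS96")
  ct_uni <- catalog_from_freq(rep(1 / 96, 96))
  rho2 <- compare_to_published(ct_uni, sig_flat)
  expect_true(is.na(rho2[["FLAT"]]))
  expect_equal(attr(rho2, "zero_variance"), "FLAT")
})

test_that("cosine similarity follows its definition", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})
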