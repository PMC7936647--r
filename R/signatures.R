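# Reference-signature refitting and baseline attribution subtraction.

#' Construct a signature matrix
#'
#' Column-stochastic matrix of reference signatures over one category
#' scheme (the layout of COSMIC signature downloads).
#'
#' @param profiles numeric matrix, one column per signature, rows aligned to
#'   `scheme$labels`; each column must be non-negative and sum to 1 within
#'   1e-8 (columns summing to something else are rejected, not silently
#'   rescaled).
#' @param scheme a [category_scheme] or scheme name.
#' @return object of class `signature_matrix` with elements `scheme`,
#'   `names`, `profiles`.
#' @export
signature_matrix <- function(profiles, scheme) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != scheme$size) {
    stop("signature_matrix: expected ", scheme$size, " rows for ",
         scheme$name, ", got ", nrow(profiles))
  }
  if (is.null(colnames(profiles))) {
    stop("signature_matrix: profiles must have signature names as colnames")
  }
  if (anyDuplicated(colnames(profiles))) {
    stop("signature_matrix: duplicate signature names")
  }
  if (any(profiles < 0)) stop("signature_matrix: negative entries")
  cs <- colSums(profiles)
  if (any(abs(cs - 1) > 1e-8)) {
    stop("signature_matrix: column(s) ",
         paste(colnames(profiles)[abs(cs - 1) > 1e-8], collapse = ", "),
         " do not sum to 1")
  }
  rownames(profiles) <- scheme$labels
  structure(
    list(scheme = scheme, names = colnames(profiles), profiles = profiles),
    class = "signature_matrix"
  )
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> ", length(x$names), " signatures over ",
      x$scheme$name, "\n", sep = "")
  invisible(x)
}

#' Read / write signature matrices in COSMIC TSV layout
#'
#' First column holds category labels; remaining columns one signature each.
#'
#' @param path TSV path.
#' @param scheme scheme of the stored signatures.
#' @export
read_signature_matrix <- function(path, scheme) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cats <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!setequal(cats, scheme$labels) || anyDuplicated(cats)) {
    stop("read_signature_matrix: categories in ", path,
         " do not match scheme ", scheme$name)
  }
  m <- m[match(scheme$labels, cats), , drop = FALSE]
  signature_matrix(m, scheme)
}

#' @rdname read_signature_matrix
#' @param sigs a [signature_matrix].
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- data.frame(category = sigs$scheme$labels, sigs$profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Constrained least squares on a fixed signature subset: minimize
# || A w - f ||^2 subject to w >= 0 and sum(w) <= 1, by cyclic coordinate
# descent with box clamping (each update is the exact 1-d constrained
# minimizer, so the objective is non-increasing and converges on this
# convex set).
nnls_simplex <- function(A, f, w0 = NULL, tol = 1e-12, maxit = 2000L) {
  k <- ncol(A)
  if (k == 0L) return(numeric(0))
  w <- if (is.null(w0)) rep(0, k) else w0
  ata <- colSums(A * A)
  repeat {
    maxit <- maxit - 1L
    delta <- 0
    r <- f - A %*% w
    for (j in seq_len(k)) {
      num <- sum(A[, j] * r) + ata[j] * w[j]
      wj <- num / ata[j]
      cap <- 1 - sum(w) + w[j]
      wj <- min(max(wj, 0), cap)
      if (wj != w[j]) {
        r <- r - A[, j] * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    if (delta < tol || maxit <= 0L) break
  }
  w
}

#' Refit a catalog against reference signatures
#'
#' Estimates non-negative mixture weights of known signatures in an observed
#' catalog by iterative forward selection: at each step the signature whose
#' optimally chosen single weight most reduces the squared reconstruction
#' error is added, all selected weights are then re-optimized jointly
#' (non-negative, total weight at most 1), and selection stops when the
#' error improvement falls below `tol`. Weights below `cutoff` are then
#' zeroed and, by default, the remaining weights re-optimized.
#'
#' @param catalog a non-empty [mutation_catalog].
#' @param sigs a [signature_matrix] on the same scheme.
#' @param cutoff minimum retained weight (default 0.06).
#' @param tol stop when an added signature improves squared error by less
#'   than this (default 1e-3).
#' @param reoptimize_after_cutoff re-optimize surviving weights after the
#'   cutoff (default TRUE).
#' @return object of class `refit_result`: `weights` (named, over all
#'   signatures), `reconstruction` (raw linear combination of profiles),
#'   `residual_error` (sum of squared differences to the catalog frequency
#'   vector), `unattributed` (1 - sum of weights), `cutoff_applied`.
#' @export
refit <- function(catalog, sigs, cutoff = 0.06, tol = 1e-3,
                  reoptimize_after_cutoff = TRUE) {
  stopifnot(inherits(catalog, "mutation_catalog"),
            inherits(sigs, "signature_matrix"))
  if (!identical(catalog$scheme$name, sigs$scheme$name)) {
    stop("refit: catalog scheme ", catalog$scheme$name,
         " does not match signature scheme ", sigs$scheme$name)
  }
  if (catalog$n_total == 0) {
    stop("refit: catalog of sample ", catalog$sample_id, " is empty")
  }
  f <- catalog_frequency(catalog)
  A <- sigs$profiles
  k <- ncol(A)
  active <- integer(0)
  w_active <- numeric(0)
  err <- sum(f^2)

  sse <- function(w, cols) {
    r <- f - A[, cols, drop = FALSE] %*% w
    sum(r^2)
  }

  repeat {
    r <- f - if (length(active)) A[, active, drop = FALSE] %*% w_active else 0
    cap <- 1 - sum(w_active)
    best_j <- 0L
    best_err <- err
    best_w <- 0
    for (j in setdiff(seq_len(k), active)) {
      a <- A[, j]
      bj <- min(max(sum(a * r) / sum(a * a), 0), cap)
      e <- sum((r - a * bj)^2)
      if (e < best_err) {
        best_err <- e
        best_j <- j
        best_w <- bj
      }
    }
    if (best_j == 0L || err - best_err < tol) break
    active <- c(active, best_j)
    w_active <- nnls_simplex(A[, active, drop = FALSE], f,
                             w0 = c(w_active, best_w))
    err <- sse(w_active, active)
  }

  # cutoff: drop small weights, optionally re-optimize the survivors
  if (length(active)) {
    keep <- w_active >= cutoff
    active <- active[keep]
    w_active <- w_active[keep]
    if (length(active)) {
      if (reoptimize_after_cutoff) {
        w_active <- nnls_simplex(A[, active, drop = FALSE], f, w0 = w_active)
      }
    }
  }

  weights <- stats::setNames(rep(0, k), sigs$names)
  weights[active] <- w_active
  recon <- as.numeric(A %*% weights)
  names(recon) <- sigs$scheme$labels
  structure(
    list(weights = weights,
         reconstruction = recon,
         residual_error = sum((f - recon)^2),
         unattributed = 1 - sum(weights),
         cutoff_applied = cutoff),
    class = "refit_result"
  )
}

#' @export
print.refit_result <- function(x, ...) {
  w <- x$weights[x$weights > 0]
  cat("<refit_result> ", length(w), " active signatures; residual SSE ",
      signif(x$residual_error, 4), "; unattributed ",
      signif(x$unattributed, 4), "\n", sep = "")
  if (length(w)) print(round(sort(w, decreasing = TRUE), 4))
  invisible(x)
}

#' Attribute categories to signatures and subtract a baseline
#'
#' After refitting the treated catalog, each mutation category is
#' probabilistically attributed to the active signature with the highest a
#' posteriori probability: `posterior(s | c) = w_s P(c | s) / sum_s' w_s'
#' P(c | s')`. Categories whose MAP signature belongs to the baseline set
#' (e.g. signatures fitted in a solvent-only control) are then removed from
#' the catalog — by zeroing the category count in the default `"hard"` mode,
#' or by subtracting the posterior-weighted expected baseline count in
#' `"soft"` mode. Categories with zero probability under every active
#' signature are passed through unadjusted and flagged; posterior ties are
#' broken by signature name order and flagged.
#'
#' @param treated a [mutation_catalog] for the treated sample.
#' @param sigs a [signature_matrix].
#' @param baseline_names signatures regarded as baseline; subset of
#'   `sigs$names`.
#' @param mode `"hard"` (MAP category zeroing, default) or `"soft"`.
#' @param cutoff,tol,reoptimize_after_cutoff passed to [refit].
#' @return object of class `attribution_result`: `map_signature` (per
#'   category; `NA` where undefined), `posterior` (categories x active
#'   signatures), `adjusted_counts`, `adjusted_catalog`, `undefined`
#'   (flagged categories), `ties` (flagged tie categories), `refit` (the
#'   underlying [refit] result).
#' @export
attribute_and_subtract <- function(treated, sigs, baseline_names,
                                   mode = c("hard", "soft"),
                                   cutoff = 0.06, tol = 1e-3,
                                   reoptimize_after_cutoff = TRUE) {
  mode <- match.arg(mode)
  bad <- setdiff(baseline_names, sigs$names)
  if (length(bad)) {
    stop("attribute_and_subtract: unknown baseline signature(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- refit(treated, sigs, cutoff = cutoff, tol = tol,
               reoptimize_after_cutoff = reoptimize_after_cutoff)
  w <- fit$weights[fit$weights > 0]
  if (length(w) == 0) {
    stop("attribute_and_subtract: no active signatures in the treated ",
         "catalog refit")
  }
  P <- sigs$profiles[, names(w), drop = FALSE]
  joint <- sweep(P, 2, w, `*`)
  denom <- rowSums(joint)
  posterior <- joint / ifelse(denom > 0, denom, NA_real_)
  undefined <- names(denom)[denom <= 0]

  map_sig <- rep(NA_character_, nrow(P))
  names(map_sig) <- rownames(P)
  ties <- character(0)
  ok <- denom > 0
  if (any(ok)) {
    ord <- order(colnames(posterior))  # lexicographic tie-break
    pc <- posterior[, ord, drop = FALSE]
    for (i in which(ok)) {
      row <- pc[i, ]
      tied <- which(row >= max(row) - 1e-9)
      if (length(tied) > 1L) ties <- c(ties, rownames(P)[i])
      map_sig[i] <- colnames(pc)[tied[1]]  # first in name order
    }
  }

  counts <- treated$counts
  adjusted <- counts
  if (mode == "hard") {
    kill <- !is.na(map_sig) & map_sig %in% baseline_names
    adjusted[kill] <- 0
  } else {
    base_frac <- rowSums(posterior[, colnames(posterior) %in% baseline_names,
                                   drop = FALSE])
    base_frac[is.na(base_frac)] <- 0
    adjusted <- counts * (1 - base_frac)
  }
  adjusted_catalog <- mutation_catalog(
    paste0(treated$sample_id, ".baseline_subtracted"),
    treated$scheme, adjusted
  )
  structure(
    list(map_signature = map_sig, posterior = posterior,
         adjusted_counts = adjusted, adjusted_catalog = adjusted_catalog,
         undefined = undefined, ties = unique(ties), refit = fit,
         baseline_names = baseline_names, mode = mode),
    class = "attribution_result"
  )
}

#' Pearson correlation between a catalog and each published signature
#'
#' @param catalog a non-empty [mutation_catalog].
#' @param sigs a [signature_matrix] on the same scheme.
#' @return named numeric vector of Pearson correlation coefficients; `NA`
#'   (with a `zero_variance` attribute) where either vector has zero
#'   variance.
#' @export
compare_to_published <- function(catalog, sigs) {
  if (!identical(catalog$scheme$name, sigs$scheme$name)) {
    stop("compare_to_published: scheme mismatch")
  }
  f <- catalog_frequency(catalog)
  out <- vapply(sigs$names, function(s) {
    col <- sigs$profiles[, s]
    if (stats::sd(f) == 0 || stats::sd(col) == 0) return(NA_real_)
    stats::cor(f, col)
  }, numeric(1))
  attr(out, "zero_variance") <- names(out)[is.na(out)]
  out
}

#' Cosine similarity between two spectra
#'
#' @param a,b numeric vectors over the same category scheme; neither may be
#'   all zero.
#' @return `dot(a, b) / (|a| |b|)`; in `[0, 1]` for non-negative spectra.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("cosine_similarity: vectors have different lengths")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector")
  sum(a * b) / (na * nb)
}
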