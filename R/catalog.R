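# Per-sample mutation catalogs over the SBS96 / DBS78 / ID83 schemes.

#' Construct a mutation catalog
#'
#' A per-sample count vector over one category scheme.
#'
#' @param sample_id sample label.
#' @param scheme a [category_scheme] or scheme name.
#' @param counts integer vector aligned to `scheme$labels` (a named vector
#'   is re-ordered by label; missing labels count 0).
#' @return object of class `mutation_catalog` with elements `sample_id`,
#'   `scheme`, `counts` (named), `n_total`.
#' @export
mutation_catalog <- function(sample_id, scheme, counts) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  stopifnot(inherits(scheme, "category_scheme"))
  if (!is.null(names(counts))) {
    bad <- setdiff(names(counts), scheme$labels)
    if (length(bad)) {
      stop("mutation_catalog: unknown categories for ", scheme$name, ": ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
    full <- stats::setNames(rep(0, scheme$size), scheme$labels)
    full[names(counts)] <- counts
    counts <- full
  } else {
    if (length(counts) != scheme$size) {
      stop("mutation_catalog: expected ", scheme$size, " counts, got ",
           length(counts))
    }
    counts <- stats::setNames(counts, scheme$labels)
  }
  if (any(counts < 0)) stop("mutation_catalog: negative counts")
  structure(
    list(sample_id = sample_id, scheme = scheme, counts = counts,
         n_total = sum(counts)),
    class = "mutation_catalog"
  )
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("<mutation_catalog> sample ", x$sample_id, ", scheme ", x$scheme$name,
      ", ", x$n_total, " mutations\n", sep = "")
  invisible(x)
}

#' Frequency view of a catalog
#' @param catalog a [mutation_catalog].
#' @return named numeric vector summing to 1 (errors on an empty catalog).
#' @export
catalog_frequency <- function(catalog) {
  if (catalog$n_total == 0) {
    stop("catalog_frequency: catalog of sample ", catalog$sample_id,
         " is empty")
  }
  catalog$counts / catalog$n_total
}

# --- genome accessors -------------------------------------------------------

# genome: a Biostrings::DNAStringSet or a named character vector of
# chromosome sequences. Returns the uppercase subsequence [start, end],
# 1-based inclusive.
get_genome_seq <- function(genome, chrom, start, end) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) {
      stop("genome does not contain chromosome '", chrom, "'")
    }
    len <- Biostrings::width(genome[chrom])
    if (start < 1L || end > len) {
      stop("locus ", chrom, ":", start, "-", end, " outside genome (length ",
           len, ")")
    }
    return(toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                   start, end))))
  }
  if (!chrom %in% names(genome)) {
    stop("genome does not contain chromosome '", chrom, "'")
  }
  len <- nchar(genome[[chrom]])
  if (start < 1L || end > len) {
    stop("locus ", chrom, ":", start, "-", end, " outside genome (length ",
         len, ")")
  }
  toupper(substr(genome[[chrom]], start, end))
}

genome_seq_length <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    return(Biostrings::width(genome[chrom]))
  }
  nchar(genome[[chrom]])
}

#' Merge immediately adjacent SNVs into doublet substitutions
#'
#' Two single-base substitutions in the same sample at consecutive positions
#' on the same chromosome are merged into one doublet (DBS) record, so a
#' doublet is never double-counted as two SBS. Runs of three or more
#' adjacent SNVs are left unmerged (reported as `multi`), since they are not
#' doublets.
#'
#' @param records a `mutation_records` data.frame.
#' @return list with `snvs` (unmerged SNVs), `dbs` (merged doublet records
#'   plus native 2-bp substitution records), `other` (indels/MNVs), and
#'   `multi` (SNVs in adjacent runs of length > 2, left as-is).
#' @export
merge_adjacent_snvs <- function(records) {
  cls <- variant_class(records)
  snv <- records[cls == "SNV", , drop = FALSE]
  native_dbs <- records[cls == "DBS", , drop = FALSE]
  other <- records[!cls %in% c("SNV", "DBS"), , drop = FALSE]

  merged <- list()
  keep_snv <- rep(TRUE, nrow(snv))
  multi_idx <- integer(0)
  if (nrow(snv) > 1) {
    o <- order(snv$sample_id, snv$chrom, snv$pos)
    snv <- snv[o, , drop = FALSE]
    adj <- which(snv$sample_id[-1] == snv$sample_id[-nrow(snv)] &
                   snv$chrom[-1] == snv$chrom[-nrow(snv)] &
                   snv$pos[-1] == snv$pos[-nrow(snv)] + 1L)
    # group adjacent runs; only runs of exactly 2 become doublets
    if (length(adj)) {
      run_id <- cumsum(c(TRUE, diff(adj) != 1L))
      for (g in split(adj, run_id)) {
        members <- unique(c(g, g + 1L))
        if (length(members) == 2L) {
          i <- members[1]; j <- members[2]
          m <- snv[i, , drop = FALSE]
          m$ref <- paste0(snv$ref[i], snv$ref[j])
          m$alt <- paste0(snv$alt[i], snv$alt[j])
          m$qual <- min(snv$qual[i], snv$qual[j])
          m$depth_tumor <- min(snv$depth_tumor[i], snv$depth_tumor[j])
          m$depth_control <- min(snv$depth_control[i], snv$depth_control[j])
          m$alt_support <- min(snv$alt_support[i], snv$alt_support[j])
          merged[[length(merged) + 1L]] <- m
          keep_snv[members] <- FALSE
        } else {
          multi_idx <- c(multi_idx, members)
          keep_snv[members] <- FALSE
        }
      }
    }
  }
  dbs <- native_dbs
  if (length(merged)) {
    dbs <- rbind(native_dbs, do.call(rbind, merged))
  }
  list(
    snvs = snv[keep_snv, , drop = FALSE],
    dbs = dbs,
    other = other,
    multi = snv[multi_idx, , drop = FALSE]
  )
}

#' Build a per-sample mutation catalog
#'
#' Classifies records against the reference genome and tallies them into the
#' requested scheme. For `SBS96`, adjacent SNV pairs are first merged into
#' doublets (see [merge_adjacent_snvs]) and excluded; for `DBS78`, those
#' merged doublets plus native 2-bp substitutions are classified; for
#' `ID83`, insertion/deletion records are classified with 60 bp flanks.
#' Records whose context contains `N` (or that cannot be classified) are
#' excluded from the counts and reported in the `n_unclassified` attribute.
#'
#' @param records `mutation_records` for one sample.
#' @param genome a named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences.
#' @param scheme a [category_scheme] or scheme name.
#' @param callable_mb optional callable genome length in Mb; when given, the
#'   catalog carries a `burden_per_mb` attribute (`n_total / callable_mb`).
#' @return a [mutation_catalog] with attributes `n_unclassified` and
#'   optionally `burden_per_mb`.
#' @export
build_catalog <- function(records, genome, scheme, callable_mb = NULL) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  sample_id <- if (nrow(records)) records$sample_id[1] else "empty"
  if (nrow(records) && length(unique(records$sample_id)) > 1L) {
    stop("build_catalog: records span multiple samples; build one catalog ",
         "per sample")
  }
  parts <- merge_adjacent_snvs(records)
  labels <- character(0)
  n_unclassified <- 0L

  if (scheme$name == "SBS96") {
    s <- parts$snvs
    if (nrow(s)) {
      ctx <- vapply(seq_len(nrow(s)), function(i) {
        get_genome_seq(genome, s$chrom[i], s$pos[i] - 1L, s$pos[i] + 1L)
      }, character(1))
      ref_obs <- substr(ctx, 2, 2)
      bad_ref <- ref_obs != s$ref
      if (any(bad_ref)) {
        i <- which(bad_ref)[1]
        stop("build_catalog: reference mismatch at ", s$chrom[i], ":",
             s$pos[i], " (VCF ref ", s$ref[i], ", genome ", ref_obs[i], ")")
      }
      lab <- classify_sbs_vec(s$ref, s$alt, substr(ctx, 1, 1),
                              substr(ctx, 3, 3))
      n_unclassified <- sum(is.na(lab))
      labels <- lab[!is.na(lab)]
    }
  } else if (scheme$name == "DBS78") {
    d <- parts$dbs
    if (nrow(d)) {
      lab <- vapply(seq_len(nrow(d)), function(i) {
        if (grepl("N", d$ref[i]) || grepl("N", d$alt[i])) {
          return(NA_character_)
        }
        classify_dbs(d$ref[i], d$alt[i])
      }, character(1))
      n_unclassified <- sum(is.na(lab))
      labels <- lab[!is.na(lab)]
    }
  } else if (scheme$name == "ID83") {
    idx <- which(variant_class(parts$other) == "indel")
    d <- parts$other[idx, , drop = FALSE]
    if (nrow(d)) {
      flank <- 60L
      lab <- vapply(seq_len(nrow(d)), function(i) {
        chrom_len <- genome_seq_length(genome, d$chrom[i])
        lo <- max(1L, d$pos[i] - flank)
        hi <- min(chrom_len, d$pos[i] + nchar(d$ref[i]) - 1L + flank)
        up <- if (d$pos[i] > lo) {
          get_genome_seq(genome, d$chrom[i], lo, d$pos[i] - 1L)
        } else ""
        down_start <- d$pos[i] + nchar(d$ref[i])
        down <- if (down_start <= hi) {
          get_genome_seq(genome, d$chrom[i], down_start, hi)
        } else ""
        if (grepl("N", paste0(up, down, d$ref[i], d$alt[i]))) {
          return(NA_character_)
        }
        classify_indel(d$ref[i], d$alt[i], flank5 = up, flank3 = down)
      }, character(1))
      n_unclassified <- sum(is.na(lab))
      labels <- lab[!is.na(lab)]
    }
  }

  counts <- table(factor(labels, levels = scheme$labels))
  out <- mutation_catalog(sample_id, scheme,
                          stats::setNames(as.numeric(counts),
                                          scheme$labels))
  attr(out, "n_unclassified") <- n_unclassified
  if (!is.null(callable_mb)) {
    attr(out, "burden_per_mb") <- out$n_total / callable_mb
  }
  out
}

#' Write / read catalogs as COSMIC-layout TSV
#'
#' Rows are scheme labels in fixed order (first column `category`); one
#' column per sample.
#'
#' @param catalogs a list of [mutation_catalog] on a common scheme.
#' @param path output path.
#' @export
write_catalogs <- function(catalogs, path) {
  stopifnot(length(catalogs) > 0)
  scheme <- catalogs[[1]]$scheme
  m <- vapply(catalogs, function(ct) {
    stopifnot(identical(ct$scheme$name, scheme$name))
    ct$counts
  }, numeric(scheme$size))
  colnames(m) <- vapply(catalogs, `[[`, character(1), "sample_id")
  df <- data.frame(category = scheme$labels, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogs
#' @param scheme scheme name of the stored catalogs.
#' @return `read_catalogs` returns a named list of [mutation_catalog].
#' @export
read_catalogs <- function(path, scheme) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(df[[1]], scheme$labels)) {
    stop("read_catalogs: categories in ", path, " do not match scheme ",
         scheme$name)
  }
  out <- lapply(names(df)[-1], function(s) {
    mutation_catalog(s, scheme, stats::setNames(df[[s]], scheme$labels))
  })
  stats::setNames(out, names(df)[-1])
}
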