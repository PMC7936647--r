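# Context-wise relative mutation frequency across genomic compartments.

#' Mutation rates per genomic context
#'
#' Counts mutations falling in each labeled compartment (genomic, epigenomic,
#' replication-timing or nuclear-localization track) and normalizes by the
#' compartment's total merged length, reporting the rate on a log10 scale.
#' A record may contribute to several overlapping tracks (e.g. exonic and
#' early-replicating); within a declared partition each record counts once.
#' Zero-count contexts get an explicit undefined log10 value (`NA`) rather
#' than `-Inf` or a pseudocount.
#'
#' @param records a `mutation_records` data.frame.
#' @param contexts list of [labeled_intervals]; every context must have
#'   positive total length.
#' @return a `data.frame` with columns `context`, `count`, `length_bp`,
#'   `rate` (count per bp) and `log10_rate` (`NA` when `count == 0`).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
#' ctx <- labeled_intervals("exonic", gr)
#' recs <- mutation_records("chr1", seq(1e4, 1e5, by = 1e4), "C", "A", "s1")
#' context_rates(recs, list(ctx))   # rate 1e-5, log10 -5
#' @export
context_rates <- function(records, contexts) {
  rgr <- records_granges(records)
  rows <- lapply(contexts, function(ctx) {
    stopifnot(inherits(ctx, "labeled_intervals"))
    if (ctx$total_length <= 0) {
      stop("context_rates: context '", ctx$label, "' has total length 0")
    }
    count <- sum(suppressWarnings(
      IRanges::overlapsAny(rgr, ctx$gr, ignore.strand = TRUE)))
    rate <- count / ctx$total_length
    data.frame(
      context = ctx$label, count = count, length_bp = ctx$total_length,
      rate = rate,
      log10_rate = if (count > 0) log10(rate) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a context-rate table to TSV
#' @param rates output of [context_rates].
#' @param path output path.
#' @export
write_context_rates <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
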