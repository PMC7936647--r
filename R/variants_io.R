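# Variant and interval I/O plus the somatic filtering cascade.
#
# Mutation records travel as a plain data.frame with the columns documented
# in `mutation_records()`; intervals travel as `labeled_intervals` objects
# wrapping a reduced GRanges.

RECORD_COLS <- c("chrom", "pos", "ref", "alt", "sample_id", "qual",
                 "depth_tumor", "depth_control", "alt_support",
                 "allele_balance")

#' Construct a mutation-record table
#'
#' The package's working representation of somatic variants: one row per
#' ALT allele with caller annotations. Missing annotations are `NA`, never
#' zero, so a filter that needs them fails loudly rather than silently
#' passing records.
#'
#' @param chrom,pos,ref,alt chromosome, 1-based position of the first
#'   reference base, and uppercase allele strings.
#' @param sample_id sample label (recycled).
#' @param qual caller quality score (QSS-like; `NA` if absent).
#' @param depth_tumor,depth_control read depth in the treated/tumor and
#'   control sample (`NA` if absent).
#' @param alt_support reads supporting the variant (`NA` if absent).
#' @param allele_balance alternate-allele fraction in `[0, 1]`, used by the
#'   doublet allele-balance filter (`NA` if absent).
#' @return a data.frame of class `mutation_records`.
#' @export
mutation_records <- function(chrom, pos, ref, alt, sample_id,
                             qual = NA_real_,
                             depth_tumor = NA_real_,
                             depth_control = NA_real_,
                             alt_support = NA_real_,
                             allele_balance = NA_real_) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = ref, alt = alt, sample_id = as.character(sample_id),
    qual = as.numeric(qual),
    depth_tumor = as.numeric(depth_tumor),
    depth_control = as.numeric(depth_control),
    alt_support = as.numeric(alt_support),
    allele_balance = as.numeric(allele_balance),
    stringsAsFactors = FALSE
  )
  bad <- which(df$ref == df$alt | df$pos < 1L |
                 nchar(df$ref) == 0L | nchar(df$alt) == 0L)
  if (length(bad)) {
    stop("mutation_records: invalid record(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (ref == alt, empty allele, or pos < 1)")
  }
  class(df) <- c("mutation_records", "data.frame")
  df
}

empty_records <- function() {
  mutation_records(character(0), integer(0), character(0), character(0),
                   character(0), qual = numeric(0),
                   depth_tumor = numeric(0), depth_control = numeric(0),
                   alt_support = numeric(0), allele_balance = numeric(0))
}

#' Variant class of each record
#'
#' @param records a `mutation_records` data.frame.
#' @return character vector: `"SNV"` (1 bp substitution), `"DBS"` (2 bp
#'   substitution with both bases changed), `"MNV"` (other same-length
#'   substitution), or `"indel"`.
#' @export
variant_class <- function(records) {
  nr <- nchar(records$ref)
  na <- nchar(records$alt)
  out <- rep("indel", nrow(records))
  sub <- nr == na
  out[sub & nr == 1L] <- "SNV"
  is_dbs <- sub & nr == 2L &
    substr(records$ref, 1, 1) != substr(records$alt, 1, 1) &
    substr(records$ref, 2, 2) != substr(records$alt, 2, 2)
  out[is_dbs] <- "DBS"
  out[sub & nr >= 2L & !is_dbs] <- "MNV"
  out
}

#' Read somatic variants from a VCF file
#'
#' Parses a VCF 4.x file with \pkg{vcfR} and returns one mutation record per
#' ALT allele. Multi-allelic sites are split; records with symbolic
#' alternate alleles (`<DEL>`, breakends, `*`) are skipped and counted in the
#' `skipped_symbolic` attribute. Caller annotations are looked up in the
#' INFO column under the keys `DPT` (treated/tumor depth), `DPC` (control
#' depth), `ALTS` (alt-supporting reads) and `AB` (allele balance); the QUAL
#' column carries the caller quality score. Absent annotations become `NA`.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample_id label attached to every returned record.
#' @return a `mutation_records` data.frame with attribute
#'   `skipped_symbolic` (count of symbolic-allele records dropped).
#' @export
read_vcf <- function(path, sample_id) {
  if (!file.exists(path)) {
    stop("read_vcf: cannot read VCF file: ", path)
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("read_vcf: failed to parse ", path, ": ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    out <- empty_records()
    attr(out, "skipped_symbolic") <- 0L
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("read_vcf: malformed POS at data line ",
         which(is.na(pos))[1], " of ", path)
  }
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  dpt <- suppressWarnings(as.numeric(info_field(fix$INFO, "DPT")))
  dpc <- suppressWarnings(as.numeric(info_field(fix$INFO, "DPC")))
  alts <- suppressWarnings(as.numeric(info_field(fix$INFO, "ALTS")))
  ab <- suppressWarnings(as.numeric(info_field(fix$INFO, "AB")))

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_flat <- unlist(alt_list, use.names = FALSE)
  symbolic <- grepl("<", alt_flat, fixed = TRUE) |
    grepl("[", alt_flat, fixed = TRUE) |
    grepl("]", alt_flat, fixed = TRUE) |
    alt_flat == "*"
  nonacgt <- !symbolic & grepl("[^ACGTNacgtn]", alt_flat)
  if (any(nonacgt)) {
    stop("read_vcf: malformed ALT allele '", alt_flat[which(nonacgt)[1]],
         "' at data line ", idx[which(nonacgt)[1]], " of ", path)
  }
  keep <- !symbolic
  out <- mutation_records(
    chrom = fix$CHROM[idx][keep], pos = pos[idx][keep],
    ref = fix$REF[idx][keep], alt = alt_flat[keep],
    sample_id = sample_id,
    qual = qual[idx][keep],
    depth_tumor = dpt[idx][keep], depth_control = dpc[idx][keep],
    alt_support = alts[idx][keep], allele_balance = ab[idx][keep]
  )
  attr(out, "skipped_symbolic") <- sum(symbolic)
  out
}

#' Labeled genomic intervals
#'
#' A named genomic compartment (context track or blacklist) stored as a
#' reduced [GenomicRanges::GRanges] with its total merged length.
#'
#' @param label compartment name.
#' @param gr a GRanges; overlapping/adjacent intervals are merged.
#' @return object of class `labeled_intervals` with elements `label`,
#'   `gr` (reduced GRanges) and `total_length` (bp).
#' @export
labeled_intervals <- function(label, gr) {
  gr <- GenomicRanges::reduce(gr)
  structure(
    list(label = label, gr = gr,
         total_length = sum(as.numeric(GenomicRanges::width(gr)))),
    class = "labeled_intervals"
  )
}

#' @export
print.labeled_intervals <- function(x, ...) {
  cat("<labeled_intervals> ", x$label, ": ", length(x$gr),
      " merged intervals, ", x$total_length, " bp\n", sep = "")
  invisible(x)
}

#' Read a BED file into labeled intervals
#'
#' BED intervals (0-based half-open) are imported with \pkg{rtracklayer},
#' merged per chromosome, and the total length computed after merging.
#'
#' @param path path to a BED3+ file.
#' @param label name for the compartment.
#' @return a [labeled_intervals] object.
#' @export
read_bed <- function(path, label) {
  if (!file.exists(path)) stop("read_bed: cannot read BED file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(labeled_intervals(label, GenomicRanges::GRanges()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3L) {
      stop("read_bed: fewer than 3 columns at line ", i, " of ", path)
    }
    s <- suppressWarnings(as.numeric(parts[[i]][2]))
    e <- suppressWarnings(as.numeric(parts[[i]][3]))
    if (is.na(s) || is.na(e) || e <= s) {
      stop("read_bed: invalid interval (end <= start) at line ", i,
           " of ", path)
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  labeled_intervals(label, gr)
}

# GRanges for the reference footprint of each record (1-based inclusive)
records_granges <- function(records) {
  GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$pos,
                              end = records$pos + nchar(records$ref) - 1L)
  )
}

#' Somatic-variant filter policy
#'
#' Thresholds of the filtering cascade applied to caller output. Defaults
#' follow stringent somatic-calling practice: quality >= 40, >= 20x depth in
#' both treated and control, >= 4 alt-supporting reads, a doublet
#' allele-balance window that keeps confident heterozygous/homozygous calls
#' (remove if depth < 20, or 0.01 < AB < 0.25, or AB > 0.75), blacklist
#' exclusion, and removal of variants shared between samples.
#'
#' @param min_qual minimum caller quality (records with `qual < min_qual`
#'   removed).
#' @param min_depth minimum depth required in both `depth_tumor` and
#'   `depth_control`.
#' @param min_alt_support minimum alt-supporting reads.
#' @param ab_rule either `NULL` (no doublet allele-balance filter) or a list
#'   with `min_depth`, `het_low`, `het_high`, `hom`: doublet records are
#'   removed when `depth_tumor < min_depth`, `het_low < AB < het_high`, or
#'   `AB > hom`.
#' @param blacklists list of [labeled_intervals] to exclude.
#' @param drop_shared remove variants whose (chrom, pos, ref, alt) key is
#'   seen in more than one sample.
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(min_qual = 40, min_depth = 20,
                          min_alt_support = 4,
                          ab_rule = list(min_depth = 20, het_low = 0.01,
                                         het_high = 0.25, hom = 0.75),
                          blacklists = list(), drop_shared = TRUE) {
  stopifnot(min_qual >= 0, min_depth >= 0, min_alt_support >= 0)
  if (!is.null(ab_rule)) {
    stopifnot(ab_rule$het_low >= 0, ab_rule$het_high <= 1,
              ab_rule$hom <= 1, ab_rule$het_low <= ab_rule$het_high)
  }
  structure(
    list(min_qual = min_qual, min_depth = min_depth,
         min_alt_support = min_alt_support, ab_rule = ab_rule,
         blacklists = blacklists, drop_shared = drop_shared),
    class = "filter_policy"
  )
}

#' Apply the somatic filtering cascade
#'
#' Filters are applied in a fixed order -- quality, depth, alt support,
#' doublet allele balance, blacklist overlap, shared-between-samples -- and
#' each removal is attributed to the first criterion that fails, so the
#' per-criterion counts in the report are reproducible. Because the kept set
#' is a conjunction of all criteria, the order affects only the attribution,
#' never the surviving records.
#'
#' @param records a `mutation_records` data.frame.
#' @param policy a [filter_policy].
#' @param cohort optional named list of `mutation_records`, one per sample,
#'   used for shared-variant removal; when `NULL`, samples are taken from
#'   `records$sample_id`.
#' @return a list with `records` (survivors) and `report` (data.frame of
#'   per-criterion removal counts, in cascade order).
#' @export
apply_filters <- function(records, policy, cohort = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  n0 <- nrow(records)
  removed_by <- rep(NA_character_, n0)
  active <- rep(TRUE, n0)

  need <- function(field, crit) {
    v <- records[[field]]
    bad <- active & is.na(v)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("apply_filters: record ", records$chrom[i], ":", records$pos[i],
           " ", records$ref[i], ">", records$alt[i], " (sample ",
           records$sample_id[i], ") is missing '", field,
           "' required by the ", crit, " filter")
    }
    v
  }

  mark <- function(fail, crit) {
    hit <- active & fail
    removed_by[hit] <<- crit
    active[hit] <<- FALSE
  }

  if (n0 > 0) {
    mark(need("qual", "quality") < policy$min_qual, "quality")
    dt <- need("depth_tumor", "depth")
    dc <- need("depth_control", "depth")
    mark(dt < policy$min_depth | dc < policy$min_depth, "depth")
    mark(need("alt_support", "support") < policy$min_alt_support, "support")

    if (!is.null(policy$ab_rule)) {
      is_dbs <- variant_class(records) == "DBS"
      if (any(active & is_dbs)) {
        ab <- records$allele_balance
        miss <- active & is_dbs & is.na(ab)
        if (any(miss)) {
          i <- which(miss)[1]
          stop("apply_filters: doublet record ", records$chrom[i], ":",
               records$pos[i], " (sample ", records$sample_id[i],
               ") is missing 'allele_balance' required by the ",
               "allele-balance filter")
        }
        r <- policy$ab_rule
        fail_ab <- is_dbs & (records$depth_tumor < r$min_depth |
                               (ab > r$het_low & ab < r$het_high) |
                               ab > r$hom)
        fail_ab[is.na(fail_ab)] <- FALSE
        mark(fail_ab, "allele_balance")
      }
    }

    if (length(policy$blacklists) > 0) {
      rgr <- records_granges(records)
      in_bl <- rep(FALSE, n0)
      for (bl in policy$blacklists) {
        in_bl <- in_bl |
          suppressWarnings(IRanges::overlapsAny(rgr, bl$gr,
                                                ignore.strand = TRUE))
      }
      mark(in_bl, "blacklist")
    }

    if (isTRUE(policy$drop_shared)) {
      if (is.null(cohort)) {
        cohort <- split(records, records$sample_id)
      }
      keyed <- unique(do.call(rbind, lapply(cohort, function(x) {
        data.frame(key = paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"),
                   sample_id = x$sample_id, stringsAsFactors = FALSE)
      })))
      n_samples <- table(keyed$key)
      key <- paste(records$chrom, records$pos, records$ref, records$alt,
                   sep = ":")
      shared <- key %in% names(n_samples)[n_samples > 1L]
      mark(shared, "shared")
    }
  }

  criteria <- c("quality", "depth", "support", "allele_balance",
                "blacklist", "shared")
  report <- data.frame(
    criterion = criteria,
    removed = vapply(criteria, function(cr) sum(removed_by == cr, na.rm = TRUE),
                     numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- records[active, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_records", "data.frame")
  list(records = out, report = report)
}

SV_CLASSES <- c("DEL", "DUP", "INV", "TRA")

sv_size_bin <- function(size) {
  vapply(size, function(s) {
    if (is.na(s)) return("interchromosomal")
    if (s < 1e2) return("<1e2")
    if (s >= 1e7) return(">=1e7")
    lo <- floor(log10(s))
    sprintf("[1e%d,1e%d)", lo, lo + 1L)
  }, character(1))
}

#' Read a structural-variant call table
#'
#' Reads a tab-delimited SV table with header columns `sample_id`, `class`,
#' `chromA`, `posA`, `chromB`, `posB`, `support`. Event size is
#' `abs(posB - posA)` for intrachromosomal events and undefined for
#' translocations; sizes are binned on a log10 grid spanning 1e2-1e7 bp.
#' Records with fewer than `min_support` spanning/split reads are flagged
#' (`below_min_support`), not dropped.
#'
#' @param path path to the TSV file.
#' @param min_support minimum spanning/split-read support (default 4).
#' @return data.frame with the input columns plus `size`, `size_bin` and
#'   `below_min_support`.
#' @export
read_sv_table <- function(path, min_support = 4) {
  if (!file.exists(path)) stop("read_sv_table: cannot read file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "class", "chromA", "posA", "chromB", "posB",
              "support")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("read_sv_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !df$class %in% SV_CLASSES
  if (any(bad)) {
    stop("read_sv_table: unknown SV class '", df$class[which(bad)[1]],
         "' at row ", which(bad)[1], " (expected DEL/DUP/INV/TRA)")
  }
  df$size <- ifelse(df$class == "TRA", NA_real_, abs(df$posB - df$posA))
  df$size_bin <- sv_size_bin(df$size)
  df$below_min_support <- df$support < min_support
  df
}

#' Write a filter report to TSV
#' @param report the report data.frame from [apply_filters].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
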