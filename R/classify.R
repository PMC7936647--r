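# Mutation classifiers: SBS96, DBS78, ID83.
#
# All three operate on plain uppercase base strings; reference context is
# supplied by the caller (build_catalog extracts it from the genome).

#' Classify a single base substitution into the SBS96 scheme
#'
#' Substitutions with a purine reference base are reverse-complemented
#' (flanks swap roles) so the reported category always has a pyrimidine
#' (C or T) reference, the convention of the COSMIC SBS96 scheme.
#'
#' @param ref,alt reference and alternate base (single characters, A/C/G/T).
#' @param five_prime,three_prime flanking reference bases on the plus strand.
#' @return an SBS96 label such as `"T[C>A]C"`.
#' @examples
#' classify_sbs("C", "A", "T", "C")  # "T[C>A]C"
#' classify_sbs("G", "T", "A", "C")  # "G[C>A]T" (reverse-complemented)
#' @export
classify_sbs <- function(ref, alt, five_prime, three_prime) {
  bases <- c(ref, alt, five_prime, three_prime)
  if (any(!bases %in% BASES)) {
    stop("classify_sbs: non-ACGT base in input (ref=", ref, ", alt=", alt,
         ", 5'=", five_prime, ", 3'=", three_prime, ")")
  }
  if (ref == alt) stop("classify_sbs: ref and alt are identical")
  if (ref %in% c("A", "G")) {
    new5 <- comp_base(three_prime)
    new3 <- comp_base(five_prime)
    ref <- comp_base(ref)
    alt <- comp_base(alt)
    five_prime <- new5
    three_prime <- new3
  }
  paste0(five_prime, "[", ref, ">", alt, "]", three_prime)
}

# Vectorized SBS96 classification; returns NA where any base is not ACGT.
classify_sbs_vec <- function(ref, alt, five_prime, three_prime) {
  ok <- ref %in% BASES & alt %in% BASES &
    five_prime %in% BASES & three_prime %in% BASES & ref != alt
  flip <- ok & ref %in% c("A", "G")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  p5 <- ifelse(flip, comp_base(three_prime), five_prime)
  p3 <- ifelse(flip, comp_base(five_prime), three_prime)
  out <- paste0(p5, "[", r, ">", a, "]", p3)
  out[!ok] <- NA_character_
  out
}

# Lookup table mapping every both-base-changed doublet substitution
# "RR>AA" (144 of them) to its canonical DBS78 label, built by exhaustive
# enumeration at load time.
build_dbs_lookup <- function() {
  map <- character(0)
  for (r1 in BASES) for (r2 in BASES) {
    ref <- paste0(r1, r2)
    for (a1 in BASES) for (a2 in BASES) {
      if (a1 == r1 || a2 == r2) next
      alt <- paste0(a1, a2)
      cref <- ref
      calt <- alt
      if (!cref %in% DBS_CANONICAL_REF) {
        cref <- revcomp(cref)
        calt <- revcomp(calt)
      }
      if (cref %in% DBS_PALINDROMIC_REF) {
        rc <- revcomp(calt)
        if (rc < calt) calt <- rc
      }
      map[paste0(ref, ">", alt)] <- paste0(cref, ">", calt)
    }
  }
  map
}

.exposig_env <- new.env(parent = emptyenv())

dbs_lookup <- function() {
  if (is.null(.exposig_env$dbs_map)) {
    .exposig_env$dbs_map <- build_dbs_lookup()
  }
  .exposig_env$dbs_map
}

#' Classify a doublet base substitution into the DBS78 scheme
#'
#' Both bases of the doublet must change. Doublets whose reference is not one
#' of the ten canonical reference doublets are reverse-complemented; for
#' palindromic references (AT, TA, CG, GC) the lexicographically smaller of
#' the alternate doublet and its reverse complement is reported, collapsing
#' each strand pair onto one of the 78 canonical categories.
#'
#' @param ref_doublet,alt_doublet reference and alternate dinucleotides.
#' @return a DBS78 label such as `"TG>CA"`.
#' @examples
#' classify_dbs("TG", "CA")  # "TG>CA"
#' classify_dbs("CA", "TG")  # "TG>CA" (reverse-complement collapse)
#' @export
classify_dbs <- function(ref_doublet, alt_doublet) {
  if (nchar(ref_doublet) != 2L || nchar(alt_doublet) != 2L) {
    stop("classify_dbs: doublets must be 2-mers")
  }
  r <- strsplit(ref_doublet, "")[[1]]
  a <- strsplit(alt_doublet, "")[[1]]
  if (any(!c(r, a) %in% BASES)) {
    stop("classify_dbs: non-ACGT base in ", ref_doublet, ">", alt_doublet)
  }
  if (r[1] == a[1] || r[2] == a[2]) {
    stop("classify_dbs: both positions must differ (", ref_doublet, ">",
         alt_doublet, " changes only one base - that is an SBS, not a DBS)")
  }
  unname(dbs_lookup()[paste0(ref_doublet, ">", alt_doublet)])
}

# run-length helpers for indel context
trailing_run <- function(s, base) {
  n <- nchar(s)
  k <- 0L
  while (k < n && substr(s, n - k, n - k) == base) k <- k + 1L
  k
}

leading_run <- function(s, base) {
  n <- nchar(s)
  k <- 0L
  while (k < n && substr(s, k + 1L, k + 1L) == base) k <- k + 1L
  k
}

# copies of `unit` tiled immediately left of the event in `upstream`
count_copies_left <- function(upstream, unit) {
  L <- nchar(unit)
  n <- 0L
  while (nchar(upstream) >= (n + 1L) * L &&
         substr(upstream, nchar(upstream) - (n + 1L) * L + 1L,
                nchar(upstream) - n * L) == unit) {
    n <- n + 1L
  }
  n
}

count_copies_right <- function(downstream, unit) {
  L <- nchar(unit)
  n <- 0L
  while (nchar(downstream) >= (n + 1L) * L &&
         substr(downstream, n * L + 1L, (n + 1L) * L) == unit) {
    n <- n + 1L
  }
  n
}

longest_common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}

#' Classify a small insertion or deletion into the ID83 scheme
#'
#' The event is reduced to its pure inserted/deleted unit (shared VCF anchor
#' bases stripped) and left-normalized against the flanking reference so that
#' caller alignment dialect cannot change the label. One-base events are
#' pyrimidine-collapsed and binned by the homopolymer run length of the
#' affected base (including the deleted base itself, so a deletion from a run
#' of six T's lands in the 6+ bin `1:Del:T:5`). Longer events are binned by
#' the number of tandem copies of the unit in the reference; deletions with a
#' single copy are assigned to microhomology bins by the longest junction
#' homology between the deleted unit's ends and the flanking sequence.
#'
#' @param ref,alt VCF-style reference and alternate allele strings (may share
#'   an anchor base).
#' @param flank5,flank3 reference sequence immediately 5' and 3' of the
#'   event (after anchor stripping); at least 6 bp and at least the event
#'   length on each side.
#' @return an ID83 label such as `"1:Del:T:5"` or `"2:Del:M:1"`.
#' @examples
#' # deletion of one T out of a 7-T homopolymer:
#' classify_indel("CT", "C", flank5 = "AGAGAC", flank3 = "TTTTTTGA")
#' @export
classify_indel <- function(ref, alt, flank5, flank3) {
  if (any(!strsplit(paste0(ref, alt), "")[[1]] %in% BASES)) {
    stop("classify_indel: non-ACGT base in alleles ", ref, "/", alt)
  }
  # strip shared prefix, then shared suffix, to isolate the indel unit
  p <- longest_common_prefix_len(ref, alt)
  ref2 <- substr(ref, p + 1L, nchar(ref))
  alt2 <- substr(alt, p + 1L, nchar(alt))
  s <- longest_common_prefix_len(
    paste(rev(strsplit(ref2, "")[[1]]), collapse = ""),
    paste(rev(strsplit(alt2, "")[[1]]), collapse = "")
  )
  up <- paste0(flank5, substr(ref, 1L, p))
  down <- paste0(substr(ref2, nchar(ref2) - s + 1L, nchar(ref2)), flank3)
  ref2 <- substr(ref2, 1L, nchar(ref2) - s)
  alt2 <- substr(alt2, 1L, nchar(alt2) - s)
  if (nchar(ref2) > 0L && nchar(alt2) > 0L) {
    stop("classify_indel: complex substitution ", ref, ">", alt,
         " is not a pure insertion or deletion")
  }
  if (nchar(ref2) == 0L && nchar(alt2) == 0L) {
    stop("classify_indel: ref and alt are identical")
  }
  type <- if (nchar(ref2) > 0L) "Del" else "Ins"
  unit <- if (type == "Del") ref2 else alt2
  L <- nchar(unit)
  if (L > 50L) stop("classify_indel: event longer than 50 bp")
  if (nchar(up) < max(6L, L) || nchar(down) < max(6L, L)) {
    stop("classify_indel: flanking sequence too short to resolve context; ",
         "provide at least ", max(6L, L), " bp on each side")
  }

  # left-normalize: shift the event left while the base preceding it equals
  # the last base of the unit
  while (nchar(up) > 0L &&
         substr(up, nchar(up), nchar(up)) == substr(unit, L, L)) {
    moved <- substr(up, nchar(up), nchar(up))
    down <- paste0(substr(unit, L, L), down)
    unit <- paste0(moved, substr(unit, 1L, L - 1L))
    up <- substr(up, 1L, nchar(up) - 1L)
  }

  if (L == 1L) {
    run <- trailing_run(up, unit) + leading_run(down, unit) +
      (if (type == "Del") 1L else 0L)
    b <- if (unit %in% c("A", "G")) comp_base(unit) else unit
    if (type == "Del") {
      return(paste0("1:Del:", b, ":", min(run, 6L) - 1L))
    }
    return(paste0("1:Ins:", b, ":", min(run, 5L)))
  }

  Lb <- min(L, 5L)
  n_copies <- count_copies_left(up, unit) + count_copies_right(down, unit) +
    (if (type == "Del") 1L else 0L)
  if (type == "Ins") {
    return(paste0(Lb, ":Ins:R:", min(n_copies, 5L)))
  }
  if (n_copies >= 2L) {
    return(paste0(Lb, ":Del:R:", min(n_copies - 1L, 5L)))
  }
  # single-copy deletion: junction microhomology between the deleted unit's
  # ends and the flanking sequence (capped below the unit length)
  mh <- max(
    longest_common_prefix_len(unit, down),
    trailing_run_match(up, unit)
  )
  mh <- min(mh, L - 1L)
  if (mh == 0L) {
    return(paste0(Lb, ":Del:R:0"))
  }
  mh_cap <- c(`2` = 1L, `3` = 2L, `4` = 3L, `5` = 5L)[[as.character(Lb)]]
  paste0(Lb, ":Del:M:", min(mh, mh_cap))
}

# length of the longest suffix of `unit` matching the suffix of `up`
trailing_run_match <- function(up, unit) {
  L <- nchar(unit)
  n <- min(L, nchar(up))
  k <- 0L
  while (k < n &&
         substr(unit, L - k, L - k) ==
         substr(up, nchar(up) - k, nchar(up) - k)) {
    k <- k + 1L
  }
  k
}

#' Constructed indel cases spanning every ID83 category
#'
#' Builds a deterministic grid of insertion/deletion inputs whose category
#' is known by construction: 1-bp events over all four bases and
#' homopolymer run lengths, multi-base events over non-periodic units with
#' 0-7 tandem copies, and single-copy deletions with engineered junction
#' microhomology of every reportable length. Enumerating [classify_indel]
#' over the grid exercises (and exactly covers) the 83-category partition.
#'
#' @return data.frame with columns `ref`, `alt`, `flank5`, `flank3` and
#'   `expected` (the category implied by the construction).
#' @export
indel_case_grid <- function() {
  pyr <- function(b) if (b %in% c("A", "G")) comp_base(b) else b
  unit_of <- function(L) paste0(strrep("A", L - 1L), "C")
  rows <- list()
  add <- function(ref, alt, flank5, flank3, expected) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ref = ref, alt = alt, flank5 = flank5, flank3 = flank3,
      expected = expected, stringsAsFactors = FALSE)
  }
  for (b in BASES) {
    fil <- setdiff(c("G", "T"), b)[1]
    for (run in 1:7) {
      add(paste0(fil, b), fil, strrep(fil, 10),
          paste0(strrep(b, run - 1L), strrep(fil, 10)),
          paste0("1:Del:", pyr(b), ":", min(run, 6L) - 1L))
    }
    for (run in 0:6) {
      add(fil, paste0(fil, b), strrep(fil, 10),
          paste0(strrep(b, run), strrep(fil, 10)),
          paste0("1:Ins:", pyr(b), ":", min(run, 5L)))
    }
  }
  for (L in 2:6) {
    u <- unit_of(L)
    Lb <- min(L, 5L)
    for (n in 1:7) {  # n tandem copies including the deleted one
      add(paste0("G", u), "G", strrep("G", 10),
          paste0(strrep(u, n - 1L), strrep("T", 12)),
          if (n >= 2) paste0(Lb, ":Del:R:", min(n - 1L, 5L)) else
            paste0(Lb, ":Del:R:0"))
    }
    for (n in 0:6) {  # n pre-existing copies at the insertion point
      add("G", paste0("G", u), strrep("G", 10),
          paste0(strrep(u, n), strrep("T", 12)),
          paste0(Lb, ":Ins:R:", min(n, 5L)))
    }
    mh_cap <- c(1L, 2L, 3L, 5L)[Lb - 1L]
    for (m in seq_len(min(L - 1L, 5L))) {
      add(paste0("G", u), "G", strrep("G", 10),
          paste0(substr(u, 1L, m), strrep("T", 12)),
          paste0(Lb, ":Del:M:", min(m, mh_cap)))
    }
  }
  do.call(rbind, rows)
}
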