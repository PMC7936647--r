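# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package classifiers: reverse
# complements go through Biostrings, and context scanning walks the genome
# string character by character.

oracle_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_comp <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[b]]
}

# SBS96: pyrimidine-strand collapse done via Biostrings on the whole triplet
oracle_sbs <- function(ref, alt, p5, p3) {
  if (ref %in% c("C", "T")) {
    paste0(p5, "[", ref, ">", alt, "]", p3)
  } else {
    tri <- oracle_rc(paste0(p5, ref, p3))
    paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">",
           oracle_comp(alt), "]", substr(tri, 3, 3))
  }
}

# DBS78: canonicalize by picking, of the pair {ref>alt, rc(ref)>rc(alt)},
# the one whose ref doublet is canonical; for palindromic refs the smaller
# alt under string comparison
oracle_dbs <- function(ref, alt) {
  canon <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  rr <- oracle_rc(ref)
  ra <- oracle_rc(alt)
  if (!ref %in% canon) {
    ref <- rr
    alt <- ra
  } else if (ref == rr && ra < alt) {
    alt <- ra
  }
  paste0(ref, ">", alt)
}

# ID83 oracle: operates directly on the genome character vector. `pos`,
# `ref`, `alt` follow VCF anchor conventions. Scans runs / copies / homology
# with explicit loops.
oracle_indel <- function(genome_chars, pos, ref, alt) {
  rc <- strsplit(ref, "")[[1]]
  ac <- strsplit(alt, "")[[1]]
  # strip common prefix
  np <- 0L
  while (np < min(length(rc), length(ac)) && rc[np + 1] == ac[np + 1]) {
    np <- np + 1L
  }
  rc2 <- rc[seq_along(rc) > np]
  ac2 <- ac[seq_along(ac) > np]
  # strip common suffix
  ns <- 0L
  while (ns < min(length(rc2), length(ac2)) &&
         rc2[length(rc2) - ns] == ac2[length(ac2) - ns]) {
    ns <- ns + 1L
  }
  if (ns > 0) {
    rc2 <- rc2[seq_len(length(rc2) - ns)]
    ac2 <- ac2[seq_len(length(ac2) - ns)]
  }
  stopifnot(length(rc2) == 0 || length(ac2) == 0)
  type <- if (length(rc2) > 0) "Del" else "Ins"
  unit <- if (type == "Del") rc2 else ac2
  L <- length(unit)
  # genome coordinates: event starts at pos + np (first deleted base /
  # first base after which insertion happens)
  if (type == "Del") {
    ev_start <- pos + np            # first deleted base (1-based)
    # left-align by scanning the genome
    while (ev_start > 1 && genome_chars[ev_start - 1] == unit[L]) {
      unit <- c(genome_chars[ev_start - 1], unit[-L])
      ev_start <- ev_start - 1L
    }
    ev_end <- ev_start + L - 1L
    if (L == 1L) {
      b <- unit[1]
      run <- 1L
      i <- ev_start - 1L
      while (i >= 1 && genome_chars[i] == b) { run <- run + 1L; i <- i - 1L }
      i <- ev_end + 1L
      while (i <= length(genome_chars) && genome_chars[i] == b) {
        run <- run + 1L; i <- i + 1L
      }
      pyr <- if (b %in% c("A", "G")) oracle_comp(b) else b
      return(paste0("1:Del:", pyr, ":", min(run, 6L) - 1L))
    }
    # count tandem copies of unit around [ev_start, ev_end]
    n <- 1L
    i <- ev_start - L
    while (i >= 1 && all(genome_chars[i:(i + L - 1)] == unit)) {
      n <- n + 1L; i <- i - L
    }
    i <- ev_end + 1L
    while (i + L - 1 <= length(genome_chars) &&
           all(genome_chars[i:(i + L - 1)] == unit)) {
      n <- n + 1L; i <- i + L
    }
    Lb <- min(L, 5L)
    if (n >= 2L) return(paste0(Lb, ":Del:R:", min(n - 1L, 5L)))
    # microhomology: prefix of deleted unit vs sequence right of deletion,
    # suffix vs sequence left of deletion
    mh_r <- 0L
    while (mh_r < L && ev_end + mh_r + 1 <= length(genome_chars) &&
           genome_chars[ev_end + mh_r + 1] == unit[mh_r + 1]) {
      mh_r <- mh_r + 1L
    }
    mh_l <- 0L
    while (mh_l < L && ev_start - mh_l - 1 >= 1 &&
           genome_chars[ev_start - mh_l - 1] == unit[L - mh_l]) {
      mh_l <- mh_l + 1L
    }
    mh <- min(max(mh_r, mh_l), L - 1L)
    if (mh == 0L) return(paste0(Lb, ":Del:R:0"))
    cap <- c(1L, 2L, 3L, 5L)[Lb - 1L]
    return(paste0(Lb, ":Del:M:", min(mh, cap)))
  }
  # insertion: inserted after genome position pos + np - 1
  after <- pos + np - 1L
  while (after >= 1 && genome_chars[after] == unit[L]) {
    unit <- c(genome_chars[after], unit[-L])
    after <- after - 1L
  }
  if (L == 1L) {
    b <- unit[1]
    run <- 0L
    i <- after
    while (i >= 1 && genome_chars[i] == b) { run <- run + 1L; i <- i - 1L }
    i <- after + 1L
    while (i <= length(genome_chars) && genome_chars[i] == b) {
      run <- run + 1L; i <- i + 1L
    }
    pyr <- if (b %in% c("A", "G")) oracle_comp(b) else b
    return(paste0("1:Ins:", pyr, ":", min(run, 5L)))
  }
  n <- 0L
  i <- after - L + 1L
  while (i >= 1 && all(genome_chars[i:(i + L - 1)] == unit)) {
    n <- n + 1L; i <- i - L
  }
  i <- after + 1L
  while (i + L - 1 <= length(genome_chars) &&
         all(genome_chars[i:(i + L - 1)] == unit)) {
    n <- n + 1L; i <- i + L
  }
  paste0(min(L, 5L), ":Ins:R:", min(n, 5L))
}

# exact two-sided Mann-Whitney p by direct enumeration over label
# assignments, written independently of the package version
oracle_mw_p <- function(x, y) {
  m <- length(x)
  pool <- c(x, y)
  u_of <- function(groupx) {
    gx <- pool[groupx]
    gy <- pool[setdiff(seq_along(pool), groupx)]
    tot <- 0
    for (v in gx) tot <- tot + sum(v > gy) + 0.5 * sum(v == gy)
    tot
  }
  obs <- u_of(seq_len(m))
  center <- m * (length(pool) - m) / 2
  sets <- utils::combn(length(pool), m)
  stat <- apply(sets, 2, u_of)
  mean(abs(stat - center) >= abs(obs - center) - 1e-9)
}

# small random genome as character string + char vector
make_genome <- function(len, seed, gc = 0.4) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  list(str = c(chrT = paste(chars, collapse = "")), chars = chars)
}

# write a small VCF from parallel vectors (test fixture builder)
write_test_vcf <- function(path, chrom, pos, ref, alt, qual = 60,
                           info = NULL) {
  n <- length(pos)
  qual <- rep(qual, length.out = n)
  if (is.null(info)) info <- rep(".", n)
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste(chrom, pos, ".", ref, alt, qual, "PASS", info, sep = "\t")
  )
  writeLines(lines, path)
  path
}
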