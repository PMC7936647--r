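BASES <- c("A", "C", "G", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Complement / reverse-complement of a base string
#'
#' Plain character helpers used throughout the classifiers; operate on
#' uppercase A/C/G/T/N strings.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' @rdname comp_base
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# The ten reference doublets kept on the "canonical" strand in the DBS78
# scheme; every other reference doublet is reverse-complemented into one
# of these before labeling.
DBS_CANONICAL_REF <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")

# Reference doublets whose reverse complement is themselves: their ALT
# doublets collapse pairwise by reverse complement.
DBS_PALINDROMIC_REF <- c("AT", "CG", "GC", "TA")

sbs96_labels <- function() {
  out <- character(0)
  for (cls in SBS_CLASSES) {
    for (p5 in BASES) {
      for (p3 in BASES) {
        out <- c(out, paste0(p5, "[", cls, "]", p3))
      }
    }
  }
  out
}

dbs78_labels <- function() {
  out <- character(0)
  for (ref in DBS_CANONICAL_REF) {
    r <- strsplit(ref, "")[[1]]
    alts <- character(0)
    for (a1 in BASES) {
      for (a2 in BASES) {
        if (a1 == r[1] || a2 == r[2]) next
        alt <- paste0(a1, a2)
        if (ref %in% DBS_PALINDROMIC_REF) {
          rc <- revcomp(alt)
          if (rc < alt) alt <- rc
        }
        alts <- c(alts, alt)
      }
    }
    alts <- sort(unique(alts))
    out <- c(out, paste0(ref, ">", alts))
  }
  out
}

id83_labels <- function() {
  lab <- character(0)
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Ins:", b, ":", 0:5))
  for (L in 2:5) lab <- c(lab, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) lab <- c(lab, paste0(L, ":Ins:R:", 0:5))
  lab <- c(lab, "2:Del:M:1")
  lab <- c(lab, paste0("3:Del:M:", 1:2))
  lab <- c(lab, paste0("4:Del:M:", 1:3))
  lab <- c(lab, paste0("5:Del:M:", 1:5))
  lab
}

#' Mutation category schemes
#'
#' The three canonical somatic-mutation category schemes used throughout the
#' package: `SBS96` (single base substitutions in trinucleotide context,
#' pyrimidine-strand collapsed), `DBS78` (doublet base substitutions collapsed
#' by reverse complement onto ten canonical reference doublets) and `ID83`
#' (small insertions/deletions stratified by length, base, homopolymer or
#' tandem-repeat context and junction microhomology).
#'
#' @param name one of `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @return an object of class `category_scheme`: a list with elements
#'   `name`, `labels` (ordered category labels) and `size`.
#' @examples
#' scheme <- category_scheme("SBS96")
#' scheme$size   # 96
#' head(scheme$labels)
#' @export
category_scheme <- function(name = c("SBS96", "DBS78", "ID83")) {
  name <- match.arg(name)
  labels <- switch(name,
    SBS96 = sbs96_labels(),
    DBS78 = dbs78_labels(),
    ID83  = id83_labels()
  )
  structure(
    list(name = name, labels = labels, size = length(labels)),
    class = "category_scheme"
  )
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme> ", x$name, ": ", x$size, " categories\n", sep = "")
  invisible(x)
}
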