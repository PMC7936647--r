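# Deterministic simulator for every input the pipeline consumes: reference
# sequence with planted homopolymer/repeat tracts, signature-mixture VCFs,
# control/treated pairs, context tracks, cohorts with age-dependent
# exposure, and SV tables.

#' Synthetic, well-separated reference signatures
#'
#' Builds a deterministic set of synthetic signatures over a scheme, each a
#' Gaussian-shaped peak over the category index on top of a small uniform
#' background. Peak centers are spread evenly, giving pairwise cosine
#' similarity below 0.3 — well-separated enough that mixture weights are
#' identifiable in recovery tests.
#'
#' @param scheme a [category_scheme] or scheme name (default `"SBS96"`).
#' @param n_signatures number of signatures (default 5).
#' @param peak_width standard deviation of the peak, in category-index
#'   units (default 5).
#' @param background uniform background mass per signature (default 0.10).
#' @return a [signature_matrix] with signatures named `SYN1`, `SYN2`, ...
#' @export
synthetic_signatures <- function(scheme = "SBS96", n_signatures = 5,
                                 peak_width = 5, background = 0.10) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  n_cat <- scheme$size
  centers <- (seq_len(n_signatures) - 0.5) * n_cat / n_signatures
  profiles <- vapply(centers, function(mu) {
    peak <- exp(-((seq_len(n_cat) - mu)^2) / (2 * peak_width^2))
    p <- (1 - background) * peak / sum(peak) + background / n_cat
    p / sum(p)
  }, numeric(n_cat))
  colnames(profiles) <- paste0("SYN", seq_len(n_signatures))
  signature_matrix(profiles, scheme)
}

#' Simulation configuration
#'
#' Bundles every tunable of the simulator with its default study
#' conditions: a 200 kb reference at 41% GC with planted homopolymer and
#' short-tandem-repeat tracts, five well-separated synthetic signatures, a
#' solvent-control sample drawn from two baseline signatures, and treated
#' replicates drawing half their mutations from an exposure signature.
#'
#' @param seed integer; fixes all randomness end-to-end.
#' @param genome_length reference length in bp (>= 10 kb).
#' @param gc_content GC fraction of the background sequence.
#' @param signature_set a [signature_matrix] (default
#'   [synthetic_signatures]).
#' @param baseline_weights named weights of the baseline (culture/solvent)
#'   signatures; must sum to 1.
#' @param exposure_signature name of the exposure signature.
#' @param exposure_fraction fraction of treated mutations drawn from the
#'   exposure signature.
#' @param n_control,n_treated mutations per control / treated sample.
#' @param n_treated_samples number of treated replicates.
#' @param indel_tract_density planted homopolymer + repeat tracts per kb.
#' @param qual_mean,qual_sd,depth_mean,alt_fraction parameters of the
#'   simulated caller annotations (normal quality, Poisson depth, binomial
#'   alt support).
#' @param cohort_specs list of cohort specifications for
#'   [simulate_cohorts]; each a list with `label`, `n_samples`,
#'   `age_range`, `exposure_base`, `exposure_slope` (admixture per year),
#'   `n_mutations`, `sv_class_probs` (named DEL/DUP/INV/TRA), `n_sv`.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 2e5,
                              gc_content = 0.41,
                              signature_set = synthetic_signatures(),
                              baseline_weights = c(SYN1 = 0.6, SYN2 = 0.4),
                              exposure_signature = "SYN3",
                              exposure_fraction = 0.5,
                              n_control = 300L,
                              n_treated = 600L,
                              n_treated_samples = 3L,
                              indel_tract_density = 2,
                              qual_mean = 70, qual_sd = 15,
                              depth_mean = 35, alt_fraction = 0.45,
                              cohort_specs = default_cohort_specs()) {
  stopifnot(genome_length >= 1e4, gc_content > 0, gc_content < 1,
            abs(sum(baseline_weights) - 1) < 1e-8,
            exposure_fraction >= 0, exposure_fraction <= 1,
            n_control > 0, n_treated > 0)
  stopifnot(all(names(baseline_weights) %in% signature_set$names),
            exposure_signature %in% signature_set$names)
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content, signature_set = signature_set,
         baseline_weights = baseline_weights,
         exposure_signature = exposure_signature,
         exposure_fraction = exposure_fraction,
         n_control = as.integer(n_control),
         n_treated = as.integer(n_treated),
         n_treated_samples = as.integer(n_treated_samples),
         indel_tract_density = indel_tract_density,
         qual_mean = qual_mean, qual_sd = qual_sd,
         depth_mean = depth_mean, alt_fraction = alt_fraction,
         cohort_specs = cohort_specs),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_cohort_specs <- function() {
  list(
    list(label = "EXPOSED-HI", n_samples = 50, age_range = c(30, 80),
         exposure_base = 0.2, exposure_slope = 0.006, n_mutations = 500,
         sv_class_probs = c(DEL = 0.45, DUP = 0.25, INV = 0.15, TRA = 0.15),
         n_sv = 20),
    list(label = "EXPOSED-LO", n_samples = 50, age_range = c(30, 80),
         exposure_base = 0.0, exposure_slope = 0.0, n_mutations = 500,
         sv_class_probs = c(DEL = 0.35, DUP = 0.2, INV = 0.15, TRA = 0.3),
         n_sv = 20)
  )
}

# mixture weight vector for a treated sample
treated_weights <- function(config) {
  w <- stats::setNames(rep(0, length(config$signature_set$names)),
                       config$signature_set$names)
  w[names(config$baseline_weights)] <-
    (1 - config$exposure_fraction) * config$baseline_weights
  w[config$exposure_signature] <-
    w[config$exposure_signature] + config$exposure_fraction
  w
}

control_weights <- function(config) {
  w <- stats::setNames(rep(0, length(config$signature_set$names)),
                       config$signature_set$names)
  w[names(config$baseline_weights)] <- config$baseline_weights
  w
}

#' Generate a synthetic reference sequence with a context index
#'
#' Draws a random sequence at the requested GC content, plants homopolymer
#' (length 4-8) and short-tandem-repeat tracts (unit 2-4 bp, 3-5 copies) at
#' `indel_tract_density` per kb, and indexes every trinucleotide's center
#' positions plus the planted tracts, so mutations of any SBS96 category
#' and plantable indels can be placed by lookup.
#'
#' @param config a [simulation_config]; the RNG is seeded from
#'   `config$seed`.
#' @param fasta optional path; when given the sequence is written as FASTA.
#' @return object of class `sim_reference`: `genome` (named character,
#'   one chromosome `"chrS"`), `tri_index` (named list: trinucleotide ->
#'   center positions), `tracts` (data.frame of planted tracts: kind, base/
#'   unit, start, length, copies).
#' @export
generate_reference <- function(config, fasta = NULL) {
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), L, replace = TRUE, prob = p)

  n_tracts <- round(config$indel_tract_density * L / 1000)
  tracts <- list()
  if (n_tracts > 0) {
    starts <- sort(sample(10:(L - 60L), n_tracts))
    # keep tracts apart so runs never merge
    starts <- starts[c(TRUE, diff(starts) > 40)]
    for (s in starts) {
      if (stats::runif(1) < 0.6) {
        b <- sample(BASES, 1)
        len <- sample(4:8, 1)
        # make sure the run is bounded by different bases
        bases[s - 1] <- sample(setdiff(BASES, b), 1)
        bases[s:(s + len - 1)] <- b
        bases[s + len] <- sample(setdiff(BASES, b), 1)
        tracts[[length(tracts) + 1L]] <- data.frame(
          kind = "homopolymer", unit = b, start = s, unit_len = 1L,
          copies = len, stringsAsFactors = FALSE)
      } else {
        ulen <- sample(2:4, 1)
        unit <- paste(sample(BASES, ulen, replace = TRUE), collapse = "")
        copies <- sample(3:5, 1)
        seg <- strsplit(strrep(unit, copies), "")[[1]]
        bases[s:(s + length(seg) - 1L)] <- seg
        # bound the tract so the copy number is exact
        u1 <- substr(unit, ulen, ulen)
        bases[s - 1] <- sample(setdiff(BASES, u1), 1)
        bases[s + length(seg)] <- sample(setdiff(BASES, substr(unit, 1, 1)), 1)
        tracts[[length(tracts) + 1L]] <- data.frame(
          kind = "str", unit = unit, start = s, unit_len = ulen,
          copies = copies, stringsAsFactors = FALSE)
      }
    }
  }
  seq_str <- paste(bases, collapse = "")

  tri <- paste0(bases[1:(L - 2)], bases[2:(L - 1)], bases[3:L])
  tri_index <- split(2:(L - 1), tri)
  missing_tri <- setdiff(
    as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0)),
    names(tri_index))
  if (length(missing_tri)) {
    stop("generate_reference: no candidate positions for trinucleotide(s) ",
         paste(missing_tri, collapse = ", "),
         "; increase genome_length")
  }
  genome <- c(chrS = seq_str)
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(genome)
    Biostrings::writeXStringSet(ss, fasta)
  }
  structure(
    list(genome = genome,
         tri_index = tri_index,
         tracts = if (length(tracts)) do.call(rbind, tracts) else
           data.frame(kind = character(0), unit = character(0),
                      start = integer(0), unit_len = integer(0),
                      copies = integer(0)),
         fasta = fasta),
    class = "sim_reference"
  )
}

# candidate plus-strand center positions for an SBS96 category: positions
# whose plus-strand triplet is the label's context or its reverse complement
sbs_candidates <- function(genref, label) {
  p5 <- substr(label, 1, 1)
  rb <- substr(label, 3, 3)
  p3 <- substr(label, 7, 7)
  tri <- paste0(p5, rb, p3)
  c(genref$tri_index[[tri]], genref$tri_index[[revcomp(tri)]])
}

# simulated caller annotation block for n records
sim_annotations <- function(n, config) {
  depth_t <- stats::rpois(n, config$depth_mean)
  depth_c <- stats::rpois(n, config$depth_mean)
  alt_s <- stats::rbinom(n, size = pmax(depth_t, 1), prob = config$alt_fraction)
  data.frame(
    qual = round(pmax(stats::rnorm(n, config$qual_mean, config$qual_sd), 0), 1),
    depth_tumor = depth_t, depth_control = depth_c,
    alt_support = alt_s,
    allele_balance = round(alt_s / pmax(depth_t, 1), 4)
  )
}

#' Simulate one sample's mutations from a signature mixture
#'
#' Draws each mutation's signature of origin from `weights`, its category
#' from that signature's profile, and places it at a uniformly chosen
#' candidate position of matching trinucleotide context (on either strand)
#' without position collisions, so a catalog rebuilt from the VCF equals
#' the truth-table tally exactly. Caller annotations (quality, depths, alt
#' support) are drawn from the configured distributions. Optional blocks
#' plant 1-bp insertions/deletions in homopolymer tracts and doublet
#' substitutions.
#'
#' @param genref a [generate_reference] result.
#' @param sample_id sample label.
#' @param weights named signature weights summing to 1.
#' @param n_mutations number of SBS to draw.
#' @param config the [simulation_config].
#' @param n_indels,n_dbs optional counts of planted 1-bp indels and doublet
#'   substitutions.
#' @param dir optional output directory; when given, writes
#'   `<sample_id>.vcf` and `<sample_id>.truth.tsv` there.
#' @param seed optional seed; `NULL` (the default) continues the current
#'   RNG stream so multi-sample simulations differ between samples.
#' @return list with `records` (a `mutation_records` data.frame), `truth`
#'   (per-mutation true category and signature of origin), `vcf`, and
#'   `truth_path`.
#' @export
simulate_sample <- function(genref, sample_id, weights, n_mutations,
                            config, n_indels = 0L, n_dbs = 0L,
                            dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigs <- config$signature_set
  stopifnot(abs(sum(weights) - 1) < 1e-8,
            all(names(weights) %in% sigs$names))
  labels <- sigs$scheme$labels
  used <- logical(nchar(genref$genome[[1]]))

  origin <- sample(names(weights), n_mutations, replace = TRUE,
                   prob = weights)
  n_by_origin <- table(origin)
  draw <- do.call(rbind, lapply(names(n_by_origin), function(s) {
    data.frame(
      origin = s,
      category = sample(labels, n_by_origin[[s]], replace = TRUE,
                        prob = sigs$profiles[, s]),
      stringsAsFactors = FALSE)
  }))

  # place each category's mutations at shuffled candidate positions,
  # keeping a one-base buffer so placed SNVs are never adjacent (an
  # adjacent pair would be a doublet, not two SBS)
  rows <- vector("list", nrow(draw))
  r_i <- 0L
  for (lab in sort(unique(draw$category))) {
    k <- sum(draw$category == lab)
    cand <- sbs_candidates(genref, lab)
    cand <- cand[!used[cand] & !used[cand - 1L] & !used[cand + 1L]]
    # draw a small oversample first; fall back to the full list only if
    # buffer collisions exhaust it
    m <- min(length(cand), 4L * k + 16L)
    pool <- if (length(cand) > 1L) sample(cand, m) else cand
    taken <- integer(0)
    take_from <- function(pool) {
      for (pos in pool) {
        if (used[pos - 1L] || used[pos] || used[pos + 1L]) next
        used[(pos - 1L):(pos + 1L)] <<- TRUE
        taken <<- c(taken, pos)
        if (length(taken) == k) break
      }
    }
    take_from(pool)
    if (length(taken) < k && m < length(cand)) {
      rest <- setdiff(cand, pool)
      take_from(if (length(rest) > 1L) sample(rest) else rest)
    }
    if (length(taken) < k) {
      stop("simulate_sample: no free candidate position left for category ",
           lab, "; increase genome_length or reduce n_mutations")
    }
    ref <- substring(genref$genome[[1]], taken, taken)
    ralt <- substr(lab, 5, 5)
    alt <- ifelse(ref %in% c("C", "T"), ralt, comp_base(ralt))
    r_i <- r_i + 1L
    rows[[r_i]] <- data.frame(
      pos = taken, ref = ref, alt = alt, category = lab,
      origin = draw$origin[draw$category == lab],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[seq_len(r_i)])

  # planted doublets
  if (n_dbs > 0L) {
    dbs_rows <- vector("list", n_dbs)
    for (i in seq_len(n_dbs)) {
      repeat {
        pos <- sample.int(nchar(genref$genome[[1]]) - 10L, 1) + 4L
        if (!any(used[(pos - 1L):(pos + 2L)])) break
      }
      used[(pos - 1L):(pos + 2L)] <- TRUE
      ref2 <- substr(genref$genome[[1]], pos, pos + 1L)
      r <- strsplit(ref2, "")[[1]]
      alt2 <- paste0(sample(setdiff(BASES, r[1]), 1),
                     sample(setdiff(BASES, r[2]), 1))
      dbs_rows[[i]] <- data.frame(
        pos = pos, ref = ref2, alt = alt2,
        category = classify_dbs(ref2, alt2), origin = "planted_dbs",
        stringsAsFactors = FALSE)
    }
    df <- rbind(df, do.call(rbind, dbs_rows))
  }

  # planted 1-bp indels in homopolymer tracts: truth label is derived from
  # the tract geometry, independently of the classifier
  if (n_indels > 0L) {
    homo <- genref$tracts[genref$tracts$kind == "homopolymer", , drop = FALSE]
    if (nrow(homo) < n_indels) {
      stop("simulate_sample: only ", nrow(homo), " homopolymer tracts for ",
           n_indels, " indels; increase indel_tract_density")
    }
    pick <- sample(seq_len(nrow(homo)), n_indels)
    ind_rows <- vector("list", n_indels)
    for (k in seq_along(pick)) {
      tr <- homo[pick[k], ]
      run <- tr$copies
      b <- tr$unit
      pyr <- if (b %in% c("A", "G")) comp_base(b) else b
      anchor_pos <- tr$start - 1L
      anchor <- substr(genref$genome[[1]], anchor_pos, anchor_pos)
      if (any(used[anchor_pos:(tr$start + run)])) next
      used[anchor_pos:(tr$start + run)] <- TRUE
      if (stats::runif(1) < 0.5) {
        ref <- paste0(anchor, b)  # delete one base of the run
        alt <- anchor
        truth_lab <- paste0("1:Del:", pyr, ":", min(run, 6L) - 1L)
      } else {
        ref <- anchor
        alt <- paste0(anchor, b)  # insert one more copy
        truth_lab <- paste0("1:Ins:", pyr, ":", min(run, 5L))
      }
      ind_rows[[k]] <- data.frame(
        pos = anchor_pos, ref = ref, alt = alt,
        category = truth_lab, origin = "planted_indel",
        stringsAsFactors = FALSE)
    }
    ind_rows <- ind_rows[!vapply(ind_rows, is.null, logical(1))]
    if (length(ind_rows)) df <- rbind(df, do.call(rbind, ind_rows))
  }

  df <- df[order(df$pos), , drop = FALSE]
  ann <- sim_annotations(nrow(df), config)
  records <- mutation_records(
    chrom = "chrS", pos = df$pos, ref = df$ref, alt = df$alt,
    sample_id = sample_id, qual = ann$qual,
    depth_tumor = ann$depth_tumor, depth_control = ann$depth_control,
    alt_support = ann$alt_support,
    allele_balance = ifelse(variant_class(
      mutation_records("chrS", df$pos, df$ref, df$alt, sample_id)
    ) == "DBS", ann$allele_balance, NA_real_)
  )
  truth <- data.frame(sample_id = sample_id, chrom = "chrS",
                      pos = df$pos, ref = df$ref, alt = df$alt,
                      category = df$category, origin = df$origin,
                      stringsAsFactors = FALSE)
  vcf <- NULL
  truth_path <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vcf <- file.path(dir, paste0(sample_id, ".vcf"))
    write_sim_vcf(records, genref, vcf)
    truth_path <- file.path(dir, paste0(sample_id, ".truth.tsv"))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(records = records, truth = truth, vcf = vcf,
       truth_path = truth_path)
}

# minimal deterministic VCF 4.2 serializer for simulated records
write_sim_vcf <- function(records, genref, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chrS,length=", nchar(genref$genome[[1]]), ">"),
    "##INFO=<ID=DPT,Number=1,Type=Integer,Description=\"Treated sample depth\">",
    "##INFO=<ID=DPC,Number=1,Type=Integer,Description=\"Control sample depth\">",
    "##INFO=<ID=ALTS,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
    "##INFO=<ID=AB,Number=1,Type=Float,Description=\"Allele balance\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- paste0(
    "DPT=", records$depth_tumor,
    ";DPC=", records$depth_control,
    ";ALTS=", records$alt_support,
    ifelse(is.na(records$allele_balance), "",
           paste0(";AB=", formatC(records$allele_balance, format = "f",
                                  digits = 4)))
  )
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                formatC(records$qual, format = "f", digits = 1), "PASS",
                info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a control / treated sample pair set
#'
#' Emulates the study design of a solvent-only control sharing baseline
#' mutational processes with exposed replicates: the control is drawn from
#' the baseline mixture alone; each treated replicate draws
#' `exposure_fraction` of its mutations from the exposure signature and the
#' rest from the baseline mixture. The truth tables record each mutation's
#' signature of origin, so exposure-derived mutations are identifiable.
#'
#' @param config a [simulation_config]; seeds all randomness.
#' @param dir optional run directory for FASTA/VCF/truth output.
#' @return list with `genref`, `control` and `treated` (list of
#'   [simulate_sample] results), `config`.
#' @export
simulate_pair <- function(config = simulation_config(), dir = NULL) {
  fasta <- if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    file.path(dir, "reference.fa")
  } else NULL
  genref <- generate_reference(config, fasta = fasta)  # seeds the stream
  control <- simulate_sample(genref, "control", control_weights(config),
                             config$n_control, config, dir = dir)
  treated <- lapply(seq_len(config$n_treated_samples), function(i) {
    simulate_sample(genref, paste0("treated", i), treated_weights(config),
                    config$n_treated, config, dir = dir)
  })
  list(genref = genref, control = control, treated = treated,
       config = config)
}

#' Simulate tumor cohorts with age-dependent exposure admixture
#'
#' For each sample the exposure admixture is `exposure_base +
#' exposure_slope * (age - min(age_range))`, clipped to `[0, 1]` (with a
#' warning counting clipped samples); its SBS96 catalog is a multinomial
#' draw from the corresponding baseline/exposure mixture, and an SV table
#' is drawn from the cohort's class proportions.
#'
#' @param config a [simulation_config] with non-empty `cohort_specs`.
#' @return list with `catalogs` (named list of [mutation_catalog]), `meta`
#'   (data.frame `sample_id`, `cohort`, `age`), `sv` (data.frame of SV
#'   records with `cohort`), `truth` (per-sample true admixture).
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  stopifnot(length(config$cohort_specs) > 0)
  set.seed(config$seed + 1L)
  sigs <- config$signature_set
  scheme <- sigs$scheme
  catalogs <- list()
  meta <- list()
  svs <- list()
  truth <- list()
  n_clipped <- 0L
  for (spec in config$cohort_specs) {
    for (i in seq_len(spec$n_samples)) {
      sid <- sprintf("%s_%03d", spec$label, i)
      age <- sample(seq(spec$age_range[1], spec$age_range[2]), 1)
      a <- spec$exposure_base +
        spec$exposure_slope * (age - spec$age_range[1])
      if (a < 0 || a > 1) n_clipped <- n_clipped + 1L
      a <- min(max(a, 0), 1)
      w <- (1 - a) * control_weights(config)
      w[config$exposure_signature] <- w[config$exposure_signature] + a
      freq <- as.numeric(sigs$profiles %*% w)
      counts <- stats::rmultinom(1, spec$n_mutations, freq)[, 1]
      catalogs[[sid]] <- mutation_catalog(
        sid, scheme, stats::setNames(counts, scheme$labels))
      meta[[sid]] <- data.frame(sample_id = sid, cohort = spec$label,
                                age = age, stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(sample_id = sid, admixture = a,
                                 stringsAsFactors = FALSE)
      if (!is.null(spec$n_sv) && spec$n_sv > 0) {
        cls <- sample(names(spec$sv_class_probs), spec$n_sv, replace = TRUE,
                      prob = spec$sv_class_probs)
        posA <- sample.int(1e6, spec$n_sv)
        size <- round(10^stats::runif(spec$n_sv, 2, 7))
        svs[[sid]] <- data.frame(
          sample_id = sid, cohort = spec$label, class = cls,
          chromA = "chrS", posA = posA,
          chromB = ifelse(cls == "TRA", "chrT", "chrS"),
          posB = ifelse(cls == "TRA", sample.int(1e6, spec$n_sv),
                        posA + size),
          support = stats::rpois(spec$n_sv, 10) + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_clipped > 0) {
    warning("simulate_cohorts: exposure admixture clipped to [0, 1] for ",
            n_clipped, " sample(s)")
  }
  list(
    catalogs = catalogs,
    meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    sv = if (length(svs))
      do.call(rbind, c(svs, list(make.row.names = FALSE)))
    else NULL,
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))
  )
}

#' Simulated context tracks over the synthetic reference
#'
#' Builds a three-way partition track (alternating `"exonic"`, `"intronic"`,
#' `"intergenic"` blocks) and one overlay track (`"early_replicating"`,
#' covering the first half of the chromosome), optionally written as BED.
#'
#' @param genref a [generate_reference] result.
#' @param block_bp block size of the partition (default 10 kb).
#' @param dir optional directory for BED output.
#' @return named list of [labeled_intervals].
#' @export
simulate_context_tracks <- function(genref, block_bp = 1e4, dir = NULL) {
  L <- nchar(genref$genome[[1]])
  starts <- seq(1, L, by = block_bp)
  labels3 <- rep(c("exonic", "intronic", "intergenic"),
                 length.out = length(starts))
  out <- list()
  for (lab in unique(labels3)) {
    s <- starts[labels3 == lab]
    gr <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(start = s,
                               end = pmin(s + block_bp - 1, L)))
    out[[lab]] <- labeled_intervals(lab, gr)
  }
  out[["early_replicating"]] <- labeled_intervals(
    "early_replicating",
    GenomicRanges::GRanges("chrS", IRanges::IRanges(1, floor(L / 2))))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(out)) {
      gr <- out[[lab]]$gr
      df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr))
      utils::write.table(df, file.path(dir, paste0(lab, ".bed")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  out
}
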