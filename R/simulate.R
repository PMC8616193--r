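# Deterministic synthetic-data generator. It plants a fully known miR/isomiR
# composition -- reference matures inside random stem-loop precursors, a
# genome embedding every precursor (mixed strands) with matching GFF3 loci,
# per-sample reads realizing each planted entry a known number of times,
# plus unassignable contamination -- so the whole pipeline can be validated
# offline against an exact truth count matrix.
#
# Classifiability is guaranteed by construction: planted template offsets
# stay within the arm extension, planted non-template suffixes start with a
# nucleotide that differs from the templated continuation, no shorter
# suffix resolves to a reference, and every planted sequence is checked to
# occur exactly where intended (entries violating a check are re-drawn).

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

count_occurrences <- function(needle, haystacks) {
  sum(vapply(haystacks, function(h)
    length(Biostrings::start(Biostrings::matchPattern(needle, Biostrings::DNAString(h)))),
    integer(1)))
}

#' Describe a synthetic isomiR simulation
#'
#' Defaults define the demo study: 5 precursors carrying 1-2 matures each,
#' 6 nt arm extension, two groups of 3 samples, roughly two template and two
#' non-template isomiRs planted per mature (about 40 entries in total) and
#' 5 unassignable contamination reads per sample.
#'
#' @param seed RNG seed; every downstream draw derives from it.
#' @param n_precursors number of synthetic precursors.
#' @param extension arm extension in nucleotides (0-8).
#' @param group_sizes integer length-2, samples per group.
#' @param templates_per_mature,nta_per_mature planted isomiRs per mature.
#' @param contamination unassignable 18-26 nt reads per sample.
#' @param long_junk additional 27-35 nt reads per sample, removed by the
#'   length filter (exercise the pre-filter length distribution).
#' @param min_len,max_len read length window used downstream.
#' @return a \code{simulation_spec} list.
#' @export
simulation_spec <- function(seed = 1L, n_precursors = 5L, extension = 6L,
                            group_sizes = c(3L, 3L), templates_per_mature = 2L,
                            nta_per_mature = 2L, contamination = 5L,
                            long_junk = 2L, min_len = 18L, max_len = 26L) {
  stopifnot(extension >= 0L, extension <= 8L, length(group_sizes) == 2L,
            all(group_sizes >= 1L), n_precursors >= 1L)
  structure(
    list(seed = as.integer(seed), n_precursors = as.integer(n_precursors),
         extension = as.integer(extension), group_sizes = as.integer(group_sizes),
         templates_per_mature = as.integer(templates_per_mature),
         nta_per_mature = as.integer(nta_per_mature),
         contamination = as.integer(contamination),
         long_junk = as.integer(long_junk),
         min_len = as.integer(min_len), max_len = as.integer(max_len)),
    class = "simulation_spec"
  )
}

#' Generate a synthetic dataset with a planted isomiR composition
#'
#' @param spec a [simulation_spec()].
#' @param dir optional output directory; when given, writes
#'   \code{mature.fa}, \code{precursors.fa}, \code{genome.fa},
#'   \code{loci.gff3}, one FASTQ per sample and the truth matrix
#'   \code{truth_combined.tsv}.
#' @return a \code{simulation} list: \code{matures}, \code{precursors}
#'   (data.frames), \code{genome} (named character), \code{gff}
#'   (data.frame of mature loci), \code{reads} (named list of per-sample
#'   read data.frames), \code{groups}, \code{truth} (combined count matrix
#'   with precursor-mode names), \code{truth_gff} (same counts under
#'   locus-qualified names), \code{planted} (entry bookkeeping) and
#'   \code{files} (when \code{dir} was given).
#' @export
simulate_dataset <- function(spec = simulation_spec(), dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  ext <- spec$extension

  # ---- precursors and matures ---------------------------------------------
  for (attempt in 1:50) {
    precursors <- data.frame(name = character(), sequence = character(),
                             stringsAsFactors = FALSE)
    mat <- data.frame(name = character(), sequence = character(),
                      precursor = character(), s0 = integer(),
                      stringsAsFactors = FALSE)
    for (i in seq_len(spec$n_precursors)) {
      plen <- sample(70:90, 1L)
      pseq <- rand_seq(plen)
      pname <- sprintf("mir-S%d", i)
      n_mat <- sample(1:2, 1L)
      labels <- if (n_mat == 2L) c("5p", "3p") else sample(c("5p", "3p"), 1L)
      for (lab in labels) {
        mlen <- sample(20:23, 1L)
        s0 <- if (lab == "5p") sample(8:12, 1L) else plen - mlen - sample(8:12, 1L)
        mat <- rbind(mat, data.frame(
          name = sprintf("miR-S%d-%s", i, lab),
          sequence = substr(pseq, s0 + 1L, s0 + mlen),
          precursor = pname, s0 = s0, stringsAsFactors = FALSE
        ))
      }
      precursors <- rbind(precursors, data.frame(name = pname, sequence = pseq,
                                                 stringsAsFactors = FALSE))
    }
    mat$mlen <- nchar(mat$sequence)
    # each mature must occur exactly once across all precursors
    occ <- vapply(mat$sequence, count_occurrences, integer(1),
                  haystacks = precursors$sequence)
    if (all(occ == 1L) && !anyDuplicated(mat$sequence)) break
    if (attempt == 50L) stop("could not draw unambiguous precursors", call. = FALSE)
  }

  # arm windows by index arithmetic, independent of the reference builder
  mat$ext5 <- pmin(ext, mat$s0)
  mat$ext3 <- pmin(ext, nchar(precursors$sequence[match(mat$precursor, precursors$name)]) -
                     (mat$s0 + mat$mlen))
  plen_of <- stats::setNames(nchar(precursors$sequence), precursors$name)
  pseq_of <- stats::setNames(precursors$sequence, precursors$name)
  arm_seqs <- substr(pseq_of[mat$precursor], mat$s0 - mat$ext5 + 1L,
                     mat$s0 + mat$mlen + mat$ext3)

  # ---- genome embedding (mixed strands) -----------------------------------
  chrom_of <- rep(c("chrA", "chrB"), length.out = spec$n_precursors)
  strand_of <- rep(c("+", "-"), length.out = spec$n_precursors)
  genome <- c(chrA = "", chrB = "")
  p_start <- integer(spec$n_precursors)      # 1-based genomic start of precursor
  for (i in seq_len(spec$n_precursors)) {
    chrom <- chrom_of[i]
    spacer <- rand_seq(sample(15:25, 1L))
    genome[[chrom]] <- paste0(genome[[chrom]], spacer)
    p_start[i] <- nchar(genome[[chrom]]) + 1L
    emb <- precursors$sequence[i]
    if (strand_of[i] == "-") emb <- revcomp(emb)
    genome[[chrom]] <- paste0(genome[[chrom]], emb)
  }
  genome <- vapply(genome, function(g) paste0(g, rand_seq(20L)), "")

  gi <- match(mat$precursor, precursors$name)
  gff <- data.frame(
    name = mat$name, chrom = chrom_of[gi], strand = strand_of[gi],
    stringsAsFactors = FALSE
  )
  plen <- plen_of[mat$precursor]
  gff$start <- ifelse(gff$strand == "+", p_start[gi] + mat$s0,
                      p_start[gi] + plen - (mat$s0 + mat$mlen))
  gff$end <- gff$start + mat$mlen - 1L

  locus_suffix <- sprintf("_%s(%s)", gff$chrom, gff$strand)

  # ---- planted entries -----------------------------------------------------
  # entry bookkeeping: name (precursor mode), name_gff, sequence, category
  planted <- list()
  add_planted <- function(name, name_gff, sequence, category) {
    planted[[length(planted) + 1L]] <<- list(name = name, name_gff = name_gff,
                                             sequence = sequence,
                                             category = category)
  }

  tmpl_by_mature <- vector("list", nrow(mat))   # planted templates per mature
  for (i in seq_len(nrow(mat))) {
    add_planted(mat$name[i], paste0(mat$name[i], locus_suffix[i]),
                mat$sequence[i], "refseq")
    pseq <- pseq_of[[mat$precursor[i]]]
    got <- list()
    guard <- 0L
    while (length(got) < spec$templates_per_mature && guard < 200L) {
      guard <- guard + 1L
      d5 <- sample(seq.int(-mat$ext5[i], mat$ext5[i]), 1L)
      d3 <- sample(seq.int(-mat$ext3[i], mat$ext3[i]), 1L)
      if (d5 == 0L && d3 == 0L) next
      rlen <- mat$mlen[i] - d5 + d3
      if (rlen < spec$min_len || rlen > spec$max_len) next
      rs <- mat$s0[i] + d5          # 0-based read start in precursor
      re <- mat$s0[i] + mat$mlen[i] + d3
      if (rs < 0L || re > plen_of[[mat$precursor[i]]]) next
      seq <- substr(pseq, rs + 1L, re)
      if (seq %in% mat$sequence) next
      if (count_occurrences(seq, arm_seqs) != 1L) next
      key <- paste(d5, d3)
      if (key %in% names(got)) next
      got[[key]] <- list(d5 = d5, d3 = d3, sequence = seq)
    }
    tmpl_by_mature[[i]] <- got
    for (tp in got) {
      suffix <- paste0("_t_", format_offset(tp$d5), "_", format_offset(tp$d3))
      add_planted(paste0(mat$name[i], suffix),
                  paste0(mat$name[i], locus_suffix[i], suffix),
                  tp$sequence, "template")
    }
  }

  # reference pool visible to the non-template step
  pool_seqs <- c(mat$sequence,
                 unlist(lapply(tmpl_by_mature, function(l)
                   vapply(l, `[[`, "", "sequence")), use.names = FALSE))

  planted_seqs <- function() vapply(planted, `[[`, "", "sequence")

  for (i in seq_len(nrow(mat))) {
    pseq <- pseq_of[[mat$precursor[i]]]
    made <- 0L; guard <- 0L
    while (made < spec$nta_per_mature && guard < 200L) {
      guard <- guard + 1L
      on_template <- length(tmpl_by_mature[[i]]) > 0L && stats::runif(1) < 0.5
      if (on_template) {
        tp <- tmpl_by_mature[[i]][[sample(length(tmpl_by_mature[[i]]), 1L)]]
        base_seq <- tp$sequence
        base_nm <- paste0(mat$name[i], "_t_", format_offset(tp$d5), "_",
                          format_offset(tp$d3))
        base_nm_gff <- paste0(mat$name[i], locus_suffix[i], "_t_",
                              format_offset(tp$d5), "_", format_offset(tp$d3))
        cont_pos <- mat$s0[i] + mat$mlen[i] + tp$d3    # 0-based next position
      } else {
        base_seq <- mat$sequence[i]
        base_nm <- mat$name[i]                 # NTA on a mature keeps the bare name
        base_nm_gff <- mat$name[i]
        cont_pos <- mat$s0[i] + mat$mlen[i]
      }
      k <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      if (nchar(base_seq) + k > spec$max_len) next
      cont <- if (cont_pos < nchar(pseq)) substr(pseq, cont_pos + 1L, cont_pos + 1L) else ""
      first <- sample(setdiff(c("A", "C", "G", "T"), cont), 1L)
      suffix <- paste0(first, if (k > 1L) rand_seq(k - 1L) else "")
      seq <- paste0(base_seq, suffix)
      # must stay unmapped and resolve to the intended reference at minimal k
      if (count_occurrences(seq, arm_seqs) != 0L) next
      shorter_hit <- any(vapply(seq_len(k - 1L), function(kk)
        substr(seq, 1L, nchar(seq) - kk) %in% pool_seqs, logical(1)))
      if (shorter_hit) next
      if (sum(pool_seqs == base_seq) != 1L) next
      nm <- paste0(base_nm, "_nont_0_+", k, "_", suffix)
      if (seq %in% planted_seqs()) next
      if (nm %in% vapply(planted, `[[`, "", "name")) next
      add_planted(nm, paste0(base_nm_gff, "_nont_0_+", k, "_", suffix),
                  seq, "nontemplate")
      made <- made + 1L
    }
  }

  # ---- per-sample counts and reads ----------------------------------------
  samples <- c(sprintf("g1_s%d", seq_len(spec$group_sizes[1L])),
               sprintf("g2_s%d", seq_len(spec$group_sizes[2L])))
  groups <- list(group1 = samples[seq_len(spec$group_sizes[1L])],
                 group2 = samples[spec$group_sizes[1L] + seq_len(spec$group_sizes[2L])])
  n_ent <- length(planted)
  lambda <- sample(3:15, n_ent, replace = TRUE)
  counts <- matrix(0L, nrow = n_ent, ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (e in seq_len(n_ent)) {
    counts[e, ] <- stats::rpois(length(samples), lambda[e])
    if (all(counts[e, ] == 0L)) counts[e, 1L] <- 1L
  }

  all_planted_seqs <- planted_seqs()
  reads <- list()
  for (s in samples) {
    seqs <- rep(all_planted_seqs, counts[, s])
    # unassignable contamination inside the length window
    n_con <- 0L; guard <- 0L
    while (n_con < spec$contamination && guard < 500L) {
      guard <- guard + 1L
      cs <- rand_seq(sample(spec$min_len:spec$max_len, 1L))
      if (count_occurrences(cs, arm_seqs) != 0L) next
      pref_hit <- any(vapply(0:3, function(kk)
        nchar(cs) - kk >= 1L && substr(cs, 1L, nchar(cs) - kk) %in% pool_seqs,
        logical(1)))
      if (pref_hit || cs %in% all_planted_seqs) next
      seqs <- c(seqs, cs)
      n_con <- n_con + 1L
    }
    # long junk removed by the length filter
    if (spec$long_junk > 0L) {
      seqs <- c(seqs, vapply(seq_len(spec$long_junk), function(...)
        rand_seq(sample(27:35, 1L)), ""))
    }
    seqs <- sample(seqs)
    reads[[s]] <- data.frame(
      read_id = sprintf("%s_r%04d", s, seq_along(seqs)),
      sequence = seqs, stringsAsFactors = FALSE
    )
  }

  truth_df <- function(names) {
    df <- data.frame(name = names, counts, stringsAsFactors = FALSE,
                     check.names = FALSE, row.names = NULL)
    df <- df[order(df$name, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  truth <- truth_df(vapply(planted, `[[`, "", "name"))
  truth_gff <- truth_df(vapply(planted, `[[`, "", "name_gff"))

  sim <- list(
    matures = mature_records(mat$name, mat$sequence),
    precursors = precursors, genome = genome, gff = gff,
    reads = reads, groups = groups, truth = truth, truth_gff = truth_gff,
    planted = planted, spec = spec
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    w_fa <- function(nm, sq, f) {
      ss <- Biostrings::DNAStringSet(sq); names(ss) <- nm
      Biostrings::writeXStringSet(ss, file.path(dir, f))
      file.path(dir, f)
    }
    files <- c(
      mature = w_fa(mat$name, mat$sequence, "mature.fa"),
      precursors = w_fa(precursors$name, precursors$sequence, "precursors.fa"),
      genome = w_fa(names(genome), unname(genome), "genome.fa")
    )
    gr <- GenomicRanges::GRanges(
      seqnames = gff$chrom,
      ranges = IRanges::IRanges(start = gff$start, end = gff$end),
      strand = gff$strand, type = "miRNA", Name = gff$name, ID = gff$name
    )
    rtracklayer::export.gff3(gr, file.path(dir, "loci.gff3"))
    files["gff"] <- file.path(dir, "loci.gff3")
    for (s in samples) {
      ss <- Biostrings::DNAStringSet(reads[[s]]$sequence)
      names(ss) <- reads[[s]]$read_id
      f <- file.path(dir, paste0(s, ".fastq"))
      Biostrings::writeXStringSet(ss, f, format = "fastq")
      files[s] <- f
    }
    write_count_matrix(truth, file.path(dir, "truth_combined.tsv"))
    files["truth"] <- file.path(dir, "truth_combined.tsv")
    sim$files <- files
  }
  class(sim) <- "simulation"
  sim
}
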