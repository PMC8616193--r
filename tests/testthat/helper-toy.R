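# Shared toy fixtures, built in code.

# One mature embedded mid-precursor; with ext = 3 the arm is
# "CTAGGATCCGTACGTTAG" and the mature sits at offset 3.
toy1 <- function(ext = 3L) {
  matures <- mature_records("miR-T1-3p", "GGATCCGTACGT")
  precursors <- data.frame(name = "pre-T1", sequence = "AAGCTAGGATCCGTACGTTAGC",
                           stringsAsFactors = FALSE)
  arms <- build_arms_from_precursors(matures, precursors, ext = ext)
  list(matures = matures, precursors = precursors, arms = arms,
       genome = c(chrT = "NNNNAAGCTAGGATCCGTACGTTAGCNNNN"),
       gff = data.frame(name = "miR-T1-3p", chrom = "chrT", start = 11L,
                        end = 22L, strand = "+", stringsAsFactors = FALSE))
}

toy_reads <- function(seqs, prefix = "r") {
  data.frame(read_id = paste0(prefix, seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

# independent oracle: scan every (read, arm, offset) triple
brute_force_hits <- function(read, arms) {
  out <- list()
  L <- nchar(read)
  for (j in seq_len(nrow(arms))) {
    a <- arms$sequence[j]
    if (nchar(a) < L) next
    for (off in 0:(nchar(a) - L)) {
      if (substr(a, off + 1L, off + L) == read) {
        out[[length(out) + 1L]] <- data.frame(ref_id = arms$arm_id[j],
                                              pos = off,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(ref_id = character(), pos = integer(), stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a small, fast simulation used where full demo size is unnecessary
small_spec <- function(seed) {
  simulation_spec(seed = seed, n_precursors = 2L, group_sizes = c(1L, 1L),
                  templates_per_mature = 1L, nta_per_mature = 1L,
                  contamination = 2L, long_junk = 1L)
}

classify_sim <- function(sim, mode = c("precursor", "gff")) {
  mode <- match.arg(mode)
  arms <- if (mode == "precursor") {
    build_arms_from_precursors(sim$matures, sim$precursors,
                               ext = sim$spec$extension)
  } else {
    build_arms_from_gff(sim$gff, sim$genome, ext = sim$spec$extension)
  }
  raw <- lapply(sim$reads, align_exact, arms = arms)
  filt <- lapply(raw, function(a) {
    ids <- unique(a$read_id[nchar(a$sequence) >= sim$spec$min_len &
                              nchar(a$sequence) <= sim$spec$max_len])
    a[a$read_id %in% ids, , drop = FALSE]
  })
  res <- classify_samples(filt, arms, sim$matures)
  list(arms = arms, raw = raw, filtered = filt, result = res,
       matrices = build_count_matrices(res, sim$groups))
}
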