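toy_classify <- function(seqs, detect_nta = TRUE, ext = 3L) {
  t1 <- toy1(ext = ext)
  aln <- align_exact(toy_reads(seqs), t1$arms)
  classify_samples(list(s1 = aln), t1$arms, t1$matures, detect_nta = detect_nta)
}

test_that("the five canonical reads classify to their exact names", {
  res <- toy_classify(c("GGATCCGTACGT",      # identity
                        "AGGATCCGTACGT",     # 5' extension
                        "GGATCCGTACGTT",     # 3' extension
                        "GGATCCGTACGTA",     # non-template A on the mature
                        "AGGATCCGTACGTC"))   # non-template C on a template
  expect_setequal(res$entries$name,
                  c("miR-T1-3p",
                    "miR-T1-3p_t_-1_0",
                    "miR-T1-3p_t_0_+1",
                    "miR-T1-3p_nont_0_+1_A",
                    "miR-T1-3p_t_-1_0_nont_0_+1_C"))
  ent <- res$entries
  expect_equal(ent$category[ent$name == "miR-T1-3p"], "refseq")
  expect_equal(ent$subtype[ent$name == "miR-T1-3p_t_-1_0"], "5p_shift")
  expect_equal(ent$subtype[ent$name == "miR-T1-3p_t_0_+1"], "3p_shift")
  expect_equal(ent$category[ent$name == "miR-T1-3p_nont_0_+1_A"], "nontemplate")
  expect_equal(ent$d5[ent$name == "miR-T1-3p_t_-1_0_nont_0_+1_C"], -1L)
  expect_equal(ent$nta[ent$name == "miR-T1-3p_t_-1_0_nont_0_+1_C"], "C")
})

test_that("classification hierarchy is sound", {
  res <- toy_classify(c("GGATCCGTACGT", "AGGATCCGTACGT", "GGATCCGTACGTA",
                        "ACGTACGTACGTACGTACGT"))
  ent <- res$entries
  # refseq and template are disjoint; non-template entries only from unmapped
  expect_false(any(duplicated(ent$sequence)))
  expect_equal(sum(ent$category == "refseq"), 1L)
  tot <- res$totals
  expect_equal(tot$refseq + tot$template + tot$nontemplate + tot$unassigned,
               tot$total)
  expect_equal(res$unassigned$s1$sequence, "ACGTACGTACGTACGTACGT")
})

test_that("without NTA detection, candidate reads stay unassigned", {
  res <- toy_classify(c("GGATCCGTACGT", "GGATCCGTACGTA"), detect_nta = FALSE)
  expect_equal(nrow(res$entries), 1L)
  expect_equal(res$totals$unassigned, 1L)
})

test_that("the NTA reference pool spans all samples of the run", {
  t1 <- toy1()
  # template discovered only in sample s1; its NTA variant appears only in s2
  a1 <- align_exact(toy_reads("AGGATCCGTACGT"), t1$arms)
  a2 <- align_exact(toy_reads("AGGATCCGTACGTC"), t1$arms)
  res <- classify_samples(list(s1 = a1, s2 = a2), t1$arms, t1$matures)
  expect_true("miR-T1-3p_t_-1_0_nont_0_+1_C" %in% res$counts$s2$name)
  # classified alone, the same read cannot resolve (no template in pool)
  solo <- classify_samples(list(s2 = a2), t1$arms, t1$matures)
  expect_equal(nrow(solo$entries), 0L)
  expect_equal(solo$totals$unassigned, 1L)
})

test_that("the smallest non-template suffix wins", {
  t1 <- toy1()
  # mature + "TA": "T" is templated (continuation), so the read maps as a
  # template isomiR rather than becoming a 2 nt addition
  res <- toy_classify("GGATCCGTACGTTA")
  expect_equal(res$entries$name, "miR-T1-3p_t_0_+2")
  # mature + "AT": unmapped; 1 nt suffix does not resolve (prefix ends ...A),
  # the 2 nt suffix resolves on the mature
  res2 <- toy_classify("GGATCCGTACGTAT")
  expect_equal(res2$entries$name[res2$entries$category == "nontemplate"],
               "miR-T1-3p_nont_0_+2_AT")
})

test_that("offsets are bounded by the applied extension", {
  for (seed in 4:6) {
    sim <- simulate_dataset(small_spec(seed = seed))
    cs <- classify_sim(sim)
    ent <- cs$result$entries
    tmpl <- ent[ent$category == "template", ]
    ext5 <- stats::setNames(cs$arms$ext5_applied, cs$arms$arm_id)
    ext3 <- stats::setNames(cs$arms$ext3_applied, cs$arms$arm_id)
    for (i in seq_len(nrow(tmpl))) {
      pa <- strsplit(tmpl$parent_arms[i], ";", fixed = TRUE)[[1]]
      expect_true(all(tmpl$d5[i] >= -ext5[pa]))
      expect_true(all(tmpl$d3[i] <= ext3[pa]))
    }
  }
})

test_that("stored entries re-classify to their own names in isolation", {
  sim <- simulate_dataset(small_spec(seed = 9))
  cs <- classify_sim(sim)
  ent <- cs$result$entries
  for (i in seq_len(nrow(ent))) {
    aln <- align_exact(toy_reads(ent$sequence[i]), cs$arms)
    solo <- classify_samples(list(x = aln), cs$arms, sim$matures)
    # NTA-on-template entries need their base template in the pool
    if (ent$category[i] == "nontemplate" && grepl("_t_", ent$name[i])) {
      base <- sub("_nont_.*$", "", ent$name[i])
      base_seq <- ent$sequence[match(base, ent$name)]
      aln2 <- align_exact(toy_reads(c(base_seq, ent$sequence[i])), cs$arms)
      solo <- classify_samples(list(x = aln2), cs$arms, sim$matures)
    }
    expect_true(ent$name[i] %in% solo$entries$name)
  }
})

test_that("a read matching two identical matures collapses their parents", {
  m_seq <- "ACGGATTCCGGAACCTTGGA"
  matures <- mature_records(c("miR-A-5p", "miR-B-5p"), c(m_seq, m_seq))
  genome <- c(chr1 = paste0("TTTTTTTT", m_seq, "CCCCCCCC"),
              chr2 = paste0("GGGGGGGG", m_seq, "AAAAAAAA"))
  gff <- data.frame(name = c("miR-A-5p", "miR-B-5p"),
                    chrom = c("chr1", "chr2"), start = 9L,
                    end = 8L + nchar(m_seq), strand = "+",
                    stringsAsFactors = FALSE)
  arms <- build_arms_from_gff(gff, genome, ext = 3L)
  aln <- align_exact(toy_reads(m_seq), arms)
  res <- classify_samples(list(s1 = aln), arms, matures)
  expect_equal(res$entries$name[res$entries$category == "refseq"],
               "miR-A-5p_chr1(+)_miR-B-5p_chr2(+)")
  # counted once for the read despite two parents
  expect_equal(res$totals$refseq, 1L)
})

test_that("count matrices are conservative, complete and group-ordered", {
  sim <- simulate_dataset(small_spec(seed = 10))
  cs <- classify_sim(sim)
  mats <- cs$matrices
  samples <- unlist(sim$groups, use.names = FALSE)
  expect_equal(names(mats$combined), c("name", samples))
  expect_false(anyDuplicated(mats$combined$name) > 0)
  # column sums equal assigned reads per sample
  tot <- cs$result$totals
  for (s in samples) {
    expect_equal(sum(mats$combined[[s]]),
                 tot$total[tot$sample == s] - tot$unassigned[tot$sample == s])
  }
  expect_length(mats$categories, 6L)
  for (nm in names(mats$categories)) {
    expect_true("sequence" %in% names(mats$categories[[nm]]))
  }
  expect_error(build_count_matrices(cs$result,
                                    list(g1 = samples[1], g2 = samples[1])),
               "both groups")
})

test_that("the arm database is sparse, sorted and deterministic", {
  sim <- simulate_dataset(small_spec(seed = 12))
  cs <- classify_sim(sim)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_arm_database(cs$result, cs$arms, f1)
  export_arm_database(cs$result, cs$arms, f2)
  expect_identical(readLines(f1), readLines(f2))
  db <- utils::read.delim(f1, stringsAsFactors = FALSE)
  expect_true(all(db$count > 0))
  expect_true(all(db$arm_id %in% cs$arms$arm_id))
  expect_equal(db$arm_id, sort(db$arm_id, method = "radix"))
  # every counted entry with a known arm appears
  known <- cs$result$entries$name
  expect_true(all(unlist(lapply(cs$result$counts, `[[`, "name")) %in% known))
})
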