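make_de_rows <- function(lfc, padj, names = NULL, base_mean = NA_real_,
                         pvalue = NA_real_) {
  data.frame(
    name = names %||% sprintf("miR-%d-5p", seq_along(lfc)),
    base_mean = rep_len(base_mean, length(lfc)),
    log2fc = lfc, pvalue = rep_len(pvalue, length(lfc)), padj = padj,
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("profile statistics normalize, window and count as defined", {
  sim <- simulate_dataset(small_spec(seed = 21))
  cs <- classify_sim(sim)
  stats <- profile_stats(cs$result, cs$raw, sim$groups)

  # breakdown sums to 100 per group
  for (g in names(sim$groups)) {
    p <- stats$category_breakdown$percent[stats$category_breakdown$group == g]
    expect_equal(sum(p), 100, tolerance = 1e-8)
  }
  # length distribution covers the 20-35 window and sees pre-filter reads
  expect_equal(range(stats$length_distribution$length), c(20L, 35L))
  long <- stats$length_distribution[stats$length_distribution$length > 26, ]
  expect_gt(sum(long$unmapped), 0)   # the simulated long junk is visible

  # redundant >= non-redundant cell-wise
  sd <- stats$subtype_distribution
  expect_true(all(sd$redundant >= sd$non_redundant))

  expect_error(profile_stats(cs$result, cs$raw,
                             list(g1 = character(), g2 = sim$groups$group2)),
               "empty")
})

test_that("breakdown percentages equal the planted composition exactly", {
  sim <- simulate_dataset(small_spec(seed = 22))
  cs <- classify_sim(sim)
  stats <- profile_stats(cs$result, cs$raw, sim$groups)
  cats <- c("refseq", "template", "nontemplate")
  planted_cat <- vapply(sim$planted, `[[`, "", "category")
  truth_counts <- as.matrix(sim$truth[, -1])
  name_cat <- stats::setNames(planted_cat,
                              vapply(sim$planted, `[[`, "", "name"))[sim$truth$name]
  for (g in names(sim$groups)) {
    ss <- sim$groups[[g]]
    planted_by_cat <- vapply(cats, function(cc)
      sum(truth_counts[name_cat == cc, ss]), numeric(1))
    n_unassigned <- sum(vapply(ss, function(s) {
      tot <- cs$result$totals
      tot$unassigned[tot$sample == s]
    }, numeric(1)))
    denom <- sum(planted_by_cat) + n_unassigned
    got <- stats$category_breakdown[stats$category_breakdown$group == g, ]
    for (cc in cats) {
      expect_equal(got$percent[got$category == cc],
                   100 * planted_by_cat[[cc]] / denom)
    }
  }
})

test_that("DE tables in both dialects map to the common row shape", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("name\tbaseMean\tlog2FoldChange\tlfcSE\tstat\tpvalue\tpadj",
      "miR-1-3p\t120.5\t2.4\t0.3\t8.0\t1e-8\t1e-6"), collapse = "\n"), f)
  rows <- read_de_table(f)
  expect_equal(attr(rows, "dialect"), "deseq2")
  expect_equal(rows$base_mean, 120.5)
  expect_equal(rows$log2fc, 2.4)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("name\tlogFC\tlogCPM\tPValue\tFDR", "miR-1-3p\t-3.1\t5.0\t1e-5\t1e-3"),
    collapse = "\n"), f2)
  rows2 <- read_de_table(f2)
  expect_equal(attr(rows2, "dialect"), "edger")
  expect_true(is.na(rows2$base_mean))
  expect_equal(rows2$padj, 1e-3)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tfoo\tbar\nx\t1\t2", f3)
  expect_error(read_de_table(f3), "columns found")
})

test_that("publication-style typesetting of numbers is ingested correctly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
               "miR-200b-3p_chr1(+)\t2838.44\t−9.29\t\t1.15 × 10^−43"),
             f)
  rows <- read_de_table(f)
  expect_equal(rows$base_mean, 2838.44)
  expect_equal(rows$log2fc, -9.29)
  expect_equal(rows$padj, 1.15e-43)
})

test_that("default DE filter keeps strict padj<0.05 and |lfc|>1", {
  rows <- make_de_rows(lfc = c(2.0, 0.5, -3.2, -1.5),
                       padj = c(1e-4, 1e-5, 0.3, 1e-7))
  kept <- filter_de(rows)
  expect_equal(kept$name, rows$name[c(1, 4)])

  boundary <- make_de_rows(lfc = 1.0, padj = 1e-4)
  expect_equal(nrow(filter_de(boundary)), 0L)

  # all thresholds off: identity
  expect_equal(filter_de(rows, min_abs_log2fc = NULL, max_padj = NULL)$name,
               rows$name)

  # NA padj dropped while the threshold is active
  na_rows <- make_de_rows(lfc = c(3, 3), padj = c(NA, 1e-4))
  expect_equal(nrow(filter_de(na_rows)), 1L)
})

test_that("tightening any threshold never grows the kept set", {
  set.seed(77)
  rows <- make_de_rows(lfc = round(runif(60, -10, 10), 2),
                       padj = signif(runif(60), 3),
                       base_mean = round(runif(60, 0, 500), 1),
                       pvalue = signif(runif(60), 3))
  for (i in 1:100) {
    th <- list(min_base_mean = runif(1, 0, 200),
               min_abs_log2fc = runif(1, 0, 5),
               max_pvalue = runif(1),
               max_padj = runif(1))
    kept <- do.call(filter_de, c(list(rows), th))
    which_th <- sample(names(th), 1)
    th2 <- th
    th2[[which_th]] <- if (startsWith(which_th, "min")) {
      th[[which_th]] + runif(1, 0, 2)
    } else {
      th[[which_th]] * runif(1)
    }
    kept2 <- do.call(filter_de, c(list(rows), th2))
    expect_true(all(kept2$name %in% kept$name))
  }
})

test_that("top_de splits by category, ranks and bounds n", {
  rows <- make_de_rows(
    lfc = c(9.2, 14.3, 7.4, -5, 3),
    padj = c(1e-5, 1e-9, 1e-4, 1e-3, 1e-2),
    names = c("miR-a-5p", "miR-b-5p", "miR-c-5p",
              "miR-a-5p_t_0_-1", "miR-b-5p_nont_0_+1_A")
  )
  top <- top_de(rows, n = 10)
  expect_equal(top$refseq_template$name[1:3],
               c("miR-b-5p", "miR-a-5p", "miR-c-5p"))   # 14.3 > 9.2 > 7.4
  expect_equal(top$nontemplate$name, "miR-b-5p_nont_0_+1_A")
  expect_equal(nrow(top$refseq_template), 4L)            # no padding

  by_p <- top_de(rows, n = 10, rank_by = "padj")
  expect_equal(by_p$refseq_template$name[1], "miR-b-5p")

  ties <- make_de_rows(lfc = c(2, 2), padj = c(1e-3, 1e-3),
                       names = c("miR-z-5p", "miR-a-5p"))
  expect_equal(top_de(ties, 10)$refseq_template$name, c("miR-a-5p", "miR-z-5p"))

  expect_error(top_de(rows, n = 9), "between 10 and 50")
  expect_error(top_de(rows, n = 51), "between 10 and 50")

  bad <- make_de_rows(lfc = 2, padj = 1e-3, names = "miR-1_t_bad")
  expect_warning(top_de(rbind(rows, bad), 10), "failed to parse")
})

test_that("arm summary strips variant segments and ranks arms by max |lfc|", {
  rows <- make_de_rows(
    lfc = c(-9.29, -8.26, -8.49, 5.0),
    padj = rep(1e-6, 4),
    names = c("miR-200b-3p_chr1(+)", "miR-200b-3p_chr1(+)_t_+1_+1",
              "miR-200b-3p_chr1(+)_t_+1_+1_nont_0_+1_A", "miR-9-5p_chr5(-)")
  )
  s <- arm_summary(rows, n_arms = 10)
  expect_setequal(unique(s$arm), c("miR-200b-3p_chr1(+)", "miR-9-5p_chr5(-)"))
  expect_equal(sum(s$arm == "miR-200b-3p_chr1(+)"), 3L)
  # ranked by max |lfc|: the miR-200b arm (9.29) precedes miR-9 (5.0)
  expect_equal(s$arm[1], "miR-200b-3p_chr1(+)")
  expect_equal(s$name[1], "miR-200b-3p_chr1(+)")

  one <- arm_summary(rows[4, , drop = FALSE], n_arms = 5)
  expect_equal(nrow(one), 1L)

  top1 <- arm_summary(rows, n_arms = 1)
  expect_equal(unique(top1$arm), "miR-200b-3p_chr1(+)")
  # every parseable filtered row appears exactly once given enough arms
  expect_equal(sort(s$name), sort(rows$name))
})

test_that("report renderers emit PDFs plus sidecars that match the inputs", {
  sim <- simulate_dataset(small_spec(seed = 30))
  cs <- classify_sim(sim)
  stats <- profile_stats(cs$result, cs$raw, sim$groups)
  dir <- withr::local_tempdir()
  pdf1 <- file.path(dir, "profile.pdf")
  files <- render_profile_report(stats, pdf1)
  expect_true(file.exists(pdf1) && file.size(pdf1) > 0)
  back <- utils::read.delim(files[["category_breakdown"]])
  expect_equal(back$percent, stats$category_breakdown$percent)

  rows <- make_de_rows(lfc = c(3, -2), padj = c(1e-3, 1e-4),
                       names = c("miR-1-5p", "miR-1-5p_t_0_-1"))
  pdf2 <- file.path(dir, "de.pdf")
  de_files <- render_de_report(top_de(rows, 10), arm_summary(rows, 5), pdf2)
  expect_true(file.exists(pdf2) && file.size(pdf2) > 0)

  # empty DE input still renders a report
  empty <- rows[0, , drop = FALSE]
  pdf3 <- file.path(dir, "de_empty.pdf")
  expect_no_error(render_de_report(top_de(empty, 10), arm_summary(empty, 5), pdf3))
  expect_true(file.exists(pdf3))

  # determinism of sidecar tables
  pdf4 <- file.path(dir, "profile2.pdf")
  files2 <- render_profile_report(stats, pdf4)
  expect_identical(readLines(files[["subtype_distribution"]]),
                   readLines(files2[["subtype_distribution"]]))
})
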