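# Profile statistics (length distribution, category breakdown, template
# subtype distribution), ingestion and filtering of external differential
# expression tables, top-entry / per-arm summaries, and PDF report
# rendering. Chart correctness is asserted on the tab-separated sidecar
# tables each renderer emits next to the PDF; pixels are not the scientific
# content.

#' Compute isomiR profile statistics for a two-group run
#'
#' The length distribution is computed over ALL alignment records, i.e.
#' before the length filter, inside a display window (default 20-35 nt);
#' category percentages use the length-filtered read totals from the
#' classification as denominator; subtype statistics cover template entries
#' only, in redundant (read-weighted) and non-redundant (unique-sequence)
#' modes.
#'
#' @param result an \code{isomir_result} over length-filtered reads.
#' @param raw_alignments named list of per-sample alignment data.frames
#'   BEFORE length filtering (the raw SAM content).
#' @param groups named list of two character vectors of sample ids.
#' @param len_window integer length-2 display window for the length
#'   distribution (default \code{c(20, 35)}).
#' @return list with data.frames \code{length_distribution} (group, length,
#'   mapped, unmapped), \code{category_breakdown} (group, category,
#'   percent) and \code{subtype_distribution} (group, subtype, redundant,
#'   non_redundant).
#' @export
profile_stats <- function(result, raw_alignments, groups,
                          len_window = c(20L, 35L)) {
  stopifnot(inherits(result, "isomir_result"), length(groups) == 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- c("group1", "group2")
  }
  if (any(lengths(groups) == 0L)) stop("empty sample group", call. = FALSE)

  lens <- seq.int(len_window[1L], len_window[2L])
  ld <- list(); cb <- list(); sd <- list()
  ent <- result$entries
  tmpl_names <- ent$name[ent$category == "template"]
  subtype_of <- stats::setNames(ent$subtype, ent$name)

  for (g in names(groups)) {
    # length distribution over all raw records, one row per read
    mapped_cnt <- stats::setNames(integer(length(lens)), lens)
    unmapped_cnt <- mapped_cnt
    for (s in groups[[g]]) {
      aln <- raw_alignments[[s]]
      if (is.null(aln)) stop("no raw alignments for sample ", s, call. = FALSE)
      rd <- unique(aln[, c("read_id", "sequence")])
      is_mapped <- rd$read_id %in% aln$read_id[aln$mapped]
      l <- nchar(rd$sequence)
      keep <- l >= len_window[1L] & l <= len_window[2L]
      tm <- table(factor(l[keep & is_mapped], levels = lens))
      tu <- table(factor(l[keep & !is_mapped], levels = lens))
      mapped_cnt <- mapped_cnt + as.integer(tm)
      unmapped_cnt <- unmapped_cnt + as.integer(tu)
    }
    ld[[g]] <- data.frame(group = g, length = lens, mapped = mapped_cnt,
                          unmapped = unmapped_cnt, stringsAsFactors = FALSE)

    # category breakdown over length-filtered reads
    tot <- result$totals[result$totals$sample %in% groups[[g]], , drop = FALSE]
    if (!nrow(tot)) stop("no classified samples in group ", g, call. = FALSE)
    denom <- sum(tot$total)
    if (denom == 0L) stop("group ", g, " has no length-filtered reads", call. = FALSE)
    counts <- c(refseq = sum(tot$refseq), template = sum(tot$template),
                nontemplate = sum(tot$nontemplate),
                unassigned = sum(tot$unassigned))
    cb[[g]] <- data.frame(group = g, category = names(counts),
                          percent = 100 * as.numeric(counts) / denom,
                          stringsAsFactors = FALSE)

    # subtype distribution over template entries
    red <- c("3p_shift" = 0L, "5p_shift" = 0L, "both_shift" = 0L)
    nonred_names <- list("3p_shift" = character(), "5p_shift" = character(),
                         "both_shift" = character())
    for (s in groups[[g]]) {
      cnt <- result$counts[[s]]
      sub <- cnt[cnt$name %in% tmpl_names, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        st <- subtype_of[[sub$name[i]]]
        red[[st]] <- red[[st]] + sub$count[i]
        nonred_names[[st]] <- c(nonred_names[[st]], sub$name[i])
      }
    }
    sd[[g]] <- data.frame(group = g, subtype = names(red),
                          redundant = as.integer(red),
                          non_redundant = lengths(lapply(nonred_names, unique)),
                          stringsAsFactors = FALSE)
  }
  out <- list(length_distribution = do.call(rbind, c(ld, list(make.row.names = FALSE))),
              category_breakdown = do.call(rbind, c(cb, list(make.row.names = FALSE))),
              subtype_distribution = do.call(rbind, c(sd, list(make.row.names = FALSE))))
  out
}

# lenient numeric parser: Unicode minus and "a x 10^b" scientific notation
# as typeset in publication tables
parse_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("\u2212", "-", x)
  x <- gsub("\\s*[x\u00d7]\\s*10\\^?(-?[0-9]+)\\^?", "e\\1", x)
  x <- gsub(",", "", x)
  suppressWarnings(as.numeric(x))
}

#' Read an external differential-expression result table
#'
#' Supports the DESeq2 column dialect (\code{baseMean},
#' \code{log2FoldChange}, \code{pvalue}, \code{padj}) and the edgeR dialect
#' (\code{logFC}, \code{PValue}, \code{FDR}; no base mean). The row
#' identifier is taken from the first column (or row names). Numbers typeset
#' with a Unicode minus or \code{"x 10^k"} notation are accepted.
#'
#' @param path tab-separated file with a header row.
#' @param dialect \code{"auto"} (detect by header), \code{"deseq2"} or
#'   \code{"edger"}.
#' @return data.frame with columns \code{name}, \code{base_mean},
#'   \code{log2fc}, \code{pvalue}, \code{padj}; attribute \code{"dialect"}
#'   records the detected dialect.
#' @export
read_de_table <- function(path, dialect = c("auto", "deseq2", "edger")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  hdr <- names(tab)
  if (dialect == "auto") {
    dialect <- if ("log2FoldChange" %in% hdr) "deseq2"
      else if ("logFC" %in% hdr) "edger"
      else stop("cannot detect DE table dialect; columns found: ",
                paste(hdr, collapse = ", "), call. = FALSE)
  }
  need <- if (dialect == "deseq2") c("log2FoldChange", "pvalue", "padj")
          else c("logFC", "PValue", "FDR")
  if (!all(need %in% hdr)) {
    stop(sprintf("DE table lacks %s column(s) %s; columns found: %s", dialect,
                 paste(setdiff(need, hdr), collapse = ", "),
                 paste(hdr, collapse = ", ")), call. = FALSE)
  }
  name_col <- setdiff(hdr, c("baseMean", "log2FoldChange", "lfcSE", "stat",
                             "pvalue", "padj", "logFC", "logCPM", "PValue",
                             "FDR", "LR", "F"))[1L]
  name <- if (!is.na(name_col)) tab[[name_col]] else rownames(tab)
  out <- if (dialect == "deseq2") {
    data.frame(
      name = name,
      base_mean = if ("baseMean" %in% hdr) parse_numeric(tab$baseMean) else NA_real_,
      log2fc = parse_numeric(tab$log2FoldChange),
      pvalue = parse_numeric(tab$pvalue),
      padj = parse_numeric(tab$padj),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = name, base_mean = NA_real_, log2fc = parse_numeric(tab$logFC),
      pvalue = parse_numeric(tab$PValue), padj = parse_numeric(tab$FDR),
      stringsAsFactors = FALSE
    )
  }
  attr(out, "dialect") <- dialect
  out
}

#' Filter a differential-expression table
#'
#' Default thresholds: adjusted p < 0.05 and |log2FC| > 1, both strict.
#' A \code{NULL} threshold deactivates its criterion; rows with missing
#' adjusted p are dropped while a padj threshold is active; the base-mean
#' criterion is skipped when the table carries no base mean (edgeR dialect).
#'
#' @param rows data.frame from [read_de_table()].
#' @param min_base_mean minimum base mean (inclusive), or \code{NULL}.
#' @param min_abs_log2fc |log2FC| must exceed this (strict; default 1).
#' @param max_pvalue raw p threshold (strict), or \code{NULL}.
#' @param max_padj adjusted p threshold (strict; default 0.05).
#' @return the filtered data.frame.
#' @export
filter_de <- function(rows, min_base_mean = NULL, min_abs_log2fc = 1,
                      max_pvalue = NULL, max_padj = 0.05) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(min_abs_log2fc)) {
    stopifnot(min_abs_log2fc >= 0)
    keep <- keep & !is.na(rows$log2fc) & abs(rows$log2fc) > min_abs_log2fc
  }
  if (!is.null(max_padj)) {
    stopifnot(max_padj >= 0)
    keep <- keep & !is.na(rows$padj) & rows$padj < max_padj
  }
  if (!is.null(max_pvalue)) {
    stopifnot(max_pvalue >= 0)
    keep <- keep & !is.na(rows$pvalue) & rows$pvalue < max_pvalue
  }
  if (!is.null(min_base_mean) && !all(is.na(rows$base_mean))) {
    stopifnot(min_base_mean >= 0)
    keep <- keep & !is.na(rows$base_mean) & rows$base_mean >= min_base_mean
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dialect") <- attr(rows, "dialect")
  out
}

de_category <- function(names) {
  vapply(names, function(nm) {
    p <- tryCatch(parse_name(nm), error = function(e) NULL)
    if (is.null(p)) return(NA_character_)
    if (nzchar(p$nta)) "nontemplate"
    else if (!is.na(p$d5)) "template"
    else "refseq"
  }, "")
}

#' Select the top differentially expressed entries
#'
#' Rows are split by entry category (parsed from the name) into a RefSeq +
#' template list and a non-template list, each ranked by the requested key
#' (|log2FC| descending by default, or adjusted p ascending), ties broken by
#' name, and truncated to \code{n}.
#'
#' @param rows filtered data.frame ([filter_de()]).
#' @param n number of entries per list, 10-50.
#' @param rank_by \code{"abs_log2fc"} or \code{"padj"}.
#' @return list with data.frames \code{refseq_template} and
#'   \code{nontemplate}.
#' @export
top_de <- function(rows, n = 20L, rank_by = c("abs_log2fc", "padj")) {
  rank_by <- match.arg(rank_by)
  n <- as.integer(n)
  if (n < 10L || n > 50L) stop("n must be between 10 and 50", call. = FALSE)
  cat <- de_category(rows$name)
  if (anyNA(cat)) {
    warning(sum(is.na(cat)), " row name(s) failed to parse; excluded from top lists",
            call. = FALSE)
  }
  pick <- function(sub) {
    o <- if (rank_by == "abs_log2fc") {
      order(-abs(sub$log2fc), sub$name, method = "radix")
    } else {
      order(sub$padj, sub$name, method = "radix")
    }
    sub <- sub[o, , drop = FALSE]
    sub <- utils::head(sub, n)
    rownames(sub) <- NULL
    sub
  }
  list(
    refseq_template = pick(rows[!is.na(cat) & cat %in% c("refseq", "template"), ,
                                drop = FALSE]),
    nontemplate = pick(rows[!is.na(cat) & cat == "nontemplate", , drop = FALSE])
  )
}

#' Summarize differentially expressed entries by miR arm
#'
#' The arm key is the base name plus locus suffixes (offset and addition
#' segments stripped). Arms are ranked by the maximum |log2FC| among their
#' members; members are sorted by |log2FC| descending.
#'
#' @param rows filtered data.frame ([filter_de()]).
#' @param n_arms number of top arms to keep.
#' @return data.frame with columns \code{arm}, \code{name}, \code{log2fc},
#'   ordered by arm rank then member rank.
#' @export
arm_summary <- function(rows, n_arms = 10L) {
  if (!nrow(rows)) {
    return(data.frame(arm = character(), name = character(),
                      log2fc = numeric(), stringsAsFactors = FALSE))
  }
  arm <- vapply(rows$name, function(nm) {
    p <- tryCatch(parse_name(nm), error = function(e) NULL)
    if (is.null(p)) return(NA_character_)
    format_name(name_parts(p$base, p$loci_suffixes))
  }, "")
  if (anyNA(arm)) {
    warning(sum(is.na(arm)), " row name(s) failed to parse; excluded from arm summary",
            call. = FALSE)
  }
  sub <- rows[!is.na(arm), , drop = FALSE]
  sub$arm <- arm[!is.na(arm)]
  arm_max <- tapply(abs(sub$log2fc), sub$arm, max)
  top_arms <- names(arm_max)[order(-arm_max, names(arm_max), method = "radix")]
  top_arms <- utils::head(top_arms, n_arms)
  sub <- sub[sub$arm %in% top_arms, , drop = FALSE]
  sub <- sub[order(match(sub$arm, top_arms), -abs(sub$log2fc), sub$name,
                   method = "radix"), , drop = FALSE]
  out <- data.frame(arm = sub$arm, name = sub$name, log2fc = sub$log2fc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

write_sidecar <- function(df, pdf_path, suffix) {
  path <- paste0(tools::file_path_sans_ext(pdf_path), "_", suffix, ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# simple radar/spider chart on base graphics
draw_radar <- function(values_list, labels, title) {
  k <- length(labels)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k
  vmax <- max(1, unlist(values_list))
  graphics::plot(0, 0, type = "n", xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                 axes = FALSE, xlab = "", ylab = "", main = title, asp = 1)
  for (r in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  }
  graphics::text(1.2 * cos(ang), 1.2 * sin(ang), labels, cex = 0.8)
  cols <- c("#1b9e77", "#d95f02")
  for (i in seq_along(values_list)) {
    v <- values_list[[i]] / vmax
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[i],
                      col = grDevices::adjustcolor(cols[i], alpha.f = 0.3))
  }
  graphics::legend("bottomright", legend = names(values_list), fill = cols,
                   bty = "n", cex = 0.8)
}

#' Render the isomiR profile report
#'
#' Multi-page PDF: stacked per-group length-distribution bars with
#' mapped/unmapped color coding, one category pie per group, and radar
#' charts of template subtypes in redundant and non-redundant modes. The
#' numbers behind every chart are also written as tab-separated sidecar
#' files next to the PDF.
#'
#' @param stats list from [profile_stats()].
#' @param path output PDF path.
#' @return named character vector of the files written, invisibly.
#' @export
render_profile_report <- function(stats, path) {
  grDevices::pdf(path, width = 8, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off())
  groups <- unique(stats$length_distribution$group)
  for (g in groups) {
    ld <- stats$length_distribution[stats$length_distribution$group == g, ]
    m <- rbind(mapped = ld$mapped, unmapped = ld$unmapped)
    colnames(m) <- ld$length
    graphics::barplot(m, col = c("#3182bd", "#bdbdbd"),
                      main = paste0("Read length distribution - ", g),
                      xlab = "read length (nt)", ylab = "reads",
                      legend.text = TRUE, args.legend = list(bty = "n"))
  }
  graphics::par(mfrow = c(1, length(groups)))
  for (g in groups) {
    cb <- stats$category_breakdown[stats$category_breakdown$group == g, ]
    graphics::pie(cb$percent,
                  labels = sprintf("%s (%.1f%%)", cb$category, cb$percent),
                  main = g,
                  col = c("#1b9e77", "#7570b3", "#d95f02", "#bdbdbd"))
  }
  graphics::par(mfrow = c(1, 2))
  sd <- stats$subtype_distribution
  subtypes <- unique(sd$subtype)
  for (mode in c("redundant", "non_redundant")) {
    vals <- lapply(groups, function(g)
      sd[[mode]][sd$group == g][match(subtypes, sd$subtype[sd$group == g])])
    names(vals) <- groups
    draw_radar(vals, subtypes, paste("Template subtypes -", mode))
  }
  graphics::par(mfrow = c(1, 1))
  files <- c(
    pdf = path,
    length_distribution = write_sidecar(stats$length_distribution, path,
                                        "length_distribution"),
    category_breakdown = write_sidecar(stats$category_breakdown, path,
                                       "category_breakdown"),
    subtype_distribution = write_sidecar(stats$subtype_distribution, path,
                                         "subtype_distribution")
  )
  invisible(files)
}

#' Render the differential-expression report
#'
#' Horizontal bar charts of the top entries signed by log2FC (one chart for
#' RefSeq + template entries, one for non-template entries) and per-arm
#' panels. When nothing passed filtering, the report states so explicitly.
#' Sidecar tables mirror each chart.
#'
#' @param top list from [top_de()].
#' @param arms_summary data.frame from [arm_summary()].
#' @param path output PDF path.
#' @return named character vector of the files written, invisibly.
#' @export
render_de_report <- function(top, arms_summary, path) {
  grDevices::pdf(path, width = 8, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off())
  bar_page <- function(df, title) {
    if (!nrow(df)) {
      graphics::plot.new()
      graphics::text(0.5, 0.5, paste0(title, ":\nno entries passed filtering"))
      return(invisible())
    }
    df <- df[order(df$log2fc), , drop = FALSE]
    op <- graphics::par(mar = c(4, 14, 3, 1))
    graphics::barplot(df$log2fc, names.arg = df$name, horiz = TRUE, las = 1,
                      col = ifelse(df$log2fc >= 0, "#d7301f", "#2b8cbe"),
                      main = title, xlab = "log2 fold change",
                      cex.names = 0.55)
    graphics::par(op)
  }
  bar_page(top$refseq_template, "Top DE RefSeq miRs and template isomiRs")
  bar_page(top$nontemplate, "Top DE non-template isomiRs")
  if (nrow(arms_summary)) {
    for (a in unique(arms_summary$arm)) {
      bar_page(arms_summary[arms_summary$arm == a, c("name", "log2fc")],
               paste("Arm:", a))
    }
  } else {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "Arm summary:\nno entries passed filtering")
  }
  files <- c(
    pdf = path,
    top_refseq_template = write_sidecar(top$refseq_template, path,
                                        "top_refseq_template"),
    top_nontemplate = write_sidecar(top$nontemplate, path, "top_nontemplate"),
    arm_summary = write_sidecar(arms_summary, path, "arm_summary")
  )
  invisible(files)
}
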