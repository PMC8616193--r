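# Hierarchical read classification:
#   1. a read whose sequence equals one or more mature miRs -> RefSeq entry
#      (all matching matures become parents, collapsed into one name);
#   2. any other mapped read -> template isomiR with end offsets
#      d5 = pos - ext5_applied and d3 = read_end - mature_end, named
#      "<parent>_t_<d5>_<d3>";
#   3. optionally, unmapped reads are tested for 3' non-template additions
#      against the pool of all matures plus every template isomiR discovered
#      in step 2 across ALL samples of the run: a read classifies iff it is
#      ref_sequence + suffix with 1-3 added nucleotides, the smallest suffix
#      (longest matching reference prefix) winning.
# Reads surviving none of the steps are unassigned; reads containing N are
# never assigned. Names must be comparable across count-matrix columns,
# which is why the non-template reference pool spans the whole run rather
# than a single sample.

#' Classify length-filtered reads of a run into miR/isomiR entries
#'
#' @param sample_alignments named list (one element per sample) of alignment
#'   data.frames as produced by [align_exact()] or [read_sam()], already
#'   length-filtered.
#' @param arms arm records the alignments refer to (with embedding metadata).
#' @param matures mature records ([mature_records()]).
#' @param detect_nta detect 3' non-template additions among unmapped reads
#'   (default \code{TRUE}).
#' @return an object of class \code{isomir_result}: list with
#'   \describe{
#'     \item{entries}{data.frame of discovered entries: \code{name},
#'       \code{category} (refseq/template/nontemplate), \code{subtype},
#'       \code{d5}, \code{d3}, \code{nta}, \code{parents},
#'       \code{parent_arms} (both \code{";"}-joined), \code{sequence}.}
#'     \item{counts}{named list: per sample, data.frame \code{name},
#'       \code{count} (reads assigned to each entry).}
#'     \item{unassigned}{named list: per sample, data.frame \code{read_id},
#'       \code{sequence}.}
#'     \item{totals}{per-sample read totals by category (reads counted once
#'       even if the entry is ambiguous).}
#'   }
#' @export
classify_samples <- function(sample_alignments, arms, matures, detect_nta = TRUE) {
  stopifnot(is.list(sample_alignments), length(sample_alignments) >= 1L,
            !is.null(names(sample_alignments)))
  if (!all(c("ext5_applied", "ext3_applied", "mature_len") %in% names(arms)) ||
      anyNA(arms$ext5_applied) || anyNA(arms$mature_len)) {
    stop("arm records lack embedding metadata (ext5/ext3/mlen)", call. = FALSE)
  }

  arm_ext5 <- stats::setNames(arms$ext5_applied, arms$arm_id)
  arm_mlen <- stats::setNames(arms$mature_len, arms$arm_id)
  arms_of_mature <- split(arms$arm_id, arms$mature_name)

  # RefSeq lookup: mature sequence -> parents (locus-qualified arm ids when
  # the mature has arms, else the bare mature name)
  refseq_lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(matures))) {
    p <- arms_of_mature[[matures$name[i]]] %||% matures$name[i]
    sq <- matures$sequence[i]
    prev <- if (exists(sq, refseq_lookup)) get(sq, refseq_lookup) else character()
    assign(sq, unique(c(prev, p)), refseq_lookup)
  }

  entries <- new.env(parent = emptyenv())   # name -> entry record (list)
  add_entry <- function(name, category, subtype, d5, d3, nta, parents,
                        parent_arms, sequence) {
    if (!exists(name, entries)) {
      assign(name, list(name = name, category = category, subtype = subtype,
                        d5 = d5, d3 = d3, nta = nta,
                        parents = parents, parent_arms = parent_arms,
                        sequence = sequence), entries)
    }
    name
  }

  # ---- pass 1+2: refseq and template entries, per sample -------------------
  seq_entries <- list()    # sample -> list(sequence -> entry names)
  seq_counts <- list()     # sample -> named integer vector (reads per sequence)
  seq_cat <- list()        # sample -> named character (category per sequence)
  unmapped_seqs <- list()  # sample -> character vector of unmapped sequences
  read_tab <- list()       # sample -> data.frame(read_id, sequence)

  for (s in names(sample_alignments)) {
    aln <- sample_alignments[[s]]
    reads <- unique(aln[, c("read_id", "sequence")])
    read_tab[[s]] <- reads
    cnt <- table(reads$sequence)
    seq_counts[[s]] <- stats::setNames(as.integer(cnt), names(cnt))
    mapped <- aln[aln$mapped, , drop = FALSE]
    ent_map <- list()
    cat_map <- character()
    for (sq in unique(mapped$sequence)) {
      if (exists(sq, refseq_lookup)) {
        parents <- get(sq, refseq_lookup)
        nm <- collapse_multi(parents)
        add_entry(nm, "refseq", "none", 0L, 0L, "", paste(parents, collapse = ";"),
                  paste(parents, collapse = ";"), sq)
        ent_map[[sq]] <- nm
        cat_map[[sq]] <- "refseq"
        next
      }
      hits <- unique(mapped[mapped$sequence == sq, c("ref_id", "pos")])
      d5 <- hits$pos - arm_ext5[hits$ref_id]
      d3 <- (hits$pos + nchar(sq) - 1L) -
        (arm_ext5[hits$ref_id] + arm_mlen[hits$ref_id] - 1L)
      grp <- paste(d5, d3, sep = "/")
      if (length(unique(grp)) > 1L) {
        message(sprintf("sequence %s maps with conflicting end offsets (%s); keeping per-parent variants",
                        sq, paste(unique(grp), collapse = ", ")))
      }
      nms <- character()
      for (g in unique(grp)) {
        idx <- which(grp == g)
        gd5 <- d5[idx[1L]]; gd3 <- d3[idx[1L]]
        parents <- unique(hits$ref_id[idx])
        nm <- paste0(collapse_multi(parents), "_t_", format_offset(gd5), "_",
                     format_offset(gd3))
        add_entry(nm, "template", offset_subtype(gd5, gd3), gd5, gd3, "",
                  paste(parents, collapse = ";"), paste(parents, collapse = ";"), sq)
        nms <- c(nms, nm)
      }
      ent_map[[sq]] <- nms
      cat_map[[sq]] <- "template"
    }
    seq_entries[[s]] <- ent_map
    cat_map_full <- cat_map
    seq_cat[[s]] <- cat_map_full
    all_seqs <- unique(reads$sequence)
    unmapped_seqs[[s]] <- setdiff(all_seqs, unique(mapped$sequence))
  }

  # ---- pass 3: non-template additions against the run-wide pool ------------
  if (detect_nta) {
    ent_list <- as.list(entries)
    tmpl <- Filter(function(e) e$category == "template", ent_list)
    pool_seq <- c(matures$sequence, vapply(tmpl, `[[`, "", "sequence"))
    pool_name <- c(matures$name, vapply(tmpl, `[[`, "", "name"))
    pool_d5 <- c(rep(0L, nrow(matures)),
                 vapply(tmpl, function(e) e$d5, integer(1)))
    pool_d3 <- c(rep(0L, nrow(matures)),
                 vapply(tmpl, function(e) e$d3, integer(1)))
    pool_arms <- c(
      vapply(matures$name, function(m)
        paste(arms_of_mature[[m]] %||% character(), collapse = ";"), ""),
      vapply(tmpl, `[[`, "", "parent_arms")
    )

    for (s in names(sample_alignments)) {
      ent_map <- seq_entries[[s]]
      cat_map <- seq_cat[[s]]
      for (sq in unmapped_seqs[[s]]) {
        if (grepl("N", sq, fixed = TRUE)) next
        len <- nchar(sq)
        for (k in 1:3) {
          if (len - k < 1L) break
          prefix <- substr(sq, 1L, len - k)
          idx <- which(pool_seq == prefix)
          if (!length(idx)) next
          suffix <- substr(sq, len - k + 1L, len)
          ref_names <- unique(pool_name[idx])
          base_nm <- collapse_multi(ref_names)
          nm <- paste0(base_nm, "_nont_0_+", k, "_", suffix)
          d5s <- unique(pool_d5[idx]); d3s <- unique(pool_d3[idx])
          nd5 <- if (length(d5s) == 1L) d5s else 0L
          nd3 <- if (length(d3s) == 1L) d3s else 0L
          add_entry(nm, "nontemplate", offset_subtype(nd5, nd3), nd5, nd3,
                    suffix, paste(ref_names, collapse = ";"),
                    paste(unique(unlist(strsplit(pool_arms[idx], ";", fixed = TRUE))),
                          collapse = ";"), sq)
          ent_map[[sq]] <- nm
          cat_map[[sq]] <- "nontemplate"
          break
        }
      }
      seq_entries[[s]] <- ent_map
      seq_cat[[s]] <- cat_map
    }
  }

  # ---- assemble counts, unassigned, totals ---------------------------------
  counts <- list(); unassigned <- list(); totals <- list()
  for (s in names(sample_alignments)) {
    ent_map <- seq_entries[[s]]
    cnts <- seq_counts[[s]]
    tab <- new.env(parent = emptyenv())
    for (sq in names(ent_map)) {
      for (nm in ent_map[[sq]]) {
        prev <- if (exists(nm, tab)) get(nm, tab) else 0L
        assign(nm, prev + cnts[[sq]], tab)
      }
    }
    nms <- c_sort(ls(tab))
    counts[[s]] <- data.frame(
      name = nms,
      count = vapply(nms, function(n) get(n, tab), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    un_seq <- setdiff(names(cnts), names(ent_map))
    ur <- read_tab[[s]]
    unassigned[[s]] <- ur[ur$sequence %in% un_seq, , drop = FALSE]
    rownames(unassigned[[s]]) <- NULL
    cat_map <- seq_cat[[s]]
    cat_reads <- function(cat) {
      sqs <- names(cat_map)[cat_map == cat]
      sum(cnts[sqs])
    }
    totals[[s]] <- data.frame(
      sample = s,
      total = sum(cnts),
      refseq = cat_reads("refseq"),
      template = cat_reads("template"),
      nontemplate = cat_reads("nontemplate"),
      unassigned = sum(cnts[un_seq]),
      stringsAsFactors = FALSE
    )
  }

  ent_list <- as.list(entries)
  ent_df <- if (length(ent_list)) {
    do.call(rbind, lapply(ent_list[c_sort(names(ent_list))], function(e)
      data.frame(e, stringsAsFactors = FALSE)))
  } else {
    data.frame(name = character(), category = character(), subtype = character(),
               d5 = integer(), d3 = integer(), nta = character(),
               parents = character(), parent_arms = character(),
               sequence = character(), stringsAsFactors = FALSE)
  }
  rownames(ent_df) <- NULL

  structure(
    list(entries = ent_df, counts = counts, unassigned = unassigned,
         totals = do.call(rbind, c(totals, list(make.row.names = FALSE))),
         detect_nta = detect_nta),
    class = "isomir_result"
  )
}

#' Classify a single sample
#'
#' Convenience wrapper around [classify_samples()] for one sample; note that
#' the non-template reference pool then only contains templates discovered
#' in that sample.
#'
#' @inheritParams classify_samples
#' @param alignments alignment data.frame for one sample.
#' @param sample sample label.
#' @return an \code{isomir_result} (see [classify_samples()]).
#' @export
classify_sample <- function(alignments, arms, matures, detect_nta = TRUE,
                            sample = "sample1") {
  classify_samples(stats::setNames(list(alignments), sample), arms, matures,
                   detect_nta = detect_nta)
}

#' @export
print.isomir_result <- function(x, ...) {
  cat(sprintf("isomir_result: %d entries (%d refseq, %d template, %d nontemplate) in %d sample(s)\n",
              nrow(x$entries), sum(x$entries$category == "refseq"),
              sum(x$entries$category == "template"),
              sum(x$entries$category == "nontemplate"), length(x$counts)))
  invisible(x)
}

#' Build the combined and per-category count matrices
#'
#' The combined matrix (all categories; rows are the union of entries over
#' all samples, missing counts 0; columns ordered group 1 then group 2) is
#' directly loadable by DESeq2/edgeR-style tools. The six category matrices
#' (\{refseq, template, nontemplate\} x group) carry the entry sequence as an
#' annotation column and keep only entries observed in that group.
#'
#' @param result an \code{isomir_result}.
#' @param groups named list of exactly two character vectors of sample ids.
#' @return list with \code{combined} (data.frame, first column \code{name}),
#'   \code{categories} (named list of six data.frames) and \code{groups}.
#' @export
build_count_matrices <- function(result, groups) {
  stopifnot(inherits(result, "isomir_result"), is.list(groups),
            length(groups) == 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- c("group1", "group2")
  }
  samples <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(samples)) {
    stop("sample id occurs in both groups: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(samples, names(result$counts))
  if (length(missing)) {
    stop("no classification for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all_names <- c_sort(unique(unlist(lapply(result$counts[samples], `[[`, "name"))))
  mat <- data.frame(name = all_names, stringsAsFactors = FALSE)
  for (s in samples) {
    v <- stats::setNames(result$counts[[s]]$count, result$counts[[s]]$name)
    mat[[s]] <- as.integer(ifelse(all_names %in% names(v), v[all_names], 0L))
  }
  seq_of <- stats::setNames(result$entries$sequence, result$entries$name)
  cat_of <- stats::setNames(result$entries$category, result$entries$name)
  categories <- list()
  for (cat in c("refseq", "template", "nontemplate")) {
    for (g in names(groups)) {
      sub <- mat[cat_of[mat$name] == cat, c("name", groups[[g]]), drop = FALSE]
      keep <- rowSums(sub[, groups[[g]], drop = FALSE]) > 0L
      sub <- sub[keep, , drop = FALSE]
      sub <- data.frame(name = sub$name, sequence = seq_of[sub$name],
                        sub[, groups[[g]], drop = FALSE],
                        stringsAsFactors = FALSE, check.names = FALSE)
      rownames(sub) <- NULL
      categories[[paste(cat, g, sep = "_")]] <- sub
    }
  }
  list(combined = mat, categories = categories, groups = groups)
}

#' Export the per-arm sequence database
#'
#' One row per (arm, entry, sample) with a positive count: every detected
#' species is traceable to the arm(s) that produced it. Rows are sorted by
#' arm id, then by descending total entry count, then entry name and sample.
#'
#' @param result an \code{isomir_result}.
#' @param arms arm records (used to restrict to known arms; entries whose
#'   parents are bare mature names are attributed to that mature's arms).
#' @param path output path for the tab-separated file, or \code{NULL} to
#'   only return the data.frame.
#' @return the database data.frame, invisibly when \code{path} is given.
#' @export
export_arm_database <- function(result, arms, path = NULL) {
  stopifnot(inherits(result, "isomir_result"))
  ent <- result$entries
  rows <- list()
  sample_order <- names(result$counts)
  for (i in seq_len(nrow(ent))) {
    parent_arms <- setdiff(split1(ent$parent_arms[i], ";"), "")
    parent_arms <- intersect(parent_arms, arms$arm_id)
    if (!length(parent_arms)) next
    for (s in sample_order) {
      cnt <- result$counts[[s]]
      m <- match(ent$name[i], cnt$name)
      if (is.na(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        arm_id = parent_arms, entry = ent$name[i], category = ent$category[i],
        sequence = ent$sequence[i], sample = s, count = cnt$count[m],
        stringsAsFactors = FALSE
      )
    }
  }
  db <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(arm_id = character(), entry = character(), category = character(),
               sequence = character(), sample = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  if (nrow(db)) {
    tot <- tapply(db$count, db$entry, sum)
    db <- db[order(db$arm_id, -as.integer(tot[db$entry]), db$entry,
                   match(db$sample, sample_order), method = "radix"), ,
             drop = FALSE]
    rownames(db) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(db))
  }
  db
}

#' Write a count matrix as a tab-separated file
#'
#' @param mat data.frame whose first column is \code{name}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
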