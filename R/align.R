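# Read ingest, length filtering, exact all-hits alignment against arm
# references, and a minimal SAM v1 dialect (header @HD/@SQ; FLAG 0 mapped,
# 4 unmapped; MAPQ 255; CIGAR "<len>M" or "*"). Alignment is zero-mismatch
# and forward-strand only: arms are already strand-resolved.

#' Read small RNA reads from FASTQ or FASTA
#'
#' Quality strings are ignored; sequences are normalized to uppercase DNA.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension/first byte), \code{"fastq"} or
#'   \code{"fasta"}.
#' @return data.frame with columns \code{read_id}, \code{sequence}.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fasta"
    } else {
      first <- readChar(path, 1L)
      if (identical(first, "@")) "fastq" else "fasta"
    }
  }
  ss <- Biostrings::readBStringSet(path, format = format)
  data.frame(
    read_id = vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L),
    sequence = normalize_seq(as.character(ss)),
    stringsAsFactors = FALSE
  )
}

#' Filter reads by length
#'
#' Keeps reads whose length lies inside \code{[min_len, max_len]}
#' (inclusive), preserving order. The number of discarded reads is reported
#' via \code{message()} and attached as attribute \code{"filtered_out"}.
#'
#' @param reads data.frame with a \code{sequence} column.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 26 nt,
#'   the usual mature-miR window).
#' @return the filtered data.frame.
#' @export
length_filter <- function(reads, min_len = 18L, max_len = 26L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_out <- sum(!keep)
  if (n_out > 0L) {
    message(sprintf("length filter [%d,%d]: removed %d of %d reads",
                    min_len, max_len, n_out, length(keep)))
  }
  attr(out, "filtered_out") <- n_out
  out
}

alignment_df <- function(read_id = character(), sequence = character(),
                         ref_id = character(), pos = integer(),
                         mapped = logical()) {
  data.frame(read_id = read_id, sequence = sequence, ref_id = ref_id,
             pos = as.integer(pos), mapped = mapped, stringsAsFactors = FALSE)
}

#' Align reads exactly against arm references, reporting all hits
#'
#' Zero mismatches, forward strand only. Every exact (possibly overlapping)
#' occurrence of a read inside any arm yields one record; a read with no
#' occurrence, or containing N, yields a single unmapped record.
#'
#' @param reads data.frame with \code{read_id}, \code{sequence}.
#' @param arms data.frame of arm records.
#' @return data.frame with columns \code{read_id}, \code{sequence},
#'   \code{ref_id}, \code{pos} (0-based offset in the arm) and
#'   \code{mapped}; unmapped rows carry \code{NA} ref/pos.
#' @export
align_exact <- function(reads, arms) {
  stopifnot(nrow(arms) > 0L)
  uniq <- unique(reads$sequence)
  arm_subjects <- lapply(arms$sequence, Biostrings::DNAString)
  hits <- lapply(uniq, function(s) {
    if (grepl("N", s, fixed = TRUE)) {
      return(alignment_df())
    }
    per_arm <- lapply(seq_len(nrow(arms)), function(j) {
      p <- as.integer(Biostrings::start(Biostrings::matchPattern(s, arm_subjects[[j]])))
      if (!length(p)) return(NULL)
      alignment_df(read_id = rep("", length(p)), sequence = rep(s, length(p)),
                   ref_id = rep(arms$arm_id[j], length(p)), pos = p - 1L,
                   mapped = rep(TRUE, length(p)))
    })
    do.call(rbind, c(list(alignment_df()), per_arm))
  })
  names(hits) <- uniq
  out <- lapply(seq_len(nrow(reads)), function(i) {
    h <- hits[[reads$sequence[i]]]
    if (nrow(h)) {
      h$read_id <- reads$read_id[i]
      h
    } else {
      alignment_df(read_id = reads$read_id[i], sequence = reads$sequence[i],
                   ref_id = NA_character_, pos = NA_integer_, mapped = FALSE)
    }
  })
  res <- do.call(rbind, c(list(alignment_df()), out))
  rownames(res) <- NULL
  res
}

#' Write alignment records as SAM
#'
#' Minimal SAM v1: \code{@HD}/\code{@SQ} header, FLAG 0 (mapped, forward) or
#' 4 (unmapped), 1-based POS, MAPQ 255, CIGAR \code{<len>M} for mapped and
#' \code{*} for unmapped records.
#'
#' @param records alignment data.frame ([align_exact()]).
#' @param arms arm records providing \code{@SQ} lines.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(records, arms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", arms$arm_id, nchar(arms$sequence)), con)
  if (nrow(records)) {
    mapped <- records$mapped
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     records$read_id,
                     ifelse(mapped, 0L, 4L),
                     ifelse(mapped, records$ref_id, "*"),
                     ifelse(mapped, records$pos + 1L, 0L),
                     ifelse(mapped, 255L, 0L),
                     ifelse(mapped, paste0(nchar(records$sequence), "M"), "*"),
                     records$sequence)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a SAM file of arm alignments
#'
#' Accepts output of an external zero-mismatch aligner. Every mapped record
#' is re-verified against the arm sequence; records that do not match
#' exactly (the external aligner may have been run permissively) and
#' reverse-strand records (FLAG 0x10) are demoted to unmapped with a
#' warning. SAM 1-based POS is converted to the internal 0-based offset.
#'
#' @param path SAM file.
#' @param arms arm records the file was aligned against.
#' @return alignment data.frame (see [align_exact()]).
#' @export
read_sam <- function(path, arms) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  rows <- vector("list", length(body_idx))
  arm_seq <- stats::setNames(arms$sequence, arms$arm_id)
  n_demoted <- 0L; n_rev <- 0L
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- split1(lines[i], "\t")
    if (length(f) < 11L) {
      stop(sprintf("malformed SAM line %d in %s: %d fields (need >= 11)",
                   i, path, length(f)), call. = FALSE)
    }
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) {
      stop(sprintf("malformed SAM line %d in %s: non-numeric FLAG '%s'",
                   i, path, f[2L]), call. = FALSE)
    }
    seq <- normalize_seq(f[10L])
    if (bitwAnd(flag, 4L) != 0L) {
      rows[[k]] <- alignment_df(f[1L], seq, NA_character_, NA_integer_, FALSE)
      next
    }
    if (bitwAnd(flag, 16L) != 0L) {
      n_rev <- n_rev + 1L
      rows[[k]] <- alignment_df(f[1L], seq, NA_character_, NA_integer_, FALSE)
      next
    }
    rname <- f[3L]
    if (!rname %in% names(arm_seq)) {
      stop(sprintf("SAM line %d in %s: unknown reference '%s'", i, path, rname),
           call. = FALSE)
    }
    pos0 <- as.integer(f[4L]) - 1L
    ref_window <- substr(arm_seq[[rname]], pos0 + 1L, pos0 + nchar(seq))
    if (!identical(ref_window, seq)) {
      n_demoted <- n_demoted + 1L
      rows[[k]] <- alignment_df(f[1L], seq, NA_character_, NA_integer_, FALSE)
      next
    }
    rows[[k]] <- alignment_df(f[1L], seq, rname, pos0, TRUE)
  }
  if (n_rev > 0L) {
    warning(sprintf("%s: %d reverse-strand records treated as unmapped", path, n_rev),
            call. = FALSE)
  }
  if (n_demoted > 0L) {
    warning(sprintf("%s: %d records failed the zero-mismatch check and were demoted to unmapped",
                    path, n_demoted), call. = FALSE)
  }
  res <- do.call(rbind, c(list(alignment_df()), rows))
  rownames(res) <- NULL
  res
}
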