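# Arm reference construction: each mature miR is widened by up to 8 templated
# nucleotides on both ends, taken either from its stem-loop precursor or from
# genome coordinates. The widened sequence ("arm") is the alignment reference
# for isomiR classification; its metadata records where the mature sits so
# end offsets can be computed without re-deriving the embedding.

MAX_EXT <- 8L

#' Read mature miR sequences from FASTA
#'
#' Sequences are normalized to uppercase DNA (U -> T). The arm label (5p/3p)
#' is inferred from the record name suffix when present.
#'
#' @param path FASTA file of mature sequences.
#' @return data.frame with columns \code{name}, \code{sequence},
#'   \code{arm_label}.
#' @export
read_mature_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  seqs <- normalize_seq(as.character(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate mature names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  mature_records(nm, seqs)
}

#' Construct mature records from names and sequences
#'
#' @param name,sequence parallel character vectors.
#' @return data.frame of mature records.
#' @export
mature_records <- function(name, sequence) {
  sequence <- normalize_seq(sequence)
  if (any(!nzchar(sequence))) stop("empty mature sequence", call. = FALSE)
  assert_alphabet(sequence, what = "mature sequence")
  arm_label <- ifelse(grepl("-5p$", name), "5p",
                ifelse(grepl("-3p$", name), "3p", "unknown"))
  data.frame(name = name, sequence = sequence, arm_label = arm_label,
             stringsAsFactors = FALSE)
}

#' Read precursor (stem-loop) sequences from FASTA
#'
#' @param path FASTA file of precursor sequences.
#' @return data.frame with columns \code{name}, \code{sequence}.
#' @export
read_precursor_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  data.frame(name = nm, sequence = normalize_seq(as.character(ss)),
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA into a named set of chromosome sequences
#'
#' @param path genome FASTA.
#' @return named character vector, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  g <- normalize_seq(as.character(ss))
  names(g) <- nm
  assert_alphabet(g, allowed = c("A", "C", "G", "T", "N"), what = "genome sequence")
  g
}

#' Read mature miR loci from a GFF3 annotation
#'
#' Keeps features of type \code{miRNA}; the record name is taken from the
#' \code{Name} attribute, falling back to \code{ID}.
#'
#' @param path GFF3 file.
#' @return data.frame with columns \code{name}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (1-based inclusive coordinates).
#' @export
read_mirna_gff <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  gr <- gr[as.character(gr$type) == "miRNA"]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  if (all(is.na(nm)) && !is.null(gr$ID)) nm <- as.character(gr$ID)
  nm[is.na(nm)] <- as.character(gr$ID)[is.na(nm)]
  data.frame(
    name = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

arm_record_df <- function(arm_id = character(), sequence = character(),
                          ext5_applied = integer(), ext3_applied = integer(),
                          mature_name = character(), mature_len = integer()) {
  data.frame(arm_id = arm_id, sequence = sequence,
             ext5_applied = as.integer(ext5_applied),
             ext3_applied = as.integer(ext3_applied),
             mature_name = mature_name, mature_len = as.integer(mature_len),
             stringsAsFactors = FALSE)
}

# Merge arm records that share mature name and sequence; locus-qualified ids
# are collapsed into one id via collapse_multi(). Records whose sequences
# differ stay separate.
merge_identical_arms <- function(arms) {
  if (!nrow(arms)) return(arms)
  key <- paste(arms$mature_name, arms$sequence, sep = "\r")
  out <- lapply(split(seq_len(nrow(arms)), key), function(idx) {
    sub <- arms[idx, , drop = FALSE]
    sub$arm_id[1L] <- collapse_multi(sub$arm_id)
    sub[1L, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  res <- res[order(res$arm_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build arm references from precursor sequences
#'
#' Each mature occurrence inside a precursor is widened by \code{ext}
#' nucleotides on both sides, clamped at the precursor boundaries. The
#' achieved widening is recorded so that classification can locate the
#' embedded mature window exactly.
#'
#' @param matures data.frame of mature records ([mature_records()]).
#' @param precursors data.frame with columns \code{name}, \code{sequence}.
#' @param ext requested extension in nucleotides, 0-8 (default 6).
#' @return data.frame of arm records with columns \code{arm_id},
#'   \code{sequence}, \code{ext5_applied}, \code{ext3_applied},
#'   \code{mature_name}, \code{mature_len}.
#' @export
build_arms_from_precursors <- function(matures, precursors, ext = 6L) {
  ext <- as.integer(ext)
  stopifnot(ext >= 0L, ext <= MAX_EXT)
  precursors$sequence <- normalize_seq(precursors$sequence)
  rows <- list()
  for (i in seq_len(nrow(matures))) {
    mname <- matures$name[i]
    mseq <- matures$sequence[i]
    mlen <- nchar(mseq)
    found <- FALSE
    for (j in seq_len(nrow(precursors))) {
      pseq <- precursors$sequence[j]
      hits <- as.integer(
        Biostrings::start(Biostrings::matchPattern(mseq, Biostrings::DNAString(pseq)))
      )
      if (length(hits) > 1L) {
        stop(sprintf("mature '%s' occurs %d times in precursor '%s'",
                     mname, length(hits), precursors$name[j]), call. = FALSE)
      }
      if (length(hits) == 1L) {
        found <- TRUE
        s0 <- hits - 1L                       # 0-based start of the mature
        a0 <- max(0L, s0 - ext)
        a1 <- min(nchar(pseq), s0 + mlen + ext)  # 0-based half-open end
        rows[[length(rows) + 1L]] <- arm_record_df(
          arm_id = mname,
          sequence = substr(pseq, a0 + 1L, a1),
          ext5_applied = s0 - a0,
          ext3_applied = a1 - (s0 + mlen),
          mature_name = mname, mature_len = mlen
        )
      }
    }
    if (!found) {
      warning(sprintf("mature '%s' not found in any precursor; skipped", mname),
              call. = FALSE)
    }
  }
  arms <- if (length(rows)) do.call(rbind, rows) else arm_record_df()
  # a mature present in several precursors: merge identical widened windows;
  # distinct windows are disambiguated with a numeric suffix
  arms <- merge_identical_arms(arms)
  dup <- duplicated(arms$arm_id) | duplicated(arms$arm_id, fromLast = TRUE)
  if (any(dup)) {
    arms$arm_id[dup] <- paste0(arms$arm_id[dup], "_v",
                               stats::ave(seq_len(nrow(arms)), arms$arm_id,
                                          FUN = seq_along)[dup])
  }
  rownames(arms) <- NULL
  arms
}

#' Build arm references from genome coordinates
#'
#' The locus of each mature is widened by \code{ext} nucleotides on both
#' genomic sides (clamped to the chromosome); minus-strand arms are
#' reverse-complemented so that the stored sequence runs 5' to 3' and
#' \code{ext5_applied}/\code{ext3_applied} refer to the mature's own ends.
#' Arm ids are locus-qualified: \code{<name>_<chrom>(<strand>)}; identical
#' arm sequences of one mature arising from several loci are merged into a
#' single record whose id concatenates the sorted locus suffixes.
#'
#' @param gff_records data.frame with columns \code{name}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (1-based inclusive).
#' @param genome named character vector of chromosome sequences
#'   ([read_genome_fasta()]).
#' @param ext requested extension, 0-8 (default 6).
#' @return data.frame of arm records (see [build_arms_from_precursors()]).
#' @export
build_arms_from_gff <- function(gff_records, genome, ext = 6L) {
  ext <- as.integer(ext)
  stopifnot(ext >= 0L, ext <= MAX_EXT)
  assert_alphabet(genome, allowed = c("A", "C", "G", "T", "N"),
                  what = "genome sequence")
  rows <- list()
  for (i in seq_len(nrow(gff_records))) {
    rec <- gff_records[i, ]
    if (!rec$chrom %in% names(genome)) {
      stop(sprintf("locus '%s': unknown chromosome '%s'", rec$name, rec$chrom),
           call. = FALSE)
    }
    clen <- nchar(genome[[rec$chrom]])
    stopifnot(rec$start >= 1L, rec$start <= rec$end, rec$end <= clen)
    ws <- max(1L, rec$start - ext)
    we <- min(clen, rec$end + ext)
    seq <- substr(genome[[rec$chrom]], ws, we)
    if (rec$strand == "-") {
      seq <- revcomp(seq)
      ext5 <- we - rec$end       # mature 5' end sits at the genomic end
      ext3 <- rec$start - ws
    } else {
      ext5 <- rec$start - ws
      ext3 <- we - rec$end
    }
    rows[[length(rows) + 1L]] <- arm_record_df(
      arm_id = sprintf("%s_%s(%s)", rec$name, rec$chrom, rec$strand),
      sequence = seq, ext5_applied = ext5, ext3_applied = ext3,
      mature_name = rec$name, mature_len = rec$end - rec$start + 1L
    )
  }
  arms <- if (length(rows)) do.call(rbind, rows) else arm_record_df()
  merge_identical_arms(arms)
}

#' Write arm records to FASTA
#'
#' The header carries the embedding metadata
#' (\code{ext5=<n> ext3=<n> mlen=<n>}) so downstream classification can
#' recover the reference window without the precursor or genome.
#'
#' @param arms data.frame of arm records.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_arms_fasta <- function(arms, path) {
  if (anyDuplicated(arms$arm_id)) {
    stop("duplicate arm_id: ",
         paste(unique(arms$arm_id[duplicated(arms$arm_id)]), collapse = ", "),
         call. = FALSE)
  }
  ss <- Biostrings::DNAStringSet(arms$sequence)
  names(ss) <- sprintf("%s ext5=%d ext3=%d mlen=%d", arms$arm_id,
                       arms$ext5_applied, arms$ext3_applied, arms$mature_len)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an arm FASTA written by [write_arms_fasta()]
#'
#' @param path arm FASTA path.
#' @return data.frame of arm records. The mature name is recovered by
#'   stripping locus suffixes from the arm id; the embedded mature sequence
#'   from the metadata window.
#' @export
read_arms_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) return(arm_record_df())
  hdr <- names(ss)
  arm_id <- sub("[ \t].*$", "", hdr)
  get_field <- function(field) {
    m <- regmatches(hdr, regexec(sprintf("%s=([0-9]+)", field), hdr))
    v <- vapply(m, function(x) if (length(x)) x[2L] else NA_character_, "")
    if (anyNA(v)) stop("arm FASTA header missing ", field, "= metadata", call. = FALSE)
    as.integer(v)
  }
  arms <- arm_record_df(
    arm_id = arm_id, sequence = normalize_seq(as.character(ss)),
    ext5_applied = get_field("ext5"), ext3_applied = get_field("ext3"),
    mature_name = vapply(arm_id, function(x) parse_name(x)$base, ""),
    mature_len = get_field("mlen")
  )
  rownames(arms) <- NULL
  arms
}

# the mature sequence embedded in an arm record
arm_mature_seq <- function(arms) {
  substr(arms$sequence, arms$ext5_applied + 1L,
         arms$ext5_applied + arms$mature_len)
}
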