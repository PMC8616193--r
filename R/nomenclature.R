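# isomiR name grammar:
#   <base>[_<chr>(<+|->)]*[_t_<d5>_<d3>][_nont_0_+<k>_<seq>]
#
# Offsets are printed as "0", "+n" or "-n". d5/d3 are coordinate deltas of the
# isomiR ends relative to the reference miR ends, measured 5'->3' along the
# arm: d5 < 0 means 5' extension, d5 > 0 means 5' trimming, d3 > 0 means 3'
# extension, d3 < 0 means 3' trimming. The non-template segment always starts
# "nont_0_" (additions are 3'-only) followed by "+<k>_<added nucleotides>".

#' Construct the parsed parts of an isomiR name
#'
#' @param base mature miR base name (e.g. \code{"miR-200b-3p"}).
#' @param loci_suffixes character vector of locus tokens such as
#'   \code{"chr1(+)"}; empty for precursor-mode names.
#' @param d5,d3 integer end offsets of a template isomiR, or \code{NA} when
#'   the name carries no \code{_t_} segment.
#' @param nta non-templated 3' addition (0-3 nt), \code{""} when absent.
#' @return an object of class \code{name_parts}.
#' @export
name_parts <- function(base, loci_suffixes = character(), d5 = NA_integer_,
                       d3 = NA_integer_, nta = "") {
  stopifnot(is.character(base), length(base) == 1L, nzchar(base))
  if (is.na(d5) != is.na(d3)) {
    stop("d5 and d3 must both be given or both be NA", call. = FALSE)
  }
  if (nchar(nta) > 3L) stop("non-template addition longer than 3 nt", call. = FALSE)
  if (nzchar(nta)) assert_alphabet(nta, what = "non-template addition")
  structure(
    list(base = base, loci_suffixes = as.character(loci_suffixes),
         d5 = as.integer(d5), d3 = as.integer(d3), nta = nta),
    class = "name_parts"
  )
}

# "0", "+n" or "-n"
format_offset <- function(d) {
  ifelse(d == 0L, "0", ifelse(d > 0L, paste0("+", d), as.character(d)))
}

#' Format an isomiR name from its parts
#'
#' Inverse of [parse_name()]: \code{parse_name(format_name(x))} recovers
#' \code{x} for any valid set of parts. ASCII \code{"-"} is always emitted.
#'
#' @param parts a [name_parts()] object.
#' @return canonical name string.
#' @export
format_name <- function(parts) {
  stopifnot(inherits(parts, "name_parts"))
  nm <- parts$base
  if (length(parts$loci_suffixes)) {
    nm <- paste0(nm, paste0("_", parts$loci_suffixes, collapse = ""))
  }
  if (!is.na(parts$d5)) {
    nm <- paste0(nm, "_t_", format_offset(parts$d5), "_", format_offset(parts$d3))
  }
  if (nzchar(parts$nta)) {
    nm <- paste0(nm, "_nont_0_+", nchar(parts$nta), "_", parts$nta)
  }
  nm
}

#' Parse an isomiR name into its parts
#'
#' Accepts the Unicode minus sign (U+2212) anywhere an ASCII \code{"-"} is
#' expected, as published tables often typeset offsets and strands with it.
#'
#' @param name a name produced by the grammar above.
#' @return a [name_parts()] object.
#' @export
parse_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  nm <- gsub("\u2212", "-", name)
  rest <- nm
  nta <- ""

  # trailing non-template segment
  m <- regmatches(rest, regexec("_nont_0_\\+([0-9]+)_([ACGTU]+)$", rest))[[1L]]
  if (length(m)) {
    k <- as.integer(m[2L])
    nta <- normalize_seq(m[3L])
    if (nchar(nta) != k || k < 1L || k > 3L) {
      stop(sprintf("cannot parse name '%s': non-template segment at position %d claims %d nt but carries '%s'",
                   name, nchar(rest) - nchar(m[1L]) + 1L, k, nta), call. = FALSE)
    }
    rest <- substr(rest, 1L, nchar(rest) - nchar(m[1L]))
  } else if (grepl("_nont_", rest)) {
    stop(sprintf("cannot parse name '%s': malformed non-template segment at position %d",
                 name, regexpr("_nont_", rest)[1L]), call. = FALSE)
  }

  # trailing template-offset segment
  d5 <- NA_integer_; d3 <- NA_integer_
  m <- regmatches(rest, regexec("_t_(0|[+-][0-9]+)_(0|[+-][0-9]+)$", rest))[[1L]]
  if (length(m)) {
    d5 <- as.integer(sub("^\\+", "", m[2L]))
    d3 <- as.integer(sub("^\\+", "", m[3L]))
    rest <- substr(rest, 1L, nchar(rest) - nchar(m[1L]))
  } else if (grepl("_t_", rest)) {
    stop(sprintf("cannot parse name '%s': malformed offset segment at position %d",
                 name, regexpr("_t_", rest)[1L]), call. = FALSE)
  }

  # trailing locus suffixes, stripped right to left
  loci <- character()
  repeat {
    m <- regmatches(rest, regexec("_([^_()]+\\([+-]\\))$", rest))[[1L]]
    if (!length(m)) break
    loci <- c(m[2L], loci)
    rest <- substr(rest, 1L, nchar(rest) - nchar(m[1L]))
  }

  if (!nzchar(rest)) {
    stop(sprintf("cannot parse name '%s': empty base name at position 1", name),
         call. = FALSE)
  }
  name_parts(rest, loci, d5, d3, nta)
}

#' Collapse the parent names of a multi-reference entry
#'
#' A sequence matching several reference records is kept as one entry whose
#' name merges the parents. Parents are deduplicated; when they share the same
#' base (and any offset/addition segments), their locus suffixes are merged
#' and sorted; otherwise the distinct full names are sorted and joined with
#' \code{"_"}. Sorting is lexicographic in the C locale, so the result is
#' deterministic for any input order.
#'
#' @param parents character vector of parent entry names (non-empty).
#' @return the canonical collapsed name.
#' @export
collapse_multi <- function(parents) {
  stopifnot(is.character(parents), length(parents) >= 1L)
  parents <- unique(parents)
  if (length(parents) == 1L) return(parents)
  parsed <- lapply(parents, parse_name)
  bases <- vapply(parsed, function(p) p$base, "")
  key <- vapply(parsed, function(p) {
    paste(p$base, p$d5, p$d3, p$nta, sep = "\r")
  }, "")
  if (length(unique(key)) == 1L) {
    sufs <- c_sort(unique(unlist(lapply(parsed, function(p) p$loci_suffixes))))
    p1 <- parsed[[1L]]
    format_name(name_parts(bases[1L], sufs, p1$d5, p1$d3, p1$nta))
  } else {
    paste(c_sort(parents), collapse = "_")
  }
}

# subtype of a template entry from its end offsets
offset_subtype <- function(d5, d3) {
  ifelse(is.na(d5) | (d5 == 0L & d3 == 0L), "none",
    ifelse(d5 != 0L & d3 != 0L, "both_shift",
      ifelse(d5 != 0L, "5p_shift", "3p_shift")))
}
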