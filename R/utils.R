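# Internal helpers shared across modules.

#' Normalize a nucleotide string to uppercase DNA
#'
#' Mature and precursor databases distribute RNA (U) while reads are DNA;
#' all classification is exact string matching, so everything is folded to
#' uppercase DNA (U -> T) on input.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector, uppercase with U replaced by T.
#' @keywords internal
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

# C-locale (radix) sort: deterministic regardless of session locale.
c_sort <- function(x) sort(x, method = "radix")

# Reverse complement via Biostrings; accepts/returns plain character.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_alphabet <- function(x, allowed = c("A", "C", "G", "T"), what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(allowed, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}: '%s'",
                 what, paste(allowed, collapse = ","),
                 substr(x[bad][1L], 1L, 40L)), call. = FALSE)
  }
  invisible(x)
}

# strsplit() helper returning a character vector for a single string
split1 <- function(x, split, fixed = TRUE) strsplit(x, split, fixed = fixed)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
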