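#' @keywords internal
"_PACKAGE"

#' @useDynLib sdblocks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang .data abort
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n distinct across all_of if_else rename
#' @importFrom generics tidy glance
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` maps to `N`.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  unname(cpp_revcomp(as.character(x)))
}

str_len <- function(x) nchar(x, type = "chars")

#' Construct a string-set
#'
#' A string-set is the tabular container used throughout the package: one row
#' per chromosome (or haplotype/contig), with a genome label so that several
#' genomes can live in one table for joint decomposition.
#'
#' @param seq character vector of uppercase DNA sequences (A/C/G/T/N).
#' @param chrom chromosome names (unique within a genome).
#' @param genome genome label(s), recycled.
#' @return a tibble with columns `genome`, `chrom`, `seq`.
#' @examples
#' string_set("ACGTACGT", chrom = "c1")
#' @export
string_set <- function(seq, chrom = paste0("chr", seq_along(seq)),
                       genome = "genome1") {
  ss <- tibble::tibble(genome = as.character(genome),
                       chrom = as.character(chrom),
                       seq = toupper(as.character(seq)))
  validate_string_set(ss)
  ss
}

validate_string_set <- function(ss) {
  stopifnot(is.data.frame(ss), all(c("genome", "chrom", "seq") %in% names(ss)))
  if (nrow(ss) == 0 || sum(str_len(ss$seq)) == 0)
    abort("string-set must contain at least one non-empty sequence")
  key <- paste(ss$genome, ss$chrom)
  if (anyDuplicated(key))
    abort("duplicated (genome, chrom) pairs in string-set")
  bad <- stringr::str_locate(ss$seq, "[^ACGTN]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("illegal character in sequence %s:%s at offset %d",
                  ss$genome[i], ss$chrom[i], bad[i] - 1))
  }
  invisible(ss)
}

#' Percent identity of two sequences
#'
#' Defined as `1 - editdistance(a, b) / max(nchar(a), nchar(b))`, i.e. a
#' global, indel-aware identity. Symmetric; `percent_identity(a, a)` is 1.
#' Two empty strings have identity 1 by convention.
#'
#' @param a,b DNA (or any) strings.
#' @return a fraction in `[0, 1]`.
#' @examples
#' percent_identity("CTCAGTAT", "CTCCGTAT") # 0.875
#' @export
percent_identity <- function(a, b) {
  la <- str_len(a); lb <- str_len(b)
  if (la == 0 && lb == 0) return(1)
  m <- max(la, lb)
  1 - cpp_edit_distance(a, b) / m
}

# letters A, B, ..., Z, AA, AB, ... for block labels
block_letters <- function(n) {
  if (n == 0) return(character())
  out <- character(n)
  for (i in seq_len(n)) {
    v <- i
    s <- ""
    while (v > 0) {
      r <- (v - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      v <- (v - 1) %/% 26
    }
    out[i] <- s
  }
  out
}
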