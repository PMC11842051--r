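# Reading and writing the standard formats the tool touches.

#' Read a genome from FASTA
#'
#' Each FASTA record becomes one chromosome of the string-set. Lowercase is
#' normalised to uppercase; characters outside A/C/G/T/N are rejected with
#' the offending offset.
#'
#' @param path FASTA file.
#' @param genome_label label attached to every record.
#' @return a string-set tibble (see [string_set()]).
#' @export
read_genome <- function(path, genome_label = "genome1") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ds <- Biostrings::readBStringSet(path)
  if (length(ds) == 0) abort(sprintf("empty FASTA: %s", path))
  nm <- sub("\\s.*$", "", names(ds))
  string_set(toupper(as.character(ds)), chrom = nm, genome = genome_label)
}

#' Write a string-set to FASTA
#'
#' Record ids are `chrom` (with `genome|chrom` when several genomes are
#' present).
#'
#' @param ss string-set tibble.
#' @param path output file.
#' @param width line width.
#' @export
write_genome <- function(ss, path, width = 80) {
  validate_string_set(ss)
  ids <- if (dplyr::n_distinct(ss$genome) > 1)
    paste(ss$genome, ss$chrom, sep = "|") else ss$chrom
  x <- Biostrings::BStringSet(ss$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene annotations from BED or GFF3
#'
#' Intervals are converted to the package-wide 0-based half-open convention
#' (BED is native; GFF3 start/end are 1-based closed and converted on read).
#' The optional columns `kind` (V/D/J/other), `hept_start` and `nona_start`
#' (0-based genome starts of the RSS heptamer and nonamer) are taken from BED
#' extra columns 7-9 or from GFF3 attributes of the same names.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   reject out-of-range intervals.
#' @return tibble with columns `chrom`, `start`, `end`, `strand`, `name`,
#'   `kind`, `hept_start`, `nona_start`.
#' @export
read_genes <- function(path, format = c("bed", "gff3"), chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(kind = "character",
                                            hept_start = "numeric",
                                            nona_start = "numeric"))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
  }
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  get_col <- function(nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  name <- get_col("name", NA_character_)
  if (all(is.na(name))) name <- get_col("Name", NA_character_)
  if (all(is.na(name))) name <- get_col("ID", NA_character_)
  genes <- tibble::tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L, # GRanges is 1-based closed
    end = as.integer(df$end),
    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
    name = as.character(name),
    kind = as.character(get_col("kind", "other")),
    hept_start = suppressWarnings(as.integer(get_col("hept_start", NA))),
    nona_start = suppressWarnings(as.integer(get_col("nona_start", NA))))
  genes$kind[is.na(genes$kind) | !(genes$kind %in% c("V", "D", "J"))] <- "other"
  if (any(genes$start < 0 | genes$end <= genes$start))
    abort("invalid interval: need 0 <= start < end")
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(genes$chrom, names(chrom_lengths))
    if (length(unknown) > 0)
      abort(sprintf("unknown chromosome in annotations: %s", unknown[1]))
    if (any(genes$end > chrom_lengths[genes$chrom]))
      abort("interval beyond chromosome end in annotations")
  }
  genes
}

decomp_tsv_cols <- c("genome", "chrom", "start", "end", "block_id", "strand",
                     "instance_length", "pct_identity_to_consensus",
                     "partial_start_offset", "partial_end_offset")

#' Write a block decomposition as TSV
#'
#' One row per block instance and per non-repetitive segment (`block_id` is
#' `"."` and offsets are `NA` for the latter), sorted by (genome, chrom,
#' start), tiling every chromosome.
#'
#' @param decomp an `sd_decomposition` (see [infer_blocks()]).
#' @param path output file.
#' @export
write_decomposition <- function(decomp, path) {
  seg <- decomposition_segments(decomp)
  out <- seg |>
    mutate(block_id = ifelse(is.na(.data$block_id), ".", .data$block_id),
           instance_length = .data$end - .data$start) |>
    select(all_of(decomp_tsv_cols)) |>
    arrange(.data$genome, .data$chrom, .data$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a block decomposition TSV
#'
#' Inverse of [write_decomposition()] up to the information stored in the
#' file (instances and tiling; consensus sequences are not in the TSV).
#'
#' @param path TSV written by [write_decomposition()].
#' @return tibble in the TSV schema with `block_id` `NA` for non-repetitive
#'   segments.
#' @export
read_decomposition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(genome = "character",
                                         chrom = "character",
                                         block_id = "character",
                                         strand = "character"))
  df <- tibble::as_tibble(df)
  if (!identical(names(df), decomp_tsv_cols))
    abort("not a decomposition TSV")
  df$block_id[df$block_id == "."] <- NA_character_
  df |> arrange(.data$genome, .data$chrom, .data$start)
}

#' Write block consensus sequences as FASTA
#'
#' @param decomp an `sd_decomposition`.
#' @param path output file.
#' @export
write_consensus_fasta <- function(decomp, path) {
  b <- decomp$blocks
  x <- Biostrings::BStringSet(b$consensus)
  names(x) <- b$block_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
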