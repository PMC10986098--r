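#' Build a genome index
#'
#' A genome index holds the ordered chromosome names and lengths used to
#' validate fragment and region coordinates, plus (optionally) the genome
#' sequence for GC-content operations. All coordinates in the package are
#' 0-based, half-open `[start, end)`.
#'
#' @param chroms A data frame with columns `chrom` (character) and `length`
#'   (positive integer bp). Chromosome order is taken from row order.
#' @param sequence Optional [Biostrings::DNAStringSet] named by chromosome;
#'   widths must match `length`.
#' @return An object of class `genome_index`: a list with elements `chroms`
#'   (tibble) and `sequence` (`DNAStringSet` or `NULL`).
#' @examples
#' gi <- genome_index(tibble::tibble(chrom = c("chr1", "chr2"),
#'                                   length = c(10000L, 5000L)))
#' @export
genome_index <- function(chroms, sequence = NULL) {
  stopifnot(is.data.frame(chroms), all(c("chrom", "length") %in% names(chroms)))
  chroms <- tibble::tibble(chrom = as.character(chroms$chrom),
                           length = as.numeric(chroms$length))
  if (anyDuplicated(chroms$chrom)) {
    rlang::abort("duplicated chromosome names in genome index")
  }
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0)) {
    rlang::abort("chromosome lengths must be positive")
  }
  if (!is.null(sequence)) {
    if (!methods::is(sequence, "DNAStringSet")) {
      rlang::abort("`sequence` must be a DNAStringSet")
    }
    if (!all(chroms$chrom %in% names(sequence))) {
      rlang::abort("`sequence` is missing some chromosomes of the index")
    }
    sequence <- sequence[chroms$chrom]
    if (!all(Biostrings::width(sequence) == chroms$length)) {
      rlang::abort("sequence widths disagree with chromosome lengths")
    }
  }
  structure(list(chroms = chroms, sequence = sequence),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", nrow(x$chroms), " chromosome(s), ",
      format(sum(x$chroms$length), big.mark = ","), " bp",
      if (!is.null(x$sequence)) ", with sequence" else "", "\n", sep = "")
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the TSV file.
#' @return A `genome_index` without sequence.
#' @export
read_chrom_sizes <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "cd", progress = FALSE)
  genome_index(tbl)
}

#' Read a genome FASTA into a genome index
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A `genome_index` carrying the sequence.
#' @export
read_genome_fasta <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  genome_index(tibble::tibble(chrom = names(seq),
                              length = Biostrings::width(seq)),
               sequence = seq)
}

#' Write a genome index to FASTA / chrom.sizes
#'
#' @param genome A `genome_index`.
#' @param fasta,chrom_sizes Output paths; either may be `NULL` to skip.
#' @return `genome`, invisibly.
#' @export
write_genome <- function(genome, fasta = NULL, chrom_sizes = NULL) {
  stopifnot(inherits(genome, "genome_index"))
  if (!is.null(fasta)) {
    if (is.null(genome$sequence)) rlang::abort("genome has no sequence")
    Biostrings::writeXStringSet(genome$sequence, fasta)
  }
  if (!is.null(chrom_sizes)) {
    readr::write_tsv(genome$chroms, chrom_sizes, col_names = FALSE)
  }
  invisible(genome)
}

#' Extract an uppercase sequence window
#'
#' @param genome A `genome_index` with sequence.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return A character scalar of uppercase bases.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_index"))
  if (is.null(genome$sequence)) rlang::abort("genome has no sequence")
  if (!chrom %in% genome$chroms$chrom) {
    rlang::abort(paste0("unknown chromosome: ", chrom))
  }
  toupper(as.character(Biostrings::subseq(genome$sequence[[chrom]],
                                          start = start + 1L, end = end)))
}

# internal: chromosome rank used for sorting output in genome order
.chrom_rank <- function(chrom, genome) {
  match(chrom, genome$chroms$chrom)
}
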