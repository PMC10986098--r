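#' Read mapped nucleosomal DNA fragments from BED
#'
#' Parses a BED3+ file of MNase-protected fragment intervals. Coordinates are
#' 0-based half-open; columns beyond the first three are ignored. Records on
#' chromosomes absent from `genome` are dropped with a message reporting the
#' count; malformed lines (non-integer coordinates, `end <= start`) abort
#' with the offending line number.
#'
#' @param path Path to a BED file.
#' @param genome A [genome_index()] used to validate chromosome names. When
#'   `NULL`, no chromosome filtering is applied.
#' @return A tibble with columns `chrom`, `start`, `end`, `length`
#'   (`length = end - start`).
#' @seealso [write_fragments()], [compute_dyad()]
#' @export
read_fragments <- function(path, genome = NULL) {
  raw <- readr::read_tsv(path,
                         col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), length = numeric()))
  }
  if (ncol(raw) < 3) rlang::abort("BED file must have at least 3 columns")
  chrom <- raw[[1]]
  s_chr <- raw[[2]]
  e_chr <- raw[[3]]
  bad_int <- !grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr)
  if (any(bad_int)) {
    rlang::abort(paste0("malformed BED line ", which(bad_int)[1],
                        ": non-integer coordinates"))
  }
  start <- as.numeric(s_chr)
  end <- as.numeric(e_chr)
  bad_iv <- end <= start
  if (any(bad_iv)) {
    rlang::abort(paste0("malformed BED line ", which(bad_iv)[1],
                        ": end <= start"))
  }
  frags <- tibble::tibble(chrom = chrom, start = start, end = end,
                          length = end - start)
  if (!is.null(genome)) {
    known <- frags$chrom %in% genome$chroms$chrom
    n_drop <- sum(!known)
    if (n_drop > 0) {
      rlang::inform(paste0("read_fragments: dropped ", n_drop,
                           " record(s) on chromosomes absent from the genome index"))
      frags <- frags[known, ]
    }
    over <- frags$end > genome$chroms$length[.chrom_rank(frags$chrom, genome)]
    if (any(over)) {
      rlang::abort(paste0("fragment extends beyond chromosome end (record ",
                          which(over)[1], ")"))
    }
  }
  frags
}

#' Write fragments as BED3
#'
#' Output is sorted by chromosome (genome-index order when supplied,
#' lexicographic otherwise), then start, then end. Duplicate fragments are
#' preserved: fragment sets have multiset semantics. A write followed by
#' [read_fragments()] reproduces the sorted input exactly.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @param genome Optional [genome_index()] fixing chromosome order.
#' @return `fragments` (sorted as written), invisibly.
#' @export
write_fragments <- function(fragments, path, genome = NULL) {
  key <- if (!is.null(genome)) .chrom_rank(fragments$chrom, genome) else fragments$chrom
  ord <- order(key, fragments$start, fragments$end)
  out <- fragments[ord, c("chrom", "start", "end")]
  readr::write_tsv(dplyr::mutate(out,
                                 start = sprintf("%.0f", .data$start),
                                 end = sprintf("%.0f", .data$end)),
                   path, col_names = FALSE, progress = FALSE)
  invisible(fragments[ord, ])
}

#' Read per-CpG methylation levels
#'
#' Three-column TSV: chromosome, 0-based position of the CpG cytosine, and
#' methylation beta value. Betas must parse as numbers in `[0, 1]`;
#' violations abort.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom`, `position`, `beta`, in file order.
#' @export
read_methylation <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "position", "beta"),
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           position = readr::col_double(),
                           beta = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), position = numeric(),
                          beta = numeric()))
  }
  beta <- suppressWarnings(as.numeric(raw$beta))
  if (anyNA(beta)) {
    rlang::abort(paste0("methylation line ", which(is.na(beta))[1],
                        ": beta not parseable as a number"))
  }
  bad <- beta < 0 | beta > 1
  if (any(bad)) {
    rlang::abort(paste0("methylation line ", which(bad)[1],
                        ": beta outside [0, 1]"))
  }
  tibble::tibble(chrom = raw$chrom, position = raw$position, beta = beta)
}

#' Read a BED file of regions
#'
#' Columns 1-3 are mandatory; 4-6 (name, score, strand) are kept when
#' present. Strand defaults to `"*"` (unstranded).
#'
#' @param path Path to a BED3/BED6 file.
#' @return A tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @export
read_regions <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  out <- tibble::tibble(chrom = raw[[1]],
                        start = as.numeric(raw[[2]]),
                        end = as.numeric(raw[[3]]))
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(out$end <= out$start)) {
    rlang::abort("malformed region BED: coordinates must be integers with end > start")
  }
  if (ncol(raw) >= 4) out$name <- raw[[4]]
  if (ncol(raw) >= 5) out$score <- suppressWarnings(as.numeric(raw[[5]]))
  if (ncol(raw) >= 6) {
    strand <- raw[[6]]
    strand[!strand %in% c("+", "-")] <- "*"
    out$strand <- strand
  }
  out
}

#' Write regions as BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (written in BED column order).
#' @param path Output path.
#' @return `regions`, invisibly.
#' @export
write_regions <- function(regions, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(regions)) cols <- c(cols, "name")
  if ("score" %in% names(regions)) {
    if (!"name" %in% cols) regions$name <- "."
    cols <- unique(c(cols[1:3], "name", "score"))
  }
  if ("strand" %in% names(regions)) {
    if (!"name" %in% cols) regions$name <- "."
    if (!"score" %in% cols) regions$score <- 0
    cols <- c("chrom", "start", "end", "name", "score", "strand")
  }
  out <- regions[, cols]
  out$start <- sprintf("%.0f", out$start)
  out$end <- sprintf("%.0f", out$end)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(regions)
}
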