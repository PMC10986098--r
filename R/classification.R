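#' Classification configuration
#'
#' Thresholds of the discrete nucleosome repositioning calls. Fraction
#' thresholds follow bedtools `intersect -f` semantics: the integer overlap
#' is compared with `>=` to the real-valued fraction of the fragment
#' length, without rounding.
#'
#' @param f_stable Fraction of a fragment that must be reproduced in
#'   another patient for the fragment to be "stable" (non-reciprocal,
#'   default 0.99, i.e. about 1 bp mismatch on a core particle).
#' @param f_common Fraction for the "common" call between conditions
#'   (non-reciprocal, default 0.99).
#' @param f_shift Reciprocal fraction whose *failure* defines "shifted"
#'   (default 0.80: a fragment whose coordinates moved by more than 20%).
#' @param size_band Fragment-length band `[low, high)` applied to all
#'   inputs (default `c(120, 180)`; the chromatosome-only alternative is
#'   `c(160, 180)`).
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(f_stable = 0.99, f_common = 0.99,
                                  f_shift = 0.80, size_band = c(120, 180)) {
  stopifnot(f_stable > 0, f_stable <= 1, f_common > 0, f_common <= 1,
            f_shift > 0, f_shift <= 1)
  structure(list(f_stable = f_stable, f_common = f_common,
                 f_shift = f_shift, size_band = size_band),
            class = "classification_config")
}

#' Overlap in base pairs between two half-open intervals
#'
#' @param a,b Tibbles (or lists) with `chrom`, `start`, `end`; recycled
#'   elementwise.
#' @return Numeric vector: `max(0, min(end) - max(start))`, 0 across
#'   chromosomes. Abutting half-open intervals overlap by 0.
#' @export
overlap_bp <- function(a, b) {
  o <- pmin(a$end, b$end) - pmax(a$start, b$start)
  o[a$chrom != b$chrom] <- 0
  pmax(o, 0)
}

# internal: IRanges per chromosome, 0-based half-open -> 1-based closed
.as_iranges <- function(x) IRanges::IRanges(start = x$start + 1, end = x$end)

#' Fraction-of-overlap matching
#'
#' For each query fragment, tests whether some subject fragment overlaps it
#' by at least `f` times the query length (and, when `reciprocal`, also at
#' least `f` times the subject length) — the semantics of
#' `bedtools intersect -u -f` / `-f -r`.
#'
#' @param query,subject Fragment tibbles.
#' @param f Required overlap fraction in `(0, 1]`.
#' @param reciprocal Require the fraction on both fragments.
#' @return Logical vector along the rows of `query`.
#' @export
has_match <- function(query, subject, f, reciprocal = FALSE) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    q <- .as_iranges(query[qi, ])
    s <- .as_iranges(subject[si, ])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(BiocGenerics::end(q)[qh], BiocGenerics::end(s)[sh]) -
      pmax(BiocGenerics::start(q)[qh], BiocGenerics::start(s)[sh]) + 1
    ok <- ov >= f * BiocGenerics::width(q)[qh]
    if (reciprocal) ok <- ok & ov >= f * BiocGenerics::width(s)[sh]
    out[qi[unique(qh[ok])]] <- TRUE
  }
  out
}

#' Call stable nucleosomes
#'
#' A fragment of one patient/condition is "stable" when its coordinates are
#' reproduced (at fraction `f_stable` of its own length, non-reciprocal) in
#' at least one other patient's fragment set from the same condition.
#'
#' @param sample Fragment tibble of the focal patient and condition,
#'   already restricted to the analysis size band.
#' @param others List of fragment tibbles from other patients (same
#'   condition, same band). Must be non-empty.
#' @param config A [classification_config()].
#' @return The stable subset of `sample`.
#' @export
call_stable <- function(sample, others, config = classification_config()) {
  if (!is.list(others) || length(others) == 0 || is.data.frame(others)) {
    rlang::abort("`others` must be a non-empty list of fragment tables")
  }
  stable <- logical(nrow(sample))
  for (o in others) {
    todo <- which(!stable)
    if (length(todo) == 0) break
    stable[todo] <- has_match(sample[todo, ], o, config$f_stable,
                              reciprocal = FALSE)
  }
  sample[stable, ]
}

#' Call common and shifted nucleosomes
#'
#' Both labels are computed independently from the reference-condition
#' stable set: "common" fragments have a non-reciprocal `f_common` match in
#' the other condition; "shifted" fragments have *no* reciprocal `f_shift`
#' match there. Fragments whose best overlap falls between the two
#' thresholds carry neither label — the classes are not a partition.
#'
#' @param stable_a Stable fragments of the reference condition (e.g.
#'   normal).
#' @param stable_b Stable fragments of the comparison condition.
#' @param config A [classification_config()].
#' @return A list with elements `common` and `shifted` (subsets of
#'   `stable_a`).
#' @export
call_common_shifted <- function(stable_a, stable_b,
                                config = classification_config()) {
  common <- has_match(stable_a, stable_b, config$f_common, reciprocal = FALSE)
  shifted <- !has_match(stable_a, stable_b, config$f_shift, reciprocal = TRUE)
  list(common = stable_a[common, ], shifted = stable_a[shifted, ])
}

#' Call gained and lost nucleosomes
#'
#' Gained fragments are stable in condition B and overlap no stable-A
#' fragment by even 1 bp; lost fragments are stable in A with zero overlap
#' against every stable-B fragment. The two calls are symmetric under
#' swapping A and B.
#'
#' @param stable_a,stable_b Stable fragment tibbles of the two conditions.
#' @return A list with elements `gained_b` and `lost_b`.
#' @export
call_gained_lost <- function(stable_a, stable_b) {
  no_overlap <- function(query, subject) {
    hit <- logical(nrow(query))
    for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
      qi <- which(query$chrom == ch)
      si <- which(subject$chrom == ch)
      hit[qi] <- IRanges::overlapsAny(.as_iranges(query[qi, ]),
                                      .as_iranges(subject[si, ]))
    }
    query[!hit, ]
  }
  list(gained_b = no_overlap(stable_b, stable_a),
       lost_b = no_overlap(stable_a, stable_b))
}

#' Classify nucleosome repositioning between two conditions
#'
#' Full discrete classification for one patient: size-band filtering,
#' stable calling against the other patients within each condition, then
#' common/shifted (from stable A) and gained/lost (zero-overlap rule)
#' between the conditions.
#'
#' @param frags_a,frags_b Fragment tibbles of the focal patient in the
#'   reference (A) and comparison (B) condition.
#' @param others_a,others_b Lists of other-patient fragment tibbles for the
#'   two conditions (same assay; pooling across assays is the caller's
#'   decision).
#' @param config A [classification_config()].
#' @return An object of class `nucleosome_class_set`: list of fragment
#'   tibbles `stable_a`, `stable_b`, `common`, `shifted`, `gained_b`,
#'   `lost_b`, plus a `counts` tibble.
#' @export
classify_pair <- function(frags_a, frags_b, others_a, others_b,
                          config = classification_config()) {
  band <- function(x) filter_by_size(x, config$size_band[1], config$size_band[2])
  stable_a <- call_stable(band(frags_a), lapply(others_a, band), config)
  stable_b <- call_stable(band(frags_b), lapply(others_b, band), config)
  cs <- call_common_shifted(stable_a, stable_b, config)
  gl <- call_gained_lost(stable_a, stable_b)
  sets <- list(stable_a = stable_a, stable_b = stable_b,
               common = cs$common, shifted = cs$shifted,
               gained_b = gl$gained_b, lost_b = gl$lost_b)
  counts <- tibble::tibble(class = names(sets),
                           n = vapply(sets, nrow, integer(1)))
  structure(c(sets, list(counts = counts, config = config)),
            class = "nucleosome_class_set")
}

#' @export
print.nucleosome_class_set <- function(x, ...) {
  cat("<nucleosome_class_set>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat("  ", format(x$counts$class[i], width = 9), x$counts$n[i], "\n")
  }
  invisible(x)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::tidy
tidy.nucleosome_class_set <- function(x, ...) {
  purrr::imap(x[c("stable_a", "stable_b", "common", "shifted",
                  "gained_b", "lost_b")],
              \(tbl, cls) dplyr::mutate(tbl, class = cls)) |>
    dplyr::bind_rows()
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::glance
glance.nucleosome_class_set <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "class", values_from = "n")
}
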