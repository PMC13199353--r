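#' Construct a plastome object
#'
#' A `plastome` bundles one sample's circular genome sequence with its
#' annotated features.  Coordinates are 1-based inclusive throughout; features
#' that span the origin of the circular molecule are stored as split intervals
#' normalized into `[1, L]` with `spans_origin = TRUE`.
#'
#' @param sample_id sample identifier.
#' @param sequence DNA string (uppercased; ambiguity codes other than N are
#'   converted to N with a warning).
#' @param features list of features built with [feature()]; sorted by 5'-most
#'   coordinate on construction.
#' @param source_path optional path the record was read from.
#' @return an object of class `plastome` with fields `sample_id`, `sequence`,
#'   `features`, `source_path`.
#' @export
plastome <- function(sample_id, sequence, features = list(),
                     source_path = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  sequence <- sanitize_dna(sequence)
  L <- nchar(sequence)
  for (f in features) {
    if (any(f$intervals[, "start"] < 1L) || any(f$intervals[, "end"] > L))
      stop("feature '", f$name, "' has intervals outside [1, ", L, "]")
  }
  features <- features[order(vapply(features, function(f)
    min(f$intervals[, "start"]), numeric(1L)))]
  structure(list(sample_id = sample_id, sequence = sequence,
                 features = features, source_path = source_path),
            class = "plastome")
}

#' Construct an annotated feature
#'
#' @param name gene symbol (e.g. `"ycf1"`, `"trnH-GUG"`).
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"gene"`, `"other"`.
#' @param intervals integer matrix with columns `start`, `end`, `strand`
#'   (1-based inclusive; strand +1/-1), rows in translation order.
#' @param spans_origin does the feature cross the circular origin?
#' @return an object of class `plastome_feature`.
#' @export
feature <- function(name, kind, intervals, spans_origin = FALSE) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "gene", "other"))
  if (is.null(dim(intervals))) intervals <- matrix(intervals, nrow = 1L)
  intervals <- matrix(as.integer(intervals), ncol = 3L,
                      dimnames = list(NULL, c("start", "end", "strand")))
  stopifnot(nrow(intervals) >= 1L,
            all(intervals[, "end"] >= intervals[, "start"]),
            all(intervals[, "strand"] %in% c(1L, -1L)))
  if (length(unique(intervals[, "strand"])) != 1L)
    stop("feature '", name, "': strand must be consistent within a feature")
  len <- sum(intervals[, "end"] - intervals[, "start"] + 1L)
  if (kind == "CDS" && len < 3L)
    stop("CDS feature '", name, "' shorter than one codon")
  structure(list(name = name, kind = kind, intervals = intervals,
                 spans_origin = isTRUE(spans_origin)),
            class = "plastome_feature")
}

#' @export
print.plastome <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, character(1L), "kind")
  cat(sprintf("<plastome> %s: %s bp, %d features (%d CDS, %d tRNA, %d rRNA)\n",
              x$sample_id, format(nchar(x$sequence), big.mark = ","),
              length(x$features), sum(kinds == "CDS"),
              sum(kinds == "tRNA"), sum(kinds == "rRNA")))
  invisible(x)
}

#' @export
print.plastome_feature <- function(x, ...) {
  iv <- apply(x$intervals, 1L, function(r)
    sprintf("%d..%d(%s)", r[["start"]], r[["end"]],
            if (r[["strand"]] > 0) "+" else "-"))
  cat(sprintf("<feature> %s [%s] %s%s\n", x$name, x$kind,
              paste(iv, collapse = ","),
              if (x$spans_origin) " spans-origin" else ""))
  invisible(x)
}

## total spliced length of a feature
#' @noRd
feature_length <- function(f) {
  sum(f$intervals[, "end"] - f$intervals[, "start"] + 1L)
}

## 5'-most genomic coordinate of a feature
#' @noRd
feature_start <- function(f) min(f$intervals[, "start"])

## Extract the spliced (translation-order) sequence of a feature.
#' @noRd
feature_sequence <- function(p, f) {
  parts <- apply(f$intervals, 1L, function(r) {
    s <- substr(p$sequence, r[["start"]], r[["end"]])
    if (r[["strand"]] < 0L) revcomp(s) else s
  })
  paste(parts, collapse = "")
}
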