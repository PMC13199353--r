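## Per-region nucleotide diversity, SNP counts, length polymorphism and
## group-diagnostic sites.
##
## Pi follows the Nei-Li definition: the average number of nucleotide
## differences per site over all pairwise sequence comparisons,
##   Pi = 2 / (n (n - 1)) * sum_{i<j} d_ij / L_ij,
## where d_ij counts alignment columns at which rows i and j carry
## different A/C/G/T bases and L_ij counts columns at which both carry an
## A/C/G/T base (pairwise deletion; gaps and N are not states).

#' @noRd
alignment_matrix <- function(a) {
  rows <- if (inherits(a, "aligned_region")) a$rows else a
  stopifnot(length(unique(nchar(rows))) == 1L)
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Nucleotide diversity (Nei-Li Pi) of an aligned region
#'
#' @param a an `aligned_region` (or named character vector of equal-length
#'   gapped sequences).
#' @param deletion `"pairwise"` (default): each pair is compared over the
#'   columns where both rows have an unambiguous base; `"complete"`:
#'   only columns where every row has an unambiguous base are used.
#' @return Pi (numeric scalar in [0, 1]).
#' @export
nucleotide_diversity <- function(a, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- alignment_matrix(a)
  n <- nrow(m)
  if (n < 2L) stop("Pi is undefined for fewer than 2 sequences")
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  if (deletion == "complete") {
    keep <- colSums(valid) == n
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  tot <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- valid[i, ] & valid[j, ]
      Lij <- sum(both)
      if (Lij == 0L) next
      dij <- sum(m[i, both] != m[j, both])
      tot <- tot + dij / Lij
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) return(NA_real_)
  tot * 2 / (n * (n - 1L))
}

#' SNP count of an aligned region
#'
#' The number of alignment columns containing at least two distinct bases
#' among A/C/G/T; gaps and N are ignored as states.
#'
#' @inheritParams nucleotide_diversity
#' @return integer count.
#' @export
count_snps <- function(a) {
  m <- alignment_matrix(a)
  if (nrow(m) < 2L) stop("SNP count needs at least 2 sequences")
  sum(apply(m, 2L, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) >= 2L
  }))
}

#' Length polymorphism of a region group
#'
#' Flags samples whose raw (unaligned) region length deviates from the group
#' median by at least `delta`.
#'
#' @param group named character vector of raw sequences (or a group entry
#'   from [group_regions_by_reference()]), or a named numeric vector of
#'   lengths.
#' @param delta minimum absolute deviation from the median, in bp
#'   (default 50).
#' @return list with `raw_len_min`, `raw_len_max`, and `expansions`
#'   (data frame sample_id, length, delta_bp = length - median).
#' @export
length_polymorphism <- function(group, delta = 50L) {
  if (is.list(group) && !is.null(group$sequences)) group <- group$sequences
  lens <- if (is.numeric(group)) group else nchar(group)
  stopifnot(length(lens) > 0L)
  med <- stats::median(lens)
  dev <- lens - med
  hit <- which(abs(dev) >= delta)
  list(raw_len_min = min(lens), raw_len_max = max(lens),
       expansions = data.frame(sample_id = names(lens)[hit] %||%
                                 as.character(hit),
                               length = unname(lens[hit]),
                               delta_bp = unname(dev[hit])))
}

#' Group-diagnostic sites in an alignment
#'
#' Returns every alignment column at which the two sample groups are each
#' monomorphic for a different unambiguous base — the pattern expected of a
#' lineage-diagnostic substitution.
#'
#' @param a an `aligned_region` (or named character vector of gapped rows).
#' @param labels named character vector mapping sample -> group label
#'   (exactly two distinct labels among the rows).
#' @param ref_row optional row name; when given, each site is also reported
#'   as the 1-based ungapped position in that row (NA if the reference row
#'   is gapped at the column).
#' @return data frame with `column` (1-based alignment column), one allele
#'   column per group label, `perfect` (always TRUE under this definition),
#'   and optionally `ref_position`.
#' @export
find_diagnostic_sites <- function(a, labels, ref_row = NULL) {
  m <- alignment_matrix(a)
  labels <- labels[rownames(m)[rownames(m) %in% names(labels)]]
  m <- m[names(labels), , drop = FALSE]
  grp <- unique(labels)
  if (length(grp) != 2L)
    stop("labels must define exactly 2 non-empty groups (got ",
         length(grp), ")")
  g1 <- m[labels == grp[1L], , drop = FALSE]
  g2 <- m[labels == grp[2L], , drop = FALSE]
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("a group is empty")
  mono <- function(g) {
    apply(g, 2L, function(col) {
      u <- unique(col)
      if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else NA_character_
    })
  }
  a1 <- mono(g1)
  a2 <- mono(g2)
  hit <- which(!is.na(a1) & !is.na(a2) & a1 != a2)
  out <- data.frame(column = hit, allele1 = a1[hit], allele2 = a2[hit],
                    perfect = rep(TRUE, length(hit)), row.names = NULL)
  names(out)[2:3] <- paste0("allele_", grp)
  if (!is.null(ref_row)) {
    stopifnot(ref_row %in% rownames(m))
    rchars <- m[ref_row, ]
    ungapped <- cumsum(rchars != "-")
    out$ref_position <- ifelse(rchars[hit] == "-", NA_integer_,
                               ungapped[hit])
  }
  out
}

#' Per-region diversity table across samples
#'
#' Runs [align_region()], [nucleotide_diversity()], [count_snps()] and
#' [length_polymorphism()] over every region group and returns the combined
#' table.
#'
#' @param groups the `groups` element of [group_regions_by_reference()].
#' @param min_n skip groups with fewer sequences (default 2).
#' @param delta length-polymorphism threshold (bp).
#' @param ... passed to [align_region()].
#' @return data frame (name, kind, n, aligned_len, pi, snp_count,
#'   raw_len_min, raw_len_max, n_expanded).
#' @export
diversity_table <- function(groups, min_n = 2L, delta = 50L, ...) {
  rows <- lapply(groups, function(g) {
    seqs <- g$sequences[nchar(g$sequences) > 0L]
    if (length(seqs) < min_n) return(NULL)
    lp <- length_polymorphism(seqs, delta = delta)
    if (length(unique(seqs)) == 1L) {
      ## identical rows align trivially; skip the aligner
      a <- structure(list(name = g$name, kind = g$kind, rows = seqs,
                          aligned_len = nchar(seqs[[1L]])),
                     class = "aligned_region")
    } else {
      a <- align_region(g, ...)
    }
    data.frame(name = g$name, kind = g$kind, n = length(seqs),
               aligned_len = a$aligned_len,
               pi = nucleotide_diversity(a), snp_count = count_snps(a),
               raw_len_min = lp$raw_len_min, raw_len_max = lp$raw_len_max,
               n_expanded = nrow(lp$expansions))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}
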