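## Codon counting and relative synonymous codon usage (RSCU).
##
## RSCU for codon i in a synonymous family F is |F| * x_i / sum_{j in F} x_j:
## 1 means the codon is used exactly as often as expected under uniform use
## of its family.  The plastid/bacterial genetic code (NCBI translation
## table 11) defines the families.

#' Extract CDS nucleotide sequences from an annotated plastome
#'
#' Concatenates each CDS feature's intervals in translation order, reverse
#' complementing minus-strand parts.  IR-duplicated genes yield one entry per
#' copy.
#'
#' @param p a [plastome()].
#' @return named character vector of CDS sequences (names are gene names;
#'   duplicated names are kept as-is — see [standardize_feature_names()] for
#'   disambiguation).
#' @export
extract_cds_sequences <- function(p) {
  cds <- p$features[vapply(p$features, `[[`, character(1L), "kind") == "CDS"]
  out <- vapply(cds, function(f) feature_sequence(p, f), character(1L))
  names(out) <- vapply(cds, `[[`, character(1L), "name")
  out
}

#' Count codons across a set of CDS sequences
#'
#' Reads non-overlapping triplets from position 1 of each CDS.  A trailing
#' remainder (length not a multiple of 3) is dropped with a warning; the
#' terminal stop codon (TAA/TAG/TGA in the last frame position) is excluded;
#' triplets containing N are skipped and tallied.  Genes with an internal
#' in-frame stop codon are listed in `skipped` and, by default, excluded
#' from the counts so that downstream RSCU is not distorted by pseudogenes.
#'
#' @param cds named character vector of CDS sequences.
#' @param sample_id identifier carried into the result.
#' @param drop_internal_stop exclude genes with internal stops from the
#'   counts (default TRUE); they are always reported in `skipped`.
#' @return object of class `codon_counts`: list with `sample_id`, `counts`
#'   (named integer vector over the 64 codons), `total_codons`,
#'   `n_genes_used`, `n_skipped_triplets`, and `skipped` (data frame
#'   gene/reason).
#' @export
count_codons <- function(cds, sample_id = NA_character_,
                         drop_internal_stop = TRUE) {
  codons64 <- all_codons()
  counts <- setNames(integer(64L), codons64)
  stops <- c("TAA", "TAG", "TGA")
  skipped <- list()
  n_skip_trip <- 0L
  n_used <- 0L
  for (g in seq_along(cds)) {
    s <- cds[[g]]
    gname <- names(cds)[g] %||% sprintf("cds%d", g)
    if (is.null(names(cds)) || is.na(gname) || gname == "")
      gname <- sprintf("cds%d", g)
    if (nchar(s) < 3L) next
    rem <- nchar(s) %% 3L
    if (rem != 0L) {
      warning("CDS '", gname, "' length ", nchar(s),
              " not a multiple of 3; trailing ", rem, " base(s) dropped",
              call. = FALSE)
      s <- substr(s, 1L, nchar(s) - rem)
    }
    starts <- seq(1L, nchar(s), by = 3L)
    trip <- substring(s, starts, starts + 2L)
    ## terminal stop excluded from counting
    if (trip[length(trip)] %in% stops) trip <- trip[-length(trip)]
    has_n <- !trip %in% codons64
    n_skip_trip <- n_skip_trip + sum(has_n)
    trip <- trip[!has_n]
    if (any(trip %in% stops)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene = gname, reason = "internal_stop")
      if (drop_internal_stop) next
    }
    tab <- table(factor(trip, levels = codons64))
    counts <- counts + as.integer(tab)
    n_used <- n_used + 1L
  }
  structure(list(sample_id = sample_id, counts = counts,
                 total_codons = sum(counts), n_genes_used = n_used,
                 n_skipped_triplets = n_skip_trip,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else data.frame(gene = character(0L),
                                           reason = character(0L))),
            class = "codon_counts")
}

#' @noRd
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

## codon -> amino acid under NCBI translation table 11
#' @noRd
codon_table11 <- function() {
  gc <- Biostrings::getGeneticCode("11")
  gc[all_codons()]
}

#' Relative synonymous codon usage
#'
#' @param x a `codon_counts` object (or a named integer vector of codon
#'   counts).
#' @return data frame of class `rscu_table` with columns `codon`,
#'   `amino_acid` (one-letter; `*` = stop), `family_size`, `count`, `rscu`.
#'   Codons of a family with zero total count have `rscu = NA` (undefined),
#'   not 0.  Within every observed family the RSCU values sum to the family
#'   size.
#' @export
rscu <- function(x) {
  counts <- if (inherits(x, "codon_counts")) x$counts else x
  code <- codon_table11()
  counts <- counts[names(code)]
  fam_tot <- tapply(counts, code, sum)
  fam_size <- table(code)
  vals <- ifelse(fam_tot[code] > 0,
                 as.numeric(fam_size[code]) * counts / as.numeric(fam_tot[code]),
                 NA_real_)
  out <- data.frame(codon = names(code), amino_acid = unname(code),
                    family_size = as.integer(fam_size[code]),
                    count = as.integer(counts), rscu = as.numeric(vals),
                    row.names = NULL)
  if (inherits(x, "codon_counts")) attr(out, "sample_id") <- x$sample_id
  class(out) <- c("rscu_table", class(out))
  out
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf(
    "<codon_counts> %s: %d codons over %d genes (%d skipped triplet(s), %d gene(s) flagged)\n",
    x$sample_id, x$total_codons, x$n_genes_used, x$n_skipped_triplets,
    nrow(x$skipped)))
  invisible(x)
}

#' Long-format RSCU table across samples
#'
#' Convenience wrapper producing the per-sample long table (sample, codon,
#' amino_acid, count, RSCU) that heatmap tools consume.
#'
#' @param plastomes list of [plastome()] objects.
#' @param ... passed to [count_codons()].
#' @return data frame with one row per sample x codon.
#' @export
rscu_batch <- function(plastomes, ...) {
  rows <- lapply(plastomes, function(p) {
    cc <- count_codons(extract_cds_sequences(p), sample_id = p$sample_id, ...)
    tab <- rscu(cc)
    cbind(sample_id = p$sample_id, tab)
  })
  do.call(rbind, rows)
}
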