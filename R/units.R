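## Gene units: the feature set used for junction reports, gene counting and
## region tiling.  Records annotated with explicit `gene` features use those;
## otherwise the CDS/tRNA/rRNA features stand in as units.

#' @noRd
select_units <- function(p) {
  kinds <- vapply(p$features, `[[`, character(1L), "kind")
  if (any(kinds == "gene")) p$features[kinds == "gene"]
  else p$features[kinds %in% c("CDS", "tRNA", "rRNA")]
}

## Genomic span of a feature as c(start, end); start > end encodes an
## origin-wrapping span (normalized split-interval form: one part ending at
## L, one starting at 1).
#' @noRd
unit_span <- function(f, L) {
  iv <- f$intervals
  if (!f$spans_origin) return(c(min(iv[, "start"]), max(iv[, "end"])))
  head_part <- iv[iv[, "end"] == L, , drop = FALSE]
  tail_part <- iv[iv[, "start"] == 1L, , drop = FALSE]
  if (nrow(head_part) == 0L || nrow(tail_part) == 0L)
    return(c(min(iv[, "start"]), max(iv[, "end"])))
  c(min(head_part[, "start"]), max(tail_part[, "end"]))
}

## Classify a gene unit as PCG / tRNA / rRNA, preferring same-name typed
## features and falling back on naming convention.
#' @noRd
classify_gene <- function(p, name) {
  base <- sub("(_part[0-9]+)?(_copy[0-9]+)?$", "", name)
  kinds <- vapply(p$features, `[[`, character(1L), "kind")
  names_ <- vapply(p$features, `[[`, character(1L), "name")
  typed <- kinds[names_ == base & kinds %in% c("CDS", "tRNA", "rRNA")]
  if (length(typed) > 0L)
    return(switch(typed[1L], CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA"))
  if (grepl("^trn", base)) "tRNA"
  else if (grepl("^rrn", base)) "rRNA"
  else "PCG"
}
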