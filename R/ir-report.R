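## Junction-gene reports and basic genome statistics.

## does circular interval span (s,e) contain position pos?
#' @noRd
circ_contains <- function(span, pos, L) {
  ((pos - span[1L]) %% L) <= ((span[2L] - span[1L]) %% L)
}

#' Genes spanning or adjacent to the IR junctions
#'
#' For each of the four junctions (JLB, JSB, JSA, JLA) reports the nearest
#' gene unit strictly on each side (constrained to the flanking region) with
#' its distance in bp from the gene's nearest end to the junction, and any
#' gene whose span contains the junction, with its overhang into each
#' region.
#'
#' @param p a [plastome()].
#' @param ir an `ir_partition` for `p`.
#' @return data frame of class `junction_gene_report` with columns
#'   `junction`, `side` (`left`/`right`/`spanning`), `gene`, `distance`
#'   (bp; NA for spanning rows), `overhang_left`, `overhang_right`
#'   (bp into the upstream/downstream region; NA unless spanning).
#' @export
junction_genes <- function(p, ir) {
  L <- ir$genome_len
  stopifnot(nchar(p$sequence) == L)
  order_ <- list(JLB = c("lsc", "irb"), JSB = c("irb", "ssc"),
                 JSA = c("ssc", "ira"), JLA = c("ira", "lsc"))
  units <- select_units(p)
  spans <- lapply(units, unit_span, L = L)
  unames <- vapply(units, `[[`, character(1L), "name")
  rows <- list()
  add <- function(junction, side, gene, distance = NA_integer_,
                  oh_l = NA_integer_, oh_r = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      junction = junction, side = side, gene = gene,
      distance = distance, overhang_left = oh_l, overhang_right = oh_r)
  }
  contained_in <- function(span, region) {
    circ_contains(region, span[1L], L) && circ_contains(region, span[2L], L) &&
      circ_len(span[1L], span[2L], L) <= circ_len(region[1L], region[2L], L)
  }
  for (jn in names(order_)) {
    J <- ir$junctions[[jn]]
    up <- ir[[order_[[jn]][1L]]]
    down <- ir[[order_[[jn]][2L]]]
    ## spanning: unit containing both base J and base J+1
    nextb <- (J %% L) + 1L
    for (i in seq_along(units)) {
      sp <- spans[[i]]
      if (circ_contains(sp, J, L) && circ_contains(sp, nextb, L)) {
        add(jn, "spanning", unames[i],
            oh_l = ((J - sp[1L]) %% L) + 1L,
            oh_r = ((sp[2L] - nextb) %% L) + 1L)
      }
    }
    ## nearest unit entirely within the upstream region
    in_up <- which(vapply(spans, contained_in, logical(1L), region = up))
    if (length(in_up) > 0L) {
      d <- vapply(in_up, function(i) (J - spans[[i]][2L]) %% L, numeric(1L))
      i <- in_up[which.min(d)]
      add(jn, "left", unames[i], distance = as.integer(min(d)))
    }
    in_down <- which(vapply(spans, contained_in, logical(1L), region = down))
    if (length(in_down) > 0L) {
      d <- vapply(in_down, function(i) (spans[[i]][1L] - nextb) %% L,
                  numeric(1L))
      i <- in_down[which.min(d)]
      add(jn, "right", unames[i], distance = as.integer(min(d)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("junction_gene_report", class(out))
  out
}

#' @noRd
gc_percent <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T", "N")))
  denom <- sum(tab[c("A", "C", "G", "T")])
  if (denom == 0L) return(NA_real_)
  100 * sum(tab[c("G", "C")]) / denom
}

#' Basic genome statistics
#'
#' Computes total and per-region GC content (N excluded from the
#' denominator), region lengths, gene counts (total units and unique gene
#' names, plus per-class unique counts), and the coding fraction (union of
#' CDS intervals over the genome length).
#'
#' @param p a [plastome()].
#' @param ir an `ir_partition` for `p`, or `NULL` for a genome without a
#'   detected quadripartite structure (region columns become `NA`).
#' @return a one-row data frame of class `genome_stats`.
#' @export
genome_stats <- function(p, ir = NULL) {
  L <- nchar(p$sequence)
  units <- select_units(p)
  unames <- vapply(units, `[[`, character(1L), "name")
  uniq <- unique(unames)
  classes <- vapply(uniq, function(nm) classify_gene(p, nm), character(1L))
  ## union of CDS intervals
  cds <- p$features[vapply(p$features, `[[`, character(1L), "kind") == "CDS"]
  coding_bp <- 0L
  if (length(cds) > 0L) {
    iv <- do.call(rbind, lapply(cds, `[[`, "intervals"))
    rng <- IRanges::reduce(IRanges::IRanges(iv[, "start"], iv[, "end"]))
    coding_bp <- sum(IRanges::width(rng))
  }
  out <- data.frame(
    sample_id = p$sample_id,
    total_len = L,
    lsc_len = if (is.null(ir)) NA_integer_ else
      circ_len(ir$lsc[1L], ir$lsc[2L], L),
    ssc_len = if (is.null(ir)) NA_integer_ else
      circ_len(ir$ssc[1L], ir$ssc[2L], L),
    ir_len = if (is.null(ir)) NA_integer_ else
      circ_len(ir$irb[1L], ir$irb[2L], L),
    gc_total = gc_percent(p$sequence),
    gc_lsc = if (is.null(ir)) NA_real_ else
      gc_percent(region_sequence(p, ir, "lsc")),
    gc_ssc = if (is.null(ir)) NA_real_ else
      gc_percent(region_sequence(p, ir, "ssc")),
    gc_ir = if (is.null(ir)) NA_real_ else
      gc_percent(region_sequence(p, ir, "irb")),
    n_genes = length(units),
    n_genes_unique = length(uniq),
    n_pcg = sum(classes == "PCG"),
    n_trna = sum(classes == "tRNA"),
    n_rrna = sum(classes == "rRNA"),
    coding_fraction = 100 * coding_bp / L)
  class(out) <- c("genome_stats", class(out))
  out
}
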