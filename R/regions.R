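## Standardized gene-unit naming and CDS/IGS region extraction.
##
## So that every intergenic spacer can be identified consistently across
## samples, gene names are standardized before tiling:
##   (1) standard gene names are retained;
##   (2) a gene represented by several distinct fragments (e.g. the
##       trans-spliced rps12) has its fragments numbered in genomic order:
##       name_part1, name_part2, ...;
##   (3) a name recurring at different start positions with the same content
##       (an IR-duplicated gene or fragment) is a duplicated copy:
##       second and later occurrences get _copy1, _copy2, ...;
##   (4) adjacent units that overlap, or whose spacer is shorter than the
##       merge threshold, become one merged unit named "A-merge-B".
## Fragments (rule 2) are distinguished from duplicated copies (rule 3) by
## their spliced length: same-name features of equal length are copies of
## one fragment; unequal lengths are different fragments.

#' Standardize gene-unit names
#'
#' Applies the four naming rules above and returns a plastome whose
#' gene-level unit features carry the standardized names (merged units are
#' single features of kind `gene` spanning their members).  Typed features
#' (CDS/tRNA/rRNA) keep their original names so sequence extraction still
#' works; each unit feature records its member loci in `$members`.
#'
#' @param p a [plastome()].
#' @param merge_threshold spacers shorter than this many bp trigger rule (4)
#'   merging (default 10).
#' @return a [plastome()] with standardized unit features.
#' @export
standardize_feature_names <- function(p, merge_threshold = 10L) {
  L <- nchar(p$sequence)
  units <- select_units(p)
  typed <- p$features[vapply(p$features, `[[`, character(1L), "kind") %in%
                        c("CDS", "tRNA", "rRNA")]
  ## ensure units are gene-level stand-ins with original name/start recorded
  units <- lapply(units, function(f) {
    f$orig_name <- f$name
    f$orig_start <- feature_start(f)
    f
  })
  units <- units[order(vapply(units, function(f) unit_span(f, L)[1L],
                              integer(1L)))]

  ## rules (2) and (3): fragment parts by distinct spliced length, copies
  ## within equal length
  unames <- vapply(units, `[[`, character(1L), "name")
  for (nm in unique(unames)) {
    idx <- which(unames == nm)
    if (length(idx) < 2L) next
    lens <- vapply(units[idx], feature_length, integer(1L))
    frag_lens <- unique(lens)          # genomic order of first occurrence
    multi_frag <- length(frag_lens) > 1L
    for (fi in seq_along(frag_lens)) {
      sub <- idx[lens == frag_lens[fi]]
      base <- if (multi_frag) sprintf("%s_part%d", nm, fi) else nm
      for (ci in seq_along(sub)) {
        units[[sub[ci]]]$name <-
          if (ci == 1L) base else sprintf("%s_copy%d", base, ci - 1L)
      }
    }
  }

  ## rule (4): merge overlapping / near-adjacent units along the forward
  ## strand (linear pass; the circular last-first gap is never merged)
  spans <- vapply(units, function(f) unit_span(f, L), integer(2L))
  merged <- list()
  i <- 1L
  while (i <= length(units)) {
    cur <- units[[i]]
    cur_span <- spans[, i]
    members <- list(list(name = cur$name, orig_name = cur$orig_name,
                         orig_start = cur$orig_start, kind = cur$kind))
    cur_name <- cur$name
    j <- i + 1L
    while (j <= length(units) && cur_span[1L] <= cur_span[2L]) {
      nxt_span <- spans[, j]
      spacer <- nxt_span[1L] - cur_span[2L] - 1L
      if (spacer >= merge_threshold) break
      nxt <- units[[j]]
      cur_name <- paste0(cur_name, "-merge-", nxt$name)
      cur_span[2L] <- max(cur_span[2L], nxt_span[2L])
      members[[length(members) + 1L]] <-
        list(name = nxt$name, orig_name = nxt$orig_name,
             orig_start = nxt$orig_start, kind = nxt$kind)
      j <- j + 1L
    }
    if (length(members) == 1L) {
      u <- cur
      u$name <- cur_name
    } else {
      u <- feature(cur_name, "gene",
                   c(cur_span[1L], cur_span[2L], cur$intervals[1L, "strand"]))
      u$orig_name <- NA_character_
      u$orig_start <- cur_span[1L]
    }
    u$members <- members
    merged[[length(merged) + 1L]] <- u
    i <- j
  }

  out <- p
  out$features <- c(lapply(merged, promote_to_gene), typed)
  out$features <- out$features[order(vapply(out$features, feature_start,
                                            integer(1L)))]
  out
}

## unit features are exposed at gene level so select_units() picks exactly
## the standardized tiling
#' @noRd
promote_to_gene <- function(f) {
  if (f$kind != "gene") f$kind <- "gene"
  f
}

#' Extract standardized CDS and IGS regions
#'
#' Tiles the genome at the gene-unit level: every standardized unit yields a
#' region (`CDS` for protein-coding units, carrying the spliced coding
#' sequence; `gene` for other units, carrying the genomic span), and every
#' gap between consecutive units yields an `IGS` region named
#' `"leftGene-rightGene"` in forward-strand order, including the circular
#' gap between the last and first unit.  Zero-length gaps emit no IGS.
#'
#' @param p a [plastome()] whose features have been passed through
#'   [standardize_feature_names()].
#' @return object of class `region_set`: list with `sample_id` and
#'   `regions`, a data frame (name, kind, start, end, strand, length,
#'   sequence).  `length` is the genomic span; for CDS regions `sequence`
#'   is the spliced CDS which may be shorter than the span.
#' @export
extract_regions <- function(p) {
  L <- nchar(p$sequence)
  units <- select_units(p)
  if (length(units) == 0L)
    stop("no gene units; run standardize_feature_names() on an annotated plastome")
  spans <- vapply(units, function(f) unit_span(f, L), integer(2L))
  ord <- order(spans[1L, ])
  units <- units[ord]
  spans <- spans[, ord, drop = FALSE]
  typed <- p$features[vapply(p$features, `[[`, character(1L), "kind") == "CDS"]
  typed_starts <- vapply(typed, feature_start, integer(1L))

  rows <- list()
  add <- function(name, kind, start, end, strand, sequence) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, start = unname(start), end = unname(end),
      strand = as.integer(unname(strand)),
      length = circ_len(unname(start), unname(end), L),
      sequence = sequence, row.names = NULL)
  }
  for (i in seq_along(units)) {
    u <- units[[i]]
    sp <- spans[, i]
    members <- u$members %||% list(list(name = u$name, orig_name = u$name,
                                        orig_start = feature_start(u),
                                        kind = u$kind))
    is_cds_unit <- length(members) == 1L && {
      hit <- which(typed_starts == members[[1L]]$orig_start &
                     vapply(typed, `[[`, character(1L), "name") ==
                       members[[1L]]$orig_name)
      length(hit) > 0L
    }
    if (is_cds_unit) {
      hit <- which(typed_starts == members[[1L]]$orig_start &
                     vapply(typed, `[[`, character(1L), "name") ==
                       members[[1L]]$orig_name)[1L]
      add(u$name, "CDS", sp[1L], sp[2L], u$intervals[1L, "strand"],
          feature_sequence(p, typed[[hit]]))
    } else {
      add(u$name, "gene", sp[1L], sp[2L], u$intervals[1L, "strand"],
          circ_substr(p$sequence, sp[1L], sp[2L]))
    }
    ## IGS gap to the next unit (circular between the last and first unit)
    nxt <- if (i < length(units)) i + 1L else 1L
    gap_len <- if (i < length(units))
      max(0L, spans[1L, nxt] - sp[2L] - 1L)
    else
      (spans[1L, 1L] - sp[2L] - 1L) %% L
    if (gap_len > 0L) {
      gs <- (sp[2L] %% L) + 1L
      ge <- ((sp[2L] + gap_len - 1L) %% L) + 1L
      add(paste0(u$name, "-", units[[nxt]]$name), "IGS", gs, ge, 1L,
          circ_substr(p$sequence, gs, ge))
    }
  }
  regions <- do.call(rbind, rows)
  if (anyDuplicated(regions$name))
    warning("duplicate region names after standardization: ",
            paste(unique(regions$name[duplicated(regions$name)]),
                  collapse = ", "), call. = FALSE)
  structure(list(sample_id = p$sample_id, regions = regions),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s: %d regions (%d CDS, %d IGS, %d other)\n",
              x$sample_id, nrow(x$regions), sum(x$regions$kind == "CDS"),
              sum(x$regions$kind == "IGS"), sum(!x$regions$kind %in%
                                                  c("CDS", "IGS"))))
  invisible(x)
}

#' Group homologous regions across samples via a reference
#'
#' Groups are keyed by the reference sample's region names (CDS and IGS).
#' Regions of other samples whose names are absent from the reference are
#' reported as structural variants; reference regions missing from a sample
#' are grouped with that sample absent.
#'
#' @param sets list of `region_set` objects (one per sample).
#' @param ref_sample sample_id of the reference; default the
#'   lexicographically first sample id.
#' @return list with `groups` (named list: region name -> list(kind,
#'   sequences = named character vector sample -> sequence, lengths)) and
#'   `structural_variants` (data frame sample_id, name, kind, length, note).
#' @export
group_regions_by_reference <- function(sets, ref_sample = NULL) {
  ids <- vapply(sets, `[[`, character(1L), "sample_id")
  names(sets) <- ids
  if (is.null(ref_sample)) ref_sample <- sort(ids)[1L]
  if (!ref_sample %in% ids) stop("reference sample '", ref_sample,
                                 "' not among the region sets")
  ref <- sets[[ref_sample]]$regions
  ref <- ref[ref$kind %in% c("CDS", "IGS"), , drop = FALSE]
  groups <- list()
  for (r in seq_len(nrow(ref))) {
    nm <- ref$name[r]
    kind <- ref$kind[r]
    seqs <- character(0L)
    for (id in ids) {
      reg <- sets[[id]]$regions
      hit <- which(reg$name == nm & reg$kind == kind)
      if (length(hit) >= 1L) seqs[id] <- reg$sequence[hit[1L]]
    }
    groups[[nm]] <- list(name = nm, kind = kind, sequences = seqs,
                         lengths = nchar(seqs))
  }
  sv <- list()
  for (id in setdiff(ids, ref_sample)) {
    reg <- sets[[id]]$regions
    reg <- reg[reg$kind %in% c("CDS", "IGS"), , drop = FALSE]
    extra <- which(!reg$name %in% ref$name)
    for (e in extra) {
      sv[[length(sv) + 1L]] <- data.frame(
        sample_id = id, name = reg$name[e], kind = reg$kind[e],
        length = reg$length[e], note = "absent-from-reference")
    }
  }
  list(groups = groups,
       structural_variants = if (length(sv)) do.call(rbind, sv)
       else data.frame(sample_id = character(0L), name = character(0L),
                       kind = character(0L), length = integer(0L),
                       note = character(0L)))
}
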