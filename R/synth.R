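## Deterministic synthetic plastomes with a ground-truth manifest.
##
## A synthetic genome is LSC + IRb + SSC + revcomp(IRb), with a gene layout
## that exercises every structural case downstream code must handle: an
## IR-duplicated gene set, a trans-spliced gene split across LSC and the
## IRs (three fragments), a cis-spliced (intron-containing) gene, a nested
## gene pair triggering the merge rule, a gene spanning the SSC/IRa
## junction, and a 2-bp spacer that a population-level insertion can
## expand.  All randomness is drawn through R's seeded integer sampler, so
## a seed reproduces sequence and manifest exactly.

#' Default synthetic gene layout
#'
#' Builds the absolute gene coordinates for given region lengths.  Genes
#' whose coordinates would not fit (small IR/SSC) are dropped, except that
#' the core layout requires `lsc_len >= 45000`, `ir_len >= 9000`,
#' `ssc_len >= 14000`.
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp.
#' @return list of gene definitions (name, type, intervals, mirror flag).
#' @export
default_gene_layout <- function(lsc_len = 80000L, ir_len = 25000L,
                                ssc_len = 17000L) {
  if (lsc_len < 45000L || ir_len < 9000L || ssc_len < 14000L)
    stop("gene layout overflow: regions too small (need LSC >= 45000, ",
         "IR >= 9000, SSC >= 14000)")
  b <- lsc_len                  # IRb = b+1 .. b+ir_len
  s <- lsc_len + ir_len         # SSC = s+1 .. s+ssc_len
  g <- function(name, type, iv, mirror = FALSE, cds_parts = NULL) {
    iv <- matrix(as.integer(iv), ncol = 3L, byrow = TRUE,
                 dimnames = list(NULL, c("start", "end", "strand")))
    list(name = name, type = type, intervals = iv, mirror = mirror,
         cds_parts = cds_parts)
  }
  layout <- list(
    ## --- LSC ---
    g("trnH-GUG", "tRNA", c(500, 574, 1)),
    g("psbA", "CDS", c(1000, 2061, 1)),
    ## nested pair for the merge rule: matK inside the trnH-UGU gene span
    g("trnH-UGU", "tRNA", c(5000, 5037, 1, 7563, 7600, 1)),
    g("matK", "CDS", c(5200, 6999, 1)),
    g("trnR-UCU", "tRNA", c(10000, 10074, 1)),
    g("atpA", "CDS", c(10500, 11999, 1)),
    g("rbcL", "CDS", c(20000, 21499, 1)),
    g("rpoB", "CDS", c(30000, 32999, -1)),
    ## trans-spliced: part1 in LSC, part2 in IRb (mirrored automatically)
    g("rps12", "trans_CDS", c(40000, 40113, 1)),
    g("rps19", "CDS", c(lsc_len - 300, lsc_len - 22, 1)),
    ## --- IRb (mirrored into IRa) ---
    g("rpl2", "CDS", c(b + 100, b + 1599, 1), mirror = TRUE),
    g("ycf2", "CDS", c(b + 1999, b + 8898, 1), mirror = TRUE))
  if (ir_len >= 21000L) {
    layout <- c(layout, list(
      g("rps12", "trans_CDS_part2", c(b + 9999, b + 10256, 1), mirror = TRUE),
      g("trnV-GAC", "tRNA", c(b + 13999, b + 14070, 1), mirror = TRUE),
      g("rrn16", "rRNA", c(b + 14999, b + 16490, 1), mirror = TRUE),
      g("ndhB", "CDS", c(b + 16999, b + 17760, 1, b + 18499, b + 19257, 1),
        mirror = TRUE)))
  }
  layout <- c(layout, list(
    ## --- SSC ---
    g("ndhF", "CDS", c(s + 100, s + 2097, -1)),
    g("ndhA", "CDS", c(s + 4999, s + 6198, 1)),
    g("ndhH", "CDS", c(s + 6201, s + 7400, 1)),
    g("rps15", "CDS", c(s + 9999, s + 10268, 1)),
    ## spans the SSC/IRa junction: 4500 bp in SSC, 1000 bp in IRa
    g("ycf1", "CDS_junction",
      c(s + ssc_len - 4499, s + ssc_len + 1000, 1))))
  layout
}

## stop-free codons for CDS synthesis
#' @noRd
sense_codons <- function() {
  setdiff(all_codons(), c("TAA", "TAG", "TGA"))
}

#' @noRd
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 2L)
  paste0("ATG",
         paste(sample(sense_codons(), n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Generate a synthetic plastome with ground truth
#'
#' @param lsc_len,ir_len,ssc_len region lengths (defaults 80000, 25000,
#'   17000; total genome 147000 bp).
#' @param gene_layout layout from [default_gene_layout()] (rebuilt for the
#'   given lengths when NULL).
#' @param seed integer RNG seed.
#' @param sample_id identifier for the plastome.
#' @param gc background GC fraction (default 0.36, plastome-like).
#' @param plant_repeats also plant a known SSR set, a tandem array and
#'   dispersed repeat pairs in the LSC (default TRUE).
#' @return list with `plastome` (a [plastome()]) and `manifest` (ground
#'   truth: seed, region intervals, junctions, gene table, planted repeat
#'   tables).
#' @export
make_plastome <- function(lsc_len = 80000L, ir_len = 25000L,
                          ssc_len = 17000L, gene_layout = NULL,
                          seed = 1L, sample_id = "synth01", gc = 0.36,
                          plant_repeats = TRUE) {
  stopifnot(lsc_len > 0L, ir_len > 0L, ssc_len > 0L)
  set.seed(seed)
  if (is.null(gene_layout))
    gene_layout <- default_gene_layout(lsc_len, ir_len, ssc_len)
  L <- lsc_len + 2L * ir_len + ssc_len
  mirror_pos <- function(x) 2L * (lsc_len + ir_len) + ssc_len + 1L - x
  irb_lo <- lsc_len + 1L; irb_hi <- lsc_len + ir_len
  ira_lo <- lsc_len + ir_len + ssc_len + 1L

  ## sequence buffers (IRa derived at the end)
  buf <- strsplit(c(random_dna(lsc_len, gc), random_dna(ir_len, gc),
                    random_dna(ssc_len, gc)), "", fixed = TRUE)
  names(buf) <- c("lsc", "irb", "ssc")

  poke <- function(pos, chars) {
    ## write characters at absolute positions; IRa positions are written as
    ## their complement at the mirrored IRb position
    if (length(chars) == 1L && length(pos) > 1L)
      chars <- rep(chars, length(pos))
    in_ira <- pos >= ira_lo
    in_ssc <- !in_ira & pos > irb_hi
    in_irb <- !in_ira & !in_ssc & pos > lsc_len
    in_lsc <- pos <= lsc_len
    if (any(in_ira))
      buf$irb[mirror_pos(pos[in_ira]) - lsc_len] <<-
        comp_chars(chars[in_ira])
    if (any(in_ssc)) buf$ssc[pos[in_ssc] - irb_hi] <<- chars[in_ssc]
    if (any(in_irb)) buf$irb[pos[in_irb] - lsc_len] <<- chars[in_irb]
    if (any(in_lsc)) buf$lsc[pos[in_lsc]] <<- chars[in_lsc]
  }
  write_exons <- function(iv, spliced) {
    chars <- strsplit(spliced, "", fixed = TRUE)[[1L]]
    off <- 0L
    for (r in seq_len(nrow(iv))) {
      w <- iv[r, "end"] - iv[r, "start"] + 1L
      chunk <- chars[(off + 1L):(off + w)]
      if (iv[r, "strand"] < 0L) chunk <- rev(comp_chars(chunk))
      poke(iv[r, "start"]:iv[r, "end"], chunk)
      off <- off + w
    }
  }

  features <- list()
  gene_rows <- list()
  add_feature <- function(name, kind, iv) {
    features[[length(features) + 1L]] <<- feature(name, kind, iv)
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      name = name, kind = kind, start = min(iv[, 1L]), end = max(iv[, 2L]),
      strand = iv[1L, 3L], n_intervals = nrow(iv))
  }
  mirror_iv <- function(iv) {
    ## reverse-complementing maps exon k to the mirrored copy's exon k, so
    ## translation order is preserved row-by-row
    out <- iv
    tmp <- mirror_pos(out[, "end"])
    out[, "end"] <- mirror_pos(out[, "start"])
    out[, "start"] <- tmp
    out[, "strand"] <- -out[, "strand"]
    out
  }

  ## the trans-spliced gene is declared in two layout pieces
  trans1 <- NULL
  for (gd in gene_layout) {
    iv <- gd$intervals
    len <- sum(iv[, "end"] - iv[, "start"] + 1L)
    if (max(iv[, "end"]) > L || min(iv[, "start"]) < 1L)
      stop("gene layout overflow: '", gd$name, "' outside [1, ", L, "]")
    if (gd$type == "trans_CDS") { trans1 <- gd; next }
    if (gd$type == "trans_CDS_part2") {
      stopifnot(!is.null(trans1))
      len1 <- sum(trans1$intervals[, "end"] - trans1$intervals[, "start"] + 1L)
      spliced <- random_cds((len1 + len) %/% 3L)
      write_exons(trans1$intervals, substr(spliced, 1L, len1))
      write_exons(iv, substr(spliced, len1 + 1L, len1 + len))
      cds_iv <- rbind(trans1$intervals, iv)
      add_feature(gd$name, "CDS", cds_iv)
      add_feature(gd$name, "gene", trans1$intervals)
      add_feature(gd$name, "gene", iv)
      add_feature(gd$name, "gene", mirror_iv(iv))
      trans1 <- NULL
      next
    }
    spliced <- switch(gd$type,
                      CDS = , CDS_junction = random_cds(len %/% 3L),
                      random_dna(len, gc = 0.5))
    if (gd$type %in% c("CDS", "CDS_junction")) {
      cds_len <- (len %/% 3L) * 3L
      ## the gene span may exceed the CDS by a trailing remainder
      cds_iv <- iv
      cds_iv[nrow(cds_iv), "end"] <- cds_iv[nrow(cds_iv), "end"] -
        (len - cds_len)
      write_exons(cds_iv, spliced)
      add_feature(gd$name, "CDS", cds_iv)
      add_feature(gd$name, "gene", iv)
      if (gd$mirror) {
        add_feature(gd$name, "CDS", mirror_iv(cds_iv))
        add_feature(gd$name, "gene", mirror_iv(iv))
      }
    } else {
      write_exons(iv, spliced)
      add_feature(gd$name, gd$type, iv)
      add_feature(gd$name, "gene", iv)
      if (gd$mirror) {
        add_feature(gd$name, gd$type, mirror_iv(iv))
        add_feature(gd$name, "gene", mirror_iv(iv))
      }
    }
  }

  if (!is.null(trans1)) {
    ## small-IR layouts have no part2: treat part1 as a plain short CDS
    len1 <- sum(trans1$intervals[, "end"] - trans1$intervals[, "start"] + 1L)
    write_exons(trans1$intervals, random_cds(len1 %/% 3L))
    add_feature(trans1$name, "CDS", trans1$intervals)
    add_feature(trans1$name, "gene", trans1$intervals)
  }

  ## planted repeats (LSC positions 50000+ are kept gene-free by the layout)
  planted <- list(ssrs = NULL, tandems = NULL, dispersed = NULL)
  if (plant_repeats && lsc_len >= 64000L) {
    planted <- plant_repeat_set(buf, poke_fun = poke)
  }

  ## make the planted IR non-extendable at both junction pairs
  break_pairing <- function(free_pos, partner_base) {
    cur <- if (free_pos <= lsc_len) buf$lsc[free_pos]
           else buf$ssc[free_pos - irb_hi]
    if (cur == comp_chars(partner_base)) {
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(cur, comp_chars(partner_base)))[1L]
      poke(free_pos, repl)
    }
  }
  break_pairing(lsc_len, buf$lsc[1L])                  # outer: JLB vs JLA
  break_pairing(irb_hi + 1L, buf$ssc[ssc_len])         # inner: JSB vs JSA

  seqchar <- c(buf$lsc, buf$irb, buf$ssc, rev(comp_chars(buf$irb)))
  p <- plastome(sample_id, paste(seqchar, collapse = ""), features)

  manifest <- list(
    seed = seed, sample_id = sample_id,
    lsc_len = lsc_len, ir_len = ir_len, ssc_len = ssc_len, genome_len = L,
    regions = list(lsc = c(1L, lsc_len), irb = c(irb_lo, irb_hi),
                   ssc = c(irb_hi + 1L, irb_hi + ssc_len),
                   ira = c(ira_lo, L)),
    junctions = c(JLB = lsc_len, JSB = irb_hi, JSA = irb_hi + ssc_len,
                  JLA = L),
    genes = do.call(rbind, gene_rows),
    planted_ssrs = planted$ssrs, planted_tandems = planted$tandems,
    planted_dispersed = planted$dispersed)
  list(plastome = p, manifest = manifest)
}

## Plant a deterministic set of SSRs, a tandem array and dispersed repeat
## pairs in the LSC block 49990..62120, with flanking bases chosen so each
## planted run is maximal exactly as recorded.
#' @noRd
plant_repeat_set <- function(buf, poke_fun) {
  put <- function(start, s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    poke_fun(start:(start + length(chars) - 1L), chars)
  }
  ssr <- function(start, motif, copies) {
    run <- strrep(motif, copies)
    m <- nchar(motif)
    first <- substr(motif, 1L, 1L)
    last <- substr(motif, m, m)
    ## flank bases differ from both motif ends so the run cannot extend in
    ## either direction (fully or by a shifted phase)
    brk_l <- setdiff(c("C", "G", "T", "A"), c(first, last))[1L]
    brk_r <- setdiff(c("C", "G", "T", "A"), c(first, last, brk_l))[1L]
    put(start - 2L, strrep(brk_l, 2L))
    put(start, run)
    put(start + nchar(run), strrep(brk_r, 2L))
    data.frame(motif = motif, copies = copies, start = start,
               end = start + nchar(run) - 1L)
  }
  ssrs <- rbind(
    ssr(50000L, "A", 12L),
    ssr(50500L, "AT", 6L),
    ssr(51000L, "AAG", 5L),
    ssr(51500L, "ACGT", 4L),
    ssr(52000L, "AATCG", 4L),
    ssr(52500L, "AATCGG", 3L))
  ## a period-12 perfect tandem array, 3 copies = 36 bp
  motif12 <- "ACGTTAGCCATA"
  put(52998L, "GG")
  put(53000L, strrep(motif12, 3L))
  put(53036L, "GG")
  tandems <- data.frame(period = 12L, copies = 3, start = 53000L,
                        end = 53035L, array_len = 36L)
  ## dispersed: one forward pair and one palindromic pair, 40 bp
  seg_f <- random_dna(40L, gc = 0.5)
  seg_p <- random_dna(40L, gc = 0.5)
  put(54000L, seg_f); put(56000L, seg_f)
  put(58000L, seg_p); put(60000L, revcomp(seg_p))
  put(53999L, "A"); put(55999L, "C")   # flank breaks
  put(54040L, "A"); put(56040L, "C")
  put(57999L, "A"); put(59999L, comp_chars("C"))
  put(58040L, "A"); put(60040L, comp_chars("C"))
  dispersed <- data.frame(
    kind = c("forward", "palindromic"), length = 40L,
    pos1 = c(54000L, 58000L), pos2 = c(56000L, 60000L))
  list(ssrs = ssrs, tandems = tandems, dispersed = dispersed)
}

#' Generate a synthetic plastome population with ground truth
#'
#' Derives `n` samples from a base genome: independent substitutions at
#' `sub_rate` per site, `n_diagnostic` sites in the `rps15` gene fixed
#' alternately between two sample groups (G1 = first half, G2 = rest), and
#' optional single-sample insertions inside a named intergenic spacer (by
#' default one 106-bp insertion in the 2-bp `ndhA-ndhH` spacer of the last
#' sample, emulating a rare species-specific length expansion).  Feature
#' annotations are lifted over insertions.
#'
#' @param base result of [make_plastome()] (list with `plastome` and
#'   `manifest`).
#' @param n number of samples (>= 2).
#' @param sub_rate per-site substitution probability in [0, 0.05].
#' @param n_diagnostic number of group-fixed sites to plant.
#' @param indel_events list of `list(sample=, igs=, length=)` events; NULL
#'   for the default single event; `list()` for none.
#' @param seed integer RNG seed.
#' @return list with `plastomes` (list of [plastome()]) and `manifest`
#'   (samples/groups, per-sample mutation tables, insertions, diagnostic
#'   sites with expected alignment columns).
#' @export
make_population <- function(base, n = 6L, sub_rate = 0.002,
                            n_diagnostic = 3L, indel_events = NULL,
                            seed = 1L) {
  stopifnot(n >= 2L, sub_rate >= 0, sub_rate <= 0.05)
  set.seed(seed)
  p0 <- base$plastome
  man0 <- base$manifest
  chars0 <- strsplit(p0$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars0)
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("%s_s%02d", man0$sample_id, seq_len(n))
  groups <- ifelse(seq_len(n) <= ceiling(n / 2), "G1", "G2")

  ## diagnostic sites: third codon positions in rps15, alleles that never
  ## create a stop codon
  diag <- NULL
  if (n_diagnostic > 0L) {
    gtab <- man0$genes
    hit <- gtab[gtab$name == "rps15" & gtab$kind == "CDS", ]
    if (nrow(hit) == 0L) stop("base layout lacks the rps15 gene")
    gstart <- hit$start[1L]
    glen <- hit$end[1L] - gstart + 1L
    codons <- sample(3:(glen %/% 3L - 2L), n_diagnostic)
    rows <- lapply(codons, function(cd) {
      off <- (cd - 1L) * 3L + 3L          # third position of codon cd
      gpos <- gstart + off - 1L
      ref <- chars0[gpos]
      cdn <- chars0[(gstart + (cd - 1L) * 3L):(gstart + (cd - 1L) * 3L + 2L)]
      alt <- NULL
      for (b in sample(setdiff(bases, ref))) {
        cdn2 <- cdn; cdn2[3L] <- b
        if (!paste(cdn2, collapse = "") %in% c("TAA", "TAG", "TGA")) {
          alt <- b; break
        }
      }
      data.frame(gene = "rps15", offset_in_gene = off, genomic_pos = gpos,
                 allele_G1 = ref, allele_G2 = alt)
    })
    diag <- do.call(rbind, rows)
  }
  diag_pos <- if (is.null(diag)) integer(0L) else diag$genomic_pos

  if (is.null(indel_events)) {
    gtab <- man0$genes
    left <- gtab[gtab$name == "ndhA" & gtab$kind == "gene", ]
    indel_events <- if (nrow(left) == 1L)
      list(list(sample = n, igs = "ndhA-ndhH", length = 106L))
    else list()
  }

  plastomes <- vector("list", n)
  mutations <- vector("list", n)
  insertions <- list()
  for (i in seq_len(n)) {
    chars <- chars0
    n_sub <- stats::rbinom(1L, L, sub_rate)
    pos <- sample.int(L, n_sub)
    while (any(pos %in% diag_pos)) {
      bad <- pos %in% diag_pos
      message("resampling ", sum(bad),
              " substitution(s) colliding with diagnostic sites")
      pos[bad] <- sample.int(L, sum(bad))
      pos <- unique(pos)
    }
    from <- chars[pos]
    to <- vapply(from, function(b) sample(setdiff(bases, b), 1L),
                 character(1L), USE.NAMES = FALSE)
    chars[pos] <- to
    mutations[[i]] <- data.frame(pos = pos, from = from, to = to)[order(pos), ]
    if (groups[i] == "G2" && !is.null(diag))
      chars[diag$genomic_pos] <- diag$allele_G2

    feats <- p0$features
    for (ev in indel_events) {
      if (ev$sample != i) next
      gtab <- man0$genes
      left_name <- sub("-.*$", "", ev$igs)
      left <- gtab[gtab$name == left_name & gtab$kind == "gene", ]
      stopifnot(nrow(left) >= 1L)
      ipos <- left$end[1L] + 1L           # insert after the first gap base
      ins_seq <- random_dna(ev$length, gc = 0.3)
      chars <- c(chars[seq_len(ipos)],
                 strsplit(ins_seq, "", fixed = TRUE)[[1L]],
                 chars[(ipos + 1L):length(chars)])
      feats <- lapply(feats, function(f) {
        iv <- f$intervals
        iv[, "start"] <- iv[, "start"] + ifelse(iv[, "start"] > ipos,
                                                ev$length, 0L)
        iv[, "end"] <- iv[, "end"] + ifelse(iv[, "end"] > ipos,
                                            ev$length, 0L)
        f$intervals <- iv
        f
      })
      insertions[[length(insertions) + 1L]] <- data.frame(
        sample_id = ids[i], igs = ev$igs, position = ipos,
        length = ev$length, sequence = ins_seq)
    }
    plastomes[[i]] <- plastome(ids[i], paste(chars, collapse = ""), feats)
  }
  names(plastomes) <- ids
  names(mutations) <- ids
  manifest <- list(
    seed = seed, base = man0,
    samples = data.frame(sample_id = ids, group = groups),
    sub_rate = sub_rate, mutations = mutations,
    insertions = if (length(insertions)) do.call(rbind, insertions)
                 else NULL,
    diagnostic = diag,
    expected_diagnostic_columns = if (is.null(diag)) integer(0L)
                                  else sort(diag$offset_in_gene))
  list(plastomes = plastomes, manifest = manifest)
}

#' Write a synthetic dataset to disk
#'
#' Writes one GenBank file per sample plus a JSON manifest.
#'
#' @param pop result of [make_population()] (or a single [make_plastome()]
#'   result).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dir <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pls <- if (!is.null(pop$plastomes)) pop$plastomes else list(pop$plastome)
  for (p in pls)
    write_genbank(p, file.path(dir, paste0(p$sample_id, ".gb")))
  jsonlite::write_json(pop$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", force = TRUE)
  invisible(dir)
}
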