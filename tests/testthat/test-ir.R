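test_that("IR detection recovers planted boundaries exactly and tiles", {
  res <- fixture_plastome()
  p <- res$plastome
  m <- res$manifest
  ir <- detect_inverted_repeats(p)
  expect_equal(unname(as.integer(ir$junctions)),
               unname(as.integer(m$junctions)))
  expect_equal(ir$lsc, unname(m$regions$lsc))
  expect_equal(ir$irb, unname(m$regions$irb))
  expect_equal(ir$ssc, unname(m$regions$ssc))
  expect_equal(ir$ira, unname(m$regions$ira))

  L <- nchar(p$sequence)
  tab <- ir_partition_table(ir, p$sample_id)
  expect_equal(sum(tab$length), L)
  expect_equal(tab$length[tab$region == "IRB"],
               tab$length[tab$region == "IRA"])
  ## forward-order concatenation reconstructs the genome
  cat_seq <- paste0(region_sequence(p, ir, "lsc"), region_sequence(p, ir, "irb"),
                    region_sequence(p, ir, "ssc"), region_sequence(p, ir, "ira"))
  expect_identical(cat_seq, p$sequence)
  ## the two copies are reverse complements
  expect_identical(revcomp(region_sequence(p, ir, "irb")),
                   region_sequence(p, ir, "ira"))
})

test_that("repeats below the length window raise a no-IR condition", {
  res <- make_plastome(ir_len = 10000L, seed = 55L, plant_repeats = FALSE)
  expect_error(detect_inverted_repeats(res$plastome),
               class = "plastidkit_no_ir")
  ## a plain random sequence has no qualifying pair either
  set.seed(5)
  expect_error(detect_inverted_repeats(random_seq(60000L)),
               class = "plastidkit_no_ir")
})

test_that("a handful of substitutions in one IR copy does not move boundaries", {
  res <- fixture_plastome()
  p <- res$plastome
  m <- res$manifest
  ch <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  ## 5 substitutions well inside IRb
  pos <- m$regions$irb[1L] + c(1000L, 6000L, 11000L, 16000L, 21000L)
  ch[pos] <- vapply(ch[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1L], character(1L))
  ir <- detect_inverted_repeats(paste(ch, collapse = ""))
  expect_equal(unname(as.integer(ir$junctions)),
               unname(as.integer(m$junctions)))
  expect_lt(ir$identity, 1)
  expect_gte(ir$identity, 0.995)
})

test_that("detection is rotation-equivariant", {
  res <- fixture_plastome()
  m <- res$manifest
  L <- nchar(res$plastome$sequence)
  for (r in c(100L, 100000L)) {     # start in LSC / inside the IR
    ir <- detect_inverted_repeats(rotate_seq(res$plastome$sequence, r))
    expect_equal(unname(as.integer(ir$junctions)),
                 unname(((as.integer(m$junctions) - r - 1L) %% L) + 1L))
  }
})

test_that("junction genes: spanning, abutting and absent sides", {
  res <- fixture_plastome()
  p <- res$plastome
  ir <- detect_inverted_repeats(p)
  jg <- junction_genes(p, ir)

  sp <- jg[jg$side == "spanning", ]
  expect_equal(sp$gene, "ycf1")
  expect_equal(sp$junction, "JSA")
  expect_equal(sp$overhang_left, 4500L)
  expect_equal(sp$overhang_right, 1000L)

  ## a gene ending exactly at the junction: distance 0, not spanning
  p2 <- p
  p2$features <- c(p2$features,
                   list(feature("probe", "gene", c(79950L, 80000L, 1L))))
  p2 <- plastome(p2$sample_id, p2$sequence, p2$features)
  jg2 <- junction_genes(p2, ir)
  probe <- jg2[jg2$gene == "probe", ]
  expect_equal(probe$side, "left")
  expect_equal(probe$distance, 0L)
  expect_false("probe" %in% jg2$gene[jg2$side == "spanning"])

  ## a junction flanked by an empty region reports that side absent
  tiny <- plastome("t", strrep("ACGT", 40000L),
                   list(feature("only", "gene", c(10L, 90L, 1L))))
  fake_ir <- structure(list(lsc = c(1L, 80000L), irb = c(80001L, 105000L),
                            ssc = c(105001L, 122000L),
                            ira = c(122001L, 160000L),
                            junctions = c(JLB = 80000L, JSB = 105000L,
                                          JSA = 122000L, JLA = 160000L),
                            identity = 1, genome_len = 160000L),
                       class = "ir_partition")
  jg3 <- junction_genes(tiny, fake_ir)
  expect_false(any(jg3$junction == "JSB"))  # nothing flanks JSB at all
})

test_that("genome stats: GC, planted lengths, coding union", {
  gc_only <- plastome("gc", "ATGC")
  expect_equal(genome_stats(gc_only)$gc_total, 50)
  ## N excluded from the denominator
  expect_equal(genome_stats(plastome("n", "ATGCNN"))$gc_total, 50)

  res <- fixture_plastome()
  ir <- detect_inverted_repeats(res$plastome)
  st <- genome_stats(res$plastome, ir)
  expect_equal(st$lsc_len, res$manifest$lsc_len)
  expect_equal(st$ssc_len, res$manifest$ssc_len)
  expect_equal(st$ir_len, res$manifest$ir_len)
  expect_equal(st$total_len, res$manifest$genome_len)
  expect_true(all(st[, grep("^gc_", names(st))] >= 0 &
                    st[, grep("^gc_", names(st))] <= 100))

  ## two CDS overlapping by 10 bp count 190 coding bases (union)
  ov <- plastome("ov", strrep("ACGT", 250L),
                 list(feature("a", "CDS", c(1L, 100L, 1L)),
                      feature("b", "CDS", c(91L, 190L, 1L))))
  expect_equal(genome_stats(ov)$coding_fraction, 100 * 190 / 1000)
})
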