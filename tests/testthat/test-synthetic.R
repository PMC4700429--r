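test_that("the toy genome partitions into the documented granule counts", {
  cfg <- syntheticConfig()
  genome <- makeGenome(cfg)
  p <- buildPartition(genome, cfg$granuleBp)
  expect_equal(nGranules(p), 230)  # 100 + 80 + 50
  expect_equal(nGranules(buildPartition(chromosomeSpec("c", 35000), 3500)),
               10)
  # deterministic construction
  expect_equal(makeGenome(cfg), makeGenome(cfg))
  # centromeres interior, telomeres terminal
  for (ch in genome) {
    expect_gt(ch@centromere[1], ch@telomeres[[1]][2])
    expect_lt(ch@centromere[2], ch@telomeres[[2]][1])
  }
})

test_that("synthetic contacts round-trip and obey the configuration", {
  cfg <- syntheticConfig()
  genome <- makeGenome(cfg)
  p <- buildPartition(genome, cfg$granuleBp)
  df <- makeContacts(genome, cfg, seed = 5)
  expect_named(df, c("chromA", "posA", "chromB", "posB", "count"))
  expect_equal(nrow(df),
               cfg$nBackgroundPairs + cfg$nCenPairs + cfg$nTelPairs)
  expect_true(all(df$count >= 1))

  # byte-identical TSV for a fixed seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeContacts(makeContacts(genome, cfg, seed = 9), f1)
  writeContacts(makeContacts(genome, cfg, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  # round-trips through the reader
  cs <- suppressMessages(readContacts(f1, p))
  expect_s4_class(cs, "GranuleContactSet")
  expect_gt(length(cs@i), 0.8 * nrow(df))

  # over-asking errors
  tiny <- syntheticConfig(chromLengths = c(c1 = 7000),
                          nBackgroundPairs = 500, nCenPairs = 0,
                          nTelPairs = 0, centromereBp = 1000,
                          telomereBp = 1000, subtelomereBp = 1000,
                          zoneFlank = 0)
  expect_error(makeContacts(makeGenome(tiny), tiny), "more distinct pairs")
})

test_that("planted centromere pairs dominate the top-frequency decile", {
  cfg <- syntheticConfig(nCenPairs = 40, cenBoost = 50,
                         nBackgroundPairs = 720)
  genome <- makeGenome(cfg)
  df <- makeContacts(genome, cfg, seed = 7)
  cens <- do.call(rbind, lapply(genome, function(ch) data.frame(
    chrom = ch@name, start = ch@centromere[1], end = ch@centromere[2])))
  inCen <- function(chrom, pos) {
    hit <- rep(FALSE, length(chrom))
    for (z in seq_len(nrow(cens)))
      hit <- hit | (chrom == cens$chrom[z] & pos >= cens$start[z] &
                      pos < cens$end[z])
    hit
  }
  cenPair <- inCen(df$chromA, df$posA) & inCen(df$chromB, df$posB)
  top <- df$count >= quantile(df$count, 0.9)
  # cen-cen pairs are ~5% of records but dominate the top decile
  expect_gt(mean(cenPair[top]), 5 * mean(cenPair))
})

test_that("unboosted flat-decay contacts place endpoints uniformly", {
  cfg <- syntheticConfig(decayExponent = 0, cenBoost = 0, telBoost = 0,
                         nCenPairs = 0, nTelPairs = 0,
                         nBackgroundPairs = 4000, intraFraction = 1,
                         chromLengths = c(cU = 350e3))
  genome <- makeGenome(cfg)
  df <- makeContacts(genome, cfg, seed = 11)
  # chi-square goodness of fit of endpoint positions against uniform bins
  pos <- c(df$posA, df$posB)
  ct <- table(cut(pos, breaks = seq(0, 350e3, length.out = 11)))
  pval <- chisq.test(ct)$p.value
  expect_gt(pval, 0.01)
})

test_that("ChIP tracks respect compartment bias", {
  cfg <- syntheticConfig()
  genome <- makeGenome(cfg)

  # bias 1: every record (hence every top-5% record) in het zones
  cfgB <- syntheticConfig(chipBias = 1)
  het <- makeChipTrack(genome, cfgB, "peripheral_het", seed = 2)
  expect_equal(length(het@records), cfgB$nPeaks)
  zones <- pombe3d:::.hetZones(genome, cfgB)
  inZone <- function(track) {
    gr <- track@records
    chrom <- as.character(GenomicRanges::seqnames(gr))
    s0 <- GenomicRanges::start(gr) - 1
    hit <- rep(FALSE, length(gr))
    for (z in seq_len(nrow(zones)))
      hit <- hit | (chrom == zones$chrom[z] & s0 >= zones$start[z] &
                      s0 < zones$end[z])
    hit
  }
  expect_true(all(inZone(topFractionFilter(het, 0.05))))

  # bias 1 euchromatic track avoids the zones entirely
  eu <- makeChipTrack(genome, cfgB, "central_eu", seed = 3)
  expect_false(any(inZone(eu)))

  # bias 0: top-5% positions indistinguishable from uniform (KS)
  cfg0 <- syntheticConfig(chipBias = 0, chromLengths = c(cU = 350e3),
                          nPeaks = 2000)
  g0 <- makeGenome(cfg0)
  tr0 <- makeChipTrack(g0, cfg0, "peripheral_het", seed = 4)
  top0 <- topFractionFilter(tr0, 0.05)
  pos <- GenomicRanges::start(top0@records) - 1
  expect_gt(suppressWarnings(
    ks.test(pos, "punif", 0, 350e3 - 300)$p.value), 0.01)

  # probe length as configured
  expect_true(all(GenomicRanges::width(het@records) == cfg$peakBp))
})

test_that("synthetic origins follow their class placement rules", {
  cfg <- syntheticConfig(originBias = 1)
  genome <- makeGenome(cfg)
  ori <- makeOrigins(genome, cfg, seed = 6)
  expect_equal(as.vector(table(ori$class)[names(cfg$originCounts)]),
               unname(cfg$originCounts))

  # with bias 1 every late origin is subtelomeric
  lens <- vapply(genome, function(c) c@length, numeric(1))
  names(lens) <- vapply(genome, function(c) c@name, character(1))
  late <- ori[grepl("^late", ori$class), ]
  subtel <- late$start < cfg$subtelomereBp |
    late$end > lens[late$chrom] - cfg$subtelomereBp
  expect_true(all(subtel))
  # and every early origin is not
  early <- ori[grepl("^early", ori$class), ]
  expect_true(all(early$start >= cfg$subtelomereBp &
                    early$end <= lens[early$chrom] - cfg$subtelomereBp))

  # reproducible
  expect_identical(makeOrigins(genome, cfg, seed = 6),
                   makeOrigins(genome, cfg, seed = 6))

  # round-trips through loadOrigins
  p <- buildPartition(genome, cfg$granuleBp)
  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(ori, f)
  sigs <- loadOrigins(f, p)
  expect_setequal(names(sigs), names(cfg$originCounts))
})
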