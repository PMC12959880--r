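test_that("metaprofile extracts windows, mirrors minus anchors, matches a naive oracle", {
  v <- numeric(1000)
  v[501] <- 7                                   # delta at base 500 (0-based)
  tr <- toy_track(list(chr1 = v))
  mp <- metaprofile(tr, anchor_set("chr1", 500, 1L), flank = 10)
  expect_equal(mp$mean_signal, c(rep(0, 10), 7, rep(0, 10)))

  # strand-antisymmetric pattern + opposite-strand anchors -> symmetric mean
  w <- numeric(1000)
  w[481:520] <- c(seq_len(20), -seq_len(20))
  tr2 <- toy_track(list(chr1 = w))
  mp2 <- metaprofile(tr2, anchor_set("chr1", c(500, 500), c(1L, -1L)),
                     flank = 30)
  expect_equal(mp2$mean_signal, rev(mp2$mean_signal))

  # naive per-anchor extraction oracle on 5 anchors
  set.seed(3)
  z <- rnorm(5000)
  tr3 <- toy_track(list(chr1 = z))
  anch <- anchor_set("chr1", c(100, 900, 2500, 3200, 4800),
                     c(1L, -1L, 1L, -1L, 1L))
  got <- metaprofile(tr3, anch, flank = 50)
  rows <- t(vapply(seq_len(5), function(i) {
    sl <- z[(anch$pos[i] - 50 + 1):(anch$pos[i] + 50 + 1)]
    if (anch$orientation[i] < 0) rev(sl) else sl
  }, numeric(101)))
  expect_equal(got$mean_signal, colMeans(rows))

  # edge anchors skipped, not padded
  got2 <- metaprofile(tr3, anchor_set("chr1", c(10, 2500), 1L), flank = 50)
  expect_equal(got2$n_skipped, 1L)
  expect_equal(got2$n_anchors, 1L)
})

test_that("strand-flipping all anchors mirrors the profile exactly", {
  s <- small_sim()
  frag <- split_by_genome(s$sim$libraries$H3K115ac)$target
  tr <- coverage_track(frag, s$sim$genome$chrom_sizes)
  anch <- tss_anchors_of(s$sim)
  mp <- metaprofile(tr, anch, flank = 400)
  flipped <- anch
  flipped$orientation <- -flipped$orientation
  mpf <- metaprofile(tr, flipped, flank = 400)
  expect_identical(mpf$mean_signal, rev(mp$mean_signal))
})

test_that("lite nucleosome caller finds isolated and paired particles", {
  cfg <- tiny_cfg()
  # single particle: coverage from many fragments around one dyad
  set.seed(1)
  dyad <- 5000
  mids <- dyad + round(rnorm(4000, 0, 10))
  f <- fragment_set(rep("chr1", 4000), mids - 73, mids + 74)
  tr <- coverage_track(f, c(chr1 = 10000))
  calls <- call_nucleosomes_lite(tr)
  expect_equal(nrow(calls), 1)
  expect_lt(abs(calls$dyad - dyad), 5)

  # two particles 200 bp apart -> two calls
  mids2 <- c(dyad + round(rnorm(3000, 0, 10)),
             dyad + 200 + round(rnorm(3000, 0, 10)))
  f2 <- fragment_set(rep("chr1", 6000), mids2 - 73, mids2 + 74)
  calls2 <- call_nucleosomes_lite(coverage_track(f2, c(chr1 = 10000)))
  expect_equal(nrow(calls2), 2)

  # flat track -> zero calls
  flat <- toy_track(list(chr1 = rep(1, 5000)))
  expect_equal(nrow(call_nucleosomes_lite(flat, min_height = 2)), 0)
})

test_that("NDR definition arithmetic and strand mirroring", {
  # plus strand: dyad 200 bp upstream -> NDR length 200 - 73 = 127
  anch <- anchor_set("chr1", 10000, 1L)
  calls <- data.frame(chrom = "chr1", dyad = 9800, height = 5)
  ndr <- define_ndrs(anch, calls)
  expect_equal(ndr$length, 127)
  expect_equal(c(ndr$start, ndr$end), c(9800 + 73, 10000))
  # minus strand, mirrored geometry, same length
  anch2 <- anchor_set("chr1", 10000, -1L)
  calls2 <- data.frame(chrom = "chr1", dyad = 10200, height = 5)
  ndr2 <- define_ndrs(anch2, calls2)
  expect_equal(ndr2$length, 127)
  # no upstream call within 1 kb -> skipped
  expect_equal(nrow(define_ndrs(anch, data.frame(chrom = "chr1",
                                                 dyad = 8000, height = 1))),
               0)
})

test_that("recovered NDR lengths track simulator truth (r > 0.9)", {
  s <- small_sim()
  frag <- split_by_genome(s$sim$libraries$input)$target
  tr <- depth_normalize(coverage_track(fractionate(frag)$mono,
                                       s$sim$genome$chrom_sizes))
  calls <- call_nucleosomes_lite(tr)
  ndrs <- define_ndrs(tss_anchors_of(s$sim), calls)
  truth <- s$sim$landscape$promoters
  m <- merge(ndrs, truth[, c("gene", "ndr_width")], by.x = "group",
             by.y = "gene")
  expect_gt(nrow(m), 0.8 * nrow(truth))
  expect_gt(cor(m$length, m$ndr_width), 0.9)
})

test_that("scaled profile rebinning is identity/mean-preserving", {
  # region exactly scaled_len with constant signal -> all bins constant
  v <- rep(2.5, 3000)
  tr <- toy_track(list(chr1 = v))
  reg <- data.frame(chrom = "chr1", start = 1000, end = 1500)
  sp <- scaled_profile(tr, reg, scaled_len = 500, flank = 100)
  expect_equal(sp$mean_signal[sp$interior], rep(2.5, 500))
  # region of 2x scaled_len -> each bin mean of 2 bases
  set.seed(4)
  z <- rnorm(5000)
  trz <- toy_track(list(chr1 = z))
  regz <- data.frame(chrom = "chr1", start = 2000, end = 3000)
  spz <- scaled_profile(trz, regz, scaled_len = 500, flank = 10)
  pairs <- colMeans(matrix(z[2001:3000], nrow = 2))
  expect_equal(spz$mean_signal[spz$interior], pairs)
  # interior mass conserved for awkward lengths
  regw <- data.frame(chrom = "chr1", start = 100, end = 477)
  spw <- scaled_profile(trz, regw, scaled_len = 500, flank = 50)
  interior_mass <- sum(spw$mean_signal[spw$interior]) * (377 / 500)
  expect_equal(interior_mass, sum(z[101:477]), tolerance = 1e-6)
  # orientation -1 mirrors the interior
  rego <- data.frame(chrom = "chr1", start = 2000, end = 3000,
                     orientation = -1L)
  spo <- scaled_profile(trz, rego, scaled_len = 500, flank = 10)
  expect_equal(spo$mean_signal[spo$interior], rev(pairs))
})

test_that("CTCF quartile profiles cover all groups and size classes", {
  s <- small_sim()
  ann <- s$sim$genome$annotations
  peaks <- data.frame(chrom = ann$ctcf$chrom, start = ann$ctcf$start - 50,
                      end = ann$ctcf$end + 50, score = ann$ctcf$score)
  anch <- ctcf_select(peaks, ann$ctcf)
  fr <- fractionate(split_by_genome(s$sim$libraries$H3K115ac)$target)
  cs <- s$sim$genome$chrom_sizes
  tracks <- list(sub = coverage_track(fr$sub, cs),
                 mono = coverage_track(fr$mono, cs))
  prof <- ctcf_quartile_profiles(tracks, anch, flank = 400)
  expect_equal(length(prof), 2)
  expect_equal(sort(names(prof$sub)), paste0("Q", 1:4))
  expect_s3_class(prof$mono$Q4, "meta_profile")
})

test_that("asymmetry statistic is zero/symmetric/antisymmetric as required", {
  sym <- structure(list(positions = -200:200,
                        mean_signal = dnorm(-200:200, 0, 50)),
                   class = "meta_profile")
  expect_equal(asymmetry_statistic(sym, 150), 0)
  spike <- structure(list(positions = -200:200,
                          mean_signal = as.numeric(-200:200 == 50)),
                     class = "meta_profile")
  expect_equal(asymmetry_statistic(spike, 150), 1, tolerance = 1e-6)
  set.seed(5)
  rough <- structure(list(positions = -200:200, mean_signal = runif(401)),
                     class = "meta_profile")
  mirrored <- rough
  mirrored$mean_signal <- rev(rough$mean_signal)
  expect_equal(asymmetry_statistic(mirrored, 150),
               -asymmetry_statistic(rough, 150))
  expect_error(asymmetry_statistic(rough, 500), "exceeds")
})
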