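test_that("fragment files round-trip and malformed lines are reported", {
  f <- fragment_set(c("chr2", "chr1", "chr1"), c(100, 900, 20),
                    c(260, 1050, 170), c("target", "spike", "target"))
  expect_equal(nrow(f), 3)
  expect_equal(f$chrom, c("chr1", "chr1", "chr2"))  # sorted on construction

  bedpe <- withr::local_tempfile(fileext = ".bedpe")
  write_fragments(f, bedpe, "bedpe")
  back <- read_fragments(bedpe, "bedpe")
  expect_equal(back$start, f$start)
  expect_equal(back$end, f$end)
  expect_equal(back$genome_label, f$genome_label)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_fragments(f, bed, "bed")
  expect_equal(read_fragments(bed, "bed")$end, f$end)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t10\t100", "chr1\t-5\t60"), bad)
  expect_error(read_fragments(bad, "bed"), "line 2")
  writeLines(c("chr1\t10\tabc"), bad)
  expect_error(read_fragments(bad, "bed"), "line 1")
  writeLines(c("chr1\t10"), bad)
  expect_error(read_fragments(bad, "bed"), "line 1")
})

test_that("fractionation boundaries are exact under both rule variants", {
  lens <- c(149, 150, 151, 225, 226, 230, 231)
  f <- fragment_set(rep("chr1", length(lens)), seq(0, by = 1000,
                                                   length.out = length(lens)),
                    seq(0, by = 1000, length.out = length(lens)) + lens)
  cls_of <- function(rule) {
    fr <- fractionate(f, rule)
    out <- character(length(lens))
    for (nm in names(fr))
      out[match(fr[[nm]]$end - fr[[nm]]$start, lens)] <- nm
    out
  }
  # default windows: sub <= 150, mono 151-230
  expect_equal(cls_of(size_class_rule()),
               c("sub", "sub", "mono", "mono", "mono", "mono", "excluded"))
  # alternative windows: sub < 150, mono 150-225
  expect_equal(cls_of(size_class_rule("methods")),
               c("sub", "mono", "mono", "mono", "excluded", "excluded",
                 "excluded"))
  expect_error(size_class_rule(sub_max = 160, mono_min = 150), "sub_max")
})

test_that("fractionation partitions 1e5 random fragments exactly", {
  set.seed(1)
  n <- 1e5
  start <- sample.int(1e6, n)
  lens <- sample(40:400, n, replace = TRUE)
  f <- fragment_set(rep("chr1", n), start, start + lens)
  for (rule in list(size_class_rule(), size_class_rule("methods"))) {
    fr <- fractionate(f, rule)
    expect_equal(nrow(fr$sub) + nrow(fr$mono) + nrow(fr$excluded), n)
    all_lens <- sort(c(fr$sub$end - fr$sub$start, fr$mono$end - fr$mono$start,
                       fr$excluded$end - fr$excluded$start))
    expect_equal(all_lens, sort(lens))
  }
})

test_that("depth normalisation scales to the target fragment total", {
  f <- fragment_set(rep("chr1", 2e3), seq_len(2e3), seq_len(2e3) + 100)
  tr <- coverage_track(f, c(chr1 = 5e3))
  norm <- depth_normalize(tr)
  expect_equal(norm$scale_factor, 1e7 / 2e3)
  expect_equal(norm$n_fragments_norm, 1e7, tolerance = 1e-6)
  # uniform scaling: ratio of max to min positive weight unchanged
  pos <- tr$values$chr1[tr$values$chr1 > 0]
  npos <- norm$values$chr1[norm$values$chr1 > 0]
  expect_equal(max(npos) / min(npos), max(pos) / min(pos))
  empty <- coverage_track(fragment_set(character(0), numeric(0), numeric(0)),
                          c(chr1 = 100))
  expect_error(depth_normalize(empty), "zero fragments")
})

test_that("spike scale factor matches the printed formula exactly", {
  expect_identical(spike_scale_factor(1e6), 1.0)
  expect_identical(spike_scale_factor(2e6), 0.5)
  expect_identical(spike_scale_factor(250000), 4.0)
  expect_error(spike_scale_factor(0), "positive")
})

test_that("genome split separates spike-ins and feeds spike scaling", {
  f <- fragment_set(c(rep("chr1", 9), "spike_bc1"),
                    0:9 * 500, 0:9 * 500 + 150,
                    c(rep("target", 9), "spike"))
  sp <- split_by_genome(f)
  expect_equal(unname(sp$counts), c(9, 1))
  expect_equal(sum(sp$counts), nrow(f))
  expect_equal(nrow(split_by_genome(sp$target)$spike), 0)
  g <- f
  g$genome_label[1] <- "mystery"
  expect_error(split_by_genome(g), "unknown genome label")

  # end-to-end scaled track on a hand-computed 5-fragment example:
  # 4 target fragments of 100 bp, 1 spike read -> factor 1e6
  h <- fragment_set(c(rep("chr1", 4), "spike_bc1"),
                    c(0, 100, 200, 300, 0), c(100, 200, 300, 400, 147),
                    c(rep("target", 4), "spike"))
  parts <- split_by_genome(h)
  tr <- scale_track(coverage_track(parts$target, c(chr1 = 500)),
                    spike_scale_factor(parts$counts[["spike"]]))
  expect_equal(sum(tr$values$chr1), 400 * 1e6)
})

test_that("coverage modes conserve mass and clip with a warning", {
  f <- fragment_set("chr1", 10, 14)
  tr <- coverage_track(f, c(chr1 = 20))
  expect_equal(tr$values$chr1, c(rep(0, 10), rep(1, 4), rep(0, 6)))
  f2 <- fragment_set(c("chr1", "chr1"), c(10, 12), c(14, 18))
  tr2 <- coverage_track(f2, c(chr1 = 20))
  expect_equal(max(tr2$values$chr1), 2)
  expect_equal(sum(tr2$values$chr1), (14 - 10) + (18 - 12))
  mid <- coverage_track(f2, c(chr1 = 20), mode = "midpoint")
  expect_equal(which(mid$values$chr1 == 1) - 1, c(12, 15))
  expect_equal(sum(mid$values$chr1), 2)
  expect_warning(coverage_track(fragment_set("chr1", 15, 30), c(chr1 = 20)),
                 "clipped")
  expect_error(coverage_track(fragment_set("chrX", 0, 10), c(chr1 = 20)),
               "unknown chromosome")
})

test_that("coverage mass equals total fragment bases on random input", {
  set.seed(7)
  n <- 2e4
  start <- sample.int(9e4, n)
  lens <- sample(40:400, n, replace = TRUE)
  f <- fragment_set(rep("chr1", n), start, start + lens)
  tr <- coverage_track(f, c(chr1 = 1e5))
  expect_identical(sum(tr$values$chr1), as.numeric(sum(lens)))
  tr10 <- coverage_track(f, c(chr1 = 1e5), bin_size = 10)
  expect_equal(track_total_mass(tr10), sum(lens), tolerance = 1e-12)
})

test_that("Tn5 offset centres 20 bp windows on corrected insertion sites", {
  f <- fragment_set("chr1", 100, 201)
  out <- tn5_offset(f)
  expect_equal(out$start, c(94, 185))
  expect_equal(out$end, c(114, 205))
  expect_true(attr(out, "tn5_offset"))
  expect_error(tn5_offset(out), "already")
})

test_that("replicate correlation over 10 kb windows matches closed form", {
  mk <- function(win_sums) {
    v <- numeric(4e4)
    v[(0:3) * 1e4 + 1] <- win_sums
    toy_track(list(chr1 = v), n_fragments = sum(win_sums))
  }
  a <- mk(c(1, 2, 3, 4))
  expect_equal(replicate_correlation(a, a), 1.0)
  b <- mk(c(4, 3, 2, 1))
  expect_equal(replicate_correlation(a, b), -1.0)
  # closed-form Pearson on a 4-window toy: x=(1,2,3,4), y=(2,1,4,3) -> 0.6
  expect_equal(replicate_correlation(a, mk(c(2, 1, 4, 3))), 0.6)
  expect_error(replicate_correlation(a, mk(rep(2, 4))), "constant track")
  short <- toy_track(list(chr1 = numeric(5e3)))
  expect_error(replicate_correlation(short, short), "two windows")
})

test_that("bedGraph round-trips track values", {
  s <- small_sim()
  frag <- split_by_genome(s$sim$libraries$input)$target
  tr <- depth_normalize(coverage_track(frag, s$sim$genome$chrom_sizes))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, s$sim$genome$chrom_sizes)
  for (ch in names(tr$values))
    expect_equal(back$values[[ch]], tr$values[[ch]], tolerance = 1e-12)
})
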