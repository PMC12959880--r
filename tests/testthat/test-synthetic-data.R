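test_that("sim_config validates fractions, lengths and class parameters", {
  expect_s3_class(tiny_cfg(), "sim_config")
  expect_error(tiny_cfg(frac_cgi_promoters = 1.2), "fraction")
  expect_error(tiny_cfg(nucleosome_spacing = 140), "147")
  expect_error(tiny_cfg(gc_cgi = 0.45), "0.10")
  bad_len <- tiny_cfg()$particle_length_params
  bad_len$subnucleosome <- c(mean = 20, sd = 5)
  expect_error(sim_config(particle_length_params = bad_len), "40, 400")
})

test_that("simulate_genome places elements and G/C-rich CGIs", {
  cfg <- sim_config(seed = 1, n_chromosomes = 2, chrom_length = 4e5,
                    n_genes = 60, frac_cgi_promoters = 0.6, n_enhancers = 10,
                    n_ctcf_sites = 10)
  g <- simulate_genome(cfg)
  ann <- g$annotations
  expect_equal(nrow(ann$tss), 60)
  # CGI-associated TSS count close to the configured fraction (binomial)
  n_cgi <- sum(ann$tss$cgi)
  expect_lt(abs(n_cgi - 0.6 * 60), 3 * sqrt(60 * 0.6 * 0.4) + 1)
  # every CGI promoter TSS within 500 bp of a CGI interval
  cgi_tss <- ann$tss[ann$tss$cgi, ]
  expect_true(all(cgi_associate(data.frame(chrom = cgi_tss$chrom,
                                           pos = cgi_tss$pos),
                                ann$cgi, radius = 500)))
  # CGI G/C content exceeds background by >= 0.10
  gc_of <- function(iv) {
    v <- Biostrings::Views(g$genome[[iv$chrom[1]]], iv$start + 1, iv$end)
    f <- Biostrings::letterFrequency(v, c("C", "G"))
    sum(f) / sum(iv$end - iv$start)
  }
  gc_cgi <- gc_of(ann$cgi[ann$cgi$chrom == "chr1", ])
  whole <- Biostrings::letterFrequency(g$genome[["chr1"]], c("C", "G"))
  expect_gt(gc_cgi, sum(whole) / (4e5) + 0.08)
})

test_that("infeasible element counts raise a sizing error", {
  expect_error(simulate_genome(sim_config(n_chromosomes = 1,
                                          chrom_length = 5e4,
                                          n_genes = 100)),
               "infeasible")
})

test_that("zero CTCF sites yield an empty BED and a runnable pipeline", {
  cfg <- tiny_cfg(n_ctcf_sites = 0)
  sim <- simulate_chromatin(cfg)
  expect_equal(nrow(sim$genome$annotations$ctcf), 0)
  expect_gt(nrow(sim$libraries$H3K115ac), 0)
})

test_that("identical configs give byte-identical outputs", {
  cfg <- tiny_cfg(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_chromatin(cfg), d1)
  write_simulation(simulate_chromatin(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 8)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("landscape respects NDR particle classes and polycomb exclusion", {
  s <- small_sim()
  pp <- s$sim$landscape$particles
  ndr <- pp[pp$element %in% c("promoter_ndr_cgi", "promoter_ndr_noncgi",
                              "ctcf_ndr"), ]
  expect_true(all(ndr$class %in% c("subnucleosome", "fragile_mono",
                                   "ctcf_complex")))
  expect_true(all(pp$occupancy > 0 & pp$occupancy <= 1))
  pc_genes <- s$sim$landscape$promoters$gene[s$sim$landscape$promoters$polycomb]
  if (length(pc_genes) > 0)
    expect_false(any(pp$h3k27ac[pp$element_id %in% pc_genes]))
})

test_that("NDR-internal promoter mark frequency matches the configured probability", {
  cfg <- sim_config(seed = 3, n_chromosomes = 3, chrom_length = 1e6,
                    n_genes = 450, frac_cgi_promoters = 0.7,
                    n_enhancers = 0, n_ctcf_sites = 0)
  g <- simulate_genome(cfg)
  ls <- simulate_landscape(cfg, g)
  ndr <- ls$particles[ls$particles$element == "promoter_ndr_cgi", ]
  n <- nrow(ndr)
  expect_gte(n, 500)
  p_cfg <- cfg$mark_probabilities$H3K115ac[["promoter_ndr_cgi"]]
  expect_lt(abs(mean(ndr$h3k115ac) - p_cfg),
            3 * sqrt(p_cfg * (1 - p_cfg) / n))
})

test_that("fragile-particle footprints carry the configured A/T enrichment", {
  s <- small_sim()
  cfg <- s$cfg
  sim <- s$sim
  pp <- sim$landscape$particles
  half <- vapply(cfg$particle_length_params,
                 function(p) floor(p[["mean"]] / 2), numeric(1))
  mean_at <- function(classes) {
    sel <- pp$class %in% classes
    at <- numeric(0)
    for (ch in unique(pp$chrom[sel])) {
      i <- sel & pp$chrom == ch
      v <- Biostrings::Views(sim$genome$genome[[ch]],
                             pmax(1, pp$dyad[i] - half[pp$class[i]] + 1),
                             pp$dyad[i] + half[pp$class[i]])
      f <- Biostrings::letterFrequency(v, c("A", "T"))
      at <- c(at, rowSums(f) / IRanges::width(v))
    }
    mean(at)
  }
  diff_at <- mean_at(c("fragile_mono", "subnucleosome")) -
    mean_at("stable_mono")
  expect_lt(abs(diff_at - cfg$at_bias_fragile), 0.02)
})

test_that("ChIP selects marked particles and marks-off gives background only", {
  s <- small_sim()
  k115 <- s$sim$libraries$H3K115ac
  target <- split_by_genome(k115)$target
  # ChIP fragments over NDR elements are abundant relative to input
  expect_gt(mean(target$element %in% c("promoter_ndr_cgi", "enhancer_ndr",
                                       "ctcf_ndr")), 0.10)
  # zero mark probabilities -> background-only ChIP (class mix ~ input)
  cfg0 <- tiny_cfg()
  cfg0$mark_probabilities$H3K115ac[] <- 0
  cfg0$mark_probabilities$H3K27ac[] <- 0
  g <- simulate_genome(cfg0)
  ls <- simulate_landscape(cfg0, g)
  chip <- simulate_fragments(ls, cfg0, "H3K115ac")
  chip_t <- split_by_genome(chip)$target
  expect_equal(nrow(chip_t), cfg0$library_depth)
  expect_gt(mean(chip_t$class == "stable_mono"), 0.8)
})

test_that("input class mixture follows occupancy weights (chi-square GOF)", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 1e6,
                    n_genes = 60, n_enhancers = 25, n_ctcf_sites = 40,
                    library_depth = 1e5, spike_in_counts = integer(0))
  g <- simulate_genome(cfg)
  ls <- simulate_landscape(cfg, g)
  frag <- simulate_fragments(ls, cfg, "input")
  # restrict to unclipped fragments so sampling weights are undistorted
  obs <- table(frag$class)
  w <- tapply(ls$particles$occupancy, ls$particles$class, sum)
  w <- w[names(obs)] / sum(w[names(obs)])
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = w))
  expect_gt(gof$p.value, 0.01)
})

test_that("library length mixture matches a direct mixture sampler (KS)", {
  s <- small_sim()
  cfg <- s$cfg
  ls <- s$sim$landscape
  frag <- split_by_genome(s$sim$libraries$input)$target
  set.seed(99)
  lens <- sample(frag$end - frag$start, 1e4)
  w <- tapply(ls$particles$occupancy, ls$particles$class, sum)
  w <- w / sum(w)
  cls <- sample(names(w), 1e4, replace = TRUE, prob = w)
  ref <- numeric(1e4)
  for (cl in unique(cls)) {
    p <- cfg$particle_length_params[[cl]]
    ref[cls == cl] <- fragilenuc:::rtrunc_norm(sum(cls == cl), p[["mean"]],
                                               p[["sd"]])
  }
  ks <- suppressWarnings(stats::ks.test(lens, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("spike-ins are exact in input and enriched on-target in ChIP", {
  cfg <- tiny_cfg(spike_in_counts = c(H3K115ac = 1000, H3K27ac = 800,
                                      unmodified = 600))
  g <- simulate_genome(cfg)
  ls <- simulate_landscape(cfg, g)
  inp <- simulate_fragments(ls, cfg, "input")
  spk <- split_by_genome(inp)$spike
  expect_equal(nrow(spk), 2400)
  expect_equal(sum(spk$chrom == "spike_H3K115ac"), 1000)
  chip <- split_by_genome(simulate_fragments(ls, cfg, "H3K115ac"))$spike
  rec <- table(chip$chrom)
  expect_gt(rec[["spike_H3K115ac"]] / 1000,
            rec[["spike_H3K27ac"]] / 800)
})

test_that("depth zero yields a valid empty genomic library", {
  cfg <- tiny_cfg(library_depth = 0, spike_in_counts = integer(0))
  g <- simulate_genome(cfg)
  ls <- simulate_landscape(cfg, g)
  frag <- simulate_fragments(ls, cfg, "input")
  expect_equal(nrow(frag), 0)
})

test_that("ground truth tables round-trip through TSV", {
  s <- small_sim()
  truth <- s$sim$truth
  d <- withr::local_tempdir()
  write_truth(truth, d)
  back <- read_truth(d)
  for (nm in c("promoters", "enhancers", "ctcf", "particles")) {
    expect_equal(nrow(back[[nm]]), nrow(truth[[nm]]))
    expect_identical(names(back[[nm]]), names(truth[[nm]]))
    num <- vapply(truth[[nm]], is.numeric, logical(1))
    for (cl in names(which(num)))
      expect_equal(back[[nm]][[cl]], truth[[nm]][[cl]], tolerance = 1e-12)
    for (cl in names(which(!num)))
      expect_identical(as.character(back[[nm]][[cl]]),
                       as.character(truth[[nm]][[cl]]))
  }
})
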