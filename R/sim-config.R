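#' Simulation configuration for the synthetic chromatin generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genome()], [simulate_landscape()] and [simulate_fragments()].
#' Defaults describe a small mammalian-like genome in which CpG-island (CGI)
#' promoters, active enhancers and CTCF sites carry nucleosome-depleted
#' regions (NDRs) flanked by phased nucleosome arrays, with fragile particles
#' (partially unwrapped mononucleosomes and subnucleosomes) inside the NDRs
#' carrying H3K115ac, and H3K27ac confined to flanking stable nucleosomes.
#'
#' @param seed integer seed; every downstream stage derives its RNG stream
#'   from this value plus a fixed per-library offset, so adding one library
#'   never perturbs another.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param n_genes number of genes (one TSS each plus decoy alternative TSSs).
#' @param frac_cgi_promoters fraction of promoters overlapping a CGI.
#' @param frac_polycomb_cgi fraction of CGI promoters that are
#'   polycomb-repressed (H3K27ac excluded, transcription initially silent).
#' @param n_enhancers number of distal enhancers.
#' @param frac_dual_oct4 fraction of enhancers with two Oct4 motifs (others
#'   carry one).
#' @param n_ctcf_sites number of CTCF motif sites.
#' @param n_tad_boundaries number of TAD boundaries per chromosome.
#' @param nucleosome_spacing nucleosome repeat length of phased arrays (bp).
#' @param ndr_width_mean,ndr_width_sd promoter/enhancer NDR width (bp).
#' @param particle_length_params named list of `c(mean, sd)` fragment-length
#'   parameters per particle class (truncated normal on \[40, 400\]):
#'   `stable_mono`, `fragile_mono`, `subnucleosome`, `ctcf_complex`,
#'   `mono_plus_factor`.
#' @param mark_probabilities named list with elements `H3K115ac` and
#'   `H3K27ac`, each a named vector of per-element-context probabilities of a
#'   particle carrying the mark (see [simulate_landscape()] for the context
#'   labels).
#' @param chip_efficiency probability that a marked particle is recovered by
#'   ChIP relative to its occupancy weight.
#' @param background_rate fraction of a ChIP library that is unselected input
#'   background.
#' @param at_bias_fragile additive A/T enrichment of the sequence under
#'   fragile (fragile_mono / subnucleosome / ctcf_complex) particles.
#' @param gc_background background G/C fraction of the genome.
#' @param gc_cgi G/C fraction inside CGI intervals (must exceed
#'   `gc_background` by >= 0.10).
#' @param ctcf_sub_shift displacement (bp) of the CTCF NDR subnucleosome
#'   towards the motif 3' end, producing the downstream occupancy asymmetry.
#' @param spike_in_counts named integer vector of spike-in nucleosome counts
#'   per barcode appended to the input library.
#' @param spike_on_target_recovery,spike_off_target_recovery recovery
#'   probability of the ChIP-matched barcode and of all other barcodes in a
#'   ChIP library.
#' @param library_depth number of genomic fragments per simulated library.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, chrom_length = 2e5,
#'                   n_chromosomes = 1, n_enhancers = 10, n_ctcf_sites = 10,
#'                   library_depth = 1e4)
#' cfg$nucleosome_spacing
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       chrom_length = 1e6,
                       n_genes = 300L,
                       frac_cgi_promoters = 0.6,
                       frac_polycomb_cgi = 0.2,
                       n_enhancers = 150L,
                       frac_dual_oct4 = 0.4,
                       n_ctcf_sites = 200L,
                       n_tad_boundaries = 5L,
                       nucleosome_spacing = 190,
                       ndr_width_mean = 160,
                       ndr_width_sd = 20,
                       particle_length_params = list(
                         stable_mono      = c(mean = 165, sd = 15),
                         fragile_mono     = c(mean = 145, sd = 12),
                         subnucleosome    = c(mean = 95,  sd = 20),
                         ctcf_complex     = c(mean = 135, sd = 20),
                         mono_plus_factor = c(mean = 280, sd = 35)),
                       mark_probabilities = default_mark_probabilities(),
                       chip_efficiency = 0.8,
                       background_rate = 0.05,
                       at_bias_fragile = 0.05,
                       gc_background = 0.42,
                       gc_cgi = 0.55,
                       ctcf_sub_shift = 15,
                       spike_in_counts = c(H3K115ac = 2000, H3K27ac = 2000,
                                           H3K9ac = 2000, unmodified = 2000),
                       spike_on_target_recovery = 0.25,
                       spike_off_target_recovery = 0.02,
                       library_depth = 1e6) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              frac_cgi_promoters = frac_cgi_promoters,
              frac_polycomb_cgi = frac_polycomb_cgi,
              n_enhancers = as.integer(n_enhancers),
              frac_dual_oct4 = frac_dual_oct4,
              n_ctcf_sites = as.integer(n_ctcf_sites),
              n_tad_boundaries = as.integer(n_tad_boundaries),
              nucleosome_spacing = nucleosome_spacing,
              ndr_width_mean = ndr_width_mean,
              ndr_width_sd = ndr_width_sd,
              particle_length_params = particle_length_params,
              mark_probabilities = mark_probabilities,
              chip_efficiency = chip_efficiency,
              background_rate = background_rate,
              at_bias_fragile = at_bias_fragile,
              gc_background = gc_background,
              gc_cgi = gc_cgi,
              ctcf_sub_shift = ctcf_sub_shift,
              spike_in_counts = spike_in_counts,
              spike_on_target_recovery = spike_on_target_recovery,
              spike_off_target_recovery = spike_off_target_recovery,
              library_depth = as.numeric(library_depth))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default per-context mark probabilities
#'
#' Context labels combine the particle's element association and position:
#' `promoter_ndr_cgi`, `promoter_ndr_noncgi`, `promoter_minus1`,
#' `promoter_plus1`, `gene_body`, `enhancer_ndr`, `enhancer_flank`,
#' `ctcf_ndr`, `ctcf_flank`, `array`. H3K115ac is concentrated on
#' NDR-internal particles (strongly at CGI promoters) and the -1 nucleosome;
#' H3K27ac sits on +1/flanking stable nucleosomes and gene bodies and is
#' excluded from NDR interiors.
#'
#' @return named list of named probability vectors.
#' @export
default_mark_probabilities <- function() {
  contexts <- c("promoter_ndr_cgi", "promoter_ndr_noncgi", "promoter_minus1",
                "promoter_plus1", "gene_body", "enhancer_ndr",
                "enhancer_flank", "ctcf_ndr", "ctcf_flank", "array")
  k115 <- c(promoter_ndr_cgi = 0.85, promoter_ndr_noncgi = 0.05,
            promoter_minus1 = 0.50, promoter_plus1 = 0.10,
            gene_body = 0.02, enhancer_ndr = 0.60, enhancer_flank = 0.10,
            ctcf_ndr = 0.60, ctcf_flank = 0.25, array = 0.02)
  k27 <- c(promoter_ndr_cgi = 0.00, promoter_ndr_noncgi = 0.00,
           promoter_minus1 = 0.35, promoter_plus1 = 0.70,
           gene_body = 0.45, enhancer_ndr = 0.00, enhancer_flank = 0.60,
           ctcf_ndr = 0.00, ctcf_flank = 0.40, array = 0.05)
  stopifnot(identical(names(k115), contexts), identical(names(k27), contexts))
  list(H3K115ac = k115, H3K27ac = k27)
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_cgi_promoters", "frac_polycomb_cgi", "frac_dual_oct4",
                   "chip_efficiency", "background_rate", "gc_background",
                   "gc_cgi", "spike_on_target_recovery",
                   "spike_off_target_recovery")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("sim_config field '", f, "' must be a fraction in [0, 1]")
  }
  if (cfg$at_bias_fragile < 0 || cfg$at_bias_fragile > 0.5)
    stop("at_bias_fragile must be in [0, 0.5]")
  if (cfg$gc_cgi < cfg$gc_background + 0.10)
    stop("gc_cgi must exceed gc_background by at least 0.10")
  pos_fields <- c("chrom_length", "nucleosome_spacing", "ndr_width_mean",
                  "ndr_width_sd", "library_depth")
  for (f in pos_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config field '", f, "' must be non-negative")
  }
  if (cfg$nucleosome_spacing <= 147)
    stop("nucleosome_spacing must exceed the 147 bp core footprint")
  classes <- c("stable_mono", "fragile_mono", "subnucleosome",
               "ctcf_complex", "mono_plus_factor")
  if (!all(classes %in% names(cfg$particle_length_params)))
    stop("particle_length_params must name all five particle classes")
  for (cl in classes) {
    p <- cfg$particle_length_params[[cl]]
    if (p[["mean"]] < 40 || p[["mean"]] > 400 || p[["sd"]] <= 0)
      stop("particle class '", cl,
           "' length distribution must have support within [40, 400]")
  }
  for (mk in c("H3K115ac", "H3K27ac")) {
    p <- cfg$mark_probabilities[[mk]]
    if (is.null(p) || any(p < 0) || any(p > 1))
      stop("mark_probabilities$", mk, " must be probabilities in [0, 1]")
  }
  if (any(cfg$spike_in_counts < 0) ||
      any(cfg$spike_in_counts != round(cfg$spike_in_counts)))
    stop("spike_in_counts must be non-negative integers")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x",
      format(x$chrom_length, big.mark = ","), "bp;",
      x$n_genes, "genes,", x$n_enhancers, "enhancers,",
      x$n_ctcf_sites, "CTCF sites; depth",
      format(x$library_depth, big.mark = ","), "fragments/library; seed",
      x$seed, "\n")
  invisible(x)
}

# Deterministic per-stage RNG streams: stage index keeps libraries
# independent of one another (adding a library never reseeds an earlier one).
sim_stream_seed <- function(cfg, stage) {
  offsets <- c(genome = 101L, landscape = 211L, truth = 307L,
               input = 1009L, H3K115ac = 2003L, H3K27ac = 3001L,
               counts = 4001L)
  if (!stage %in% names(offsets)) stop("unknown simulation stage: ", stage)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

# Truncated-normal fragment lengths on [lo, hi] via inverse-CDF sampling.
rtrunc_norm <- function(n, mean, sd, lo = 40, hi = 400) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  round(stats::qnorm(stats::runif(n, plo, phi), mean, sd))
}
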