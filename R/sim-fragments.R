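#' Simulate a paired-end fragment library from a nucleosome landscape
#'
#' Emits `config$library_depth` genomic fragments. For the input library a
#' particle is picked proportional to its occupancy; for a ChIP library a
#' signal fragment is picked proportional to occupancy x mark presence x
#' `chip_efficiency`, and a `background_rate` fraction of the library is
#' drawn from the input (occupancy-only) distribution. Fragment length is
#' drawn from the particle-class truncated-normal distribution and the
#' fragment midpoint is the particle dyad plus Normal(0, positioning_sd)
#' noise. Spike-in fragments (genome_label `"spike"`) are appended: at the
#' exact configured per-barcode counts for the input library, and at
#' binomially sampled counts with on-/off-target recovery for ChIP
#' libraries. Output is sorted by (chrom, start).
#'
#' Each library uses its own RNG stream derived from `config$seed` plus a
#' fixed per-library offset, so simulating one library never perturbs
#' another.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param config the same [sim_config()] used to build the landscape.
#' @param library one of `"input"`, `"H3K115ac"`, `"H3K27ac"`.
#' @return A fragment set (see [fragment_set()]) with provenance columns
#'   `class` and `element` for ground-truth checks (writers drop them).
#' @export
simulate_fragments <- function(landscape, config,
                               library = c("input", "H3K115ac", "H3K27ac")) {
  library <- match.arg(library)
  pp <- landscape$particles
  set.seed(sim_stream_seed(config, library))
  n <- config$library_depth

  if (library == "input") {
    n_bg <- 0L
    n_sig <- n
    w_sig <- pp$occupancy
  } else {
    mark <- if (library == "H3K115ac") pp$h3k115ac else pp$h3k27ac
    w_sig <- pp$occupancy * as.numeric(mark) * config$chip_efficiency
    n_bg <- stats::rbinom(1L, size = as.integer(n), prob = config$background_rate)
    n_sig <- n - n_bg
    if (sum(w_sig) == 0) {            # nothing ChIP-able: background only
      n_bg <- n
      n_sig <- 0L
    }
  }

  draw <- function(k, w) {
    if (k == 0 || nrow(pp) == 0 || sum(w) == 0)
      return(integer(0))
    sample.int(nrow(pp), k, replace = TRUE, prob = w)
  }
  idx <- c(draw(n_sig, w_sig), draw(n_bg, pp$occupancy))

  if (length(idx) > 0) {
    lens <- integer(length(idx))
    cls <- pp$class[idx]
    for (cl in unique(cls)) {
      j <- which(cls == cl)
      par <- config$particle_length_params[[cl]]
      lens[j] <- rtrunc_norm(length(j), par[["mean"]], par[["sd"]])
    }
    mids <- pp$dyad[idx] + round(stats::rnorm(length(idx), 0,
                                              pp$positioning_sd[idx]))
    start <- mids - floor(lens / 2)
    end <- start + lens
    L <- landscape$chrom_sizes[pp$chrom[idx]]
    start <- pmax(0, start)
    end <- pmin(L, end)
    ok <- end > start
    frag <- data.frame(chrom = pp$chrom[idx][ok], start = start[ok],
                       end = end[ok], genome_label = "target",
                       class = cls[ok], element = pp$element[idx][ok],
                       stringsAsFactors = FALSE)
  } else {
    frag <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), genome_label = character(0),
                       class = character(0), element = character(0))
  }

  spk <- simulate_spike_ins(config, library)
  frag <- rbind(frag, spk)
  frag <- frag[order(frag$chrom, frag$start), , drop = FALSE]
  rownames(frag) <- NULL
  out <- fragment_set(frag$chrom, frag$start, frag$end, frag$genome_label)
  out$class <- frag$class
  out$element <- frag$element
  attr(out, "library") <- library
  out
}

# Spike-in barcoded nucleosomes: exact counts in the input library;
# binomial recovery (on-target vs cross-reactive) in ChIP libraries.
simulate_spike_ins <- function(config, library) {
  counts <- config$spike_in_counts
  if (length(counts) == 0 || sum(counts) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), genome_label = character(0),
                      class = character(0), element = character(0)))
  if (library != "input") {
    rec <- ifelse(names(counts) == library,
                  config$spike_on_target_recovery,
                  config$spike_off_target_recovery)
    counts <- stats::setNames(
      stats::rbinom(length(counts), size = as.integer(counts), prob = rec),
      names(counts))
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), genome_label = character(0),
                      class = character(0), element = character(0)))
  data.frame(chrom = rep(paste0("spike_", names(counts)), counts),
             start = 0, end = 147, genome_label = "spike",
             class = "spike", element = "spike", stringsAsFactors = FALSE)
}

#' Imprint particle-footprint sequence composition onto the genome
#'
#' Rewrites the reference sequence under particle footprints so that the
#' configured compositional contrast between fragile and stable particles
#' holds exactly: stable nucleosome footprints (stable_mono,
#' mono_plus_factor) are written at the background base composition, and
#' fragile-particle footprints (fragile_mono, subnucleosome, ctcf_complex)
#' at background A/T plus `config$at_bias_fragile`. Fragile footprints take
#' precedence where the two overlap. Footprint half-width is half the
#' class mean fragment length.
#'
#' @param genome output of [simulate_genome()].
#' @param landscape matching [simulate_landscape()] result.
#' @param config the shared [sim_config()].
#' @return `genome` with a modified `$genome` DNAStringSet.
#' @export
imprint_fragile_sequence <- function(genome, landscape, config) {
  set.seed(sim_stream_seed(config, "genome") + 7L)
  at_bg <- 1 - config$gc_background
  at_fragile <- min(0.95, at_bg + config$at_bias_fragile)
  pp <- landscape$particles
  fragile <- c("fragile_mono", "subnucleosome", "ctcf_complex")
  stable <- c("stable_mono", "mono_plus_factor")
  half <- vapply(config$particle_length_params,
                 function(p) floor(p[["mean"]] / 2), numeric(1))
  seqs <- genome$genome
  for (ch in names(seqs)) {
    L <- genome$chrom_sizes[[ch]]
    on_ch <- pp$chrom == ch
    for (grp in list(list(cls = stable, at = at_bg),
                     list(cls = fragile, at = at_fragile))) {
      sel <- on_ch & pp$class %in% grp$cls
      if (!any(sel)) next
      h <- half[pp$class[sel]]
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(1, pp$dyad[sel] - h + 1),        # 1-based
        end = pmin(L, pp$dyad[sel] + h)))
      probs <- c(A = grp$at / 2, C = (1 - grp$at) / 2,
                 G = (1 - grp$at) / 2, T = grp$at / 2)
      repl <- Biostrings::DNAStringSet(vapply(IRanges::width(ir), function(w)
        paste(sample(names(probs), w, replace = TRUE, prob = probs),
              collapse = ""), character(1)))
      seqs[[ch]] <- Biostrings::replaceAt(seqs[[ch]], ir, repl)
    }
  }
  genome$genome <- seqs
  genome
}

#' Run the full synthetic chromatin pipeline
#'
#' Convenience wrapper: genome, landscape, footprint sequence imprinting,
#' ground truth, and the three fragment libraries.
#'
#' @param config a [sim_config()].
#' @param libraries which libraries to simulate.
#' @return list with `genome`, `landscape`, `truth`, and `libraries` (a
#'   named list of fragment sets).
#' @export
simulate_chromatin <- function(config,
                               libraries = c("input", "H3K115ac", "H3K27ac")) {
  genome <- simulate_genome(config)
  landscape <- simulate_landscape(config, genome)
  genome <- imprint_fragile_sequence(genome, landscape, config)
  truth <- ground_truth(landscape, genome$annotations, config)
  libs <- lapply(libraries, function(lb) simulate_fragments(landscape, config, lb))
  names(libs) <- libraries
  list(genome = genome, landscape = landscape, truth = truth,
       libraries = libs)
}
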