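#' Simulate the ground-truth nucleosome landscape
#'
#' Places particles on the annotated genome: phased stable-nucleosome arrays
#' flanking each promoter, enhancer and CTCF NDR; fragile mononucleosomes and
#' subnucleosomes inside promoter and enhancer NDRs; a CTCF-subnucleosome
#' complex plus larger nucleosome-factor particles at CTCF sites. Mark
#' assignment (H3K115ac / H3K27ac) is Bernoulli per particle with the
#' per-context probabilities in `config$mark_probabilities`; polycomb CGI
#' promoters never carry H3K27ac on any of their particles.
#'
#' Geometry per promoter (transcription orientation): the NDR spans
#' `ndr_width` bases immediately upstream of the TSS; the -1 nucleosome dyad
#' sits 73 bp (half a 147 bp core) upstream of the NDR 5' edge and the +1
#' dyad 73 bp downstream of the TSS; arrays extend outwards at
#' `nucleosome_spacing`. Inside the NDR the subnucleosome is TSS-proximal
#' (1/4 of the NDR from the TSS) and the fragile mononucleosome is displaced
#' towards the -1 nucleosome (3/4 of the NDR from the TSS). At CTCF sites the
#' NDR subnucleosome is displaced `ctcf_sub_shift` bp towards the motif 3'
#' end, and the positioning spread of the downstream (+1 side) nucleosomes
#' grows as site occupancy falls.
#'
#' Elements whose anchors lie closer than twice the nucleosome spacing are
#' resolved by dropping the later element with a warning.
#'
#' @param config a [sim_config()] object.
#' @param genome output of [simulate_genome()] (uses `$annotations` and
#'   `$chrom_sizes`).
#' @return An object of class `nucleosome_landscape`: a list with
#'   \describe{
#'     \item{particles}{data frame: `chrom`, `dyad`, `class`, `occupancy`,
#'       `positioning_sd`, `h3k115ac`, `h3k27ac`, `element` (context label),
#'       `element_id`.}
#'     \item{promoters}{per-promoter table with true NDR interval and
#'       flanking dyads.}
#'     \item{ctcf}{per-site table with occupancy and orientation.}
#'     \item{chrom_sizes}{named vector.}
#'   }
#' @export
simulate_landscape <- function(config, genome) {
  validate_sim_config(config)
  ann <- genome$annotations
  chrom_sizes <- genome$chrom_sizes
  set.seed(sim_stream_seed(config, "landscape"))
  spacing <- config$nucleosome_spacing

  keep <- drop_crowded_elements(ann, spacing)
  tss <- keep$tss; enh <- keep$enhancers; ctcf <- keep$ctcf
  oct4 <- ann$oct4

  parts <- list()
  add <- function(chrom, dyad, class, occ, sd, element, id) {
    data.frame(chrom = chrom, dyad = dyad, class = class, occupancy = occ,
               positioning_sd = sd, element = element, element_id = id,
               stringsAsFactors = FALSE)
  }

  promoters <- NULL
  for (i in seq_len(nrow(tss))) {
    p <- tss$pos[i]; dir <- if (tss$strand[i] == "+") 1 else -1
    ch <- tss$chrom[i]; id <- tss$gene[i]
    ndr_w <- max(100, round(stats::rnorm(1, config$ndr_width_mean,
                                         config$ndr_width_sd)))
    m1 <- p - dir * (ndr_w + 73)
    p1 <- p + dir * 73
    ndr_ctx <- if (tss$cgi[i]) "promoter_ndr_cgi" else "promoter_ndr_noncgi"
    pr <- list(
      add(ch, m1, "stable_mono", 0.9, 10, "promoter_minus1", id),
      add(ch, p1, "stable_mono", 0.9, 10, "promoter_plus1", id),
      add(ch, p - dir * round(0.25 * ndr_w), "subnucleosome", 0.45, 20,
          ndr_ctx, id),
      add(ch, p - dir * round(0.75 * ndr_w), "fragile_mono", 0.30, 20,
          ndr_ctx, id),
      add(ch, m1 - dir * spacing * (1:4), "stable_mono", 1.0, 15, "array", id),
      add(ch, p1 + dir * spacing * (1:10), "stable_mono", 1.0, 15,
          c(rep("gene_body", 10))[1:10], id))
    # array beyond ~2 kb of gene body reverts to plain array context
    gb <- pr[[6]]
    gb$element[abs(gb$dyad - p) > 2000] <- "array"
    pr[[6]] <- gb
    parts <- c(parts, pr)
    promoters <- rbind(promoters, data.frame(
      chrom = ch, gene = id, tss = p, strand = tss$strand[i],
      cgi = tss$cgi[i], polycomb = tss$polycomb[i],
      ndr_width = ndr_w,
      ndr_start = if (dir == 1) p - ndr_w else p + 1,
      ndr_end = if (dir == 1) p else p + ndr_w + 1,
      minus1_dyad = m1, plus1_dyad = p1, stringsAsFactors = FALSE))
  }

  for (i in seq_len(nrow(enh))) {
    ch <- enh$chrom[i]; id <- enh$name[i]
    center <- (enh$start[i] + enh$end[i]) / 2
    mot <- oct4[grepl(paste0("^", id_to_oct4(id), "_"), oct4$name), ,
                drop = FALSE]
    mids <- if (nrow(mot) > 0) (mot$start + mot$end) / 2 else center
    inner <- round(mean(mids))
    parts <- c(parts, list(
      add(ch, inner, "subnucleosome", 0.30, 20, "enhancer_ndr", id),
      add(ch, inner, "fragile_mono", 0.35, 25, "enhancer_ndr", id),
      add(ch, center - 400 - spacing * (0:2), "stable_mono", 0.9, 15,
          "enhancer_flank", id),
      add(ch, center + 400 + spacing * (0:2), "stable_mono", 0.9, 15,
          "enhancer_flank", id)))
  }

  ctcf_tab <- NULL
  for (i in seq_len(nrow(ctcf))) {
    ch <- ctcf$chrom[i]; id <- ctcf$name[i]
    m <- floor((ctcf$start[i] + ctcf$end[i]) / 2)
    dir <- if (ctcf$strand[i] == "+") 1 else -1
    occ <- ctcf$occupancy[i]
    sd_dn <- 12 + 35 * (1 - occ)      # downstream fuzziness grows as occ drops
    parts <- c(parts, list(
      add(ch, m, "ctcf_complex", occ, 10, "ctcf_ndr", id),
      add(ch, m + dir * config$ctcf_sub_shift, "subnucleosome", 0.4 * occ, 15,
          "ctcf_ndr", id),
      add(ch, m - dir * 150, "mono_plus_factor", 0.15 * occ, 15,
          "ctcf_flank", id),
      add(ch, m + dir * 150, "mono_plus_factor", 0.15 * occ, 15,
          "ctcf_flank", id),
      add(ch, m - dir * (150 + spacing * (0:3)), "stable_mono",
          0.6 + 0.4 * occ, 12, "ctcf_flank", id),
      add(ch, m + dir * (150 + spacing * (0:3)), "stable_mono",
          0.6 + 0.4 * occ, sd_dn, "ctcf_flank", id)))
    ctcf_tab <- rbind(ctcf_tab, data.frame(
      chrom = ch, name = id, motif_mid = m, strand = ctcf$strand[i],
      occupancy = occ, score = ctcf$score[i], stringsAsFactors = FALSE))
  }

  particles <- do.call(rbind, parts)
  if (is.null(particles))
    particles <- data.frame(chrom = character(0), dyad = numeric(0),
                            class = character(0), occupancy = numeric(0),
                            positioning_sd = numeric(0),
                            element = character(0), element_id = character(0))
  # enforce chromosome bounds (dyad plus half-core inside the chromosome)
  ok <- particles$dyad >= 74 &
    particles$dyad <= chrom_sizes[particles$chrom] - 74
  particles <- particles[ok, , drop = FALSE]
  rownames(particles) <- NULL

  particles <- assign_marks(particles, config, promoters)
  structure(list(particles = particles, promoters = promoters,
                 ctcf = ctcf_tab, chrom_sizes = chrom_sizes),
            class = "nucleosome_landscape")
}

# enhancer "enh_3" owns motifs named "oct4_3_*"
id_to_oct4 <- function(id) sub("^enh_", "oct4_", id)

# Elements whose anchor points lie closer than 2x spacing on the same
# chromosome cannot host non-overlapping arrays; the later one is dropped.
drop_crowded_elements <- function(ann, spacing) {
  one <- function(chrom, pos, set) {
    data.frame(chrom = chrom, pos = pos,
               set = rep(set, length(chrom)), row = seq_along(chrom),
               stringsAsFactors = FALSE)
  }
  anchors <- rbind(
    one(ann$tss$chrom, ann$tss$pos, "tss"),
    one(ann$enhancers$chrom,
        (ann$enhancers$start + ann$enhancers$end) / 2, "enhancers"),
    one(ann$ctcf$chrom, (ann$ctcf$start + ann$ctcf$end) / 2, "ctcf"))
  drop <- rep(FALSE, nrow(anchors))
  for (ch in unique(anchors$chrom)) {
    i <- which(anchors$chrom == ch)
    o <- i[order(anchors$pos[i])]
    last_kept <- -Inf
    for (j in o) {
      if (anchors$pos[j] - last_kept < 2 * spacing) {
        drop[j] <- TRUE
      } else {
        last_kept <- anchors$pos[j]
      }
    }
  }
  if (any(drop))
    warning(sum(drop), " element(s) closer than 2x nucleosome spacing ",
            "to a neighbour were dropped")
  keep_set <- function(set, df) df[setdiff(seq_len(nrow(df)),
                                           anchors$row[drop & anchors$set == set]), ,
                                  drop = FALSE]
  list(tss = keep_set("tss", ann$tss),
       enhancers = keep_set("enhancers", ann$enhancers),
       ctcf = keep_set("ctcf", ann$ctcf))
}

assign_marks <- function(particles, config, promoters) {
  n <- nrow(particles)
  if (n == 0) {
    particles$h3k115ac <- logical(0)
    particles$h3k27ac <- logical(0)
    return(particles)
  }
  p115 <- config$mark_probabilities$H3K115ac[particles$element]
  p27 <- config$mark_probabilities$H3K27ac[particles$element]
  p115[is.na(p115)] <- 0; p27[is.na(p27)] <- 0
  particles$h3k115ac <- stats::runif(n) < p115
  particles$h3k27ac <- stats::runif(n) < p27
  # polycomb promoters: no H3K27ac anywhere on the element
  if (!is.null(promoters) && any(promoters$polycomb)) {
    pc <- promoters$gene[promoters$polycomb]
    particles$h3k27ac[particles$element_id %in% pc] <- FALSE
  }
  particles
}

#' @export
print.nucleosome_landscape <- function(x, ...) {
  cat("nucleosome_landscape:", nrow(x$particles), "particles on",
      length(x$chrom_sizes), "chromosome(s)\n")
  print(table(x$particles$class))
  invisible(x)
}
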