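#' Construct an anchor set
#'
#' Anchors are single-base reference points (TSSs, motif midpoints) with an
#' orientation (+1/-1) applied when profiles and V-plots are computed, and
#' a group label (quartile, class, ...).
#'
#' @param chrom chromosome per anchor.
#' @param pos 0-based anchor base.
#' @param orientation +1 or -1 (recycled).
#' @param group group label (recycled).
#' @return data frame of class `anchor_set`.
#' @export
anchor_set <- function(chrom, pos, orientation = 1L, group = "all") {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  orientation <- rep_len(as.integer(orientation), n)
  if (n > 0 && !all(orientation %in% c(-1L, 1L)))
    stop("orientation must be +1 or -1")
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   orientation = orientation,
                   group = rep_len(as.character(group), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("anchor_set", "data.frame")
  df
}

#' Strand-aware TSS base of a stranded BED-like interval
#'
#' The transcription-start base is `start` for plus-strand records and
#' `end - 1` for minus-strand records (0-based half-open convention).
#'
#' @param df data frame with `start`, `end`, `strand`.
#' @return numeric vector of single-base positions.
#' @export
tss_position <- function(df) {
  ifelse(df$strand == "+", df$start, df$end - 1)
}

#' Conservative TSS selection
#'
#' Per gene, keeps the single TSS with the highest activity count (ties
#' broken to the smaller coordinate), then removes any kept TSS that has a
#' TSS of a different gene within `exclusion_radius`, so local directional
#' analyses are not confounded by neighbouring transcription.
#'
#' @param tss_all data frame with `chrom`, `pos`, `strand`, `gene`.
#' @param activity_counts numeric activity (e.g. nascent-transcription
#'   reads) aligned with `tss_all` rows.
#' @param exclusion_radius neighbour exclusion distance in bases.
#' @return an [anchor_set()] with `group` = gene; pairwise distances of the
#'   result exceed `exclusion_radius`.
#' @export
conservative_tss <- function(tss_all, activity_counts,
                             exclusion_radius = 1000) {
  stopifnot(nrow(tss_all) == length(activity_counts))
  if (nrow(tss_all) == 0)
    return(anchor_set(character(0), numeric(0)))
  # argmax per gene; tie -> smaller coordinate (stable via ordering)
  o <- order(tss_all$gene, -activity_counts, tss_all$pos)
  first <- !duplicated(tss_all$gene[o])
  keep_idx <- o[first]
  kept <- tss_all[keep_idx, , drop = FALSE]
  # drop any kept TSS with a neighbouring TSS (another gene, full input set)
  drop <- vapply(seq_len(nrow(kept)), function(i) {
    other <- tss_all$chrom == kept$chrom[i] & tss_all$gene != kept$gene[i]
    any(abs(tss_all$pos[other] - kept$pos[i]) <= exclusion_radius)
  }, logical(1))
  kept <- kept[!drop, , drop = FALSE]
  anchor_set(kept$chrom, kept$pos,
             ifelse(kept$strand == "+", 1L, -1L), kept$gene)
}

#' CGI association of TSSs
#'
#' TRUE iff the minimum distance from the TSS base to a CGI interval is at
#' most `radius` bases (a TSS inside a CGI has distance 0). Independent of
#' TSS strand.
#'
#' @param tss_set data frame with `chrom`, `pos`.
#' @param cgi_intervals data frame with `chrom`, `start`, `end`.
#' @param radius association distance in bases.
#' @return logical vector per TSS.
#' @export
cgi_associate <- function(tss_set, cgi_intervals, radius = 500) {
  vapply(seq_len(nrow(tss_set)), function(i) {
    ci <- cgi_intervals[cgi_intervals$chrom == tss_set$chrom[i], ,
                        drop = FALSE]
    if (nrow(ci) == 0) return(FALSE)
    p <- tss_set$pos[i]
    d <- pmax(0, pmax(ci$start - p, p - (ci$end - 1)))
    min(d) <= radius
  }, logical(1))
}

#' Rank-based quartile labels
#'
#' Assigns Q1 (lowest values) to Q4 (highest) by rank, with group sizes
#' differing by at most one and ties broken by stable input order. Labels
#' are invariant under monotone transforms of the values.
#'
#' @param values numeric vector, length >= 4.
#' @return character vector of `"Q1"`..`"Q4"`.
#' @export
quartile_assign <- function(values) {
  n <- length(values)
  if (n < 4) stop("need at least 4 values for quartiles")
  r <- rank(values, ties.method = "first")
  paste0("Q", ceiling(r * 4 / n))
}

#' Oriented CTCF anchor selection
#'
#' Keeps ChIP peaks overlapping exactly one CTCF motif, anchors each at
#' the motif midpoint with the motif strand as orientation, and groups
#' anchors by quartile of peak score (Q4 = strongest).
#'
#' @param peaks data frame with `chrom`, `start`, `end`, `score`.
#' @param motif_hits data frame with `chrom`, `start`, `end`, `strand`.
#' @return an [anchor_set()].
#' @export
ctcf_select <- function(peaks, motif_hits) {
  hit_idx <- lapply(seq_len(nrow(peaks)), function(i) {
    m <- which(motif_hits$chrom == peaks$chrom[i] &
                 motif_hits$start < peaks$end[i] &
                 motif_hits$end > peaks$start[i])
    m
  })
  keep <- which(lengths(hit_idx) == 1L)
  if (length(keep) < 4)
    stop("fewer than 4 single-motif peaks: cannot assign quartiles")
  mi <- unlist(hit_idx[keep])
  anchor_set(peaks$chrom[keep],
             floor((motif_hits$start[mi] + motif_hits$end[mi]) / 2),
             ifelse(motif_hits$strand[mi] == "+", 1L, -1L),
             quartile_assign(peaks$score[keep]))
}

#' TAD-boundary-distance quartiles
#'
#' Distance from each anchor to the nearest TAD boundary on its
#' chromosome, labelled into quartiles (Q1 = closest to a boundary).
#'
#' @param anchors an [anchor_set()].
#' @param tad_boundaries data frame with `chrom`, `pos`.
#' @return character vector of quartile labels per anchor.
#' @export
tad_score_quartiles <- function(anchors, tad_boundaries) {
  if (nrow(tad_boundaries) == 0)
    stop("empty TAD boundary set")
  d <- vapply(seq_len(nrow(anchors)), function(i) {
    b <- tad_boundaries$pos[tad_boundaries$chrom == anchors$chrom[i]]
    if (length(b) == 0) return(NA_real_)
    min(abs(b - anchors$pos[i]))
  }, numeric(1))
  if (anyNA(d))
    stop("anchor chromosome(s) without any TAD boundary")
  quartile_assign(d)
}

#' Enhancers with exactly two Oct4 motifs
#'
#' Selects enhancers (accessible intervals) containing exactly two motifs
#' whose midpoints span at most `max_pair_span` bases, and emits the
#' ordered motif pair. Enhancers with more than two motifs are excluded
#' rather than sub-paired.
#'
#' @param enhancer_intervals data frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param oct4_motifs data frame with `chrom`, `start`, `end`.
#' @param max_pair_span maximum motif-pair span in bases.
#' @return data frame with one row per retained enhancer: `chrom`, `left`,
#'   `right` (motif midpoints, left < right), `group` (enhancer name).
#' @export
dual_motif_enhancers <- function(enhancer_intervals, oct4_motifs,
                                 max_pair_span = 300) {
  if (is.null(enhancer_intervals$name))
    enhancer_intervals$name <- paste0("enh_", seq_len(nrow(enhancer_intervals)))
  mid <- floor((oct4_motifs$start + oct4_motifs$end) / 2)
  rows <- lapply(seq_len(nrow(enhancer_intervals)), function(i) {
    inside <- which(oct4_motifs$chrom == enhancer_intervals$chrom[i] &
                      mid >= enhancer_intervals$start[i] &
                      mid < enhancer_intervals$end[i])
    if (length(inside) != 2L) return(NULL)
    m <- sort(mid[inside])
    if (m[2] - m[1] > max_pair_span) return(NULL)
    data.frame(chrom = enhancer_intervals$chrom[i], left = m[1],
               right = m[2], group = enhancer_intervals$name[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), left = numeric(0),
                      right = numeric(0), group = character(0))
  out
}

#' Randomise anchor orientations
#'
#' Control for orientation-dependent statistics: each anchor keeps its
#' position but receives a random +1/-1 orientation.
#'
#' @param anchors an [anchor_set()].
#' @param seed RNG seed for reproducibility.
#' @return the anchor set with shuffled orientations.
#' @export
randomize_orientation <- function(anchors, seed = 1L) {
  set.seed(seed)
  anchors$orientation <- sample(c(-1L, 1L), nrow(anchors), replace = TRUE)
  anchors
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set:", nrow(x), "anchors;", length(unique(x$group)),
      "group(s)\n")
  invisible(x)
}
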