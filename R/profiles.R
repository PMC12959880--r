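#' Anchor-centred mean meta-profile
#'
#' Extracts the window `anchor +/- flank` from a base-resolution track for
#' every anchor, mirrors windows of minus-oriented anchors, and averages.
#' Anchors whose window exceeds a chromosome are skipped and counted in
#' `n_skipped` (no zero padding, which would bias the mean).
#'
#' @param track a base-resolution [coverage_track()].
#' @param anchors an [anchor_set()].
#' @param flank half-window in bases.
#' @return object of class `meta_profile`: list with `positions`
#'   (-flank..flank), `mean_signal`, `n_anchors`, `n_skipped`,
#'   `orientation_applied`.
#' @export
metaprofile <- function(track, anchors, flank) {
  stopifnot(track$bin_size == 1, flank >= 1)
  acc <- numeric(2 * flank + 1)
  n_used <- 0L
  n_skipped <- 0L
  for (ch in unique(anchors$chrom)) {
    v <- track$values[[ch]]
    if (is.null(v)) {
      n_skipped <- n_skipped + sum(anchors$chrom == ch)
      next
    }
    sel <- which(anchors$chrom == ch)
    for (i in sel) {
      p <- anchors$pos[i]
      if (p - flank < 0 || p + flank > length(v) - 1) {
        n_skipped <- n_skipped + 1L
        next
      }
      w <- v[(p - flank + 1):(p + flank + 1)]
      if (anchors$orientation[i] < 0) w <- rev(w)
      acc <- acc + w
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0) stop("no usable anchors for metaprofile")
  structure(list(positions = seq(-flank, flank),
                 mean_signal = acc / n_used,
                 n_anchors = n_used, n_skipped = n_skipped,
                 orientation_applied = TRUE),
            class = "meta_profile")
}

#' Lightweight nucleosome dyad caller
#'
#' Gaussian-smooths a coverage track and reports local maxima above a
#' height threshold, enforcing a minimum 120 bp spacing between calls
#' (the higher peak wins). Intended for well-phased simulated or deeply
#' sequenced MNase coverage, not as a full-featured positioning caller.
#'
#' @param mnase_track a base-resolution [coverage_track()].
#' @param smoothing_sd Gaussian smoothing bandwidth in bases.
#' @param min_height minimum smoothed height of a call; default is the
#'   chromosome mean of the smoothed signal.
#' @param min_spacing minimum distance between reported dyads.
#' @return data frame with `chrom`, `dyad` (0-based), `height`.
#' @export
call_nucleosomes_lite <- function(mnase_track, smoothing_sd = 30,
                                  min_height = NULL, min_spacing = 120) {
  stopifnot(mnase_track$bin_size == 1)
  half <- ceiling(3 * smoothing_sd)
  kern <- stats::dnorm(-half:half, sd = smoothing_sd)
  kern <- kern / sum(kern)
  out <- NULL
  for (ch in names(mnase_track$values)) {
    v <- mnase_track$values[[ch]]
    if (length(v) < 2 * half + 1 || sum(v) == 0) next
    sm <- as.numeric(stats::filter(v, kern, sides = 2))
    sm[is.na(sm)] <- 0
    thr <- if (is.null(min_height)) mean(sm) else min_height
    n <- length(sm)
    is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                  sm[2:(n - 1)] >= sm[3:n], FALSE) & sm > thr
    cand <- which(is_max)
    if (length(cand) == 0) next
    cand <- cand[order(-sm[cand])]
    accepted <- integer(0)
    for (p in cand) {
      if (length(accepted) == 0 || all(abs(accepted - p) >= min_spacing))
        accepted <- c(accepted, p)
    }
    accepted <- sort(accepted)
    out <- rbind(out, data.frame(chrom = ch, dyad = accepted - 1L,
                                 height = sm[accepted],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), dyad = numeric(0),
                      height = numeric(0))
  rownames(out) <- NULL
  out
}

#' Define promoter NDRs from TSSs and nucleosome calls
#'
#' The -1 nucleosome of a TSS is the nearest called dyad upstream in
#' transcription orientation (within `max_search` bases); the NDR runs
#' from the 3' boundary of the -1 nucleosome (dyad + 73 bp, half the
#' 147 bp core, towards the TSS) to the TSS. TSSs with no upstream call in
#' range, or whose boundary reaches past the TSS, are skipped.
#'
#' @param tss_anchors an oriented [anchor_set()] of TSSs.
#' @param nucleosome_calls data frame from [call_nucleosomes_lite()].
#' @param max_search maximum TSS-to-dyad distance in bases.
#' @param half_width half-width of the nucleosome core (73 bp).
#' @return data frame with `chrom`, `start`, `end` (the NDR, 0-based
#'   half-open), `orientation`, `tss_pos`, `group`, `length`. Passed to
#'   [scaled_profile()], bin 1 of the scaled interior is the -1-proximal
#'   edge and the last bin is TSS-proximal.
#' @export
define_ndrs <- function(tss_anchors, nucleosome_calls, max_search = 1000,
                        half_width = 73) {
  rows <- lapply(seq_len(nrow(tss_anchors)), function(i) {
    p <- tss_anchors$pos[i]
    dir <- tss_anchors$orientation[i]
    dy <- nucleosome_calls$dyad[nucleosome_calls$chrom == tss_anchors$chrom[i]]
    up <- if (dir > 0) dy[dy < p & p - dy <= max_search]
          else dy[dy > p & dy - p <= max_search]
    if (length(up) == 0) return(NULL)
    d <- if (dir > 0) max(up) else min(up)
    len <- abs(p - d) - half_width
    if (len <= 0) return(NULL)
    if (dir > 0) {
      start <- d + half_width; end <- p
    } else {
      start <- p + 1; end <- d - half_width + 1
    }
    data.frame(chrom = tss_anchors$chrom[i], start = start, end = end,
               orientation = dir, tss_pos = p, group = tss_anchors$group[i],
               length = len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), orientation = integer(0),
                      tss_pos = numeric(0), group = character(0),
                      length = numeric(0))
  rownames(out) <- NULL
  out
}

# Mean-preserving linear rebinning of a base-resolution vector to S bins:
# each output bin is the length-weighted mean of the overlapping input
# bases, so sum(out) * (L/S) == sum(v) up to float rounding.
rebin_mean <- function(v, S) {
  L <- length(v)
  stopifnot(L >= 1, S >= 1)
  Fcum <- c(0, cumsum(v))
  at <- function(t) {
    i <- pmin(floor(t), L)
    Fcum[i + 1] + (t - i) * c(v, 0)[i + 1]
  }
  e <- (0:S) * (L / S)
  (at(e[-1]) - at(e[-(S + 1)])) / (L / S)
}

#' Region-scaled meta-profile
#'
#' Linearly rebins the coverage of each variable-length region to a common
#' number of bins (mean-preserving) and appends unscaled flanks, then
#' averages over regions. Regions with `orientation = -1` are mirrored
#' before scaling, so bin 1 of the interior always corresponds to the
#' region's left edge in its own orientation (for NDRs from
#' [define_ndrs()]: the -1-nucleosome-proximal edge). Regions shorter than
#' 2 bases or whose flanks leave the chromosome are skipped.
#'
#' @param track a base-resolution [coverage_track()].
#' @param regions data frame with `chrom`, `start`, `end` and optionally
#'   `orientation`.
#' @param scaled_len number of interior bins.
#' @param flank unscaled flank width in bases.
#' @return a `meta_profile` whose `positions` are bin indices
#'   `-flank..-1` (5' flank), `1..scaled_len` (scaled interior, marked by
#'   the logical `interior` element) and `scaled_len+1..scaled_len+flank`
#'   (3' flank).
#' @export
scaled_profile <- function(track, regions, scaled_len = 500, flank = 500) {
  stopifnot(track$bin_size == 1)
  if (is.null(regions$orientation)) regions$orientation <- 1L
  total <- flank + scaled_len + flank
  acc <- numeric(total)
  n_used <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    v <- track$values[[regions$chrom[i]]]
    s <- regions$start[i]; e <- regions$end[i]
    if (is.null(v) || e - s < 2 || s - flank < 0 || e + flank > length(v)) {
      n_skipped <- n_skipped + 1L
      next
    }
    interior <- v[(s + 1):e]
    left <- if (flank > 0) v[(s - flank + 1):s] else numeric(0)
    right <- if (flank > 0) v[(e + 1):(e + flank)] else numeric(0)
    if (regions$orientation[i] < 0) {
      tmp <- left
      left <- rev(right)
      right <- rev(tmp)
      interior <- rev(interior)
    }
    acc <- acc + c(left, rebin_mean(interior, scaled_len), right)
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable regions for scaled_profile")
  positions <- c(seq(-flank, -1, length.out = flank),
                 seq_len(scaled_len),
                 scaled_len + seq_len(flank))
  structure(list(positions = positions, mean_signal = acc / n_used,
                 interior = c(rep(FALSE, flank), rep(TRUE, scaled_len),
                              rep(FALSE, flank)),
                 n_anchors = n_used, n_skipped = n_skipped,
                 orientation_applied = TRUE),
            class = "meta_profile")
}

#' Per-quartile, per-size-class CTCF profiles
#'
#' One oriented [metaprofile()] per anchor group (occupancy quartile) per
#' size-class track. Empty groups are skipped with a warning.
#'
#' @param tracks named list of base-resolution tracks (e.g. `sub`, `mono`).
#' @param ctcf_anchors an oriented, grouped [anchor_set()].
#' @param flank half-window in bases.
#' @return nested list `result[[class]][[group]]` of `meta_profile`s.
#' @export
ctcf_quartile_profiles <- function(tracks, ctcf_anchors, flank = 500) {
  groups <- sort(unique(ctcf_anchors$group))
  lapply(tracks, function(track) {
    out <- list()
    for (g in groups) {
      a <- ctcf_anchors[ctcf_anchors$group == g, , drop = FALSE]
      if (nrow(a) == 0) {
        warning("empty anchor group: ", g)
        next
      }
      out[[g]] <- metaprofile(track, a, flank)
    }
    out
  })
}

#' Downstream/upstream asymmetry of an oriented profile
#'
#' `(mean signal in (0, +window] - mean in [-window, 0)) /
#' (sum of both means + epsilon)`: positive when occupancy is higher 3' of
#' the anchor, zero for a symmetric profile, and exactly negated when the
#' profile is mirrored.
#'
#' @param profile a `meta_profile` centred on the anchor.
#' @param window half-window in bases.
#' @param eps denominator guard for empty windows.
#' @return the asymmetry statistic in \[-1, 1\].
#' @export
asymmetry_statistic <- function(profile, window = 150, eps = 1e-9) {
  p <- profile$positions
  if (window > max(p) || -window < min(p))
    stop("window exceeds profile extent")
  m_pos <- mean(profile$mean_signal[p > 0 & p <= window])
  m_neg <- mean(profile$mean_signal[p < 0 & p >= -window])
  (m_pos - m_neg) / (m_pos + m_neg + eps)
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", length(x$positions), "positions over", x$n_anchors,
      "anchors (", x$n_skipped, "skipped )\n")
  invisible(x)
}
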