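#' Fragment coverage track
#'
#' Computes per-base (or per-bin) coverage from a fragment set. In
#' `full_fragment` mode every base in \[start, end) receives weight 1; in
#' `midpoint` mode a single count is added at `floor((start + end) / 2)`.
#' For `bin_size > 1` each bin stores the mean per-base weight over the
#' bin, so `sum(values) * bin_size` equals the total base mass. Fragments
#' extending beyond a chromosome end are clipped with a warning; fragments
#' on chromosomes absent from `chrom_sizes` raise an error.
#'
#' @param fragments a [fragment_set()] (spike-in fragments should be
#'   removed first with [split_by_genome()]).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bases (1 = base resolution).
#' @param mode `"full_fragment"` or `"midpoint"`.
#' @param metadata free-form list recorded on the track (library, size
#'   class, ...).
#' @return object of class `coverage_track`: list with `values` (named list
#'   of per-chromosome numeric vectors), `bin_size`, `scale_factor`,
#'   `n_fragments`, `metadata`.
#' @export
coverage_track <- function(fragments, chrom_sizes, bin_size = 1,
                           mode = c("full_fragment", "midpoint"),
                           metadata = list()) {
  mode <- match.arg(mode)
  stopifnot(bin_size >= 1)
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    stop("fragments on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  values <- vector("list", length(chrom_sizes))
  names(values) <- names(chrom_sizes)
  clipped <- 0L
  for (ch in names(chrom_sizes)) {
    L <- as.integer(chrom_sizes[[ch]])
    sel <- fragments$chrom == ch
    s <- fragments$start[sel]
    e <- fragments$end[sel]
    if (mode == "midpoint") {
      m <- floor((s + e) / 2)
      clipped <- clipped + sum(m < 0 | m >= L)
      m <- pmax(0L, pmin(L - 1L, m))
      v <- tabulate(m + 1L, nbins = L)
    } else {
      clipped <- clipped + sum(s < 0 | e > L)
      s <- pmax(0, s)
      e <- pmin(L, e)
      keep <- e > s
      cov <- IRanges::coverage(IRanges::IRanges(start = s[keep] + 1,
                                                end = e[keep]), width = L)
      v <- as.numeric(cov)
    }
    if (bin_size > 1) {
      nb <- ceiling(L / bin_size)
      idx <- rep(seq_len(nb), each = bin_size, length.out = L)
      v <- as.numeric(rowsum(v, idx)) / bin_size
    }
    values[[ch]] <- as.numeric(v)
  }
  if (clipped > 0)
    warning(clipped, " fragment(s) extended beyond a chromosome end and ",
            "were clipped")
  structure(list(values = values, bin_size = bin_size, scale_factor = 1,
                 n_fragments = nrow(fragments), metadata = metadata),
            class = "coverage_track")
}

#' Normalise a track to a target sequencing depth
#'
#' Scales the track so that the implied fragment total equals
#' `target_total` (default 10^7): every weight is multiplied by
#' `target_total / n_fragments`.
#'
#' @param track a [coverage_track()].
#' @param target_total normalised fragment total.
#' @return the rescaled track; `n_fragments_norm` records the implied
#'   total.
#' @export
depth_normalize <- function(track, target_total = 1e7) {
  if (is.null(track$n_fragments) || is.na(track$n_fragments) ||
      track$n_fragments <= 0)
    stop("cannot depth-normalise a track built from zero fragments")
  scale_track(track, target_total / track$n_fragments)
}

#' Multiply a track by a scale factor
#'
#' Used for spike-in scaling: `scale_track(track, spike_scale_factor(n))`.
#'
#' @param track a [coverage_track()].
#' @param factor positive multiplier.
#' @return the rescaled track.
#' @export
scale_track <- function(track, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  track$values <- lapply(track$values, function(v) v * factor)
  track$scale_factor <- track$scale_factor * factor
  track$n_fragments_norm <- track$n_fragments * factor
  track
}

#' Total signal mass of a track
#' @param track a [coverage_track()].
#' @return `sum(values) * bin_size` over all chromosomes.
#' @export
track_total_mass <- function(track) {
  sum(vapply(track$values, sum, numeric(1))) * track$bin_size
}

#' Pearson correlation of two tracks in genomic windows
#'
#' Sums the per-base (or per-bin) weights of both tracks in consecutive
#' fixed-width windows across the genome and returns the Pearson
#' correlation of the two window vectors. Errors with fewer than two
#' windows or when either window vector is constant.
#'
#' @param track_a,track_b tracks on the same chromosomes and bin size.
#' @param window window width in bases (default 10 kb).
#' @return Pearson r.
#' @export
replicate_correlation <- function(track_a, track_b, window = 10000) {
  stopifnot(identical(names(track_a$values), names(track_b$values)),
            track_a$bin_size == track_b$bin_size)
  win_sums <- function(track) {
    unlist(lapply(names(track$values), function(ch) {
      v <- track$values[[ch]]
      per_win <- max(1L, floor(window / track$bin_size))
      idx <- (seq_along(v) - 1L) %/% per_win + 1L
      as.numeric(rowsum(v, idx))
    }), use.names = FALSE)
  }
  a <- win_sums(track_a)
  b <- win_sums(track_b)
  if (length(a) < 2)
    stop("need at least two windows to correlate")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant track: window correlation undefined (zero variance)")
  stats::cor(a, b)
}

#' Write / read a coverage track as bedGraph
#'
#' Runs of equal non-zero weight become bedGraph intervals; zero runs are
#' omitted. `read_bedgraph()` reconstructs the per-base values (the
#' fragment count is not recoverable from bedGraph and is `NA` on the
#' result).
#'
#' @param track a [coverage_track()] at base resolution.
#' @param path file path.
#' @return `write_bedgraph` returns `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(track$bin_size == 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(ch, fmt_coord(s[keep]), fmt_coord(e[keep]),
                     format(r$values[keep], digits = 15, trim = TRUE,
                            scientific = FALSE), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_sizes named vector of chromosome lengths for the
#'   reconstruction.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  values <- lapply(chrom_sizes, function(L) numeric(as.integer(L)))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  for (ch in unique(tab$chrom)) {
    if (!ch %in% names(chrom_sizes))
      stop("bedGraph chromosome not in chrom_sizes: ", ch)
    sel <- tab[tab$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sel)))
      values[[ch]][(sel$start[i] + 1):sel$end[i]] <- sel$value[i]
  }
  structure(list(values = values, bin_size = 1, scale_factor = 1,
                 n_fragments = NA_real_, metadata = list(source = path)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s), bin_size",
      x$bin_size, "| fragments:", x$n_fragments, "| scale_factor:",
      format(x$scale_factor, digits = 6), "\n")
  invisible(x)
}
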