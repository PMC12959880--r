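#' Construct a validated fragment set
#'
#' The unit container for sequenced chromatin fragments: a data frame with
#' columns `chrom`, `start`, `end` (0-based half-open) and `genome_label`
#' (`"target"` for the genome under study, `"spike"` for exogenous spike-in
#' chromatin), sorted by (chrom, start).
#'
#' @param chrom chromosome identifiers.
#' @param start,end 0-based half-open interval; `end > start` and fragment
#'   length must lie in \[1, 2000\].
#' @param genome_label `"target"` or `"spike"` per fragment (recycled).
#' @return data frame of class `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end, genome_label = "target") {
  n <- length(chrom)
  genome_label <- rep_len(genome_label, n)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   genome_label = as.character(genome_label),
                   stringsAsFactors = FALSE)
  validate_fragments(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("fragment_set", "data.frame")
  df
}

validate_fragments <- function(df, lines = NULL) {
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start | (df$end - df$start) > 2000)
  if (length(bad) > 0) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    stop("malformed fragment at ", if (is.null(lines)) "row " else "line ",
         where, ": start=", df$start[bad[1]], " end=", df$end[bad[1]])
  }
  invisible(df)
}

#' Read a fragment library from BEDPE or fragment-BED text
#'
#' BEDPE records (chrom1, start1, end1, chrom2, start2, end2, \[name, ...\])
#' are collapsed to the outer span of the two reads; fragment BED records
#' are (chrom, start, end, \[name, ...\]). A `name` field equal to
#' `"spike"` labels spike-in fragments; anything else is `"target"`.
#' Malformed lines raise an error naming the offending line number. Output
#' is validated and sorted by (chrom, start).
#'
#' @param path input file.
#' @param format `"bedpe"` or `"bed"`.
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path, format = c("bedpe", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(fragment_set(character(0), numeric(0), numeric(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (format == "bedpe") 6L else 3L
  nf <- lengths(fields)
  if (any(nf < need))
    stop("malformed line ", which(nf < need)[1], ": expected >= ", need,
         " tab-separated fields")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v))
      stop("malformed line ", which(is.na(v))[1],
           ": non-numeric coordinate in field ", i)
    v
  }
  if (format == "bedpe") {
    c1 <- get(1); c2 <- get(4)
    if (any(c1 != c2))
      stop("malformed line ", which(c1 != c2)[1],
           ": read mates on different chromosomes")
    start <- pmin(num(2), num(5))
    end <- pmax(num(3), num(6))
    name <- if (all(nf >= 7)) get(7) else rep("target", length(c1))
  } else {
    c1 <- get(1)
    start <- num(2)
    end <- num(3)
    name <- if (all(nf >= 4)) get(4) else rep("target", length(c1))
  }
  df <- data.frame(chrom = c1, start = start, end = end,
                   genome_label = ifelse(name == "spike", "spike", "target"),
                   stringsAsFactors = FALSE)
  validate_fragments(df, lines = seq_len(nrow(df)))
  fragment_set(df$chrom, df$start, df$end, df$genome_label)
}

#' Write a fragment library
#'
#' BEDPE output represents each fragment as a 50 bp read pair whose outer
#' span is the fragment (reads are clipped for fragments shorter than
#' 50 bp), with the genome label in the name field, so
#' `read_fragments(write_fragments(x))` round-trips the fragment
#' coordinates. Fragment-BED output writes the span directly.
#'
#' @param fragments a [fragment_set()].
#' @param path output file.
#' @param format `"bedpe"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path, format = c("bedpe", "bed")) {
  format <- match.arg(format)
  f <- as.data.frame(fragments)
  if (format == "bedpe") {
    e1 <- pmin(f$start + 50, f$end)
    s2 <- pmax(f$end - 50, f$start)
    out <- data.frame(f$chrom, fmt_coord(f$start), fmt_coord(e1), f$chrom,
                      fmt_coord(s2), fmt_coord(f$end), f$genome_label, 0,
                      "+", "-")
  } else {
    out <- data.frame(f$chrom, fmt_coord(f$start), fmt_coord(f$end),
                      f$genome_label)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Fragment-length size classification rule
#'
#' Defaults follow the size windows used for the main figures:
#' subnucleosomes are fragments <= 150 bp and mononucleosomes 151-230 bp.
#' The `"methods"` preset is the alternative printed variant
#' (subnucleosomes < 150 bp, mononucleosomes 150-225 bp). Fragments longer
#' than `mono_max` are retained in an `excluded` class (they matter for
#' CTCF 225-350 bp analyses).
#'
#' @param preset `"results"` (default windows) or `"methods"`.
#' @param sub_max,mono_min,mono_max override the class boundaries
#'   (`sub_max < mono_min <= mono_max`).
#' @return object of class `size_class_rule`.
#' @export
size_class_rule <- function(preset = c("results", "methods"),
                            sub_max = NULL, mono_min = NULL, mono_max = NULL) {
  preset <- match.arg(preset)
  d <- if (preset == "results") c(150, 151, 230) else c(149, 150, 225)
  rule <- list(sub_max = if (is.null(sub_max)) d[1] else sub_max,
               mono_min = if (is.null(mono_min)) d[2] else mono_min,
               mono_max = if (is.null(mono_max)) d[3] else mono_max)
  if (!(rule$sub_max < rule$mono_min && rule$mono_min <= rule$mono_max))
    stop("size_class_rule requires sub_max < mono_min <= mono_max")
  class(rule) <- "size_class_rule"
  rule
}

#' Partition fragments into subnucleosomal / mononucleosomal / excluded
#'
#' Exhaustive and disjoint by construction:
#' `|sub| + |mono| + |excluded| = |input|`.
#'
#' @param fragments a [fragment_set()].
#' @param rule a [size_class_rule()].
#' @return list with fragment sets `sub`, `mono`, `excluded`.
#' @export
fractionate <- function(fragments, rule = size_class_rule()) {
  stopifnot(inherits(rule, "size_class_rule"))
  len <- fragments$end - fragments$start
  sub <- len <= rule$sub_max
  mono <- len >= rule$mono_min & len <= rule$mono_max
  excl <- !(sub | mono)
  pick <- function(sel) {
    out <- fragments[sel, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(sub = pick(sub), mono = pick(mono), excluded = pick(excl))
}

#' Separate target-genome from spike-in fragments
#'
#' @param fragments a [fragment_set()] with `genome_label` set.
#' @return list with fragment sets `target` and `spike` and an integer
#'   vector `counts` (sums to the input size).
#' @export
split_by_genome <- function(fragments) {
  lab <- fragments$genome_label
  bad <- setdiff(unique(lab), c("target", "spike"))
  if (length(bad) > 0)
    stop("unknown genome label(s): ", paste(bad, collapse = ", "))
  target <- fragments[lab == "target", , drop = FALSE]
  spike <- fragments[lab == "spike", , drop = FALSE]
  rownames(target) <- rownames(spike) <- NULL
  list(target = target, spike = spike,
       counts = c(target = nrow(target), spike = nrow(spike)))
}

#' Spike-in scaling factor
#'
#' `10^6 / n_spike_reads`: libraries are placed on a common scale by the
#' number of reads mapping to the exogenous spike-in chromatin.
#'
#' @param n_spike_reads positive spike-in read count.
#' @return the scaling factor.
#' @examples
#' spike_scale_factor(1e6)   # 1
#' spike_scale_factor(25e4)  # 4
#' @export
spike_scale_factor <- function(n_spike_reads) {
  if (!is.numeric(n_spike_reads) || length(n_spike_reads) != 1L ||
      n_spike_reads <= 0)
    stop("n_spike_reads must be a single positive count")
  1e6 / n_spike_reads
}

#' Centre Tn5 insertion sites (ATAC-seq offset convention)
#'
#' The 5' end of the plus-strand read is shifted +4 and of the minus-strand
#' read -5 to the actual Tn5 insertion position, and a 20 bp interval is
#' centred on each corrected site (two sites per fragment). The output is
#' tagged so that applying the offset twice raises an error.
#'
#' @param fragments a [fragment_set()] of paired-end fragments (plus-strand
#'   5' end = `start`, minus-strand 5' end = `end - 1`).
#' @return a [fragment_set()] of 20 bp insertion-centred intervals with
#'   attribute `tn5_offset = TRUE`.
#' @export
tn5_offset <- function(fragments) {
  if (isTRUE(attr(fragments, "tn5_offset")))
    stop("fragments are already Tn5 insertion-centred")
  site <- c(fragments$start + 4, (fragments$end - 1) - 5)
  chrom <- rep(fragments$chrom, 2)
  label <- rep(fragments$genome_label, 2)
  out <- fragment_set(chrom, pmax(0, site - 10), pmax(site + 10, 1), label)
  attr(out, "tn5_offset") <- TRUE
  out
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x), "fragments")
  if (!is.null(attr(x, "library"))) cat(" [", attr(x, "library"), "]", sep = "")
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
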