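#' Build ground-truth tables for parameter-recovery tests
#'
#' Assigns the latent differential labels and rates the simulator commits
#' to: per-promoter H3K115ac gain/loss/nc class during the simulated
#' differentiation, a congruent expression up/down/nc class, and per-day
#' signal rates; per-enhancer motif count and activity; per-CTCF-site
#' occupancy quartile and distance to the nearest TAD boundary. Particle
#' mark assignments are carried over from the landscape.
#'
#' Label joint distribution (the configured congruence): P(gain) = P(loss)
#' = 0.15; conditional on gain, expression is up/down/nc with probability
#' 0.7/0.1/0.2 (mirrored for loss); nc promoters are up/down/nc with
#' probability 0.1/0.1/0.8. Signal fold changes are 4 (gain/up), 1/4
#' (loss/down) and 1 (nc).
#'
#' @param landscape a [simulate_landscape()] result.
#' @param annotations the `$annotations` element of [simulate_genome()].
#' @param config the shared [sim_config()].
#' @return An object of class `ground_truth`: list of data frames
#'   `promoters`, `enhancers`, `ctcf`, `particles`.
#' @export
ground_truth <- function(landscape, annotations, config) {
  set.seed(sim_stream_seed(config, "truth"))
  pr <- landscape$promoters
  if (is.null(pr)) pr <- data.frame()
  n <- nrow(pr)
  if (n > 0) {
    k115_class <- sample(c("gain", "loss", "nc"), n, replace = TRUE,
                         prob = c(0.15, 0.15, 0.70))
    expr_class <- vapply(k115_class, function(cl) {
      p <- switch(cl,
                  gain = c(up = 0.7, down = 0.1, nc = 0.2),
                  loss = c(up = 0.1, down = 0.7, nc = 0.2),
                  nc   = c(up = 0.1, down = 0.1, nc = 0.8))
      sample(names(p), 1L, prob = p)
    }, character(1))
    base_k115 <- stats::rlnorm(n, meanlog = log(60), sdlog = 0.4) *
      ifelse(pr$cgi, 1, 0.3)
    base_expr <- stats::rlnorm(n, meanlog = log(80), sdlog = 0.6) *
      ifelse(pr$polycomb, 0.05, 1)
    fc_of <- function(cl) c(gain = 4, up = 4, loss = 0.25, down = 0.25,
                            nc = 1)[cl]
    pr$k115_class <- k115_class
    pr$expr_class <- expr_class
    pr$k115_rate_day0 <- base_k115
    pr$k115_rate_day7 <- base_k115 * fc_of(k115_class)
    pr$expr_rate_day0 <- base_expr
    pr$expr_rate_day7 <- base_expr * fc_of(expr_class)
  }

  enh <- annotations$enhancers
  if (nrow(enh) > 0) enh$activity <- stats::runif(nrow(enh), 0.2, 1)

  ct <- landscape$ctcf
  if (is.null(ct)) ct <- data.frame()
  if (nrow(ct) > 0) {
    tad <- annotations$tad
    ct$tad_distance <- vapply(seq_len(nrow(ct)), function(i) {
      b <- tad$pos[tad$chrom == ct$chrom[i]]
      if (length(b) == 0) return(NA_real_)
      min(abs(b - ct$motif_mid[i]))
    }, numeric(1))
    r <- rank(-ct$occupancy, ties.method = "first")
    ct$occupancy_quartile <- paste0("Q", 5 - ceiling(r * 4 / nrow(ct)))
  }

  structure(list(promoters = pr, enhancers = enh, ctcf = ct,
                 particles = landscape$particles),
            class = "ground_truth")
}

#' Simulate per-promoter count tables for the differential analysis
#'
#' Poisson counts over TSS +/- 500 bp windows at day 0 and day 7 for the
#' H3K115ac ChIP signal and the nascent-transcription (4SU) signal, drawn
#' from the ground-truth rates. Unequal sequencing depths are emulated by
#' per-day depth factors.
#'
#' @param truth a [ground_truth()] object.
#' @param config the shared [sim_config()].
#' @param depth_factors length-2 multiplier of day-0 / day-7 sequencing
#'   depth (the normalisation factors downstream analysis must undo).
#' @return data frame with columns `gene`, `k115_day0`, `k115_day7`,
#'   `expr_day0`, `expr_day7` plus the truth labels.
#' @export
simulate_counts <- function(truth, config, depth_factors = c(1, 1.3)) {
  pr <- truth$promoters
  set.seed(sim_stream_seed(config, "counts"))
  n <- nrow(pr)
  data.frame(
    gene = pr$gene,
    k115_day0 = stats::rpois(n, pr$k115_rate_day0 * depth_factors[1]),
    k115_day7 = stats::rpois(n, pr$k115_rate_day7 * depth_factors[2]),
    expr_day0 = stats::rpois(n, pr$expr_rate_day0 * depth_factors[1]),
    expr_day7 = stats::rpois(n, pr$expr_rate_day7 * depth_factors[2]),
    cgi = pr$cgi,
    k115_class = pr$k115_class,
    expr_class = pr$expr_class,
    stringsAsFactors = FALSE)
}

#' Write / read ground-truth tables as TSV
#'
#' Lossless round trip: `read_truth(write_truth(x, dir))` reproduces the
#' tables (numeric columns to full precision via decimal text). An empty
#' table writes a header-only file.
#'
#' @param truth a [ground_truth()] object.
#' @param dir output directory (created if missing).
#' @return `write_truth` returns `dir` invisibly; `read_truth` returns a
#'   `ground_truth` object.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("promoters", "enhancers", "ctcf", "particles")) {
    utils::write.table(
      format_truth_table(truth[[nm]]),
      file.path(dir, paste0(nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

format_truth_table <- function(df) {
  if (is.null(df)) return(data.frame())
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  df
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  tabs <- lapply(c(promoters = "promoters", enhancers = "enhancers",
                   ctcf = "ctcf", particles = "particles"), function(nm) {
    utils::read.table(file.path(dir, paste0(nm, ".tsv")), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  })
  structure(tabs, class = "ground_truth")
}
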