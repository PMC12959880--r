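#' Simulate a small genome with regulatory annotation
#'
#' Generates per-chromosome random sequence at a configured background G/C
#' content, places genes, enhancers and CTCF sites on non-overlapping slots,
#' and overwrites CGI intervals with G/C-rich sequence. All coordinates are
#' 0-based half-open (BED convention); a TSS is a single base.
#'
#' Element slots are allocated deterministically: genes, enhancers and CTCF
#' sites are distributed round-robin over chromosomes and placed on a
#' jittered lattice so that no two elements come closer than one slot width.
#' If the requested element count cannot fit at the minimum slot width the
#' function stops with a sizing error.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{genome}{`Biostrings::DNAStringSet`, one entry per chromosome.}
#'     \item{chrom_sizes}{named numeric vector of chromosome lengths.}
#'     \item{annotations}{list of BED-writable data frames: `tss` (stranded,
#'       with `gene`, `cgi`, `polycomb` columns), `cgi`, `ctcf` (stranded,
#'       scored, with latent `occupancy`), `oct4`, `enhancers` (with
#'       `n_motifs`), `tad` (boundary positions).}
#'   }
#' @examples
#' g <- simulate_genome(sim_config(seed = 1, n_chromosomes = 1,
#'                                 chrom_length = 2e5, n_genes = 10,
#'                                 n_enhancers = 5, n_ctcf_sites = 5))
#' names(g$annotations)
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(sim_stream_seed(config, "genome"))
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(L, config$n_chromosomes), chroms)

  min_slot <- 5000
  n_elem <- config$n_genes + config$n_enhancers + config$n_ctcf_sites
  per_chrom <- ceiling(n_elem / config$n_chromosomes)
  if (per_chrom > 0 && L / per_chrom < min_slot)
    stop("element count infeasible for chromosome length: ", per_chrom,
         " elements on ", L, " bp needs < ", min_slot, " bp per slot")

  # round-robin element type assignment, then a deterministic shuffle
  types <- c(rep("gene", config$n_genes),
             rep("enhancer", config$n_enhancers),
             rep("ctcf", config$n_ctcf_sites))
  types <- if (n_elem > 0) sample(types) else character(0)
  elem_chrom <- if (n_elem > 0) chroms[(seq_len(n_elem) - 1L) %% config$n_chromosomes + 1L] else character(0)

  tss <- cgi <- ctcf <- oct4 <- enh <- NULL
  gene_i <- enh_i <- ctcf_i <- 0L
  for (ch in chroms) {
    idx <- which(elem_chrom == ch)
    n_ch <- length(idx)
    if (n_ch == 0) next
    slot <- floor(L / n_ch)
    centers <- round((seq_len(n_ch) - 0.5) * slot +
                       stats::runif(n_ch, -slot / 8, slot / 8))
    for (k in seq_len(n_ch)) {
      type <- types[idx[k]]
      pos <- centers[k]
      if (type == "gene") {
        gene_i <- gene_i + 1L
        strand <- sample(c("+", "-"), 1L)
        is_cgi <- stats::runif(1) < config$frac_cgi_promoters
        is_pc <- is_cgi && stats::runif(1) < config$frac_polycomb_cgi
        tss <- rbind(tss, data.frame(
          chrom = ch, pos = pos, strand = strand,
          gene = paste0("gene_", gene_i), cgi = is_cgi, polycomb = is_pc,
          stringsAsFactors = FALSE))
        if (is_cgi) {
          cgi <- rbind(cgi, data.frame(
            chrom = ch, start = pos - 500, end = pos + 500,
            name = paste0("cgi_", gene_i), stringsAsFactors = FALSE))
        }
      } else if (type == "enhancer") {
        enh_i <- enh_i + 1L
        width <- 600
        dual <- stats::runif(1) < config$frac_dual_oct4
        if (dual) {
          gap <- round(stats::runif(1, 100, 250))
          mids <- c(pos - floor(gap / 2), pos + ceiling(gap / 2))
        } else {
          mids <- pos
        }
        oct4 <- rbind(oct4, data.frame(
          chrom = ch, start = mids - 4, end = mids + 4,
          name = paste0("oct4_", enh_i, "_", seq_along(mids)),
          stringsAsFactors = FALSE))
        enh <- rbind(enh, data.frame(
          chrom = ch, start = pos - width / 2, end = pos + width / 2,
          name = paste0("enh_", enh_i), n_motifs = length(mids),
          stringsAsFactors = FALSE))
      } else {
        ctcf_i <- ctcf_i + 1L
        occ <- stats::runif(1, 0.15, 1)
        strand <- sample(c("+", "-"), 1L)
        ctcf <- rbind(ctcf, data.frame(
          chrom = ch, start = pos - 9, end = pos + 10,
          name = paste0("ctcf_", ctcf_i), score = round(1000 * occ),
          strand = strand, occupancy = occ, stringsAsFactors = FALSE))
      }
    }
  }
  empty <- function(...) {
    cols <- list(...)
    structure(lapply(cols, function(cl) vector(cl, 0L)), names = names(cols),
              class = "data.frame", row.names = integer(0))
  }
  if (is.null(tss))
    tss <- empty(chrom = "character", pos = "numeric", strand = "character",
                 gene = "character", cgi = "logical", polycomb = "logical")
  if (is.null(cgi))
    cgi <- empty(chrom = "character", start = "numeric", end = "numeric",
                 name = "character")
  if (is.null(ctcf))
    ctcf <- empty(chrom = "character", start = "numeric", end = "numeric",
                  name = "character", score = "numeric", strand = "character",
                  occupancy = "numeric")
  if (is.null(oct4))
    oct4 <- empty(chrom = "character", start = "numeric", end = "numeric",
                  name = "character")
  if (is.null(enh))
    enh <- empty(chrom = "character", start = "numeric", end = "numeric",
                 name = "character", n_motifs = "numeric")

  tad <- do.call(rbind, lapply(chroms, function(ch) {
    n <- config$n_tad_boundaries
    if (n == 0) return(NULL)
    pos <- round(seq_len(n) * L / (n + 1) + stats::runif(n, -2000, 2000))
    data.frame(chrom = ch, pos = pmax(0, pmin(L - 1, pos)),
               name = paste0(ch, "_tad_", seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tad))
    tad <- empty(chrom = "character", pos = "numeric", name = "character")

  genome <- generate_sequences(chrom_sizes, cgi, config)
  list(genome = genome, chrom_sizes = chrom_sizes,
       annotations = list(tss = tss, cgi = cgi, ctcf = ctcf, oct4 = oct4,
                          enhancers = enh, tad = tad))
}

# Random sequence at background G/C; CGI intervals rewritten G/C-rich.
generate_sequences <- function(chrom_sizes, cgi, config) {
  base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                               G = gc / 2, T = (1 - gc) / 2)
  bg <- base_probs(config$gc_background)
  cg <- base_probs(config$gc_cgi)
  seqs <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]]
    s <- sample(names(bg), n, replace = TRUE, prob = bg)
    ci <- cgi[cgi$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ci))) {
      a <- max(0, ci$start[i]) + 1L           # 1-based index into s
      b <- min(n, ci$end[i])
      if (b >= a)
        s[a:b] <- sample(names(cg), b - a + 1L, replace = TRUE, prob = cg)
    }
    paste(s, collapse = "")
  })
  Biostrings::DNAStringSet(stats::setNames(unlist(seqs), names(chrom_sizes)))
}
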