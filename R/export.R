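#' Write annotation tables as BED
#'
#' BED6 for stranded/scored sets (TSS, CTCF motifs), BED4 otherwise.
#' Single-base features (TSS, TAD boundaries) are written as 1 bp
#' intervals.
#'
#' @param annotations the `$annotations` list from [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_annotation_beds <- function(annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
  }
  a <- annotations
  bed(data.frame(a$tss$chrom, fmt_coord(a$tss$pos), fmt_coord(a$tss$pos + 1),
                 a$tss$gene, ifelse(a$tss$cgi, 1, 0), a$tss$strand),
      file.path(dir, "tss.bed"))
  bed(data.frame(a$cgi$chrom, fmt_coord(a$cgi$start), fmt_coord(a$cgi$end),
                 a$cgi$name),
      file.path(dir, "cgi.bed"))
  bed(data.frame(a$ctcf$chrom, fmt_coord(a$ctcf$start),
                 fmt_coord(a$ctcf$end), a$ctcf$name, a$ctcf$score,
                 a$ctcf$strand),
      file.path(dir, "ctcf_motifs.bed"))
  bed(data.frame(a$oct4$chrom, fmt_coord(a$oct4$start),
                 fmt_coord(a$oct4$end), a$oct4$name),
      file.path(dir, "oct4_motifs.bed"))
  bed(data.frame(a$enhancers$chrom, fmt_coord(a$enhancers$start),
                 fmt_coord(a$enhancers$end), a$enhancers$name,
                 a$enhancers$n_motifs),
      file.path(dir, "enhancers.bed"))
  bed(data.frame(a$tad$chrom, fmt_coord(a$tad$pos), fmt_coord(a$tad$pos + 1),
                 a$tad$name),
      file.path(dir, "tad_boundaries.bed"))
  invisible(dir)
}

#' Write a full simulation to disk
#'
#' Reference FASTA, annotation BEDs, ground-truth TSVs and one BEDPE per
#' fragment library. Running this twice with the same configuration
#' produces byte-identical files.
#'
#' @param sim a [simulate_chromatin()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome$genome,
                              file.path(dir, "genome.fa"))
  write_annotation_beds(sim$genome$annotations, dir)
  write_truth(sim$truth, file.path(dir, "truth"))
  for (nm in names(sim$libraries))
    write_fragments(sim$libraries[[nm]],
                    file.path(dir, paste0(nm, ".bedpe")), format = "bedpe")
  invisible(dir)
}
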