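# Shared fixtures, built in code once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_cfg <- function(seed = 5L, ...) {
  args <- list(seed = seed, n_chromosomes = 1, chrom_length = 2e5,
               n_genes = 15, n_enhancers = 6, n_ctcf_sites = 10,
               n_tad_boundaries = 3, library_depth = 2e4,
               spike_in_counts = c(H3K115ac = 500, H3K27ac = 500,
                                   unmodified = 500))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# moderate-scale simulation shared across module tests
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- sim_config(seed = 11L, n_chromosomes = 2, chrom_length = 3e5,
                      n_genes = 40, n_enhancers = 16, n_ctcf_sites = 40,
                      n_tad_boundaries = 4, library_depth = 2e5)
    list(cfg = cfg, sim = simulate_chromatin(cfg))
  })
}

tss_anchors_of <- function(sim) {
  tss <- sim$genome$annotations$tss
  anchor_set(tss$chrom, tss$pos, ifelse(tss$strand == "+", 1L, -1L),
             tss$gene)
}

# hand-built base-resolution track from a list of numeric vectors
toy_track <- function(values, n_fragments = NA_real_) {
  structure(list(values = values, bin_size = 1, scale_factor = 1,
                 n_fragments = n_fragments, metadata = list()),
            class = "coverage_track")
}

# ---- independent oracles -------------------------------------------------

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact Wilcoxon rank-sum p by enumeration of all rank splits
wilcox_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided exact binomial p by direct enumeration of the density
binom_oracle <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}
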