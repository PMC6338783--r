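# shared fixture builders and independent brute-force oracles

# GRanges from 0-based half-open coordinates (BED frame)
gr0 <- function(chrom, start0, end0, name = NULL, class = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0))
  if (!is.null(name)) gr$name <- name
  if (!is.null(class)) gr$element_class <- class
  gr
}

# random intervals on a single toy chromosome
random_intervals <- function(n, chrom_len, max_width = 200,
                             chrom = "chrT") {
  s <- sample.int(chrom_len - max_width, n)
  w <- sample.int(max_width, n)
  gr0(chrom, s, pmin(s + w, chrom_len))
}

# per-base membership oracle: total shared positions of two interval sets
brute_overlap <- function(a, b, chrom_len) {
  mask <- function(gr) {
    v <- logical(chrom_len)
    for (i in seq_along(gr)) {
      v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
    }
    v
  }
  sum(mask(a) & mask(b))
}

brute_total_length <- function(a, chrom_len) {
  brute_overlap(a, a, chrom_len)
}

# exhaustive signed-rank null: two-sided p by full sign enumeration
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wd <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(wd <= W), mean(wd >= W)))
}

# a tiny paired methylome pair over given 0-based CpG positions
toy_methylome <- function(pos, beta, coverage = 30L, id = "S1",
                          condition = "tumor", chrom = "chrT") {
  cpg_methylome(rep(chrom, length(pos)), pos, beta,
                rep(coverage, length.out = length(pos)),
                sample_id = id, condition = condition)
}
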