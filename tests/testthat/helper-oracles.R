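# Brute-force oracles and small fixture builders. The oracles deliberately
# share no code with the implementation paths they check.

make_ps <- function(chrom, start, end, name = "ps") {
  peak_set(data.frame(chrom = chrom, start = start, end = end), name = name)
}

# random non-degenerate peak set (duplicates possible and intended)
random_ps <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                      max_len = 200, name = "rand") {
  start <- sample.int(max_pos, n, replace = TRUE)
  make_ps(sample(chroms, n, replace = TRUE), start,
          start + sample.int(max_len, n, replace = TRUE), name = name)
}

# O(n*m) double loop: does row i of a share >= min_ov bases with any b row?
oracle_overlap_flags <- function(a_iv, b_iv, min_ov = 1) {
  vapply(seq_len(nrow(a_iv)), function(i) {
    any(vapply(seq_len(nrow(b_iv)), function(j) {
      a_iv$chrom[i] == b_iv$chrom[j] &&
        min(a_iv$end[i], b_iv$end[j]) -
          max(a_iv$start[i], b_iv$start[j]) >= min_ov
    }, TRUE))
  }, TRUE)
}

# percentage matrix by brute force (unique intervals, row denominator)
oracle_overlap_matrix <- function(sets, min_ov = 1) {
  uiv <- lapply(sets, function(s)
    s$intervals[!duplicated(s$intervals[, 1:3]), , drop = FALSE])
  n <- length(sets)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- 100 * sum(oracle_overlap_flags(uiv[[i]], uiv[[j]], min_ov)) /
      nrow(uiv[[i]])
  m
}

# hypergeometric upper tail by term summation with choose()
oracle_hyper_tail <- function(k, size_a, size_b, n) {
  ks <- k:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(n - size_a, size_b - ks)) /
    choose(n, size_b)
}

# binomial upper tail by term summation
oracle_binom_tail <- function(k, n, f) {
  sum(choose(n, k:n) * f^(k:n) * (1 - f)^(n - (k:n)))
}

# literal BH step-up applied right to left
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# linear-scan nearest TSS with the lexicographic tie rule
oracle_closest <- function(mid, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  d <- abs(mid - g$tss)
  hit <- which(d == min(d))
  hit <- hit[order(g$gene_id[hit])][1L]
  list(gene_id = g$gene_id[hit], distance = d[hit])
}

# small survival dataset with continuous (untied) times
random_surv <- function(n, beta = 0, censor = 0.2) {
  x <- stats::rbinom(n, 1, 0.5)
  tm <- stats::rexp(n, 0.05 * exp(beta * x))
  cens <- stats::runif(n) < censor
  tm[cens] <- stats::runif(sum(cens)) * tm[cens]
  survival_records(sprintf("s%03d", seq_len(n)), tm, !cens,
                   covariates = data.frame(x = x))
}
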