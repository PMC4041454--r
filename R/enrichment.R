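# ---- GenomeSpec --------------------------------------------------------

#' Define a genome as a set of chromosome lengths
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @return a \code{GenomeSpec}.
#' @export
genome_spec <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  structure(list(chrom_lengths = chrom_lengths), class = "GenomeSpec")
}

.check_in_genome <- function(ps, genome) {
  iv <- ps$intervals
  missing <- setdiff(unique(iv$chrom), names(genome$chrom_lengths))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  len <- genome$chrom_lengths[iv$chrom]
  if (any(iv$end > len))
    stop("interval exceeding chromosome length in set '", ps$name, "'")
  invisible(TRUE)
}

.enrich_result <- function(method, observed, expected, statistic, p_value,
                           n_perm = NA_integer_, seed = NA_integer_,
                           universe = "") {
  structure(list(method = method, observed = observed, expected = expected,
                 statistic = statistic, p_value = p_value, n_perm = n_perm,
                 seed = seed, universe_descriptor = universe),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult [", x$method, "] observed=", x$observed,
      " expected=", signif(x$expected, 4), " p=", signif(x$p_value, 4),
      if (!is.na(x$n_perm)) paste0(" (n_perm=", x$n_perm, ")"), "\n", sep = "")
  invisible(x)
}

# ---- hypergeometric ----------------------------------------------------

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= overlap_k) where X counts successes among \code{size_b} draws
#' without replacement from a universe of \code{universe_n} items of which
#' \code{size_a} are successes. Expected overlap is
#' \code{size_a * size_b / universe_n}.
#'
#' @param overlap_k observed overlap count.
#' @param size_a,size_b set sizes.
#' @param universe_n universe size.
#' @return an \code{EnrichmentResult}.
#' @export
hypergeometric_tail <- function(overlap_k, size_a, size_b, universe_n) {
  if (overlap_k < 0) stop("violated bound: overlap_k >= 0")
  if (overlap_k > min(size_a, size_b))
    stop("violated bound: overlap_k <= min(size_a, size_b)")
  if (size_a > universe_n) stop("violated bound: size_a <= universe_n")
  if (size_b > universe_n) stop("violated bound: size_b <= universe_n")
  p <- stats::phyper(overlap_k - 1, size_a, universe_n - size_a, size_b,
                     lower.tail = FALSE)
  .enrich_result("hypergeometric", observed = overlap_k,
                 expected = size_a * size_b / universe_n,
                 statistic = overlap_k, p_value = min(1, p),
                 universe = paste0("n=", universe_n))
}

# ---- BH FDR ------------------------------------------------------------

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Adjusted value for the i-th smallest p is
#' \code{min over j >= i of (m/j) p_(j)}, capped at 1; input order restored.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- permutation proximity test ---------------------------------------

# count of a-intervals overlapping (>=1 bp) the merged b intervals,
# vectorised for use inside the permutation loop
.count_overlapping <- function(as_, ae_, chrom, b_by_chrom) {
  total <- 0L
  for (ch in names(b_by_chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    b <- b_by_chrom[[ch]]
    j <- findInterval(ae_[sel] - 1, b$start)
    ok <- j >= 1L
    ok[ok] <- b$cme[j[ok]] > as_[sel][ok]
    total <- total + sum(ok)
  }
  total
}

#' Permutation test for peak-set proximity/overlap
#'
#' The statistic is the number of \code{a} intervals overlapping \code{b}
#' (>= 1 bp). The null redistributes each \code{a} interval uniformly at
#' random on its own chromosome with its length preserved (independent
#' placement), \code{n_perm} times. The p-value uses the add-one estimator
#' \code{(1 + #(null >= observed)) / (1 + n_perm)}, so it is never 0 and
#' never below \code{1/(n_perm + 1)}.
#'
#' @param a,b \code{PeakSet}s.
#' @param genome a \code{GenomeSpec} covering all chromosomes present.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed, recorded in the result.
#' @return an \code{EnrichmentResult} with method \code{"permutation"}.
#' @export
permutation_proximity_test <- function(a, b, genome, n_perm = 1000L,
                                       seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  .check_in_genome(a, genome); .check_in_genome(b, genome)
  bm <- merge_intervals(b)$intervals
  b_by_chrom <- lapply(split(bm, bm$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    list(start = d$start, cme = cummax(d$end))
  })
  iv <- a$intervals
  obs <- .count_overlapping(iv$start, iv$end, iv$chrom, b_by_chrom)
  lens <- iv$end - iv$start
  chrom_len <- genome$chrom_lengths[iv$chrom]
  null_stats <- integer(n_perm)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (r in seq_len(n_perm)) {
    st <- floor(stats::runif(length(lens)) * (chrom_len - lens + 1))
    null_stats[r] <- .count_overlapping(st, st + lens, iv$chrom, b_by_chrom)
  }
  p <- (1 + sum(null_stats >= obs)) / (1 + n_perm)
  .enrich_result("permutation", observed = obs,
                 expected = mean(null_stats), statistic = obs, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 universe = "uniform per-chromosome placement, lengths preserved")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- region binomial test ---------------------------------------------

#' Region-fraction binomial enrichment test
#'
#' With \code{f} the fraction of the genome covered by the (merged)
#' domains, and \code{k} the number of peaks whose midpoint falls inside a
#' domain, p = P(X >= k | n = number of peaks, f) — the region-based
#' binomial enrichment in the style of annotation-region tools.
#'
#' @param peaks \code{PeakSet} (non-empty).
#' @param domains \code{PeakSet} of target regions (merged before use).
#' @param genome a \code{GenomeSpec}.
#' @return an \code{EnrichmentResult} with method \code{"binomial"}.
#' @export
region_binomial_test <- function(peaks, domains, genome) {
  if (length(peaks) == 0L) stop("empty peak set")
  .check_in_genome(peaks, genome); .check_in_genome(domains, genome)
  dm <- merge_intervals(domains)$intervals
  f <- sum(dm$end - dm$start) / sum(genome$chrom_lengths)
  iv <- peaks$intervals
  mid <- floor((iv$start + iv$end) / 2)
  pt <- peak_set(data.frame(chrom = iv$chrom, start = mid, end = mid + 1))
  k <- sum(.overlap_flags(pt$intervals, dm, 1))
  n <- nrow(iv)
  if (f == 0 && k > 0) stop("impossible state: zero domain coverage with hits")
  p <- if (f >= 1) 1 else stats::pbinom(k - 1, n, f, lower.tail = FALSE)
  .enrich_result("binomial", observed = k, expected = n * f,
                 statistic = k, p_value = min(1, p),
                 universe = sprintf("domain fraction f=%.6g of %d bp",
                                    f, sum(genome$chrom_lengths)))
}

# ---- gene-set hypergeometric ------------------------------------------

#' Gene-set overrepresentation by hypergeometric tail
#'
#' Tests whether a query gene set is enriched for a signature within a
#' stated universe; the signature is first intersected with the universe.
#'
#' @param query character vector of gene ids (must lie in \code{universe}).
#' @param signature character vector of gene ids.
#' @param universe character vector of gene ids.
#' @return an \code{EnrichmentResult}.
#' @export
geneset_hypergeometric <- function(query, signature, universe) {
  query <- unique(query); signature <- unique(signature)
  universe <- unique(universe)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query ids outside universe: ",
         paste(utils::head(out, 5), collapse = ", "),
         if (length(out) > 5) " ...")
  sig <- intersect(signature, universe)
  k <- length(intersect(query, sig))
  res <- hypergeometric_tail(k, length(sig), length(query), length(universe))
  res$method <- "geneset_hypergeometric"
  res$universe_descriptor <- paste0("genes n=", length(universe))
  res
}
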