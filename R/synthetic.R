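# ---- SyntheticSpec -----------------------------------------------------

#' Specification for the synthetic-data generators
#'
#' Defaults state the simulated world once: a 2 x 50 Mb genome carrying
#' 2000 non-overlapping 10 kb genes; 2000 peaks of 200-400 bp per set with
#' promoter bias 0.8 (the promoter-enriched profile) and planted pairwise
#' overlap 0.88 (the concordant-cistrome magnitude); expression contrasts
#' with log2 effect 2.0 on 5% of genes, noise sd 0.5 and 3 replicates per
#' arm (triplicate arrays); survival with hazard ratio 3 tied to a score
#' step at 0.6 and 20% censoring. A master seed deterministically derives
#' per-generator child seeds so partial reruns are stable.
#'
#' @param seed master seed.
#' @param genome a \code{GenomeSpec}.
#' @param n_genes,gene_length,n_peaks,peak_length_range generator sizes.
#' @param promoter_bias probability a peak is placed within 5 kb of a TSS.
#' @param overlap_fraction planted pairwise peak overlap fraction.
#' @param de_effect,de_frac,noise_sd,n_reps expression parameters.
#' @param hr,censor_frac,step_at survival parameters.
#' @return a \code{SyntheticSpec} list.
#' @export
synthetic_spec <- function(seed = 1L,
                           genome = genome_spec(c(chr1 = 5e7, chr2 = 5e7)),
                           n_genes = 2000L, gene_length = 1e4,
                           n_peaks = 2000L,
                           peak_length_range = c(200, 400),
                           promoter_bias = 0.8,
                           overlap_fraction = 0.88,
                           de_effect = 2.0, de_frac = 0.05,
                           noise_sd = 0.5, n_reps = 3L,
                           hr = 3, censor_frac = 0.2, step_at = 0.6) {
  stopifnot(promoter_bias >= 0, promoter_bias <= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            hr > 0, n_genes >= 1, n_peaks >= 1, censor_frac < 1,
            de_frac >= 0, de_frac <= 1)
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = as.integer(n_genes), gene_length = gene_length,
                 n_peaks = as.integer(n_peaks),
                 peak_length_range = peak_length_range,
                 promoter_bias = promoter_bias,
                 overlap_fraction = overlap_fraction,
                 de_effect = de_effect, de_frac = de_frac,
                 noise_sd = noise_sd, n_reps = as.integer(n_reps),
                 hr = hr, censor_frac = censor_frac, step_at = step_at),
            class = "SyntheticSpec")
}

# child seed derivation: deterministic, stays below 2^31
.child_seed <- function(seed, stage) {
  offs <- c(genome = 101L, peaks = 211L, overlap = 307L,
            expression = 401L, survival = 503L)
  (as.integer(seed) * 7919L + offs[[stage]]) %% 2147483647L
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

# ---- genome + genes ----------------------------------------------------

#' Generate a genome annotation with non-overlapping genes
#'
#' Genes of fixed length are placed uniformly without span overlap,
#' chromosomes receiving gene counts proportional to their lengths;
#' strands are Bernoulli(0.5). Deterministic given the spec seed.
#'
#' @param spec a \code{SyntheticSpec}.
#' @return list(genome = GenomeSpec, genes = gene-model data.frame).
#' @export
gen_genome <- function(spec) {
  glen <- spec$gene_length
  lens <- spec$genome$chrom_lengths
  n_by_chrom <- round(spec$n_genes * lens / sum(lens))
  n_by_chrom[1L] <- spec$n_genes - sum(n_by_chrom[-1L])
  if (any(n_by_chrom * glen > lens))
    stop("genome too small to place ", spec$n_genes, " genes of ", glen, " bp")
  .with_seed(.child_seed(spec$seed, "genome"), {
    rows <- lapply(seq_along(lens), function(ci) {
      n <- n_by_chrom[ci]
      if (n == 0L) return(NULL)
      # uniform non-overlapping placement: spread n gene slots over the
      # free space, then add cumulative gene-length offsets
      free <- lens[ci] - n * glen
      starts <- sort(floor(stats::runif(n, 0, free + 1))) +
        (seq_len(n) - 1L) * glen
      data.frame(gene_id = sprintf("g%s_%04d", names(lens)[ci], seq_len(n)),
                 chrom = names(lens)[ci],
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 start = starts, end = starts + glen,
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    list(genome = spec$genome,
         genes = gene_models(ann$gene_id, ann$chrom, ann$strand,
                             ann$start, ann$end))
  })
}

# ---- peak sets ---------------------------------------------------------

#' Generate a peak set with a planted promoter bias
#'
#' With probability \code{promoter_bias} a peak midpoint is drawn within
#' 5 kb of a randomly chosen TSS; otherwise uniformly on the genome.
#' Lengths are uniform in \code{peak_length_range}.
#'
#' @param genome a \code{GenomeSpec}; \code{genes} a gene-model table.
#' @param genes gene-model data.frame.
#' @param spec a \code{SyntheticSpec}.
#' @param name set label.
#' @param seed override seed (default: child of the spec seed).
#' @return a \code{PeakSet}.
#' @export
gen_peakset <- function(genome, genes, spec, name = "synthetic",
                        seed = .child_seed(spec$seed, "peaks")) {
  lens <- genome$chrom_lengths
  .with_seed(seed, {
    n <- spec$n_peaks
    plen <- floor(stats::runif(n, spec$peak_length_range[1],
                               spec$peak_length_range[2] + 1))
    promo <- stats::runif(n) < spec$promoter_bias
    mid <- numeric(n); chrom <- character(n)
    if (any(promo)) {
      gi <- sample(nrow(genes), sum(promo), replace = TRUE)
      chrom[promo] <- genes$chrom[gi]
      off <- floor(stats::runif(sum(promo), -5000, 5000))
      mid[promo] <- pmin(pmax(genes$tss[gi] + off, 0),
                         lens[chrom[promo]] - 1)
    }
    if (any(!promo)) {
      ci <- sample(names(lens), sum(!promo), replace = TRUE,
                   prob = lens / sum(lens))
      chrom[!promo] <- ci
      mid[!promo] <- floor(stats::runif(sum(!promo), 0, lens[ci]))
    }
    start <- pmax(floor(mid - plen / 2), 0)
    end <- pmin(start + plen, lens[chrom])
    peak_set(data.frame(chrom = chrom, start = start, end = end),
             name = name, source = "synthetic")
  })
}

#' Generate a peak set with a planted overlap fraction against a base set
#'
#' A fraction \code{f} of the new peaks is centred inside a randomly
#' chosen base peak (guaranteeing >= 1 shared bp); the remainder are
#' placed uniformly, rejecting positions that touch any base peak.
#'
#' @param base a \code{PeakSet}.
#' @param f planted overlap fraction in [0, 1].
#' @param genome a \code{GenomeSpec}.
#' @param spec a \code{SyntheticSpec} (peak count and lengths).
#' @param seed RNG seed.
#' @param name label of the new set.
#' @return a \code{PeakSet}; attribute \code{planted_f} records f.
#' @export
gen_overlapping_peakset <- function(base, f, genome, spec,
                                    seed = .child_seed(spec$seed, "overlap"),
                                    name = "overlapping") {
  stopifnot(f >= 0, f <= 1)
  lens <- genome$chrom_lengths
  bm <- merge_intervals(base)$intervals
  b_by_chrom <- lapply(split(bm, bm$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    list(start = d$start, cme = cummax(d$end))
  })
  .with_seed(seed, {
    n <- spec$n_peaks
    plen <- floor(stats::runif(n, spec$peak_length_range[1],
                               spec$peak_length_range[2] + 1))
    hit <- stats::runif(n) < f
    chrom <- character(n); start <- numeric(n)
    if (any(hit)) {
      bi <- sample(nrow(base$intervals), sum(hit), replace = TRUE)
      biv <- base$intervals[bi, , drop = FALSE]
      # centre the new peak on a uniform point inside the base interval
      anchor <- floor(stats::runif(sum(hit), biv$start, biv$end))
      chrom[hit] <- biv$chrom
      start[hit] <- pmax(floor(anchor - plen[hit] / 2), 0)
      start[hit] <- pmin(start[hit], lens[biv$chrom] - plen[hit])
    }
    if (any(!hit)) {
      need <- which(!hit)
      tries <- 0L
      while (length(need) && tries < 200L) {
        tries <- tries + 1L
        ci <- sample(names(lens), length(need), replace = TRUE,
                     prob = lens / sum(lens))
        st <- floor(stats::runif(length(need), 0, lens[ci] - plen[need] + 1))
        cand <- data.frame(chrom = ci, start = st, end = st + plen[need])
        bad <- .overlap_flags(cand, bm, 1)
        ok <- which(!bad)
        chrom[need[ok]] <- ci[ok]; start[need[ok]] <- st[ok]
        need <- need[bad]
      }
      if (length(need))
        stop("could not place ", length(need),
             " non-overlapping peaks: genome too crowded for f = ", f)
    }
    out <- peak_set(data.frame(chrom = chrom, start = start,
                               end = start + plen),
                    name = name, source = sprintf("synthetic f=%g", f))
    attr(out, "planted_f") <- f
    out
  })
}

# ---- expression --------------------------------------------------------

#' Generate an expression matrix with planted concordant OE/KD effects
#'
#' Per-gene baselines are Normal(8, 1); a planted fraction of genes gains
#' \code{+de_effect} log2 units in the OE arm and \code{-de_effect} in the
#' KD arm; iid Normal(0, noise_sd) noise is added everywhere. The planted
#' gene ids are recorded in attribute \code{planted}.
#'
#' @param genes gene-model data.frame (row per gene).
#' @param spec a \code{SyntheticSpec}.
#' @param seed RNG seed.
#' @param planted_ids optionally force the planted gene set.
#' @return an \code{ExpressionMatrix} with groups control/OE/KD.
#' @export
gen_expression <- function(genes, spec,
                           seed = .child_seed(spec$seed, "expression"),
                           planted_ids = NULL) {
  n_genes <- nrow(genes)
  n_planted <- if (is.null(planted_ids)) round(spec$de_frac * n_genes) else
    length(planted_ids)
  if (n_planted < 1 && spec$de_frac > 0)
    stop("de_frac * n_genes < 1: no gene to plant")
  if (spec$n_reps < 2L) stop("need >= 2 replicates per arm")
  .with_seed(seed, {
    if (is.null(planted_ids))
      planted_ids <- sort(sample(genes$gene_id, n_planted))
    arms <- c("control", "OE", "KD")
    samples <- paste0(rep(arms, each = spec$n_reps), "_",
                      rep(seq_len(spec$n_reps), times = 3))
    base <- stats::rnorm(n_genes, 8, 1)
    vals <- matrix(base, n_genes, length(samples))
    rownames(vals) <- genes$gene_id; colnames(vals) <- samples
    grp <- stats::setNames(rep(arms, each = spec$n_reps), samples)
    pi <- rownames(vals) %in% planted_ids
    vals[pi, grp == "OE"] <- vals[pi, grp == "OE"] + spec$de_effect
    vals[pi, grp == "KD"] <- vals[pi, grp == "KD"] - spec$de_effect
    vals <- vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                          nrow(vals))
    m <- expression_matrix(vals, grp)
    attr(m, "planted") <- planted_ids
    m
  })
}

# ---- survival ----------------------------------------------------------

#' Generate survival records with a planted score-linked hazard ratio
#'
#' Scores are Uniform(0, 1). Event times are exponential with baseline
#' rate 0.02/month, multiplied by \code{hr} for subjects above the planted
#' step (\code{score_link = "step"}) or by \code{exp(log(hr) * score)}
#' (\code{"linear"}); \code{"none"} ignores the score. Censoring is
#' independent Uniform(0, m), with m solved numerically so that the
#' expected censored fraction equals \code{censor_frac}; a subject is
#' censored when its censoring time precedes its event time.
#'
#' @param n number of subjects (>= 10).
#' @param spec a \code{SyntheticSpec}.
#' @param score_link one of "none", "step", "linear".
#' @param seed RNG seed.
#' @return list(scores, records) with planted parameters as attributes.
#' @export
gen_survival <- function(n, spec, score_link = c("step", "linear", "none"),
                         seed = .child_seed(spec$seed, "survival")) {
  score_link <- match.arg(score_link)
  if (n < 10L) stop("n must be >= 10")
  if (spec$censor_frac >= 1) stop("censor_frac must be < 1")
  .with_seed(seed, {
    score <- stats::runif(n)
    rate <- 0.02 * switch(score_link,
                          none = rep(1, n),
                          step = ifelse(score > spec$step_at, spec$hr, 1),
                          linear = exp(log(spec$hr) * score))
    etime <- stats::rexp(n, rate)
    if (spec$censor_frac > 0) {
      # P(C < T) for C ~ U(0, m), T ~ Exp(rate): (1 - exp(-rate*m))/(rate*m)
      target <- function(m) mean((1 - exp(-rate * m)) / (rate * m)) -
        spec$censor_frac
      m <- stats::uniroot(target, c(1e-8, 1e8), tol = 1e-10)$root
      ctime <- stats::runif(n, 0, m)
    } else ctime <- rep(Inf, n)
    cens <- ctime < etime
    time <- pmax(pmin(etime, ctime), 1e-6)
    rec <- survival_records(sprintf("s%04d", seq_len(n)), time, !cens,
                            covariates = data.frame(score = score))
    out <- list(scores = stats::setNames(score, rec$subject_id),
                records = rec)
    attr(out, "hr") <- spec$hr
    attr(out, "step_at") <- spec$step_at
    out
  })
}
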