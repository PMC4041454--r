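# ---- binding x expression integration ---------------------------------

#' Fraction of a core gene set bound within a window
#'
#' A gene counts as bound when some peak-gene assignment places a peak
#' midpoint strictly closer than \code{window} bp to its TSS. The
#' assignments must have been produced at a window at least as wide as the
#' query window.
#'
#' @param assignments output of \code{\link{assign_peaks_to_genes}}.
#' @param core a \code{GeneSet} (non-empty).
#' @param window query window in bp (strict inequality).
#' @return list(records = per-gene data.frame with gene_id, bound,
#'   min_distance; fraction_bound; n_bound; n_core).
#' @export
integrate_binding_expression <- function(assignments, core, window) {
  if (length(core$gene_ids) == 0L) stop("empty core gene set")
  if (nrow(assignments) > 0 && window > assignments$window[1L])
    stop("assignments were made at window ", assignments$window[1L],
         " < query window ", window)
  sub <- assignments[assignments$gene_id %in% core$gene_ids, , drop = FALSE]
  mind <- if (nrow(sub)) tapply(sub$distance, sub$gene_id, min) else
    numeric(0)
  recs <- data.frame(gene_id = core$gene_ids,
                     min_distance = as.numeric(mind[core$gene_ids]),
                     stringsAsFactors = FALSE)
  recs$bound <- !is.na(recs$min_distance) & recs$min_distance < window
  n_bound <- sum(recs$bound)
  list(records = recs, fraction_bound = n_bound / nrow(recs),
       n_bound = n_bound, n_core = nrow(recs))
}

#' Check a gene panel for direct regulation
#'
#' A panel gene is "regulated" iff a peak lies strictly within
#' \code{window} bp of its TSS AND its differential expression is
#' concordant: up in OE-vs-control and down in KD-vs-control at the
#' (integrative) adjusted-p threshold. \code{rule = "either"} relaxes
#' concordance to significance at the threshold in either contrast in any
#' direction.
#'
#' @param panel a \code{GeneSet} (non-empty); members missing from the DE
#'   universe are reported, not fatal.
#' @param assignments peak-gene assignments at window >= \code{window}.
#' @param de_oe,de_kd DE tables (OE-vs-control, KD-vs-control).
#' @param window bp, default 25000.
#' @param threshold adjusted-p cut, default 0.1 (integrative threshold).
#' @param rule "concordant" (default) or "either".
#' @return list(per_gene data.frame, n_regulated, n_panel, missing ids).
#' @export
panel_regulation_check <- function(panel, assignments, de_oe, de_kd,
                                   window = 25000, threshold = 0.1,
                                   rule = c("concordant", "either")) {
  rule <- match.arg(rule)
  if (length(panel$gene_ids) == 0L) stop("empty panel")
  missing <- setdiff(panel$gene_ids, de_oe$gene_id)
  if (length(missing))
    warning(length(missing), " panel gene(s) absent from the DE universe: ",
            paste(missing, collapse = ", "))
  ib <- integrate_binding_expression(assignments,
                                     gene_set("panel", panel$gene_ids),
                                     window)
  bound <- stats::setNames(ib$records$bound, ib$records$gene_id)
  oe <- de_oe[match(panel$gene_ids, de_oe$gene_id), , drop = FALSE]
  kd <- de_kd[match(panel$gene_ids, de_kd$gene_id), , drop = FALSE]
  conc <- if (rule == "concordant") {
    (oe$adj_p < threshold & oe$log_fc > 0) &
      (kd$adj_p < threshold & kd$log_fc < 0)
  } else {
    (oe$adj_p < threshold) | (kd$adj_p < threshold)
  }
  conc[is.na(conc)] <- FALSE
  per_gene <- data.frame(gene_id = panel$gene_ids,
                         bound_lt_window = unname(bound[panel$gene_ids]),
                         de_concordant = conc,
                         stringsAsFactors = FALSE)
  per_gene$regulated <- per_gene$bound_lt_window & per_gene$de_concordant
  list(per_gene = per_gene,
       n_regulated = sum(per_gene$regulated),
       n_panel = nrow(per_gene),
       window = window, threshold = threshold, missing = missing)
}

# ---- concordance report ------------------------------------------------

#' Multi-set cistrome concordance report
#'
#' For every ordered pair of peak sets: direct-overlap counts and
#' percentages (row-set denominator), hypergeometric p (universe = merged
#' union of all sets, overridable) and a seeded permutation p; per set, a
#' TSS-distance profile; per pair and window, the number of shared closest
#' genes. All components are returned in one bundle and optionally
#' serialized to a directory.
#'
#' @param peak_sets list of >= 2 \code{PeakSet}s.
#' @param genes gene-model data.frame.
#' @param genome a \code{GenomeSpec}.
#' @param windows bp windows for gene-level overlap.
#' @param n_perm permutations for the proximity test.
#' @param seed RNG seed.
#' @param universe_n override for the hypergeometric universe size.
#' @param out_dir if non-NULL, write TSVs and a JSON manifest there.
#' @return list(overlap_matrix, pairwise data.frame, profiles,
#'   gene_overlap data.frame, parameters).
#' @export
cistrome_concordance_report <- function(peak_sets, genes, genome,
                                        windows = c(5e3, 1e4, 2.5e4, 5e4),
                                        n_perm = 200L, seed = 1L,
                                        universe_n = NULL,
                                        out_dir = NULL) {
  if (length(peak_sets) < 2L) stop("need >= 2 peak sets")
  nm <- vapply(peak_sets, function(s) s$name, "")
  om <- pairwise_overlap_matrix(peak_sets)
  union_iv <- do.call(rbind, lapply(peak_sets, function(s) s$intervals))
  if (is.null(universe_n))
    universe_n <- length(merge_intervals(peak_set(union_iv, "union")))
  pairs <- which(upper.tri(matrix(0, length(nm), length(nm))) |
                   lower.tri(matrix(0, length(nm), length(nm))),
                 arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    k <- om$counts[i, j]
    hg <- hypergeometric_tail(min(k, min(om$sizes[i], om$sizes[j],
                                         universe_n)),
                              min(om$sizes[i], universe_n),
                              min(om$sizes[j], universe_n), universe_n)
    pp <- permutation_proximity_test(peak_sets[[i]], peak_sets[[j]],
                                     genome, n_perm = n_perm,
                                     seed = seed + i * 131L + j)
    data.frame(set_a = nm[i], set_b = nm[j], n_a = om$sizes[i],
               n_b = om$sizes[j], n_overlap = k,
               pct_of_a = om$values[i, j],
               p_hypergeometric = hg$p_value,
               p_permutation = pp$p_value, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  profiles <- lapply(peak_sets, function(s) distance_distribution(s, genes))
  names(profiles) <- nm
  cg <- lapply(peak_sets, function(s) closest_gene(s, genes))
  gene_rows <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    for (w in windows) {
      gi <- unique(cg[[i]]$gene_id[cg[[i]]$distance < w])
      gj <- unique(cg[[j]]$gene_id[cg[[j]]$distance < w])
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(set_a = nm[i], set_b = nm[j], window = w,
                   n_genes_a = length(gi), n_genes_b = length(gj),
                   n_shared = length(intersect(gi, gj)),
                   stringsAsFactors = FALSE)
    }
  }
  gene_overlap <- do.call(rbind, gene_rows)
  params <- list(windows = windows, n_perm = n_perm, seed = seed,
                 universe_n = universe_n)
  bundle <- list(overlap_matrix = om, pairwise = pairwise,
                 profiles = profiles, gene_overlap = gene_overlap,
                 parameters = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_overlap_matrix(om, file.path(out_dir, "overlap_matrix.tsv"))
    utils::write.table(pairwise, file.path(out_dir, "pairwise_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_overlap,
                       file.path(out_dir, "gene_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(parameters = params, profiles = profiles),
                         file.path(out_dir, "concordance_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
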