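# ---- ExpressionMatrix --------------------------------------------------

#' Construct an expression matrix with sample groups
#'
#' @param values numeric matrix of log2 intensities, genes x samples, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param groups named character vector mapping sample_id -> group label.
#' @return an \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values needs unique gene-id rownames")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values needs unique sample-id colnames")
  if (any(!is.finite(values))) stop("non-finite expression values")
  miss <- setdiff(colnames(values), names(groups))
  if (length(miss)) stop("samples without group label: ",
                         paste(miss, collapse = ", "))
  structure(list(values = values,
                 groups = groups[colnames(values)]),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (groups: ",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and sample-group table from TSV
#' @param expr_path genes x samples TSV, header row of sample ids, first
#'   column gene ids.
#' @param groups_path two-column TSV (sample_id, group).
#' @export
read_expression <- function(expr_path, groups_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  gd <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_matrix(values, stats::setNames(gd[[2]], gd[[1]]))
}

#' Write an expression matrix (and its groups) to TSV
#' @param m \code{ExpressionMatrix}; paths for the matrix and group table.
#' @param expr_path,groups_path output paths.
#' @export
write_expression <- function(m, expr_path, groups_path) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(m$groups), group = unname(m$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

# ---- quantile normalization -------------------------------------------

#' Quantile-normalize the columns of an expression matrix
#'
#' Each column's sorted values are replaced by the cross-column mean of
#' sorted values; tied values within a column receive the mean of their
#' candidate reference values (average ranks interpolate between adjacent
#' reference quantiles). Column distributions are identical afterwards and
#' the operation is idempotent.
#'
#' @param m an \code{ExpressionMatrix} or numeric matrix.
#' @return same type as the input.
#' @export
quantile_normalize <- function(m) {
  x <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  if (ncol(x) < 2L) stop("need >= 2 samples")
  if (any(!is.finite(x))) stop("non-finite values")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    new <- numeric(length(col))
    new[order(col)] <- ref
    # tied values receive the mean of the reference values they straddle
    stats::ave(new, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  if (inherits(m, "ExpressionMatrix")) {
    m$values <- out
    m
  } else out
}

# ---- differential expression ------------------------------------------

#' Two-group differential expression (moderated-t stand-in)
#'
#' Per-gene two-sample t-test of \code{group_b} minus \code{group_a} on
#' log2 values, with a fully specified variance stabilization that stands
#' in for empirical-Bayes moderation (it is NOT a reimplementation of it):
#' the per-gene pooled variance is shrunk toward the mean variance across
#' all genes with a FIXED prior weight of \code{prior_df} degrees of
#' freedom, the resulting sd is floored at the 10th percentile of all
#' moderated sds, and the statistic is referred to a t distribution on
#' residual + prior df. P-values are BH-adjusted across all genes.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param group_a,group_b group labels (log_fc = mean(b) - mean(a)).
#' @param threshold adjusted-p threshold used only to label
#'   \code{direction} as up/down/ns.
#' @param prior_df prior degrees of freedom for the variance shrinkage.
#' @return data.frame: gene_id, log_fc, p, adj_p, direction.
#' @export
differential_expression <- function(m, group_a, group_b, threshold = 0.05,
                                    prior_df = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  for (g in c(group_a, group_b))
    if (!g %in% m$groups) stop("unknown group label: ", g)
  ia <- which(m$groups == group_a); ib <- which(m$groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 samples")
  xa <- m$values[, ia, drop = FALSE]; xb <- m$values[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / (na + nb - 2)
  d <- na + nb - 2
  s2_mod <- (prior_df * mean(s2) + d * s2) / (prior_df + d)
  floor_sd <- stats::quantile(sqrt(s2_mod), 0.10, names = FALSE)
  s_mod <- pmax(sqrt(s2_mod), floor_sd)
  tstat <- (mb - ma) / (s_mod * sqrt(1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), d + prior_df)
  adj <- bh_fdr(p)
  lfc <- mb - ma
  dir <- ifelse(adj < threshold & lfc > 0, "up",
                ifelse(adj < threshold & lfc < 0, "down", "ns"))
  data.frame(gene_id = rownames(m$values), log_fc = lfc, p = p,
             adj_p = adj, direction = dir, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- core regulated set ------------------------------------------------

#' Concordant core regulated gene set from OE and KD contrasts
#'
#' Genes significantly up-regulated in the overexpression contrast
#' (adj_p < threshold, log_fc > 0 in OE-vs-control) AND significantly
#' down-regulated in the knockdown contrast (adj_p < threshold,
#' log_fc < 0 in KD-vs-control).
#'
#' @param de_oe,de_kd DE tables over the same gene universe.
#' @param threshold adjusted-p cut (default 0.05; integrative analyses
#'   conventionally use 0.1).
#' @param name label for the resulting set.
#' @return a \code{GeneSet}: list(name, gene_ids, provenance).
#' @export
core_regulated_set <- function(de_oe, de_kd, threshold = 0.05,
                               name = "core_regulated") {
  sdiff <- length(union(setdiff(de_oe$gene_id, de_kd$gene_id),
                        setdiff(de_kd$gene_id, de_oe$gene_id)))
  if (sdiff > 0)
    stop("mismatched gene universes (symmetric difference ", sdiff, ")")
  up <- de_oe$gene_id[de_oe$adj_p < threshold & de_oe$log_fc > 0]
  dn <- de_kd$gene_id[de_kd$adj_p < threshold & de_kd$log_fc < 0]
  ids <- sort(intersect(up, dn))
  if (length(ids) == 0L)
    warning("empty core regulated set at threshold ", threshold)
  gene_set(name, ids,
           provenance = sprintf("OE-up AND KD-down at adj_p < %g", threshold))
}

#' Construct a named gene set
#' @param name set label.
#' @param gene_ids character vector (may be empty).
#' @param provenance free text.
#' @export
gene_set <- function(name, gene_ids, provenance = "") {
  structure(list(name = name, gene_ids = unique(as.character(gene_ids)),
                 provenance = provenance), class = "GeneSet")
}

#' Read/write one-id-per-line gene-set files (comment lines start with #)
#' @param path file path.
#' @param name set label.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  prov <- paste(sub("^#\\s*", "", lines[grepl("^#", lines)]), collapse = "; ")
  ids <- trimws(lines[!grepl("^#", lines)])
  gene_set(name, ids[nzchar(ids)], provenance = prov)
}

#' @rdname read_gene_set
#' @param gs a \code{GeneSet}.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(c(paste0("# ", gs$name, ": ", gs$provenance), gs$gene_ids), path)
  invisible(path)
}

#' Overlap summary of two gene sets
#'
#' The reported percentage uses the SMALLER set as denominator,
#' \code{100 * |a intersect b| / min(|a|, |b|)} (the convention under which
#' printed overlap percentages of unequal set pairs are reproducible);
#' both raw ratios are also returned. \code{pct_overlap} is the raw value;
#' \code{pct_rounded} the integer used for reporting.
#'
#' @param a,b \code{GeneSet}s (not both empty).
#' @return list: n_a, n_b, n_overlap, pct_overlap, pct_rounded,
#'   pct_of_a, pct_of_b.
#' @export
set_overlap_summary <- function(a, b) {
  na <- length(a$gene_ids); nb <- length(b$gene_ids)
  if (na == 0L && nb == 0L) stop("both gene sets empty")
  k <- length(intersect(a$gene_ids, b$gene_ids))
  pct <- 100 * k / min(na, nb)
  list(n_a = na, n_b = nb, n_overlap = k,
       pct_overlap = pct, pct_rounded = round(pct),
       pct_of_a = 100 * k / na, pct_of_b = 100 * k / nb)
}

# ---- signature projection ---------------------------------------------

#' Adjusted Rand index between two labelings
#' @param a,b equal-length label vectors.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)   # degenerate: all singletons / one block
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Project samples onto a gene signature and cluster them
#'
#' Restricts the matrix to signature genes, standardizes each gene row,
#' clusters SAMPLES by average linkage on 1 - Pearson correlation, and cuts
#' the tree into \code{k} clusters. When true sample labels are supplied,
#' the adjusted Rand index against them is returned.
#'
#' @param m \code{ExpressionMatrix}.
#' @param sig \code{GeneSet}; genes missing from the matrix are counted
#'   and reported in the result.
#' @param k number of clusters (>= 2).
#' @param true_labels optional named (or matrix-ordered) sample labels.
#' @return list: sample_order, cluster (named), n_signature_used,
#'   n_signature_missing, ari (or NA).
#' @export
signature_projection <- function(m, sig, k, true_labels = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (k < 2L) stop("k must be >= 2")
  present <- intersect(sig$gene_ids, rownames(m$values))
  n_missing <- length(sig$gene_ids) - length(present)
  if (length(present) < 2L)
    stop("fewer than 2 signature genes present in the matrix (",
         n_missing, " missing)")
  if (n_missing > 0)
    message(n_missing, " of ", length(sig$gene_ids),
            " signature genes absent from the matrix")
  x <- m$values[present, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  x <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  k <- min(k, ncol(x))
  cr <- suppressWarnings(stats::cor(x))
  cr[!is.finite(cr)] <- 0
  d <- stats::as.dist(1 - cr)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  ari <- NA_real_
  if (!is.null(true_labels)) {
    if (!is.null(names(true_labels)))
      true_labels <- true_labels[colnames(m$values)]
    ari <- adjusted_rand_index(cl, true_labels)
  }
  list(sample_order = hc$order, cluster = cl,
       n_signature_used = nrow(x), n_signature_missing = n_missing,
       ari = ari)
}
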