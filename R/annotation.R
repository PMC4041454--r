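# ---- gene annotation ---------------------------------------------------

#' Load a gene annotation table
#'
#' Expects a TSV with header columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{start}, \code{end} (half-open span). The TSS is
#' derived from strand: span start for \code{+} genes, span end (the
#' half-open end coordinate) for \code{-} genes.
#'
#' @param path TSV path.
#' @return data.frame of \code{GeneModel} rows: gene_id, chrom, strand,
#'   tss, span_start, span_end.
#' @export
load_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed strand at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  gene_models(df$gene_id, df$chrom, df$strand, df$start, df$end)
}

#' Build a gene-model table in memory
#'
#' @param gene_id,chrom,strand,start,end vectors of equal length;
#'   spans are half-open \code{[start, end)}.
#' @return data.frame with a derived strand-aware \code{tss} column.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end) {
  n <- length(gene_id)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  start <- rep_len(start, n); end <- rep_len(end, n)
  if (anyDuplicated(gene_id)) {
    d <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene_id: ", paste(utils::head(d, 5), collapse = ", "))
  }
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(start >= end)) stop("gene span with start >= end")
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             strand = strand,
             tss = ifelse(strand == "+", start, end),
             span_start = as.numeric(start), span_end = as.numeric(end),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation table as TSV
#' @param genes gene-model data.frame.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, start = genes$span_start,
                    end = genes$span_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.peak_midpoints <- function(ps) {
  iv <- ps$intervals
  floor((iv$start + iv$end) / 2)
}

# ---- peak-to-gene assignment ------------------------------------------

#' Assign peaks to all genes within a window of their TSS
#'
#' A peak (anchored at its midpoint, floor of (start+end)/2) is assigned to
#' every gene on the same chromosome whose TSS lies strictly within
#' \code{window} bp (distance < window). A peak near several TSSs yields
#' several assignments.
#'
#' @param peaks a \code{PeakSet}.
#' @param genes gene-model data.frame (see \code{\link{gene_models}}).
#' @param window window size in bp (> 0); strict inequality.
#' @param anchor \code{"tss"} (default) measures to the TSS;
#'   \code{"span"} measures to the nearest gene-body edge (0 inside).
#' @return data.frame: chrom, peak_start, peak_end, midpoint, gene_id,
#'   distance, window.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window, anchor = c("tss", "span")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  iv <- peaks$intervals
  mid <- .peak_midpoints(peaks)
  res <- vector("list", length(unique(iv$chrom)))
  i <- 0L
  for (ch in unique(iv$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    pi <- which(iv$chrom == ch)
    # all pairs on this chromosome within window
    dmat <- if (anchor == "tss") {
      abs(outer(mid[pi], g$tss, `-`))
    } else {
      lo <- outer(mid[pi], g$span_start, `-`)   # mid - start
      hi <- outer(mid[pi], g$span_end - 1, `-`) # mid - last base
      pmax(pmax(-lo, hi), 0)                    # 0 when inside the span
    }
    hit <- which(dmat < window, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    i <- i + 1L
    res[[i]] <- data.frame(
      chrom = ch,
      peak_start = iv$start[pi[hit[, 1L]]],
      peak_end = iv$end[pi[hit[, 1L]]],
      midpoint = mid[pi[hit[, 1L]]],
      gene_id = g$gene_id[hit[, 2L]],
      distance = dmat[hit],
      window = window, stringsAsFactors = FALSE)
  }
  if (i == 0L)
    return(data.frame(chrom = character(), peak_start = numeric(),
                      peak_end = numeric(), midpoint = numeric(),
                      gene_id = character(), distance = numeric(),
                      window = numeric()))
  out <- do.call(rbind, res[seq_len(i)])
  out <- out[order(out$chrom, out$peak_start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fast vectorised nearest-TSS distance for a vector of midpoints, one chrom
.nearest_tss <- function(mids, tss_sorted, ids_sorted) {
  j <- findInterval(mids, tss_sorted)
  n <- length(tss_sorted)
  lo <- pmax(j, 1L); hi <- pmin(j + 1L, n)
  dlo <- abs(mids - tss_sorted[lo])
  dhi <- abs(mids - tss_sorted[hi])
  # tie broken by lexicographically smallest gene id
  use_lo <- (dlo < dhi) |
    (dlo == dhi & ids_sorted[lo] <= ids_sorted[hi]) |
    (j >= n)
  use_lo[j < 1L] <- FALSE
  idx <- ifelse(use_lo, lo, hi)
  list(gene_id = ids_sorted[idx], distance = ifelse(use_lo, dlo, dhi))
}

#' Closest gene (by TSS) for each peak
#'
#' Minimal |peak midpoint - TSS| on the peak's chromosome; exact ties are
#' broken by the lexicographically smallest gene_id.
#'
#' @param peaks a \code{PeakSet}.
#' @param genes gene-model data.frame.
#' @return data.frame: chrom, start, end, gene_id, distance (one row per
#'   peak, in the peak set's order).
#' @export
closest_gene <- function(peaks, genes) {
  iv <- peaks$intervals
  mid <- .peak_midpoints(peaks)
  gene_id <- character(nrow(iv)); distance <- numeric(nrow(iv))
  for (ch in unique(iv$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(iv$chrom == ch)
    if (nrow(g) == 0L)
      stop("no gene on chromosome '", ch, "'")
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    # genes sharing a TSS are equidistant; smallest id wins by the tie rule
    g <- g[!duplicated(g$tss), , drop = FALSE]
    nn <- .nearest_tss(mid[pi], g$tss, g$gene_id)
    gene_id[pi] <- nn$gene_id; distance[pi] <- nn$distance
  }
  data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
             gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Distribution of peak-to-nearest-TSS distances
#'
#' Bins each peak by its closest-TSS distance into the named categories
#' promoter-proximal (< 5 kb), gene-proximal (5-50 kb), gene-distal
#' (50-500 kb) and desert (>= 500 kb), returning the fraction of peaks per
#' bin. Bin edges are configurable.
#'
#' @param peaks non-empty \code{PeakSet}; every peak chromosome must carry
#'   at least one gene.
#' @param genes gene-model data.frame.
#' @param breaks ascending inner bin edges in bp.
#' @return list with \code{bin_labels}, \code{fractions} (sum 1) and
#'   \code{counts}.
#' @export
distance_distribution <- function(peaks, genes,
                                  breaks = c(5e3, 5e4, 5e5)) {
  if (length(peaks) == 0L) stop("empty peak set")
  d <- closest_gene(peaks, genes)$distance
  edges <- c(0, breaks, Inf)
  labs <- paste0("[", format(edges[-length(edges)], scientific = FALSE,
                             trim = TRUE, big.mark = ""),
                 ",", c(format(breaks, scientific = FALSE, trim = TRUE),
                        "Inf"), ")")
  counts <- as.integer(table(cut(d, edges, right = FALSE, labels = labs)))
  list(bin_labels = labs, fractions = counts / length(d), counts = counts)
}
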