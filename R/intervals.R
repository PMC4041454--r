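# ---- PeakSet -----------------------------------------------------------

#' Construct a PeakSet of half-open genomic intervals
#'
#' A \code{PeakSet} holds the binding sites ("peaks") of one ChIP experiment
#' as BED-style 0-based half-open intervals \code{[start, end)}, sorted by
#' (chrom, start, end).
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end} and optionally \code{score}.
#' @param name label for the set (e.g. factor + cell line).
#' @param source free-text provenance.
#' @return an object of class \code{PeakSet} with elements \code{name},
#'   \code{intervals} (sorted data.frame) and \code{source}.
#' @export
peak_set <- function(intervals, name = "peaks", source = "") {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), score = numeric())
  }
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(intervals))
      stop("intervals must have a '", col, "' column")
  }
  if (!"score" %in% names(intervals)) intervals$score <- NA_real_
  intervals <- intervals[, c("chrom", "start", "end", "score")]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  if (nrow(intervals) > 0L) {
    if (any(!nzchar(intervals$chrom))) stop("empty chromosome name")
    if (any(!is.finite(intervals$start)) || any(!is.finite(intervals$end)))
      stop("non-finite coordinates")
    if (any(intervals$start < 0)) stop("negative start coordinate")
    if (any(intervals$end <= intervals$start))
      stop("interval with end <= start (zero or negative length)")
    o <- order(intervals$chrom, intervals$start, intervals$end)
    intervals <- intervals[o, , drop = FALSE]
    rownames(intervals) <- NULL
    dup <- duplicated(intervals[, c("chrom", "start", "end")])
    if (any(dup))
      warning(sum(dup), " duplicate interval(s) in set '", name,
              "' kept but counted once in overlap numerators")
  }
  structure(list(name = name, intervals = intervals, source = source),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet '", x$name, "': ", nrow(x$intervals), " intervals on ",
      length(unique(x$intervals$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$intervals)

# unique intervals: duplicates are counted once in all overlap numerators
.ps_unique <- function(ps) {
  iv <- ps$intervals
  iv[!duplicated(iv[, c("chrom", "start", "end")]), , drop = FALSE]
}

# ---- BED I/O -----------------------------------------------------------

#' Read a BED3+ file into a PeakSet
#'
#' Coordinates are interpreted as BED 0-based half-open. \code{track},
#' \code{browser} and \code{#} comment lines are skipped.
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @param name set label; defaults to the file name without extension.
#' @return a sorted \code{PeakSet}.
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(peak_set(data.frame(), name, source = path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", idx[which(nf < 3L)[1L]], ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  s_raw <- vapply(fields, `[[`, "", 2L)
  e_raw <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_raw))
  end <- suppressWarnings(as.numeric(e_raw))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", idx[bad[1L]], ": non-integer coordinate ('",
         s_raw[bad[1L]], "', '", e_raw[bad[1L]], "')")
  bad <- which(start < 0)
  if (length(bad)) stop("line ", idx[bad[1L]], ": negative coordinate")
  bad <- which(end <= start)
  if (length(bad))
    stop("line ", idx[bad[1L]], ": end <= start (zero-length interval)")
  score <- rep(NA_real_, length(idx))
  has5 <- nf >= 5L
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  peak_set(data.frame(chrom = chrom, start = start, end = end, score = score),
           name = name, source = path)
}

#' Write a PeakSet to a BED file
#'
#' @param ps a \code{PeakSet}.
#' @param path output path.
#' @export
write_bed <- function(ps, path) {
  iv <- ps$intervals
  df <- data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
                   format(iv$end, scientific = FALSE, trim = TRUE),
                   name = ps$name,
                   score = ifelse(is.na(iv$score), 0, iv$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- interval algebra --------------------------------------------------

#' Merge overlapping intervals
#'
#' Returns the minimal set of non-overlapping intervals covering the same
#' bases. Touching intervals (\code{[0,10)}, \code{[10,20)}) share no base
#' under half-open coordinates and are NOT merged.
#'
#' @param ps a \code{PeakSet}.
#' @return a merged \code{PeakSet}.
#' @export
merge_intervals <- function(ps) {
  iv <- ps$intervals
  if (nrow(iv) == 0L) return(ps)
  out <- do.call(rbind, lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    n <- nrow(d)
    # new run starts where start >= running max of previous ends
    cme <- cummax(d$end)
    newrun <- c(TRUE, d$start[-1L] >= cme[-n])
    grp <- cumsum(newrun)
    data.frame(chrom = d$chrom[1L],
               start = tapply(d$start, grp, min),
               end = as.numeric(tapply(d$end, grp, max)))
  }))
  peak_set(out, name = ps$name, source = ps$source)
}

# per-row flags: does each a interval share >= min_overlap bases with some b?
.overlap_flags <- function(a_iv, b_iv, min_overlap = 1) {
  flags <- logical(nrow(a_iv))
  if (nrow(a_iv) == 0L || nrow(b_iv) == 0L) return(flags)
  for (ch in unique(a_iv$chrom)) {
    ai <- which(a_iv$chrom == ch)
    b <- b_iv[b_iv$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0L) next
    b <- b[order(b$start, b$end), , drop = FALSE]
    bs <- b$start; be <- b$end; cme <- cummax(be)
    as_ <- a_iv$start[ai]; ae_ <- a_iv$end[ai]
    j <- findInterval(ae_ - 1, bs)     # last b with start < a end
    if (min_overlap == 1) {
      ok <- j >= 1L
      ok[ok] <- cme[j[ok]] > as_[ok]
      flags[ai] <- ok
    } else {
      for (k in seq_along(ai)) {
        if (j[k] < 1L) next
        idx <- seq_len(j[k])
        ov <- pmin(ae_[k], be[idx]) - pmax(as_[k], bs[idx])
        flags[ai[k]] <- any(ov >= min_overlap)
      }
    }
  }
  flags
}

#' Intervals of one set supported by another
#'
#' Returns the subset of \code{a}'s intervals having at least
#' \code{min_overlap} shared bases with at least one interval of \code{b};
#' \code{a}'s original coordinates are retained.
#'
#' @param a,b \code{PeakSet}s.
#' @param min_overlap minimum shared base count (>= 1).
#' @return a \code{PeakSet} subset of \code{a}.
#' @export
intersect_sets <- function(a, b, min_overlap = 1) {
  if (!is.numeric(min_overlap) || min_overlap < 1)
    stop("min_overlap must be >= 1")
  keep <- .overlap_flags(a$intervals, b$intervals, min_overlap)
  peak_set(a$intervals[keep, , drop = FALSE],
           name = paste0(a$name, "&", b$name), source = a$source)
}

#' High-confidence consensus peaks from two callers
#'
#' Retains peaks of \code{caller1} having >= 1 bp overlap with any peak of
#' \code{caller2} — the two-caller consensus rule. The first caller's
#' coordinates survive; \code{symmetric = TRUE} additionally requires the
#' union view (peaks of caller2 supported by caller1 appended, deduplicated).
#'
#' @param caller1,caller2 \code{PeakSet}s from the same experiment.
#' @param symmetric also keep caller2 peaks supported by caller1.
#' @return \code{PeakSet} labelled \code{"high_confidence"}.
#' @export
consensus_peaks <- function(caller1, caller2, symmetric = FALSE) {
  if (length(caller1) == 0L || length(caller2) == 0L) {
    warning("empty caller peak set; consensus is empty")
    return(peak_set(data.frame(), name = "high_confidence"))
  }
  out <- intersect_sets(caller1, caller2, 1)
  if (symmetric) {
    rev <- intersect_sets(caller2, caller1, 1)
    iv <- rbind(out$intervals, rev$intervals)
    iv <- iv[!duplicated(iv[, c("chrom", "start", "end")]), , drop = FALSE]
    out <- peak_set(iv, name = "high_confidence")
  }
  out$name <- "high_confidence"
  out
}

# ---- overlap matrix ----------------------------------------------------

#' All-pairs peak-set overlap percentages
#'
#' Entry (i, j) is 100 * |peaks of set i with >= min_overlap shared bases
#' with set j| / |set i| — the percentage of the ROW set supported by the
#' column set. The matrix need not be symmetric; the orientation is recorded
#' so downstream plots cannot silently transpose. Duplicate intervals count
#' once in both numerator and denominator.
#'
#' @param sets list of non-empty \code{PeakSet}s (length >= 2).
#' @param min_overlap minimum shared bases.
#' @return an \code{OverlapMatrix}: list with \code{set_names},
#'   \code{values} (percentages), \code{counts} (numerators), \code{sizes},
#'   \code{orientation}.
#' @export
pairwise_overlap_matrix <- function(sets, min_overlap = 1) {
  if (length(sets) < 2L) stop("need >= 2 peak sets")
  nm <- vapply(sets, function(s) s$name, "")
  for (s in sets) if (length(s) == 0L) stop("empty peak set: '", s$name, "'")
  uiv <- lapply(sets, .ps_unique)
  n <- length(sets)
  sizes <- vapply(uiv, nrow, 0L)
  counts <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    counts[i, j] <- if (i == j) sizes[i] else
      sum(.overlap_flags(uiv[[i]], uiv[[j]], min_overlap))
  }
  vals <- 100 * counts / sizes
  structure(list(set_names = nm, values = vals, counts = counts,
                 sizes = stats::setNames(sizes, nm),
                 orientation = "row_pct_of_row_set_overlapping_column_set",
                 min_overlap = min_overlap),
            class = "OverlapMatrix")
}

#' @export
print.OverlapMatrix <- function(x, ...) {
  cat("OverlapMatrix (", x$orientation, ")\n", sep = "")
  print(round(x$values, 1))
  invisible(x)
}

#' Write an OverlapMatrix as TSV plus a JSON sidecar
#' @param m an \code{OverlapMatrix}.
#' @param path TSV output path; sidecar written to \code{paste0(path,".json")}.
#' @export
write_overlap_matrix <- function(m, path) {
  df <- data.frame(set = m$set_names, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(orientation = m$orientation,
                            min_overlap = m$min_overlap,
                            sizes = as.list(m$sizes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# ---- clustering --------------------------------------------------------

# deterministic leaf order: at each merge node children are ordered by
# (subtree size, then smallest leaf label); replaces hclust's input-order tie
.deterministic_order <- function(merge, labels) {
  n <- nrow(merge) + 1L
  node <- function(i) {
    if (i < 0) {
      list(leaves = -i, size = 1L, minlab = labels[-i])
    } else {
      a <- node(merge[i, 1L]); b <- node(merge[i, 2L])
      first_a <- (a$size < b$size) ||
        (a$size == b$size && a$minlab <= b$minlab)
      kids <- if (first_a) list(a, b) else list(b, a)
      list(leaves = c(kids[[1L]]$leaves, kids[[2L]]$leaves),
           size = a$size + b$size, minlab = min(a$minlab, b$minlab))
    }
  }
  node(n - 1L)$leaves
}

#' Cluster the rows of an overlap (or any numeric) matrix
#'
#' Average-linkage hierarchical clustering of matrix rows with distance
#' 1 - Pearson correlation, plus a deterministic leaf ordering for
#' reproducible heatmaps. Rows with zero variance get distance 1 to every
#' other row (correlation undefined), with a warning.
#'
#' @param m an \code{OverlapMatrix} or a numeric matrix with rownames.
#' @return list with \code{hclust}, \code{order} (row indices),
#'   \code{labels} (ordered), \code{matrix} (rows and, when square with
#'   matching names, columns reordered).
#' @export
cluster_matrix <- function(m) {
  vals <- if (inherits(m, "OverlapMatrix")) m$values else as.matrix(m)
  if (nrow(vals) < 2L) stop("need >= 2 rows to cluster")
  if (is.null(rownames(vals))) rownames(vals) <- paste0("row", seq_len(nrow(vals)))
  sds <- apply(vals, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning("constant row(s) ", paste(rownames(vals)[const], collapse = ", "),
            ": correlation undefined, distance set to 1")
  cr <- suppressWarnings(stats::cor(t(vals)))
  cr[!is.finite(cr)] <- 0
  d <- 1 - cr
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ord <- .deterministic_order(hc$merge, rownames(vals))
  hc$order <- ord
  out_m <- vals[ord, , drop = FALSE]
  if (ncol(vals) == nrow(vals) &&
      identical(colnames(vals), rownames(vals)))
    out_m <- out_m[, ord, drop = FALSE]
  list(hclust = hc, order = ord, labels = rownames(vals)[ord], matrix = out_m)
}
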