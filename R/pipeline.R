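# ---- run configuration -------------------------------------------------

.num_keys <- c("de_threshold", "integrative_threshold", "n_perm", "seed",
               "panel_window")

#' Read a plain-text "key: value" run configuration
#'
#' Recognised keys: \code{peaks} (comma-separated BED paths),
#' \code{annotation}, \code{expression}, \code{groups}, \code{clinical},
#' \code{panel}, \code{out_dir}, \code{windows} (comma-separated bp,
#' ascending), \code{de_threshold} (default 0.05),
#' \code{integrative_threshold} (default 0.1), \code{panel_window}
#' (default 25000), \code{n_perm} (default 200), \code{seed} (default 1).
#' Lines starting with \code{#} are comments. Unknown keys error.
#'
#' @param path config file path.
#' @return a validated \code{RunConfig} list (includes \code{config_hash}).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  cfg <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
  known <- c("peaks", "annotation", "expression", "groups", "clinical",
             "panel", "out_dir", "windows", .num_keys)
  unk <- setdiff(names(cfg), known)
  if (length(unk)) stop("unknown config key(s): ", paste(unk, collapse = ", "))
  defaults <- list(windows = "5000,10000,25000,50000", de_threshold = "0.05",
                   integrative_threshold = "0.1", panel_window = "25000",
                   n_perm = "200", seed = "1")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in .num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$windows <- as.numeric(strsplit(cfg$windows, ",")[[1]])
  if (any(diff(cfg$windows) <= 0) || any(cfg$windows <= 0))
    stop("windows must be positive and ascending")
  for (k in c("de_threshold", "integrative_threshold"))
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1) stop(k, " must lie in (0, 1)")
  if (!is.null(cfg$peaks))
    cfg$peaks <- trimws(strsplit(cfg$peaks, ",")[[1]])
  cfg$config_hash <- unname(tools::md5sum(path))
  structure(cfg, class = "RunConfig")
}

# ---- simulate ----------------------------------------------------------

#' Write a full synthetic input directory
#'
#' Generates every input class the pipeline reads — two BED peak sets
#' (the second with the planted overlap fraction against the first), a
#' gene annotation TSV, an expression matrix + sample-group TSV with
#' planted concordant OE/KD genes, a clinical TSV with a planted
#' score-linked hazard — plus a manifest JSON echoing the spec and a
#' ready-to-run pipeline config.
#'
#' @param spec a \code{SyntheticSpec}.
#' @param dir output directory (created).
#' @return the directory path, invisibly; the manifest lists all files.
#' @export
simulate_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gg <- gen_genome(spec)
  ps_a <- gen_peakset(gg$genome, gg$genes, spec, name = "setA")
  ps_b <- gen_overlapping_peakset(ps_a, spec$overlap_fraction, gg$genome,
                                  spec, name = "setB")
  expr <- gen_expression(gg$genes, spec)
  surv <- gen_survival(max(100L, 10L), spec, score_link = "step")
  paths <- list(
    peaks_a = file.path(dir, "setA.bed"),
    peaks_b = file.path(dir, "setB.bed"),
    annotation = file.path(dir, "genes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    panel = file.path(dir, "panel.txt"))
  write_bed(ps_a, paths$peaks_a)
  write_bed(ps_b, paths$peaks_b)
  write_gene_annotation(gg$genes, paths$annotation)
  write_expression(expr, paths$expression, paths$groups)
  clin <- surv$records
  names(clin)[names(clin) == "time"] <- "time_months"
  utils::write.table(clin, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel <- gene_set("synthetic_panel",
                    sort(sample(attr(expr, "planted"),
                                min(16L, length(attr(expr, "planted"))))),
                    provenance = "synthetic panel drawn from planted genes")
  write_gene_set(panel, paths$panel)
  jsonlite::write_json(
    list(spec = spec[setdiff(names(spec), "genome")],
         chrom_lengths = as.list(spec$genome$chrom_lengths),
         planted_de_genes = attr(expr, "planted"),
         files = lapply(paths, basename)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  cfg <- c(paste0("peaks: ", paths$peaks_a, ",", paths$peaks_b),
           paste0("annotation: ", paths$annotation),
           paste0("expression: ", paths$expression),
           paste0("groups: ", paths$groups),
           paste0("clinical: ", paths$clinical),
           paste0("panel: ", paths$panel),
           paste0("seed: ", spec$seed),
           paste0("out_dir: ", file.path(dir, "results")))
  writeLines(cfg, file.path(dir, "run_config.txt"))
  invisible(dir)
}

# ---- full pipeline -----------------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full integrative analysis from a configuration
#'
#' Stages, in order: read peak sets, pairwise cistrome concordance
#' (overlap matrix + enrichment tests + clustering), peak-to-gene
#' annotation and distance profiles, expression normalization and
#' OE/KD differential expression, concordant core-set derivation,
#' binding-expression integration (fraction bound per window; panel
#' regulation check when a panel is supplied), and survival analysis
#' (first-quartile dichotomization of the score covariate, KM, log-rank,
#' optimal cutpoint, Cox). Deterministic given config + seed; every output
#' table is written under \code{out_dir} and a manifest JSON carries the
#' config hash, seeds and per-stage counts.
#'
#' @param config a \code{RunConfig} (or path to one).
#' @param genome optional \code{GenomeSpec}; by default inferred from the
#'   data (chromosome ends padded by 1 kb).
#' @return the report bundle (named list of stage outputs), invisibly
#'   written to \code{out_dir}.
#' @export
run_pipeline <- function(config, genome = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  peak_sets <- .stage("read_peaks", lapply(config$peaks, read_bed))
  genes <- .stage("read_annotation", load_gene_annotation(config$annotation))
  counts$n_peak_sets <- length(peak_sets)
  counts$n_genes <- nrow(genes)

  if (is.null(genome)) {
    allc <- c(unlist(lapply(peak_sets, function(s) s$intervals$chrom)),
              genes$chrom)
    maxend <- vapply(split(
      c(unlist(lapply(peak_sets, function(s) s$intervals$end)),
        genes$span_end),
      c(unlist(lapply(peak_sets, function(s) s$intervals$chrom)),
        genes$chrom)), max, 0)
    genome <- genome_spec(maxend + 1000)
  }

  concordance <- .stage("concordance",
    cistrome_concordance_report(peak_sets, genes, genome,
                                windows = config$windows,
                                n_perm = config$n_perm,
                                seed = config$seed,
                                out_dir = out_dir))
  clust <- if (length(peak_sets) >= 3L)
    .stage("cluster", cluster_matrix(concordance$overlap_matrix)) else NULL

  wmax <- max(config$windows)
  assignments <- .stage("annotate",
    assign_peaks_to_genes(peak_sets[[1L]], genes, wmax))
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$n_assignments <- nrow(assignments)

  expr <- .stage("read_expression",
                 read_expression(config$expression, config$groups))
  expr <- .stage("normalize", quantile_normalize(expr))
  de_oe <- .stage("de_oe",
    differential_expression(expr, "control", "OE", config$de_threshold))
  de_kd <- .stage("de_kd",
    differential_expression(expr, "control", "KD", config$de_threshold))
  utils::write.table(de_oe, file.path(out_dir, "de_oe.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de_kd, file.path(out_dir, "de_kd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  core <- .stage("core_set",
    suppressWarnings(core_regulated_set(de_oe, de_kd, config$de_threshold)))
  write_gene_set(core, file.path(out_dir, "core_set.txt"))
  counts$n_core <- length(core$gene_ids)

  integration <- .stage("integrate", lapply(config$windows, function(w) {
    ib <- integrate_binding_expression(assignments, core, w)
    list(window = w, fraction_bound = ib$fraction_bound,
         n_bound = ib$n_bound, n_core = ib$n_core)
  }))
  frac_tab <- do.call(rbind, lapply(integration, as.data.frame))
  utils::write.table(frac_tab, file.path(out_dir, "fraction_bound.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  panel_res <- NULL
  if (!is.null(config$panel)) {
    panel <- read_gene_set(config$panel)
    panel_res <- .stage("panel_check",
      suppressWarnings(
        panel_regulation_check(panel, assignments, de_oe, de_kd,
                               window = config$panel_window,
                               threshold = config$integrative_threshold)))
    utils::write.table(panel_res$per_gene,
                       file.path(out_dir, "panel_check.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$n_panel_regulated <- panel_res$n_regulated
  }

  surv_res <- NULL
  if (!is.null(config$clinical)) {
    clin <- .stage("read_clinical", read_clinical(config$clinical))
    covars <- setdiff(names(clin), c("subject_id", "time", "event"))
    if (length(covars)) {
      sc <- clin[[covars[1L]]]
      dich <- .stage("dichotomize", dichotomize_first_quartile(sc))
      km_low <- km_estimate(clin[dich$group == "low", , drop = FALSE])
      km_high <- km_estimate(clin[dich$group == "high", , drop = FALSE])
      write_km(km_low, file.path(out_dir, "km_low.tsv"))
      write_km(km_high, file.path(out_dir, "km_high.tsv"))
      lr <- .stage("logrank",
        logrank_test(clin[dich$group == "low", , drop = FALSE],
                     clin[dich$group == "high", , drop = FALSE]))
      oc <- .stage("cutpoint",
        optimal_cutpoint(stats::setNames(sc, clin$subject_id), clin,
                         n_perm = 0L, seed = config$seed))
      cox <- .stage("cox", cox_ph(clin, covars[1L]))
      surv_res <- list(covariate = covars[1L], q1_cut = dich$cut,
                       logrank = lr, cutpoint = oc,
                       cox = cox[c("coef", "hr", "se", "p_wald",
                                   "score_chi2", "p_score")])
      jsonlite::write_json(surv_res, file.path(out_dir, "survival.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }

  manifest <- list(config_hash = config$config_hash,
                   seed = config$seed,
                   windows = config$windows,
                   de_threshold = config$de_threshold,
                   integrative_threshold = config$integrative_threshold,
                   n_perm = config$n_perm,
                   counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(concordance = concordance, cluster = clust,
                 assignments = assignments, de_oe = de_oe, de_kd = de_kd,
                 core = core, integration = integration,
                 panel = panel_res, survival = surv_res,
                 manifest = manifest))
}
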