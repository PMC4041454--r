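# 16-gene panel fixture built to the "< 25 kb + concordant DE" rule:
# genes 1-9 are bound and concordant (regulated); 10-12 bound only;
# 13-14 concordant only; 15-16 neither.
panel_fixture <- function() {
  ids <- sprintf("panel%02d", 1:16)
  genes <- gene_models(ids, "chr1", "+", seq(0, 15) * 1e6,
                       seq(0, 15) * 1e6 + 1e4)
  bound_idx <- 1:12
  pk <- make_ps("chr1", genes$tss[bound_idx] + 20000,
                genes$tss[bound_idx] + 20200, "gabpa")
  assignments <- assign_peaks_to_genes(pk, genes, 50000)
  conc_idx <- c(1:9, 13:14)
  mk_de <- function(sign) data.frame(
    gene_id = ids,
    log_fc = ifelse(seq_along(ids) %in% conc_idx, sign * 2, sign * 0.1),
    p = 0.01,
    adj_p = ifelse(seq_along(ids) %in% conc_idx, 0.01, 0.5),
    direction = "x", stringsAsFactors = FALSE)
  list(ids = ids, genes = genes, assignments = assignments,
       de_oe = mk_de(+1), de_kd = mk_de(-1))
}
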