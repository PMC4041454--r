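make_expr <- function(vals, groups) {
  rownames(vals) <- paste0("g", seq_len(nrow(vals)))
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  expression_matrix(vals, stats::setNames(groups, colnames(vals)))
}

test_that("quantile_normalize equalizes column distributions", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(unname(quantile_normalize(same)), unname(same))
  set.seed(8)
  x <- matrix(rnorm(300), 50, 6)
  qn <- quantile_normalize(x)
  sorted_cols <- apply(qn, 2, sort)
  for (j in 2:6) expect_equal(sorted_cols[, j], sorted_cols[, 1])
  # idempotence
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-9)
  # rank preservation within column
  expect_equal(apply(x, 2, rank), apply(qn, 2, rank))
  expect_error(quantile_normalize(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("differential_expression: zero effect, antisymmetry, errors", {
  set.seed(9)
  vals <- matrix(rnorm(100 * 8, 8, 1), 100, 8)
  vals[1, ] <- 8  # identical gene within the variance floor
  m <- make_expr(vals, rep(c("ctl", "trt"), each = 4))
  de <- differential_expression(m, "ctl", "trt")
  expect_equal(de$p[1], 1, tolerance = 1e-6)
  expect_equal(de$direction[1], "ns")
  expect_true(all(de$adj_p >= de$p))
  de_rev <- differential_expression(m, "trt", "ctl")
  expect_equal(de_rev$log_fc, -de$log_fc)
  expect_equal(de_rev$p, de$p)
  expect_error(differential_expression(m, "ctl", "nope"), "unknown")
  m1 <- make_expr(vals[, 1:5], c("a", "b", "b", "b", "b"))
  expect_error(differential_expression(m1, "a", "b"), ">= 2")
})

test_that("planted effects are recovered with high sensitivity", {
  # the stated simulation: 1000 genes, 50 planted at log2 effect 2,
  # noise sd 0.5, 4 vs 4
  set.seed(10)
  n <- 1000; planted <- 1:50
  base <- matrix(rnorm(n * 8, 8, 1)[rep(1:n, 8)], n, 8)
  base[planted, 5:8] <- base[planted, 5:8] + 2
  vals <- base + matrix(rnorm(n * 8, 0, 0.5), n, 8)
  m <- make_expr(vals, rep(c("ctl", "oe"), each = 4))
  de <- differential_expression(m, "ctl", "oe")
  hits <- which(de$adj_p < 0.05 & de$log_fc > 0)
  expect_gte(length(intersect(hits, planted)) / 50, 0.90)
  # false calls stay near the FDR level
  expect_lte(length(setdiff(hits, planted)), 0.05 * length(hits) + 3)
})

test_that("core_regulated_set intersects concordant calls", {
  mk_de <- function(ids, lfc, adj) data.frame(
    gene_id = ids, log_fc = lfc, p = adj / 2, adj_p = adj,
    direction = "x", stringsAsFactors = FALSE)
  ids <- paste0("g", 1:5)
  oe <- mk_de(ids, c(1, 2, 1, -1, 1), c(0.01, 0.01, 0.01, 0.01, 0.5))
  kd <- mk_de(ids, c(1, -2, -1, -1, -1), c(0.01, 0.01, 0.01, 0.01, 0.01))
  cs <- core_regulated_set(oe, kd)
  expect_equal(cs$gene_ids, c("g2", "g3"))
  # threshold semantics: adj_p 0.06 excluded at 0.05, included at 0.10
  oe$adj_p[2] <- 0.06
  expect_false("g2" %in% core_regulated_set(oe, kd, 0.05)$gene_ids)
  expect_true("g2" %in% core_regulated_set(oe, kd, 0.10)$gene_ids)
  # monotone in threshold
  expect_true(all(core_regulated_set(oe, kd, 0.05)$gene_ids %in%
                    core_regulated_set(oe, kd, 0.10)$gene_ids))
  expect_warning(core_regulated_set(mk_de(ids, 1, 0.9), kd), "empty")
  expect_error(core_regulated_set(oe, mk_de(paste0("h", 1:5), 1, 0.1)),
               "mismatched")
})

test_that("set_overlap_summary reproduces the printed-count arithmetic", {
  a <- gene_set("AD", paste0("g", 1:1825))
  b <- gene_set("CR", c(paste0("g", 1:316), paste0("x", 1:(1655 - 316))))
  s <- set_overlap_summary(a, b)
  expect_equal(s$n_overlap, 316)
  expect_equal(s$pct_rounded, 19)
  expect_equal(s$pct_overlap, 100 * 316 / 1655, tolerance = 1e-12)
  # symmetry
  s2 <- set_overlap_summary(b, a)
  expect_equal(s2$pct_overlap, s$pct_overlap)
  ident <- gene_set("i", paste0("g", 1:10))
  expect_equal(set_overlap_summary(ident, ident)$pct_overlap, 100)
  expect_equal(set_overlap_summary(gene_set("a", "x"),
                                   gene_set("b", "y"))$pct_overlap, 0)
  expect_error(set_overlap_summary(gene_set("a", character()),
                                   gene_set("b", character())), "empty")
})

test_that("signature_projection separates planted sample groups", {
  set.seed(12)
  n_genes <- 120; n_samp <- 12
  vals <- matrix(rnorm(n_genes * n_samp, 8, 1), n_genes, n_samp)
  sig_genes <- 1:30
  grp <- rep(c(1, 2), each = 6)
  # gene-specific effect directions (3 sd): up for half the signature,
  # down for the rest, as in a real expression signature
  eff <- rep(c(3, -3), length.out = 30)
  vals[sig_genes, grp == 2] <- vals[sig_genes, grp == 2] + eff
  m <- make_expr(vals, rep("t", n_samp))
  sig <- gene_set("sig", paste0("g", sig_genes))
  pr <- signature_projection(m, sig, k = 2, true_labels = grp)
  expect_equal(pr$ari, 1.0)
  expect_equal(pr$n_signature_used, 30)
  expect_error(signature_projection(m, gene_set("no", "zz"), 2),
               "signature genes")
  # degenerate cut: every sample its own cluster, ARI defined
  pr_n <- signature_projection(m, sig, k = n_samp, true_labels = grp)
  expect_equal(length(unique(pr_n$cluster)), n_samp)
  expect_true(is.finite(pr_n$ari))
  # missing signature members are counted
  sig2 <- gene_set("sig2", c(paste0("g", sig_genes), "absent1", "absent2"))
  expect_message(pr2 <- signature_projection(m, sig2, 2), "2 of 32")
  expect_equal(pr2$n_signature_missing, 2)
})
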