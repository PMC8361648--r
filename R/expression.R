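#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct(target) - Ct(reference gene)` within each sample;
#' `ddCt = dCt(test) - dCt(calibrator)`; relative expression is `2^-ddCt`.
#' Technical-replicate rows for the same (sample, gene) are averaged before
#' the differences are taken.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `ct`.
#' @param target_gene gene of interest.
#' @param test_sample sample whose expression is quantified.
#' @param reference_gene internal control gene (e.g. Actin).
#' @param calibrator_sample baseline sample.
#' @return list with `delta_ct_test`, `delta_ct_calibrator`, `ddct` and
#'   `rel_expression` (= 2^-ddct).
#' @export
ddct <- function(ct_table, target_gene, test_sample,
                 reference_gene, calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)))
  get_ct <- function(s, g) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene == g]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop(sprintf("missing Ct for sample '%s', gene '%s'", s, g))
    mean(v)
  }
  dct_test <- get_ct(test_sample, target_gene) -
    get_ct(test_sample, reference_gene)
  dct_cal <- get_ct(calibrator_sample, target_gene) -
    get_ct(calibrator_sample, reference_gene)
  dd <- dct_test - dct_cal
  list(delta_ct_test = dct_test, delta_ct_calibrator = dct_cal,
       ddct = dd, rel_expression = 2^-dd)
}

#' Group fold change on an expression matrix
#'
#' Ratio of group mean abundances (test over base, e.g. mutant over wild
#' type) and its log2. Genes where either group mean is zero are flagged
#' `undefined` with NA fold change rather than reported as infinite.
#'
#' @param mat numeric gene x sample matrix (FPKM semantics, values >= 0).
#' @param groups character/factor of group labels, one per column of `mat`.
#' @param test_group,base_group the two labels to compare.
#' @return data.frame: `gene`, `mean_test`, `mean_base`, `fold_change`,
#'   `log2fc`, `undefined`.
#' @export
group_fold_change <- function(mat, groups, test_group = "mutant",
                              base_group = "wildtype") {
  stopifnot(ncol(mat) == length(groups))
  if (any(mat < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  for (g in c(test_group, base_group))
    if (!g %in% groups) stop(sprintf("group '%s' has no samples", g))
  m_test <- rowMeans(mat[, groups == test_group, drop = FALSE])
  m_base <- rowMeans(mat[, groups == base_group, drop = FALSE])
  undef <- m_test == 0 | m_base == 0
  fc <- ifelse(undef, NA_real_, m_test / m_base)
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             mean_test = m_test, mean_base = m_base,
             fold_change = fc, log2fc = log2(fc), undefined = undef,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene two-group comparison
#'
#' Plain Welch t-test per gene on a gene x sample matrix; a convenience for
#' synthetic data when no externally computed p-values are available. Genes
#' where the test is degenerate (e.g. zero variance in both groups) get NA.
#'
#' @inheritParams group_fold_change
#' @return data.frame with `gene` and `p`.
#' @export
deg_test <- function(mat, groups, test_group = "mutant",
                     base_group = "wildtype") {
  stopifnot(ncol(mat) == length(groups))
  x <- mat[, groups == test_group, drop = FALSE]
  y <- mat[, groups == base_group, drop = FALSE]
  p <- vapply(seq_len(nrow(mat)), function(i) {
    tryCatch(stats::t.test(x[i, ], y[i, ])$p.value, error = function(e)
      NA_real_)
  }, numeric(1))
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-expression threshold filter
#'
#' Declares genes differentially expressed when `|log2fc| >= lfc_min` and
#' `p < p_max` (defaults 1 and 0.05; the boundary fold change is retained,
#' the boundary p-value is not). Genes with NA fold change or p-value are
#' excluded.
#'
#' @param df data.frame with columns `gene`, `log2fc`, `p`.
#' @param lfc_min minimum absolute log2 fold change.
#' @param p_max exclusive p-value threshold.
#' @return list with `up`, `down` (character vectors of gene ids), `n_up`,
#'   `n_down`.
#' @export
deg_filter <- function(df, lfc_min = 1, p_max = 0.05) {
  stopifnot(all(c("gene", "log2fc", "p") %in% names(df)))
  ok <- !is.na(df$log2fc) & !is.na(df$p) & df$p < p_max
  up <- df$gene[ok & df$log2fc >= lfc_min]
  down <- df$gene[ok & df$log2fc <= -lfc_min]
  list(up = up, down = down, n_up = length(up), n_down = length(down))
}
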