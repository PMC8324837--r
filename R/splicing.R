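# RNA maturation analysis from exon/intron fragment counts. Intron signal
# reflects unspliced pre-mRNA, so a shift in the exon/intron ratio between
# conditions indicates a splicing change. Per gene: a binomial logistic
# model of exon fragments out of (exon + intron) with condition as the sole
# covariate, BH adjustment across genes, and a splicing score
#   IE = log2( sum over treatment replicates of exon/intron
#            / sum over control replicates of exon/intron ),
# where 0 means no change and negative values mean reduced splicing under
# treatment.

check_splicing_table <- function(table) {
  need <- c("gene_id", "condition", "replicate", "exon_count", "intron_count")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("splicing table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(table$exon_count < 0) || any(table$intron_count < 0)) {
    stopf("counts must be nonnegative")
  }
  conds <- unique(table$condition)
  if (!all(c("control", "treatment") %in% conds)) {
    stopf("table must contain both 'control' and 'treatment' conditions")
  }
  invisible(table)
}

#' Per-gene logistic test of the exon/intron ratio
#'
#' Fits, per gene, `glm(cbind(exon, intron) ~ condition, family = binomial)`
#' and reports the Wald p-value of the condition coefficient. Genes whose
#' fit is degenerate (zero totals, perfect separation yielding an unstable
#' coefficient) get `p = NA` with a reason instead of an error.
#'
#' @param table Data.frame with columns `gene_id, condition, replicate,
#'   exon_count, intron_count`; conditions `control` and `treatment`.
#' @return Data.frame `gene_id, estimate, p_value, note` (one row per gene;
#'   `estimate` is the log-odds shift of exon fraction under treatment).
#' @export
exon_intron_glm <- function(table) {
  check_splicing_table(table)
  genes <- split(table, table$gene_id)
  out <- lapply(names(genes), function(g) {
    d <- genes[[g]]
    res <- data.frame(gene_id = g, estimate = NA_real_, p_value = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    if (any(d$exon_count + d$intron_count == 0)) {
      res$note <- "zero total count in a replicate"
      return(res)
    }
    cond <- factor(d$condition, levels = c("control", "treatment"))
    fit <- tryCatch(
      suppressWarnings(stats::glm(cbind(exon_count, intron_count) ~ cond,
                                  family = stats::binomial(), data = d)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      res$note <- "glm failed"
      return(res)
    }
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L || !is.finite(co[2, 4])) {
      res$note <- "degenerate fit"
      return(res)
    }
    res$estimate <- co[2, 1]
    res$p_value <- co[2, 4]
    res
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); `NA` p-values are passed through.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene splicing score
#'
#' `IE = log2( sum_treatment(exon/intron) / sum_control(exon/intron) )`,
#' with the sums running over replicates' per-replicate ratios. A gene with
#' a zero intron count in any replicate is flagged and gets `IE = NA`
#' (the score is undefined there), unless a `pseudocount` is supplied.
#'
#' @param table Splicing count table (see [exon_intron_glm()]).
#' @param pseudocount Optional count added to exons and introns before the
#'   ratio; default `0` (off).
#' @return Data.frame `gene_id, IE, zero_intron`.
#' @export
splicing_score <- function(table, pseudocount = 0) {
  check_splicing_table(table)
  genes <- split(table, table$gene_id)
  out <- lapply(names(genes), function(g) {
    d <- genes[[g]]
    zero <- any(d$intron_count == 0) && pseudocount == 0
    ie <- if (zero) NA_real_ else {
      r <- (d$exon_count + pseudocount) / (d$intron_count + pseudocount)
      log2(sum(r[d$condition == "treatment"]) / sum(r[d$condition == "control"]))
    }
    data.frame(gene_id = g, IE = ie, zero_intron = zero, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full splicing analysis
#'
#' Per-gene logistic test, BH adjustment, splicing score, and significance
#' flag at `alpha`.
#'
#' @inheritParams exon_intron_glm
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param pseudocount Passed to [splicing_score()].
#' @return Data.frame `gene_id, estimate, p_value, p_adj, IE, zero_intron,
#'   significant, note`.
#' @export
analyze_splicing <- function(table, alpha = 0.05, pseudocount = 0) {
  glm_res <- exon_intron_glm(table)
  glm_res$p_adj <- bh_adjust(glm_res$p_value)
  ie <- splicing_score(table, pseudocount = pseudocount)
  res <- merge(glm_res, ie, by = "gene_id", sort = TRUE)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res[, c("gene_id", "estimate", "p_value", "p_adj", "IE", "zero_intron",
          "significant", "note")]
}

#' Splicing-score distribution of significant genes
#'
#' @param results Output of [analyze_splicing()].
#' @param alpha FDR level (default 0.05).
#' @return List with `IE` (scores of significant genes, NA dropped),
#'   `n_significant`, and `median_IE`.
#' @export
splicing_summary <- function(results, alpha = 0.05) {
  sig <- results[!is.na(results$p_adj) & results$p_adj < alpha, , drop = FALSE]
  ie <- sig$IE[!is.na(sig$IE)]
  list(IE = ie, n_significant = nrow(sig),
       median_IE = if (length(ie)) stats::median(ie) else NA_real_)
}

#' Read/write splicing count tables as TSV
#' @param path TSV path with the standard exon/intron column layout.
#' @export
read_splicing_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  check_splicing_table(tab)
}

#' @rdname read_splicing_table
#' @param table Splicing count table.
#' @export
write_splicing_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
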