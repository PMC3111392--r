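#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) of a log2 intensity matrix onto the same
#' distribution: the sorted values of each column are replaced by the
#' row-wise mean of the column-wise order statistics. Ties within a column
#' receive the average of the reference values across the tied ranks. The
#' operation is idempotent. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param m Numeric matrix, probes as rows, samples as columns; at least
#'   two columns and no missing values.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(matrix(c(1, 5, 3, 7), 2, 2))
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`m` must be a numeric matrix", call. = FALSE)
  }
  if (ncol(m) < 2) stop("need at least 2 columns", call. = FALSE)
  if (any(!is.finite(m))) {
    stop("missing or non-finite values are not allowed", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Discovery-stage expression screen over the four group comparisons
#'
#' Runs the array screening filter on a summarized log2 expression matrix:
#' for each of the four genotype comparisons (wild type vs all knockouts
#' pooled, wild type vs each knockout arm, and knockout vs knockout), every
#' probe is tested with an unpaired pooled-variance Student t-test,
#' p-values are Benjamini-Hochberg adjusted across probes within the
#' comparison, and the fold change is taken from the difference of group
#' mean log2 intensities. A probe is selected when its fold change is at
#' least `fc_threshold` and its adjusted p-value is below `alpha`.
#'
#' @param m Log2 expression matrix (probes x samples). Apply
#'   [quantile_normalize()] first if the columns are not yet on a common
#'   distribution.
#' @param sample_sheet `data.frame` with columns `sample`, `group`
#'   (`WT`/`GKO`/`KKO`) labelling each column of `m`.
#' @param fc_threshold Fold-change filter (default 1.5).
#' @param alpha Adjusted-p filter (default 0.05).
#' @param level Summarization tag carried through to the hits
#'   (`"gene"` or `"exon"`).
#' @return List with `hits` (one row per probe x comparison: `probe`,
#'   `comparison`, `level`, `log2fc`, `fc`, `direction`, `p_raw`, `p_adj`,
#'   `selected`), `union` (probe identifiers selected in any comparison,
#'   the unique-gene set of the screen), and `near_misses` (unselected
#'   probes ranked by adjusted p, for manual review).
#' @examples
#' sheet <- data.frame(sample = paste0("s", 1:9),
#'                     group = rep(c("WT", "GKO", "KKO"), each = 3))
#' sim <- generate_expression_matrix(20, sheet,
#'   planted = data.frame(probe = 3, comparison = "WT_vs_GKO", log2fc = 2),
#'   noise_sd = 0.1, seed = 1)
#' scr <- screen_comparisons(sim$matrix, sheet)
#' scr$union
#' @export
screen_comparisons <- function(m, sample_sheet, fc_threshold = 1.5,
                               alpha = 0.05, level = c("gene", "exon")) {
  level <- match.arg(level)
  if (!is.data.frame(sample_sheet) ||
      !all(c("sample", "group") %in% names(sample_sheet))) {
    stop("`sample_sheet` needs columns sample and group", call. = FALSE)
  }
  bad <- setdiff(unique(sample_sheet$group), c("WT", "GKO", "KKO"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(m) != nrow(sample_sheet)) {
    stop("sample sheet does not match the matrix columns", call. = FALSE)
  }
  probes <- rownames(m) %||% sprintf("probe_%04d", seq_len(nrow(m)))
  comparisons <- screen_comparison_groups()
  hits <- list()
  for (cmp in names(comparisons)) {
    ga <- comparisons[[cmp]]$a
    gb <- comparisons[[cmp]]$b
    ia <- which(sample_sheet$group %in% ga)
    ib <- which(sample_sheet$group %in% gb)
    if (length(ia) < 2 || length(ib) < 2) {
      stop(sprintf("comparison %s needs >= 2 samples per group", cmp),
           call. = FALSE)
    }
    res <- t(apply(m, 1, function(x) {
      tt <- stats::t.test(x[ib], x[ia], var.equal = TRUE)
      c(log2fc = unname(tt$estimate[1] - tt$estimate[2]),
        p_raw = tt$p.value)
    }))
    p_adj <- benjamini_hochberg(res[, "p_raw"])
    log2fc <- res[, "log2fc"]
    fc <- 2^abs(log2fc)
    hits[[cmp]] <- data.frame(
      probe = probes,
      comparison = cmp,
      level = level,
      log2fc = log2fc,
      fc = fc,
      direction = ifelse(log2fc == 0, "none",
                         ifelse(log2fc > 0, "Up", "Down")),
      p_raw = res[, "p_raw"],
      p_adj = p_adj,
      selected = fc >= fc_threshold & p_adj < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL
  near <- hits[!hits$selected & (hits$fc >= fc_threshold |
                                   hits$p_adj < alpha), ]
  near <- near[order(near$p_adj, -near$fc), ]
  list(hits = hits,
       union = unique(hits$probe[hits$selected]),
       near_misses = utils::head(near, 20))
}
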