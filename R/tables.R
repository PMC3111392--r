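#' Build the four regulation-class report tables
#'
#' Lays out a collection of classified genes the way the study reports
#' them: one table per regulation class, fold changes printed to two
#' decimals with the 95% CI in parentheses, and a `Direction` column per
#' contrast. The interaction-class table carries four contrast blocks
#' (genotype effect within each hormonal group, hormonal effect within
#' each genotype); the independent-effects table carries two; the
#' single-effect tables one. Only calls whose `passes_fc_filter` flag is
#' set are listed; `none` calls are never listed. Both the term-specific
#' and the omnibus p-values are emitted, clearly labelled.
#'
#' @param calls List of [classify_regulation()] results (ideally after
#'   [adjust_regulation_calls()]).
#' @return Named list of four `data.frame`s: `hormone_only`,
#'   `genotype_only`, `both_independent`, `both_interacting`. Empty classes
#'   give zero-row tables with headers.
#' @export
report_tables <- function(calls) {
  stopifnot(all(vapply(calls, inherits, logical(1), "regulation_call")))
  fc_str <- function(ct) {
    sprintf("%.2f(%.2f-%.2f)", ct$fc, ct$ci_low, ct$ci_high)
  }
  row_for <- function(call, labels, colnames_fc) {
    ctr <- call$contrasts
    out <- data.frame(genotype_arm = call$genotype_arm,
                      gene = call$gene,
                      loading_control = call$loading_control,
                      stringsAsFactors = FALSE)
    for (k in seq_along(labels)) {
      ct <- ctr[ctr$label == labels[k], ]
      out[[paste0(colnames_fc[k], "_fc_ci")]] <- fc_str(ct)
      out[[paste0(colnames_fc[k], "_direction")]] <- ct$direction
    }
    out$term_p <- unname(switch(call$reg_class,
      hormone_only = call$term_p[["gene_hormone"]],
      genotype_only = call$term_p[["gene_genotype"]],
      both_independent = min(call$term_p[["gene_genotype"]],
                             call$term_p[["gene_hormone"]]),
      both_interacting = call$term_p[["three_way"]]
    ))
    out$omnibus_p <- call$omnibus_p
    out$omnibus_p_adj <- call$omnibus_p_adj
    out
  }
  layouts <- list(
    hormone_only = list(labels = "hormone_effect", cols = "hormonal"),
    genotype_only = list(labels = "genotype_effect", cols = "genotype"),
    both_independent = list(
      labels = c("genotype_effect", "hormone_effect"),
      cols = c("genotype", "hormonal")),
    both_interacting = list(
      labels = c("genotype_within_placebo", "genotype_within_T",
                 "hormone_within_WT", "hormone_within_KO"),
      cols = c("genotype_no_T", "genotype_T", "hormonal_WT", "hormonal_KO"))
  )
  out <- list()
  for (cls in names(layouts)) {
    lay <- layouts[[cls]]
    keep <- Filter(function(x) x$reg_class == cls && x$passes_fc_filter,
                   calls)
    if (length(keep)) {
      out[[cls]] <- do.call(rbind, lapply(keep, row_for,
                                          labels = lay$labels,
                                          colnames_fc = lay$cols))
    } else {
      # zero-row table with the class's full header
      tmpl <- row_for(empty_call_template(cls), lay$labels, lay$cols)
      out[[cls]] <- tmpl[0, , drop = FALSE]
    }
  }
  out
}

empty_call_template <- function(cls) {
  labels <- switch(cls,
    hormone_only = "hormone_effect",
    genotype_only = "genotype_effect",
    both_independent = c("genotype_effect", "hormone_effect"),
    both_interacting = c("genotype_within_placebo", "genotype_within_T",
                         "hormone_within_WT", "hormone_within_KO"))
  ctr <- do.call(rbind, lapply(labels, new_ddct_contrast, ddct = 0, se = 1))
  structure(list(gene = "", loading_control = "", genotype_arm = "",
                 reg_class = cls, omnibus_p = 1, omnibus_p_adj = 1,
                 term_p = c(three_way = 1, gene_genotype = 1,
                            gene_hormone = 1),
                 contrasts = ctr, passes_fc_filter = TRUE),
            class = "regulation_call")
}

#' Write the report tables as TSV and aligned text
#'
#' @param tables Result of [report_tables()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(tables, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cls in names(tables)) {
    tsv <- file.path(dir, paste0("class_", cls, ".tsv"))
    utils::write.table(tables[[cls]], tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    txt <- file.path(dir, paste0("class_", cls, ".txt"))
    writeLines(utils::capture.output(print(tables[[cls]],
                                           row.names = FALSE)), txt)
    paths <- c(paths, tsv, txt)
  }
  invisible(paths)
}
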