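#' Simulate a probe-by-sample expression matrix with planted fold changes
#'
#' Generates Gaussian log2 intensities around a common baseline and plants
#' mean shifts for selected probes between named comparison groups. Used to
#' exercise the discovery-stage screen ([screen_comparisons()]) against a
#' known truth table.
#'
#' A planted `log2fc` for comparison `"A_vs_B"` is added to the samples of
#' the second-named group (`B`); for the pooled `"WT_vs_KO"` comparison it is
#' added to all knockout (`GKO` and `KKO`) samples. Positive `log2fc`
#' therefore means higher expression on the knockout side.
#'
#' @param n_probes Number of probes (rows).
#' @param groups Sample sheet: `data.frame` with columns `sample` and
#'   `group`, groups drawn from `WT`, `GKO`, `KKO`; each compared group
#'   needs at least 2 samples.
#' @param planted `data.frame` with columns `probe` (row index),
#'   `comparison` (one of `WT_vs_KO`, `WT_vs_GKO`, `WT_vs_KKO`,
#'   `GKO_vs_KKO`) and `log2fc`, or `NULL` for none.
#' @param noise_sd Within-group SD of log2 intensities (> 0).
#' @param seed Integer seed.
#' @param baseline Baseline mean log2 intensity.
#' @return A list with `matrix` (probes x samples, dimnames set),
#'   `sample_sheet`, and `truth` (the planted table, empty if none).
#' @examples
#' sheet <- data.frame(sample = paste0("s", 1:6),
#'                     group = rep(c("WT", "GKO"), each = 3))
#' sim <- generate_expression_matrix(50, sheet,
#'   planted = data.frame(probe = 7, comparison = "WT_vs_GKO", log2fc = 2),
#'   noise_sd = 0.2, seed = 1)
#' dim(sim$matrix)
#' @export
generate_expression_matrix <- function(n_probes, groups, planted = NULL,
                                       noise_sd = 0.25, seed = 1,
                                       baseline = 8) {
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    stop("`groups` must be a data.frame with columns sample and group",
         call. = FALSE)
  }
  if (!all(groups$group %in% c("WT", "GKO", "KKO"))) {
    stop("group labels must be WT, GKO or KKO", call. = FALSE)
  }
  tab <- table(groups$group)
  if (any(tab < 2)) {
    stop("design error: every group needs >= 2 samples (t-test undefined); ",
         "offending group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be > 0", call. = FALSE)
  }
  comparisons <- screen_comparison_groups()
  truth <- data.frame(probe = integer(), comparison = character(),
                      log2fc = numeric(), stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted)) {
    if (!all(c("probe", "comparison", "log2fc") %in% names(planted))) {
      stop("`planted` needs columns probe, comparison, log2fc", call. = FALSE)
    }
    if (any(planted$probe < 1 | planted$probe > n_probes)) {
      stop("planted probe index out of range", call. = FALSE)
    }
    if (!all(planted$comparison %in% names(comparisons))) {
      stop("unknown comparison in `planted`; expected one of ",
           paste(names(comparisons), collapse = ", "), call. = FALSE)
    }
    truth <- planted[, c("probe", "comparison", "log2fc")]
  }

  n_samples <- nrow(groups)
  m <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_probes * n_samples, baseline, noise_sd),
                n_probes, n_samples)
    for (r in seq_len(nrow(truth))) {
      shifted <- comparisons[[truth$comparison[r]]]$b
      cols <- groups$group %in% shifted
      m[truth$probe[r], cols] <- m[truth$probe[r], cols] + truth$log2fc[r]
    }
    m
  })
  dimnames(m) <- list(sprintf("probe_%04d", seq_len(n_probes)), groups$sample)
  list(matrix = m, sample_sheet = groups, truth = truth)
}

# The four discovery-screen comparisons: group a vs group(s) b.
screen_comparison_groups <- function() {
  list(
    WT_vs_KO  = list(a = "WT",  b = c("GKO", "KKO")),
    WT_vs_GKO = list(a = "WT",  b = "GKO"),
    WT_vs_KKO = list(a = "WT",  b = "KKO"),
    GKO_vs_KKO = list(a = "GKO", b = "KKO")
  )
}
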