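#' Pipeline configuration
#'
#' Central knob set shared by the command-style entry points of
#' [run_pipeline()]. All randomness flows from the single `seed`, expanded
#' deterministically per stage; no hidden global RNG state is used.
#'
#' @param alpha Significance level for every test stage (0 < alpha < 1).
#' @param fc_threshold Fold-change reporting filter (>= 1).
#' @param ci_z Normal quantile of the fold-change CIs.
#' @param loading_controls Loading-control names analyzed per gene.
#' @param seed Top-level integer seed.
#' @param illumination Illumination constant for densitometry (`NULL` =
#'   estimate per image batch).
#' @param ball_radius Background-subtraction radius, pixels.
#' @param min_area Minimum nucleus area, pixels.
#' @param out_dir Output directory for artifacts.
#' @param verbose Log filter decisions to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, fc_threshold = 1.5,
                            ci_z = 1.959964,
                            loading_controls = c("18S", "Gapdh"),
                            seed = 1, illumination = NULL,
                            ball_radius = 15, min_area = 20,
                            out_dir = ".", verbose = TRUE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, fc_threshold = fc_threshold, ci_z = ci_z,
                 loading_controls = loading_controls, seed = seed,
                 illumination = illumination, ball_radius = ball_radius,
                 min_area = min_area, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
}

#' Run one pipeline stage end to end
#'
#' File-to-file driver over the package's functions. Outputs are
#' deterministic given the configuration seed; a JSON run manifest
#' (inputs, configuration, package version, seeds) is written alongside
#' the results so any run can be reproduced byte-identically. Stage errors
#' propagate as R errors carrying the stage name.
#'
#' Commands:
#' * `simulate` - write a simulated Ct table and its ground truth
#'   (`input` = an [effect_spec()], or `NULL` for the default spec).
#' * `fit` - fit the mixed model to a Ct CSV and write a fit report.
#' * `classify` - classify every test gene in a Ct CSV against each
#'   loading control present; writes the four class tables and a calls
#'   summary.
#' * `screen` - run [screen_comparisons()] on a TSV matrix + sample sheet
#'   (paths in `input$matrix`, `input$sample_sheet`); writes hits and the
#'   union list.
#' * `quantify-ish` - run [quantify_ish()] on each image path in `input`;
#'   writes a per-object CSV per image.
#'
#' @param config A [pipeline_config()].
#' @param command One of `simulate`, `fit`, `classify`, `screen`,
#'   `quantify-ish`.
#' @param input Command-specific input (see above): a path, a list of
#'   paths, or an `effect_spec`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config, command, input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command, c("simulate", "fit", "classify", "screen",
                                  "quantify-ish"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  out <- file.path(config$out_dir)
  artifacts <- tryCatch(
    switch(command,
      "simulate" = stage_simulate(config, input, out),
      "fit" = stage_fit(config, input, out),
      "classify" = stage_classify(config, input, out),
      "screen" = stage_screen(config, input, out),
      "quantify-ish" = stage_quantify_ish(config, input, out)
    ),
    error = function(e) {
      stop(sprintf("[%s] %s", command, conditionMessage(e)), call. = FALSE)
    }
  )
  manifest <- list(
    command = command,
    input = if (is.character(input)) input else
      if (inherits(input, "effect_spec")) unclass(input) else input,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("qpcrlmm")),
    r_version = R.version.string,
    artifacts = artifacts
  )
  mpath <- file.path(out, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(artifacts, manifest = mpath))
}

stage_simulate <- function(config, input, out) {
  spec <- input %||% effect_spec()
  if (!inherits(spec, "effect_spec")) {
    stop("simulate needs an effect_spec (or NULL for defaults)")
  }
  d <- generate_ct_dataset(spec, seed = child_seed(config$seed, 1))
  ct_path <- file.path(out, "simulated_ct.csv")
  write_ct_table(d, ct_path)
  truth_path <- file.path(out, "simulated_ct_truth.csv")
  utils::write.csv(as.data.frame(unclass(spec)[1:12]), truth_path,
                   row.names = FALSE)
  log_msg(config, "simulate: wrote %d observations", nrow(d))
  list(ct = ct_path, truth = truth_path)
}

stage_fit <- function(config, input, out) {
  d <- read_ct_table(input)
  fit <- fit_mixed_model(d)
  se <- sqrt(diag(fit$vcov))
  rep_df <- data.frame(term = names(fit$coefficients),
                       estimate = fit$coefficients, se = se,
                       row.names = NULL)
  fit_path <- file.path(out, "fit_report.csv")
  utils::write.csv(rep_df, fit_path, row.names = FALSE)
  vc_path <- file.path(out, "fit_variance_components.csv")
  utils::write.csv(data.frame(component = c("sigma_alpha", "sigma_eps"),
                              estimate = c(fit$sigma_alpha,
                                           fit$sigma_eps)),
                   vc_path, row.names = FALSE)
  txt_path <- file.path(out, "fit_report.txt")
  writeLines(utils::capture.output(print(fit)), txt_path)
  log_msg(config, "fit: %d obs, %d animals, sigma_alpha=%.3f sigma_eps=%.3f",
          fit$n_obs, fit$n_animals, fit$sigma_alpha, fit$sigma_eps)
  list(report = fit_path, variance_components = vc_path, text = txt_path)
}

stage_classify <- function(config, input, out) {
  d <- read_ct_table(input)
  genes <- unique(d$gene[d$role == "test"])
  controls <- intersect(unique(d$gene[d$role == "loading_control"]),
                        config$loading_controls)
  if (!length(controls)) {
    controls <- unique(d$gene[d$role == "loading_control"])
  }
  calls <- list()
  for (ctrl in controls) {
    family <- list()
    for (g in genes) {
      sub <- d[(d$gene == g & d$role == "test") |
                 (d$gene == ctrl & d$role == "loading_control"), ]
      family[[g]] <- classify_regulation(
        sub, alpha = config$alpha, fc_threshold = config$fc_threshold,
        z = config$ci_z)
    }
    calls <- c(calls, adjust_regulation_calls(family))
  }
  tables <- report_tables(calls)
  paths <- write_report_tables(tables, out)
  summary_df <- do.call(rbind, lapply(calls, function(x) {
    data.frame(gene = x$gene, loading_control = x$loading_control,
               reg_class = x$reg_class, omnibus_p = x$omnibus_p,
               omnibus_p_adj = x$omnibus_p_adj,
               passes_fc_filter = x$passes_fc_filter)
  }))
  sum_path <- file.path(out, "regulation_calls.csv")
  utils::write.csv(summary_df, sum_path, row.names = FALSE)
  log_msg(config, "classify: %d gene/control pairings; %d pass the %.2g-fold filter",
          nrow(summary_df), sum(summary_df$passes_fc_filter),
          config$fc_threshold)
  c(list(calls = sum_path), as.list(paths))
}

stage_screen <- function(config, input, out) {
  m <- read_expression_matrix(input$matrix)
  sheet <- read_sample_sheet(input$sample_sheet)
  m <- quantile_normalize(m)
  scr <- screen_comparisons(m, sheet, fc_threshold = config$fc_threshold,
                            alpha = config$alpha)
  hits_path <- file.path(out, "screen_hits.tsv")
  utils::write.table(scr$hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  union_path <- file.path(out, "screen_union.txt")
  writeLines(scr$union, union_path)
  log_msg(config, "screen: %d probe-comparison tests, %d selected, %d unique probes",
          nrow(scr$hits), sum(scr$hits$selected), length(scr$union))
  list(hits = hits_path, union = union_path)
}

stage_quantify_ish <- function(config, input, out) {
  paths <- character(0)
  for (img_path in input) {
    img <- read_rgb_image(img_path)
    res <- quantify_ish(img, illumination = config$illumination,
                        ball_radius = config$ball_radius,
                        min_area = config$min_area)
    obj_path <- file.path(
      out, paste0(tools::file_path_sans_ext(basename(img_path)),
                  "_objects.csv"))
    utils::write.csv(res$objects, obj_path, row.names = FALSE)
    log_msg(config, "quantify-ish: %s -> %d objects (threshold %.1f)",
            basename(img_path), nrow(res$objects), res$threshold)
    paths <- c(paths, obj_path)
  }
  list(objects = paths)
}
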