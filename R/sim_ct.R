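#' Simulate a factorial QPCR Ct dataset with known ground truth
#'
#' Draws a long-format Ct table from the factorial mixed model encoded in an
#' [effect_spec()]: each animal receives one Gaussian random intercept
#' (SD `sigma_alpha`) shared by all of its observations, and every technical
#' replicate adds independent Gaussian noise (SD `sigma_eps`) on top of the
#' cell's linear predictor. Animal identifiers never recur across
#' (genotype, hormone) cells, matching the nesting of animals within
#' experimental groups.
#'
#' @param spec An [effect_spec()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param gene Name recorded for test-gene rows.
#' @param control Name recorded for loading-control rows.
#' @return A `data.frame` with columns `gene`, `role`
#'   (`loading_control`/`test`), `genotype` (`wild_type`/`knockout`),
#'   `hormone` (`placebo`/`testosterone`, or `not_applicable` for intact
#'   designs), `animal`, `rep` and `ct` (cycles).
#' @examples
#' d <- generate_ct_dataset(effect_spec(delta_gamma = -1), seed = 1)
#' head(d)
#' @export
generate_ct_dataset <- function(spec, seed, gene = "Gene1",
                                control = "Gapdh") {
  if (!inherits(spec, "effect_spec")) {
    stop("`spec` must be an effect_spec object", call. = FALSE)
  }
  validate_effect_spec(spec)
  hormones <- if (spec$design == "intact_2x2") "not_applicable" else
    c("placebo", "testosterone")
  cells <- expand.grid(genotype = c("wild_type", "knockout"),
                       hormone = hormones, stringsAsFactors = FALSE)
  na <- spec$n_animals_per_cell
  nr <- spec$n_tech_reps

  with_seed(seed, {
    rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      g <- cells$genotype[ci]
      h <- cells$hormone[ci]
      ti <- c(loading_control = 0, test = 1)
      gi <- as.numeric(g == "knockout")
      hi <- as.numeric(h == "testosterone")
      animal_ids <- sprintf("%s_%s_a%d",
                            c(wild_type = "wt", knockout = "ko")[g],
                            c(placebo = "P", testosterone = "T",
                              not_applicable = "I")[h],
                            seq_len(na))
      alpha <- stats::rnorm(na, 0, spec$sigma_alpha)
      cell <- expand.grid(role = c("loading_control", "test"),
                          animal = animal_ids,
                          rep = seq_len(nr),
                          stringsAsFactors = FALSE)
      t_ind <- ti[cell$role]
      mean_ct <- spec$mu + spec$delta * t_ind + spec$gamma * gi +
        spec$tau * hi + spec$delta_gamma * t_ind * gi +
        spec$delta_tau * t_ind * hi + spec$gamma_tau * gi * hi +
        spec$delta_gamma_tau * t_ind * gi * hi
      a_ind <- match(cell$animal, animal_ids)
      eps <- stats::rnorm(nrow(cell), 0, spec$sigma_eps)
      rows[[ci]] <- data.frame(
        gene = ifelse(cell$role == "test", gene, control),
        role = cell$role,
        genotype = g,
        hormone = h,
        animal = cell$animal,
        rep = cell$rep,
        ct = mean_ct + alpha[a_ind] + eps,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
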