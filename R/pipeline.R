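#' Screening-pipeline configuration
#'
#' Thresholds for the multi-stage switch screen: keep the `top_fraction` of
#' genes by delta-AIC rank, pass genes whose separation D against the target
#' phenotype exceeds `d_min` (default 1.8, "greater than or close to 2"),
#' validate on an independent paired dataset at `enrichment_alpha` after
#' multiple-testing adjustment, and classify switch types by mixture-mode
#' occupancy: Type 1 when both modes hold at least `type1_minor_mode_min` of
#' the target samples (bimodal within the target phenotype), Type 2 when at
#' least `type2_on_fraction_min` of target samples sit in one mode and the
#' other samples predominantly occupy the opposite mode.
#'
#' @param top_fraction fraction (0, 1] of genes kept by delta-AIC rank.
#' @param d_min separation-D screening threshold.
#' @param type1_minor_mode_min minimum minor-mode occupancy among target
#'   samples for a Type 1 call.
#' @param type2_on_fraction_min minimum same-mode occupancy (target) and
#'   opposite-mode occupancy (others) for a Type 2 call.
#' @param enrichment_alpha significance level for validation and enrichment.
#' @param multiple_testing `stats::p.adjust` method name.
#' @return A `screen_config` list.
#' @export
screen_config <- function(top_fraction = 0.10, d_min = 1.8,
                          type1_minor_mode_min = 0.15,
                          type2_on_fraction_min = 0.90,
                          enrichment_alpha = 0.05,
                          multiple_testing = "BH") {
  cfg <- list(top_fraction = top_fraction, d_min = d_min,
              type1_minor_mode_min = type1_minor_mode_min,
              type2_on_fraction_min = type2_on_fraction_min,
              enrichment_alpha = enrichment_alpha,
              multiple_testing = multiple_testing)
  for (nm in c("top_fraction", "type1_minor_mode_min", "type2_on_fraction_min",
               "enrichment_alpha")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) validation_error("`%s` must be in (0, 1]", nm)
  }
  if (cfg$d_min <= 0) validation_error("`d_min` must be positive")
  structure(cfg, class = "screen_config")
}

check_annotations <- function(annotations, sample_ids) {
  if (!all(c("sample_id", "phenotype") %in% names(annotations))) {
    validation_error("annotations need `sample_id` and `phenotype` columns")
  }
  idx <- match(sample_ids, annotations$sample_id)
  if (anyNA(idx)) {
    validation_error("annotations missing samples: %s",
                     paste(head(sample_ids[is.na(idx)], 5L), collapse = ", "))
  }
  annotations[idx, , drop = FALSE]
}

#' Screen top-ranked bimodal genes for a phenotype-specific state
#'
#' Stage one/two of the switch-mining pipeline: take the top
#' `ceiling(top_fraction * G)` genes by delta-AIC (ties broken by gene id for
#' determinism), compute the separation D between the target-phenotype samples
#' and all other samples, and flag genes with `D > d_min` as passing the
#' screen.
#'
#' @param scores score table from [score_bimodality()].
#' @param x expression matrix (genes x samples) the scores came from.
#' @param annotations tibble with `sample_id` and `phenotype` covering every
#'   matrix column.
#' @param target_label phenotype whose samples define the target condition
#'   (>= 2 samples required).
#' @param config a [screen_config()].
#' @return Tibble of switch calls: `gene_id`, `delta_aic`, `delta_aic_rank`,
#'   `D`, group means/SDs, `passed_screen`.
#' @export
screen_switches <- function(scores, x, annotations, target_label,
                            config = screen_config()) {
  m <- as_expression_matrix(x)
  ann <- check_annotations(annotations, colnames(m))
  mask <- ann$phenotype == target_label
  if (sum(mask, na.rm = TRUE) < 2L) {
    validation_error("target phenotype '%s' has fewer than 2 samples", target_label)
  }
  scored <- dplyr::filter(scores, !is.na(.data$delta_aic))
  n_top <- ceiling(config$top_fraction * nrow(scored))
  cand <- scored |>
    dplyr::arrange(dplyr::desc(.data$delta_aic), .data$gene_id) |>
    head(n_top)
  calls <- purrr::map(cand$gene_id, function(g) {
    separation_d(m[g, ], mask, gene_id = g, target_label = target_label)
  }) |> dplyr::bind_rows()
  cand |>
    dplyr::select("gene_id", "delta_aic", delta_aic_rank = "rank") |>
    dplyr::left_join(calls, by = "gene_id") |>
    dplyr::mutate(passed_screen = .data$D > config$d_min) |>
    dplyr::arrange(.data$delta_aic_rank)
}

#' Validate screened genes on an independent paired dataset
#'
#' For each screened gene, fits the two-component mixture on the pooled
#' validation samples, assigns each sample a mode, and tests whether ON-mode
#' occupancy differs between the tumor-side and normal-side samples of the
#' pairs (two-sided Fisher exact test on the 2x2 mode-by-group table,
#' adjusted across genes). A gene is `validated` when the adjusted p-value
#' falls below `enrichment_alpha`. Genes absent from the validation matrix are
#' marked not validated with reason `"absent"`.
#'
#' @param calls switch-call table from [screen_switches()]; only genes with
#'   `passed_screen` are tested.
#' @param x validation expression matrix sharing gene identifiers.
#' @param pairs tibble with columns `pair_id`, `tumor_sample`, `normal_sample`
#'   naming columns of the validation matrix.
#' @param config a [screen_config()].
#' @param seed deterministic EM seeding for the validation fits.
#' @return `calls` with `validated`, `validation_p`, `validation_p_adj`, and
#'   `validation_reason` columns added.
#' @export
validate_switches <- function(calls, x, pairs, config = screen_config(),
                              seed = 0L) {
  m <- as_expression_matrix(x)
  need <- c("pair_id", "tumor_sample", "normal_sample")
  if (!all(need %in% names(pairs))) {
    validation_error("`pairs` needs columns %s", paste(need, collapse = ", "))
  }
  missing_samples <- setdiff(c(pairs$tumor_sample, pairs$normal_sample), colnames(m))
  if (length(missing_samples) > 0L) {
    validation_error("validation matrix missing samples: %s",
                     paste(head(missing_samples, 5L), collapse = ", "))
  }
  genes <- calls$gene_id[calls$passed_screen]
  if (length(intersect(genes, rownames(m))) == 0L && length(genes) > 0L) {
    validation_error("no screened gene is present in the validation matrix")
  }
  cols <- c(pairs$tumor_sample, pairs$normal_sample)
  group <- rep(c("tumor", "normal"), each = nrow(pairs))
  res <- purrr::map(genes, function(g) {
    if (!g %in% rownames(m)) {
      return(tibble::tibble(gene_id = g, validation_p = NA_real_,
                            validation_reason = "absent"))
    }
    fit <- delta_aic(m[g, cols], gene_id = g, seed = seed + match(g, genes))
    tab <- table(factor(fit$mode_assignment, levels = c("low", "high")),
                 factor(group, levels = c("tumor", "normal")))
    p <- fisher.test(tab)$p.value
    tibble::tibble(gene_id = g, validation_p = p, validation_reason = NA_character_)
  }) |> dplyr::bind_rows()
  if (nrow(res) > 0L) {
    res$validation_p_adj <- p.adjust(res$validation_p, method = config$multiple_testing)
    res$validated <- !is.na(res$validation_p_adj) &
      res$validation_p_adj < config$enrichment_alpha
  } else {
    res <- tibble::tibble(gene_id = character(), validation_p = numeric(),
                          validation_reason = character(),
                          validation_p_adj = numeric(), validated = logical())
  }
  calls |>
    dplyr::left_join(res, by = "gene_id") |>
    dplyr::mutate(validated = dplyr::coalesce(.data$validated, FALSE))
}

#' Classify validated switches into Type 1 / Type 2
#'
#' Uses the global two-component fit's mode assignments: among target-phenotype
#' samples, a gene is **Type 1** when both modes are substantially occupied
#' (each holding at least `type1_minor_mode_min` of target samples — bimodal
#' within the target phenotype), and **Type 2** when at least
#' `type2_on_fraction_min` of target samples sit in one mode while the other
#' samples predominantly (same threshold) occupy the opposite mode. Genes
#' meeting neither rule get `"none"`. Only calls with `passed_screen` and
#' `validated` are classified; others are skipped with a reason.
#'
#' @inheritParams screen_switches
#' @param calls output of [validate_switches()].
#' @param seed deterministic EM seeding for the global fits.
#' @return `calls` with `switch_type`, `on_fraction_target`,
#'   `on_fraction_other`, and `classify_reason` columns added.
#' @export
classify_switch_types <- function(calls, x, annotations, target_label,
                                  config = screen_config(), seed = 0L) {
  m <- as_expression_matrix(x)
  ann <- check_annotations(annotations, colnames(m))
  mask <- ann$phenotype == target_label
  res <- purrr::map(seq_len(nrow(calls)), function(i) {
    g <- calls$gene_id[i]
    if (!isTRUE(calls$passed_screen[i]) || !isTRUE(calls$validated[i])) {
      return(tibble::tibble(gene_id = g, switch_type = "none",
                            on_fraction_target = NA_real_,
                            on_fraction_other = NA_real_,
                            classify_reason = "not screened/validated"))
    }
    fit <- delta_aic(m[g, ], gene_id = g, seed = seed + i)
    high <- fit$mode_assignment == "high"
    f_t <- mean(high[mask])
    f_o <- mean(high[!mask])
    type <- "none"
    if (min(f_t, 1 - f_t) >= config$type1_minor_mode_min) {
      type <- "type1"
    } else if ((f_t >= config$type2_on_fraction_min &&
                (1 - f_o) >= config$type2_on_fraction_min) ||
               ((1 - f_t) >= config$type2_on_fraction_min &&
                f_o >= config$type2_on_fraction_min)) {
      type <- "type2"
    }
    tibble::tibble(gene_id = g, switch_type = type,
                   on_fraction_target = f_t, on_fraction_other = f_o,
                   classify_reason = NA_character_)
  }) |> dplyr::bind_rows()
  dplyr::left_join(calls, res, by = "gene_id")
}

#' Mode-by-category enrichment for one bimodal gene
#'
#' Tests whether one of the gene's two expression modes is enriched for
#' samples from the same condition category — e.g. a metabolic switch whose
#' OFF mode collects all "extra carbon source" conditions. For every (mode,
#' category) pair the one-sided hypergeometric over-representation p-value is
#' computed from the overlap, and Benjamini-Hochberg adjustment is applied
#' across all tested pairs.
#'
#' @param fit a [delta_aic()] result (its per-sample mode assignment is used),
#'   or a character vector of `"low"`/`"high"` assignments.
#' @param condition_categories per-sample category labels aligned with the
#'   samples (an "other" bucket is fine).
#' @param multiple_testing `stats::p.adjust` method.
#' @return Tibble: `gene_id`, `mode`, `category`, `overlap`, `mode_size`,
#'   `category_size`, `expected`, `p_value`, `adjusted_p`, sorted by adjusted
#'   then raw p-value.
#' @export
mode_enrichment <- function(fit, condition_categories,
                            multiple_testing = "BH") {
  if (inherits(fit, "bimodality_fit")) {
    modes <- fit$mode_assignment
    gene <- fit$gene_id
  } else {
    modes <- as.character(fit)
    gene <- NA_character_
  }
  if (length(modes) != length(condition_categories)) {
    validation_error("category table is misaligned with the samples (%d vs %d)",
                     length(condition_categories), length(modes))
  }
  keep <- !is.na(modes) & !is.na(condition_categories)
  modes <- modes[keep]
  cats <- as.character(condition_categories[keep])
  n <- length(modes)
  grid <- tidyr::expand_grid(mode = c("low", "high"), category = unique(cats))
  out <- purrr::pmap(grid, function(mode, category) {
    in_mode <- modes == mode
    in_cat <- cats == category
    k <- sum(in_mode & in_cat)
    tibble::tibble(gene_id = gene, mode = mode, category = category,
                   overlap = k, mode_size = sum(in_mode),
                   category_size = sum(in_cat),
                   expected = sum(in_mode) * sum(in_cat) / n,
                   p_value = phyper(k - 1L, sum(in_cat), n - sum(in_cat),
                                    sum(in_mode), lower.tail = FALSE))
  }) |> dplyr::bind_rows()
  out$adjusted_p <- p.adjust(out$p_value, method = multiple_testing)
  dplyr::arrange(out, .data$adjusted_p, .data$p_value)
}

#' Run the full switch-mining pipeline
#'
#' Convenience wrapper chaining [score_bimodality()], [screen_switches()],
#' [validate_switches()] and [classify_switch_types()] on a global expression
#' compendium plus an independent paired validation dataset.
#'
#' @param x global expression matrix (genes x samples).
#' @param annotations sample annotations for the global matrix.
#' @param target_label target phenotype label.
#' @param validation_x independent validation matrix; `NULL` skips validation
#'   (calls are then classified only if they pass the screen and every call's
#'   `validated` is `NA`).
#' @param pairs pairing table for the validation matrix.
#' @param config a [screen_config()].
#' @param seed master seed for all EM fits.
#' @param scores optional precomputed [score_bimodality()] table.
#' @return The final switch-call tibble (see the stage functions).
#' @export
run_switch_pipeline <- function(x, annotations, target_label,
                                validation_x = NULL, pairs = NULL,
                                config = screen_config(), seed = 0L,
                                scores = NULL) {
  scores <- scores %||% score_bimodality(x, seed = seed)
  calls <- screen_switches(scores, x, annotations, target_label, config)
  if (!is.null(validation_x)) {
    calls <- validate_switches(calls, validation_x, pairs, config, seed = seed)
  } else {
    calls$validated <- calls$passed_screen
    calls$validation_p <- NA_real_
    calls$validation_p_adj <- NA_real_
    calls$validation_reason <- "no validation dataset"
  }
  classify_switch_types(calls, x, annotations, target_label, config, seed = seed)
}
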