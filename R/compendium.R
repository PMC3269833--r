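#' Simulate a benchmark compendium with planted switch genes
#'
#' Builds a synthetic expression compendium emulating a large multi-condition
#' microarray collection with a designated target-condition block (labelled
#' `"cancer"`) plus a paired independent validation dataset, with full ground
#' truth. Three gene classes are planted:
#'
#' * **Type 2 switches** — self-activating switch circuits
#'   ([circuit_self_activation()]) receiving an ON-window stimulus in the
#'   target block and an OFF stimulus elsewhere, with initial conditions well
#'   above the activation threshold: nearly all target samples land in the ON
#'   state and all others in OFF.
#' * **Type 1 switches** — the same circuit, but target-block initial
#'   conditions straddle the activation threshold so the target samples split
#'   between ON and OFF (bimodal within the target phenotype) while other
#'   samples stay OFF.
#' * **Unimodal null genes** — iid log-scale Gaussian profiles (gene-specific
#'   mean and spread), identical in distribution across conditions.
#'
#' Each circuit gene is an independent simulation with its own parameter noise
#' (CV `param_cv`) and measurement noise, following the clone-sampling
#' protocol of [simulate_expression()]. Clone-to-clone noise is applied to the
#' kinetic rates (`p`, `d`); the stimulus-coupling constant `K` defines the
#' condition blocks and is held fixed, so "ON stimulus" and "OFF stimulus"
#' remain meaningful condition labels rather than per-clone lotteries. The
#' validation dataset draws `n_pairs` tumor/normal pairs from the same
#' generative process.
#'
#' @param n_type2,n_type1,n_null planted gene counts per class.
#' @param n_samples total global samples; `ceiling(target_fraction *
#'   n_samples)` fall in the target block.
#' @param target_fraction fraction of samples in the target ("cancer") block.
#' @param n_pairs tumor/normal pairs in the validation dataset.
#' @param param_cv,measurement_noise_sd noise levels passed to the circuit
#'   simulations.
#' @param stim_on,stim_off stimulus levels inside/outside the bistable window
#'   of the self-activation circuit (defaults 33 and 5 for the default
#'   parameters, whose ON window is roughly stimulus 23.5-47.2).
#' @param type1_on_target ON-state fraction aimed for among target samples of
#'   Type 1 genes (sets the initial-condition upper bound relative to the
#'   activation threshold); the default 0.8 mirrors an ESR1-like 80/20 split
#'   of the target samples across the two modes.
#' @param seed RNG seed; the compendium is a pure function of its arguments.
#' @return A list with `global` (expression matrix), `annotations`,
#'   `validation` (matrix), `pairs`, and `truth` (gene_id, is_switch,
#'   switch_type, circuit_role).
#' @examples
#' \donttest{
#' comp <- simulate_compendium(n_type2 = 2, n_type1 = 2, n_null = 20,
#'                             n_samples = 60, n_pairs = 10, seed = 1)
#' comp$truth
#' }
#' @export
simulate_compendium <- function(n_type2 = 20, n_type1 = 10, n_null = 970,
                                n_samples = 300, target_fraction = 1 / 3,
                                n_pairs = 40, param_cv = 0.2,
                                measurement_noise_sd = 0.2,
                                stim_on = 33, stim_off = 5,
                                type1_on_target = 0.8, seed = 1L) {
  if (n_samples < 4L) validation_error("`n_samples` must be >= 4")
  with_seed(seed, {
    n_target <- ceiling(target_fraction * n_samples)
    n_other <- n_samples - n_target
    sample_ids <- sprintf("G%04d", seq_len(n_samples))
    phenotype <- c(rep("cancer", n_target), rep("other", n_other))
    # non-target samples spread over a few condition categories
    other_cat <- sort(rep_len(c("tissue_panel", "immune", "neuro"), n_other))
    categories <- c(rep("cancer", n_target), other_cat)
    stim <- ifelse(phenotype == "cancer", stim_on, stim_off)

    tumor_ids <- sprintf("T%03d", seq_len(n_pairs))
    normal_ids <- sprintf("N%03d", seq_len(n_pairs))
    stim_val <- c(rep(stim_on, n_pairs), rep(stim_off, n_pairs))

    # activation threshold of the default circuit at full stimulus (~0.127);
    # type-1 inits straddle it, type-2 inits sit far above it
    thr <- 0.127
    init_hi_type1 <- thr / (1 - type1_on_target)

    sim_gene <- function(role) {
      circuit <- circuit_self_activation()
      params <- lapply(names(circuit$params), function(nm) {
        p <- circuit$params[[nm]]
        if (nm == "K") return(p) # condition design, not clone variation
        p * pmax(rnorm(n_samples + 2L * n_pairs, 1, param_cv), 0.1)
      })
      names(params) <- names(circuit$params)
      upper <- if (role == "type1") init_hi_type1 else 12
      init <- matrix(runif(n_samples + 2L * n_pairs, 0, upper), ncol = 1L)
      res <- rk4_batch(circuit, init, c(stim, stim_val), params,
                       h = 0.01, t_end = 500, steady_tol = 1e-6)
      vals <- log2(pmax(drop(res$final), 0) + 1) +
        rnorm(n_samples + 2L * n_pairs, 0, measurement_noise_sd)
      vals
    }

    n_genes <- n_type2 + n_type1 + n_null
    gene_ids <- c(sprintf("SW2_%03d", seq_len(n_type2)),
                  sprintf("SW1_%03d", seq_len(n_type1)),
                  sprintf("NULL_%04d", seq_len(n_null)))
    all_vals <- matrix(NA_real_, n_genes, n_samples + 2L * n_pairs)
    row <- 0L
    for (j in seq_len(n_type2)) {
      row <- row + 1L
      all_vals[row, ] <- sim_gene("type2")
    }
    for (j in seq_len(n_type1)) {
      row <- row + 1L
      all_vals[row, ] <- sim_gene("type1")
    }
    for (j in seq_len(n_null)) {
      row <- row + 1L
      mu <- runif(1, 2, 8)
      sdv <- runif(1, 0.3, 1)
      all_vals[row, ] <- rnorm(n_samples + 2L * n_pairs, mu, sdv)
    }
    rownames(all_vals) <- gene_ids
    global <- all_vals[, seq_len(n_samples), drop = FALSE]
    colnames(global) <- sample_ids
    validation <- all_vals[, n_samples + seq_len(2L * n_pairs), drop = FALSE]
    colnames(validation) <- c(tumor_ids, normal_ids)

    list(
      global = global,
      annotations = tibble::tibble(sample_id = sample_ids,
                                   phenotype = phenotype,
                                   condition_category = categories),
      validation = validation,
      pairs = tibble::tibble(pair_id = sprintf("P%03d", seq_len(n_pairs)),
                             tumor_sample = tumor_ids,
                             normal_sample = normal_ids),
      truth = tibble::tibble(
        gene_id = gene_ids,
        is_switch = c(rep(TRUE, n_type2 + n_type1), rep(FALSE, n_null)),
        switch_type = c(rep("type2", n_type2), rep("type1", n_type1),
                        rep("none", n_null)),
        circuit_role = c(rep("switch", n_type2 + n_type1), rep("noise", n_null))
      )
    )
  })
}
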