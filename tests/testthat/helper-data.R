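# fixture builders (all programmatic; no files)

null_matrix <- function(genes, samples, seed, mean = 5, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, mean, sd), genes, samples)
  dimnames(m) <- list(sprintf("null_%04d", seq_len(genes)),
                      sprintf("s%03d", seq_len(samples)))
  m
}

# matrix with `n_on` planted genes ON only in the target block (two tight
# modes), the rest unimodal; returns matrix + annotations
planted_target_matrix <- function(n_on = 5, n_null = 495, n_target = 40,
                                  n_other = 80, seed = 13) {
  set.seed(seed)
  n <- n_target + n_other
  on_gene <- function() c(rnorm(n_target, 5, 0.4), rnorm(n_other, 0, 0.4))
  m <- rbind(
    t(vapply(seq_len(n_on), function(i) on_gene(), numeric(n))),
    matrix(rnorm(n_null * n, 4, 1), n_null, n)
  )
  dimnames(m) <- list(c(sprintf("on_%02d", seq_len(n_on)),
                        sprintf("bg_%03d", seq_len(n_null))),
                      sprintf("s%03d", seq_len(n)))
  ann <- tibble::tibble(
    sample_id = colnames(m),
    phenotype = c(rep("cancer", n_target), rep("other", n_other))
  )
  list(matrix = m, annotations = ann)
}

# two-mode expression vector with given ON fractions in two sample blocks
two_block_gene <- function(n_target, n_other, f_target_on, f_other_on,
                           lo = 0, hi = 5, sd = 0.3, seed = 1) {
  set.seed(seed)
  on_t <- round(f_target_on * n_target)
  on_o <- round(f_other_on * n_other)
  c(rnorm(on_t, hi, sd), rnorm(n_target - on_t, lo, sd),
    rnorm(on_o, hi, sd), rnorm(n_other - on_o, lo, sd))
}
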