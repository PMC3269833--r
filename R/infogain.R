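#' Shannon entropy of a categorical label vector
#'
#' Plug-in entropy `H(X) = -sum p(x) log2 p(x)` with probabilities estimated
#' by frequency and the convention `0 log 0 = 0`. Reported in bits
#' (`base = 2`); the information-gain percentage downstream is base-invariant.
#'
#' @param labels vector of category labels (NA dropped).
#' @param base logarithm base (2 = bits, `exp(1)` = nats).
#' @return Entropy in units of `log(base)`.
#' @examples
#' entropy(c("C", "C", "C", "N")) # ~0.811 bits
#' @export
entropy <- function(labels, base = 2) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) validation_error("`labels` must contain at least one value")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Equal-frequency discretization of a continuous gene profile
#'
#' Cuts the values at the `i/n_bins` empirical quantiles so bins hold (close
#' to) equal numbers of samples. Duplicated quantile edges — arising from tied
#' values — collapse the affected bins, so the effective number of bins can be
#' smaller than requested; this keeps the assignment deterministic instead of
#' splitting tied values arbitrarily. Every sample receives exactly one bin.
#'
#' @param values numeric vector (NA allowed; assigned NA bins).
#' @param n_bins requested number of bins (>= 2); needs at least `n_bins`
#'   observed values.
#' @return A `discretized_gene` list: `bin` (integer per sample),
#'   `bin_edges`, `n_bins_requested`, `effective_bins`, `collapsed` flag.
#' @examples
#' discretize_equal_frequency(1:8, 4)$bin
#' @export
discretize_equal_frequency <- function(values, n_bins = 4L) {
  if (n_bins < 2L) validation_error("`n_bins` must be >= 2")
  obs <- !is.na(values)
  x <- values[obs]
  if (length(x) < n_bins) {
    validation_error("need at least `n_bins` = %d observed values (got %d)", n_bins, length(x))
  }
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE, type = 7))
  bin <- rep(NA_integer_, length(values))
  if (length(edges) < 2L) {
    bin[obs] <- 1L # all values identical: a single degenerate bin
    eff <- 1L
  } else {
    bin[obs] <- as.integer(cut(x, breaks = edges, include.lowest = TRUE))
    eff <- length(edges) - 1L
  }
  structure(
    list(bin = bin, bin_edges = edges, n_bins_requested = as.integer(n_bins),
         effective_bins = eff, collapsed = eff < n_bins),
    class = "discretized_gene"
  )
}

#' Percentage information gain of a gene for a phenotype
#'
#' Discretizes the gene's expression into equal-frequency bins `Y` and
#' measures how much the phenotype uncertainty drops once the bin is known:
#' \deqn{gain = 100 (H(X) - H(X|Y)) / H(X)} with
#' `H(X|Y) = sum_y p(y) H(X|Y=y)` (plug-in estimates). 0% means the gene
#' carries no phenotype information; 100% means the bins determine the
#' phenotype exactly. The percentage is invariant to the logarithm base, and
#' the bin count shifts absolute entropies but not comparisons between genes.
#'
#' @param phenotype_labels per-sample phenotype categories (>= 2 classes).
#' @param gene_values per-sample expression values, aligned with the labels.
#' @param n_bins number of equal-frequency bins for the gene (default 4).
#' @param gene_id optional identifier carried into the result.
#' @return One-row tibble: `gene_id`, `H_X`, `H_X_given_Y` (bits),
#'   `gain_percent`, `effective_bins`.
#' @examples
#' information_gain(rep(c("C", "N"), each = 4),
#'                  c(5, 5, 5, 1, 5, 1, 1, 1), n_bins = 2)
#' @export
information_gain <- function(phenotype_labels, gene_values, n_bins = 4L,
                             gene_id = NULL) {
  if (length(phenotype_labels) != length(gene_values)) {
    validation_error("`phenotype_labels` and `gene_values` must be aligned")
  }
  keep <- !is.na(phenotype_labels) & !is.na(gene_values)
  ph <- as.character(phenotype_labels[keep])
  gv <- gene_values[keep]
  if (length(gv) < n_bins) validation_error("need at least `n_bins` samples")
  if (length(unique(ph)) < 2L) {
    validation_error("phenotype has a single class; H(X) = 0 and the gain is undefined")
  }
  disc <- discretize_equal_frequency(gv, n_bins)
  y <- disc$bin
  h_x <- entropy(ph)
  h_cond <- sum(vapply(unique(y), function(b) {
    sel <- y == b
    mean(sel) * entropy(ph[sel])
  }, numeric(1)))
  tibble::tibble(gene_id = gene_id %||% NA_character_,
                 H_X = h_x, H_X_given_Y = h_cond,
                 gain_percent = 100 * (h_x - h_cond) / h_x,
                 effective_bins = disc$effective_bins)
}

#' Information gain for every gene of a matrix
#'
#' @param x genes x samples matrix (or data frame with gene-id first column).
#' @param phenotype_labels per-sample phenotype categories aligned with the
#'   matrix columns.
#' @inheritParams information_gain
#' @return Tibble with one row per gene, ordered as the input, with a `rank`
#'   by decreasing gain (ties broken by gene id).
#' @export
information_gain_matrix <- function(x, phenotype_labels, n_bins = 4L) {
  m <- as_expression_matrix(x)
  if (length(phenotype_labels) != ncol(m)) {
    validation_error("`phenotype_labels` must match the matrix columns")
  }
  out <- purrr::map(seq_len(nrow(m)), function(i) {
    information_gain(phenotype_labels, m[i, ], n_bins = n_bins,
                     gene_id = rownames(m)[i])
  }) |> dplyr::bind_rows()
  ord <- order(-out$gain_percent, out$gene_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out
}
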