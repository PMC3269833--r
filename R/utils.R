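# internal helpers shared across modules

# run `expr` under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# population (1/n) variance, the MLE convention used throughout
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

assert_positive <- function(params, names) {
  for (nm in names) {
    val <- params[[nm]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      abort(sprintf("parameter `%s` must be a single positive finite number", nm),
            class = "switchscan_validation_error")
    }
  }
  invisible(params)
}

validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "switchscan_validation_error")
}

# coerce an expression input (numeric matrix with rownames, or data frame whose
# first column holds gene ids) to the canonical genes x samples numeric matrix
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    validation_error("expression input must be a numeric matrix or a data frame with a gene-id first column")
  }
  if (is.null(rownames(x))) validation_error("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    validation_error("duplicate gene identifiers: %s", paste(dup, collapse = ", "))
  }
  if (nrow(x) == 0L || ncol(x) == 0L) validation_error("expression matrix is empty")
  x
}

# stable md5 of a canonical YAML rendering, used to stamp result files
config_hash <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
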