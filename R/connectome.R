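#' Random Gaussian connectivity scaled by network size
#'
#' Draws i.i.d. weights \eqn{W_{ij} \sim N(0, (\sigma/\sqrt{n})^2)}.
#' The \eqn{1/\sqrt{n}} scaling of the standard deviation keeps the
#' largest singular value of the matrix approximately constant as the
#' network grows, so network dynamics remain comparably stable across
#' sizes.  `W[i, j]` is the weight from presynaptic neuron `j` onto
#' postsynaptic neuron `i`; the diagonal (autapses) is set to zero --
#' self-history is carried by the refractory filter instead.
#'
#' @param n number of neurons.
#' @param sigma scale; entry standard deviation is `sigma / sqrt(n)`.
#' @param seed optional integer seed.
#' @return A `weight_matrix`: a numeric matrix with a `neuron_sign`
#'   attribute (here `"unconstrained"` for every neuron).
#' @export
gaussian_weights <- function(n, sigma = 1, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    abort("`n` must be a positive integer.", class = "refractiv_config_error")
  }
  if (sigma < 0) abort("`sigma` must be >= 0.", class = "refractiv_config_error")
  w <- with_seed_if(seed, matrix(rnorm(n * n, 0, sigma / sqrt(n)), n, n))
  diag(w) <- 0
  new_weight_matrix(w, rep("unconstrained", n))
}

new_weight_matrix <- function(w, neuron_sign) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), length(neuron_sign) == nrow(w))
  if (any(!is.finite(w))) {
    abort("weights must be finite.", class = "refractiv_config_error")
  }
  structure(w, neuron_sign = neuron_sign, class = c("weight_matrix", class(w)))
}

#' Neuron sign labels of a weight matrix
#'
#' @param w a `weight_matrix`.
#' @return Character vector, one of `"excitatory"`, `"inhibitory"`,
#'   `"unconstrained"` per neuron.
#' @export
neuron_sign <- function(w) {
  attr(w, "neuron_sign") %||% rep("unconstrained", ncol(w))
}

#' Split a network into excitatory and inhibitory neurons (Dale's law)
#'
#' Expands an `n/2 x n/2` Gaussian draw into an `n x n` matrix in which
#' half the neurons are excitatory (outgoing weights are the positive
#' part of the draw) and half inhibitory (the negative part), so every
#' column is single-signed.  Each half-column is tiled into both row
#' blocks, which approximately preserves the spectral radius of the
#' half-size draw and keeps dynamics stable.
#'
#' With `arrangement = "interleaved"` (default) excitatory and
#' inhibitory neurons alternate along the index so that any contiguous
#' subset of neurons mixes both classes; `"block"` puts all excitatory
#' neurons first.
#'
#' @param half_matrix square numeric matrix of size `n/2`.
#' @param arrangement `"interleaved"` or `"block"`.
#' @return An `n x n` `weight_matrix` with `neuron_sign` labels.
#' @examples
#' h <- gaussian_weights(10, sigma = 1, seed = 1)
#' w <- dale_split(h)
#' table(neuron_sign(w))
#' @export
dale_split <- function(half_matrix, arrangement = c("interleaved", "block")) {
  arrangement <- match.arg(arrangement)
  m <- nrow(half_matrix)
  if (m != ncol(half_matrix)) {
    abort("`half_matrix` must be square.", class = "refractiv_config_error")
  }
  h <- unclass(half_matrix)
  pos <- pmax(h, 0)
  neg <- pmin(h, 0)
  n <- 2L * m
  w <- matrix(0, n, n)
  sign_lab <- character(n)
  if (arrangement == "interleaved") {
    exc_cols <- seq(1L, n, by = 2L)
    inh_cols <- seq(2L, n, by = 2L)
  } else {
    exc_cols <- seq_len(m)
    inh_cols <- m + seq_len(m)
  }
  # tile each half-column into both row blocks, mirroring the column layout
  row_map <- integer(n)
  row_map[exc_cols] <- seq_len(m)
  row_map[inh_cols] <- seq_len(m)
  w[, exc_cols] <- pos[row_map, , drop = FALSE]
  w[, inh_cols] <- neg[row_map, , drop = FALSE]
  sign_lab[exc_cols] <- "excitatory"
  sign_lab[inh_cols] <- "inhibitory"
  diag(w) <- 0
  new_weight_matrix(w, sign_lab)
}

#' Sparsify a weight matrix
#'
#' Sets a uniformly chosen fraction of the off-diagonal entries to
#' exactly zero.  A sparsity of 0 leaves the matrix fully connected;
#' 0.9 leaves 10% connectivity.  Dale sign labels are preserved (zeros
#' never flip a sign).
#'
#' @param w a `weight_matrix` (or plain square matrix).
#' @param fraction fraction of off-diagonal entries to zero, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return The sparsified `weight_matrix`.
#' @export
sparsify <- function(w, fraction, seed = NULL) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must be in [0, 1].", class = "refractiv_config_error")
  }
  n <- nrow(w)
  off <- which(row(w) != col(w))
  k <- round(fraction * length(off))
  zap <- with_seed_if(seed, sample(off, k))
  out <- unclass(w)
  out[zap] <- 0
  diag(out) <- 0
  new_weight_matrix(out, neuron_sign(w))
}

#' Read or write a dense weight matrix as CSV
#'
#' Plain dense CSV, no header, one row per postsynaptic neuron.  Sign
#' labels travel in a `.signs` sidecar column file when present.
#'
#' @param w a `weight_matrix`.
#' @param path file path.
#' @return `write_weights()` returns `path` invisibly; `read_weights()`
#'   returns a `weight_matrix`.
#' @export
write_weights <- function(w, path) {
  utils::write.table(unclass(w), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  writeLines(neuron_sign(w), paste0(path, ".signs"))
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(w) <- NULL
  signs_path <- paste0(path, ".signs")
  signs <- if (file.exists(signs_path)) readLines(signs_path) else
    rep("unconstrained", ncol(w))
  new_weight_matrix(w, signs)
}
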