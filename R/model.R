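#' Define a convolutional architecture
#'
#' Describes the layer hyperparameters of the multi-task accessibility
#' network: a stack of (convolution, batch norm, ReLU, max pool) blocks,
#' then fully connected blocks (linear, batch norm, ReLU, dropout), then a
#' linear map to `n_targets` sigmoid outputs.
#'
#' Convolutions are valid (unpadded): a filter of width W over an input of
#' spatial length P yields P - W + 1 positions. Max pooling uses
#' non-overlapping windows; a trailing partial window is kept and pooled
#' over the remainder.
#'
#' @param input_length sequence length in bp the model accepts.
#' @param n_targets number of cell types (sigmoid outputs).
#' @param conv_layers list of numeric triples `c(n_filters, filter_width,
#'   pool_width)`, one per convolution block.
#' @param fc_layers integer vector of hidden-unit counts for the fully
#'   connected blocks.
#' @param dropout dropout probability per fully connected block (recycled
#'   to `length(fc_layers)`).
#' @return an `accessnet_arch` list.
#' @examples
#' architecture_spec(600, 4,
#'                   conv_layers = list(c(50, 19, 6), c(50, 7, 4)),
#'                   fc_layers = 100)
#' @export
architecture_spec <- function(input_length, n_targets,
                              conv_layers = list(c(300, 19, 3),
                                                 c(200, 11, 4),
                                                 c(200, 7, 4)),
                              fc_layers = c(1000, 1000),
                              dropout = 0.3) {
  stopifnot(input_length >= 1, n_targets >= 1, length(conv_layers) >= 1)
  conv_layers <- lapply(conv_layers, function(cl) {
    stopifnot(length(cl) == 3, all(cl >= 1))
    list(n_filters = as.integer(cl[1]), filter_width = as.integer(cl[2]),
         pool_width = as.integer(cl[3]))
  })
  fc_layers <- as.integer(fc_layers)
  dropout <- rep_len(as.numeric(dropout), length(fc_layers))
  stopifnot(all(dropout >= 0 & dropout < 1))
  # trace the spatial extent through the stack
  p <- as.integer(input_length)
  for (cl in conv_layers) {
    p <- p - cl$filter_width + 1L
    if (p < 1L) stop("spatial extent collapses below 1 position; ",
                     "filter widths too large for input_length")
    p <- as.integer(ceiling(p / cl$pool_width))
  }
  structure(list(input_length = as.integer(input_length),
                 n_targets = as.integer(n_targets),
                 conv_layers = conv_layers, fc_layers = fc_layers,
                 dropout = dropout, flat_size = conv_layers[[length(conv_layers)]]$n_filters * p),
            class = "accessnet_arch")
}

#' @export
print.accessnet_arch <- function(x, ...) {
  cat("accessnet architecture: input", x$input_length, "bp ->",
      x$n_targets, "targets\n")
  for (cl in x$conv_layers) {
    cat(sprintf("  conv %dx%d, pool %d\n", cl$n_filters, cl$filter_width,
                cl$pool_width))
  }
  cat("  fc:", paste(x$fc_layers, collapse = ", "),
      " (dropout ", paste(x$dropout, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

init_bn <- function(n) {
  list(gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n))
}

#' Initialize model parameters for an architecture
#'
#' Weights are drawn from a centered normal with standard deviation
#' `1/sqrt(fan_in)` (small values scaled by fan-in); biases start at zero;
#' batch-norm scale/shift at 1/0 with running moments 0/1.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed for the weight draw.
#' @return an `accessnet_model` holding `spec` and `params`.
#' @export
new_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "accessnet_arch"))
  with_seed(seed, {
    params <- list(conv = list(), fc = list(), out = NULL)
    c_in <- 4L
    for (cl in spec$conv_layers) {
      fan_in <- c_in * cl$filter_width
      params$conv[[length(params$conv) + 1L]] <- c(list(
        W = matrix(stats::rnorm(cl$n_filters * fan_in, sd = 1 / sqrt(fan_in)),
                   nrow = cl$n_filters),
        b = rep(0, cl$n_filters)), init_bn(cl$n_filters))
      c_in <- cl$n_filters
    }
    d_in <- spec$flat_size
    for (h in spec$fc_layers) {
      params$fc[[length(params$fc) + 1L]] <- c(list(
        W = matrix(stats::rnorm(h * d_in, sd = 1 / sqrt(d_in)), nrow = h),
        b = rep(0, h)), init_bn(h))
      d_in <- h
    }
    params$out <- list(
      W = matrix(stats::rnorm(spec$n_targets * d_in, sd = 1 / sqrt(d_in)),
                 nrow = spec$n_targets),
      b = rep(0, spec$n_targets))
    structure(list(spec = spec, params = params, seed = seed),
              class = "accessnet_model")
  })
}

#' @export
print.accessnet_model <- function(x, ...) {
  print(x$spec)
  n_par <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 1))
  cat("  parameters:", format(n_par, big.mark = ","), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file native R containers holding the
#' architecture, parameters (including batch-norm running moments) and any
#' attached training metadata.
#'
#' @param model an `accessnet_model`.
#' @param path file path (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "accessnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "accessnet_model")) stop("not an accessnet model: ", path)
  x
}
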