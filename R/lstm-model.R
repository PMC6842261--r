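sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct an LSTM parameter set
#'
#' One recurrent layer is parameterized by input-to-hidden weights `W`,
#' hidden-to-hidden weights `U` and biases `b` for the input (`i`),
#' forget (`f`) and output (`o`) gates and the cell candidate (`g`).
#'
#' @param W,U,b named lists with elements `i`, `f`, `o`, `g`: `W[[k]]` is
#'   hidden x |D|, `U[[k]]` hidden x hidden, `b[[k]]` a hidden vector.
#' @return an `lstm_params` object.
#' @export
lstm_params <- function(W, U, b) {
  gates <- c("i", "f", "o", "g")
  stopifnot(all(gates %in% names(W)), all(gates %in% names(U)),
            all(gates %in% names(b)))
  h <- nrow(W$i)
  for (k in gates) {
    stopifnot(nrow(W[[k]]) == h, identical(dim(U[[k]]), c(h, h)),
              length(b[[k]]) == h)
    if (!all(is.finite(W[[k]])) || !all(is.finite(U[[k]])) || !all(is.finite(b[[k]])))
      stop("non-finite LSTM parameters")
  }
  structure(list(W = W[gates], U = U[gates], b = b[gates],
                 hidden = h, input = ncol(W$i)), class = "lstm_params")
}

# Seeded uniform(+-1/sqrt(hidden)) initialization; biases start at zero.
init_lstm_params <- function(hidden, input) {
  s <- 1 / sqrt(hidden)
  rm_ <- function(r, c) matrix(runif(r * c, -s, s), r, c)
  lstm_params(W = lapply(setNames(nm = c("i", "f", "o", "g")), function(k) rm_(hidden, input)),
              U = lapply(setNames(nm = c("i", "f", "o", "g")), function(k) rm_(hidden, hidden)),
              b = lapply(setNames(nm = c("i", "f", "o", "g")), function(k) numeric(hidden)))
}

#' Construct the output (classification) layer
#'
#' @param weights C x H matrix (H = hidden size for an LSTM, twice that
#'   for a BiLSTM); row `j` scores class `j - 1`.
#' @param bias length-C vector.
#' @return an `output_params` object.
#' @export
output_params <- function(weights, bias) {
  stopifnot(is.matrix(weights), length(bias) == nrow(weights))
  structure(list(weights = weights, bias = as.numeric(bias)), class = "output_params")
}

#' Assemble an LSTM or BiLSTM classifier
#'
#' @param direction `"forward-only"` or `"bidirectional"`.
#' @param forward [lstm_params()] of the forward layer.
#' @param backward [lstm_params()] of the backward layer
#'   (bidirectional models only).
#' @param output [output_params()]; its feature width must match the
#'   direction (hidden, or 2 x hidden).
#' @param vocab the `code_vocabulary` the model was trained against.
#' @return a `bilstm_model`.
#' @export
bilstm_model <- function(direction = c("forward-only", "bidirectional"),
                         forward, backward = NULL, output, vocab) {
  direction <- match.arg(direction)
  stopifnot(inherits(forward, "lstm_params"), inherits(output, "output_params"))
  if (direction == "bidirectional") {
    if (is.null(backward)) stop("bidirectional model requires backward parameters")
    stopifnot(inherits(backward, "lstm_params"),
              backward$hidden == forward$hidden, backward$input == forward$input)
  } else if (!is.null(backward)) {
    stop("forward-only model must not carry backward parameters")
  }
  feat <- forward$hidden * if (direction == "bidirectional") 2L else 1L
  stopifnot(ncol(output$weights) == feat)
  structure(list(direction = direction, forward = forward, backward = backward,
                 output = output, vocab = vocab, hidden = forward$hidden),
            class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  cat(sprintf("<bilstm_model: %s, hidden=%d, |D|=%d>\n",
              x$direction, x$hidden, x$forward$input))
  invisible(x)
}

#' One LSTM time step
#'
#' Computes the gate activations and state update for a single visit:
#' sigmoid input/forget/output gates, tanh cell candidate,
#' `c_t = f * c_prev + i * g`, `h_t = o * tanh(c_t)`.
#'
#' @param x_t length-|D| input vector (multi-hot visit encoding).
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @param params an [lstm_params()].
#' @return list with `i`, `f`, `o`, `g`, `c`, `h` (hidden vectors).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  pre <- function(k) drop(params$W[[k]] %*% x_t + params$U[[k]] %*% h_prev) + params$b[[k]]
  i <- sigmoid(pre("i")); f <- sigmoid(pre("f"))
  o <- sigmoid(pre("o")); g <- tanh(pre("g"))
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  if (!all(is.finite(h_t))) stop("non-finite LSTM state")
  list(i = i, f = f, o = o, g = g, c = c_t, h = h_t)
}

# Run one direction over rows 1..T of `mat`, collecting per-step states.
run_direction <- function(params, mat) {
  h <- numeric(params$hidden); c_ <- numeric(params$hidden)
  states <- vector("list", nrow(mat))
  for (t in seq_len(nrow(mat))) {
    states[[t]] <- lstm_step(mat[t, ], h, c_, params)
    h <- states[[t]]$h; c_ <- states[[t]]$c
  }
  states
}

#' Forward pass over one encoded sequence
#'
#' Runs the forward layer over visits `1..T` (true length only; padding
#' rows are never read) and, for bidirectional models, the backward
#' layer over the reversed visits. The learned feature vector presented
#' to the classifier is the forward final state, concatenated for
#' BiLSTMs with the backward layer's final state (its state at visit 1).
#'
#' @param model a [bilstm_model()].
#' @param seq an `encoded_sequence` from [encode_patient()].
#' @return list with `features`, `forward` (per-step states, visits
#'   `1..T`) and `backward` (per-step states of the reversed pass, or
#'   `NULL`).
#' @export
sequence_forward <- function(model, seq) {
  T_p <- seq$true_length
  if (T_p < 1L) stop("cannot run an empty sequence")
  mat <- seq$matrix[seq_len(T_p), , drop = FALSE]
  fwd <- run_direction(model$forward, mat)
  bwd <- NULL
  features <- fwd[[T_p]]$h
  if (model$direction == "bidirectional") {
    bwd <- run_direction(model$backward, mat[rev(seq_len(T_p)), , drop = FALSE])
    features <- c(features, bwd[[T_p]]$h)
  }
  list(features = features, forward = fwd, backward = bwd)
}

#' Class probabilities from a feature vector
#'
#' Softmax over the output layer's pre-activations `W h + b`.
#'
#' @param h feature vector.
#' @param out an [output_params()].
#' @return probability vector over classes (positive, sums to 1).
#' @export
class_probabilities <- function(h, out) {
  z <- drop(out$weights %*% h) + out$bias
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Save / load a model as self-describing JSON
#'
#' Arrays are stored flattened (column-major) with their dimensions;
#' doubles are written as 17-significant-digit decimal strings, which
#' reparse to the identical IEEE value, so the round-trip is bit-exact.
#'
#' @param model a [bilstm_model()].
#' @param path file path.
#' @return `path` / a `bilstm_model`.
#' @export
save_model <- function(model, path) {
  enc_num <- function(x) sprintf("%.17g", x)
  enc_mat <- function(m) list(dim = dim(m), data = enc_num(as.numeric(m)))
  enc_lstm <- function(p) list(W = lapply(p$W, enc_mat), U = lapply(p$U, enc_mat),
                               b = lapply(p$b, enc_num))
  obj <- list(direction = model$direction,
              hidden = model$hidden,
              forward = enc_lstm(model$forward),
              backward = if (!is.null(model$backward)) enc_lstm(model$backward),
              output = list(weights = enc_mat(model$output$weights),
                            bias = enc_num(model$output$bias)),
              vocab = list(codes = model$vocab$codes, level = model$vocab$level))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dec_mat <- function(m) matrix(as.numeric(m$data), m$dim[1], m$dim[2])
  dec_lstm <- function(p) lstm_params(W = lapply(p$W, dec_mat),
                                      U = lapply(p$U, dec_mat),
                                      b = lapply(p$b, as.numeric))
  vocab <- structure(list(codes = obj$vocab$codes, level = obj$vocab$level),
                     class = "code_vocabulary")
  bilstm_model(direction = obj$direction,
               forward = dec_lstm(obj$forward),
               backward = if (!is.null(obj$backward)) dec_lstm(obj$backward),
               output = output_params(dec_mat(obj$output$weights),
                                      as.numeric(obj$output$bias)),
               vocab = vocab)
}
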