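# Independent oracles: scalar-loop re-implementations of the declared
# equations, written without the package's vectorized code paths, used to
# freeze expected values for the model and decomposition tests.

# All permutations of 1..n, generated recursively.
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# Permutation-average linearization, scalar loop over elements, with the
# activation(0) offset assigned to the last summand.
shapley_oracle <- function(summands, act) {
  k <- length(summands)
  len <- length(summands[[1]])
  contrib <- lapply(summands, function(s) numeric(len))
  ps <- perms_of(k)
  for (e in seq_len(len)) {
    for (p in ps) {
      run <- 0
      for (j in p) {
        newv <- run + summands[[j]][e]
        contrib[[j]][e] <- contrib[[j]][e] + act(newv) - act(run)
        run <- newv
      }
    }
  }
  contrib <- lapply(contrib, function(x) x / length(ps))
  contrib[[k]] <- contrib[[k]] + act(0)
  contrib
}

sig_ <- function(x) 1 / (1 + exp(-x))

# Eqs-by-element LSTM step: plain loops, no matrix products.
scalar_lstm_step <- function(x, h_prev, c_prev, params) {
  H <- params$hidden
  pre <- function(gate, j) {
    s <- params$b[[gate]][j]
    for (d in seq_along(x)) s <- s + params$W[[gate]][j, d] * x[d]
    for (u in seq_len(H)) s <- s + params$U[[gate]][j, u] * h_prev[u]
    s
  }
  i <- f <- o <- g <- c_t <- h_t <- numeric(H)
  for (j in seq_len(H)) {
    i[j] <- sig_(pre("i", j)); f[j] <- sig_(pre("f", j))
    o[j] <- sig_(pre("o", j)); g[j] <- tanh(pre("g", j))
    c_t[j] <- f[j] * c_prev[j] + i[j] * g[j]
    h_t[j] <- o[j] * tanh(c_t[j])
  }
  list(i = i, f = f, o = o, g = g, c = c_t, h = h_t)
}

# Scalar re-implementation of the whole CD recursion for one direction
# (any hidden size / length, used at hidden 1 and T <= 2 for the exact
# equivalence check). Independent of cd_direction: scalar loops and the
# recursive permutation enumerator above.
scalar_cd_direction <- function(params, mat, S) {
  H <- params$hidden
  bh <- gh <- bc <- numeric(H)
  h_prev <- c_prev <- numeric(H)
  for (t in seq_len(nrow(mat))) {
    st <- scalar_lstm_step(mat[t, ], h_prev, c_prev, params)
    in_S <- t %in% S
    lin <- list()
    for (gate in c("i", "f", "g")) {
      wx <- rel <- irr <- numeric(H)
      for (j in seq_len(H)) {
        for (d in seq_len(ncol(mat))) wx[j] <- wx[j] + params$W[[gate]][j, d] * mat[t, d]
        for (u in seq_len(H)) {
          rel[j] <- rel[j] + params$U[[gate]][j, u] * bh[u]
          irr[j] <- irr[j] + params$U[[gate]][j, u] * gh[u]
        }
      }
      if (in_S) rel <- rel + wx else irr <- irr + wx
      act <- if (gate == "g") tanh else sig_
      lin[[gate]] <- shapley_oracle(list(rel, irr, params$b[[gate]]), act)
    }
    bc_new <- (lin$f[[1]] + lin$f[[3]]) * bc +
      (lin$i[[1]] + lin$i[[3]]) * lin$g[[1]] +
      lin$i[[1]] * lin$g[[3]] +
      (if (in_S) lin$i[[3]] * lin$g[[3]] else 0)
    gc_new <- st$c - bc_new
    tanh_split <- shapley_oracle(list(bc_new, gc_new), tanh)
    bh <- st$o * tanh_split[[1]]
    gh <- st$h - bh
    bc <- bc_new
    h_prev <- st$h; c_prev <- st$c
  }
  list(beta = bh, gamma = gh, h = h_prev)
}

# ---- randomized fixtures ----

rand_lstm_params <- function(H, D, scale = NULL) {
  s <- scale %||% (1 / sqrt(H))
  gates <- c("i", "f", "o", "g")
  lstm_params(W = lapply(setNames(nm = gates), function(k) matrix(runif(H * D, -s, s), H, D)),
              U = lapply(setNames(nm = gates), function(k) matrix(runif(H * H, -s, s), H, H)),
              b = lapply(setNames(nm = gates), function(k) runif(H, -s, s)))
}

zero_lstm_params <- function(H, D) {
  gates <- c("i", "f", "o", "g")
  lstm_params(W = lapply(setNames(nm = gates), function(k) matrix(0, H, D)),
              U = lapply(setNames(nm = gates), function(k) matrix(0, H, H)),
              b = lapply(setNames(nm = gates), function(k) numeric(H)))
}

toy_vocab <- function(D) {
  structure(list(codes = visitCD:::synthetic_code_names(D), level = "4-digit"),
            class = "code_vocabulary")
}

rand_model <- function(direction = "forward-only", H = 6, D = 12) {
  vocab <- toy_vocab(D)
  feat <- H * if (direction == "bidirectional") 2L else 1L
  bilstm_model(direction,
               forward = rand_lstm_params(H, D),
               backward = if (direction == "bidirectional") rand_lstm_params(H, D),
               output = output_params(matrix(rnorm(2 * feat, sd = 0.4), 2, feat),
                                      rnorm(2, sd = 0.1)),
               vocab = vocab)
}

rand_sequence <- function(T_p, D, max_codes = 3) {
  m <- matrix(0, T_p, D)
  for (t in seq_len(T_p)) m[t, sample.int(D, sample(1:max_codes, 1))] <- 1
  structure(list(matrix = m, true_length = as.integer(T_p), patient_id = "SYN"),
            class = "encoded_sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small labeled cohort + split for training tests
small_training_split <- function(n = 160, vocab_size = 20, seed = 7,
                                 penetrance_case = 1, penetrance_control = 0,
                                 carrier = "random") {
  cfg <- cohort_config(n_patients = n, vocab_size = vocab_size,
                       visit_count_range = c(4L, 8L),
                       codes_per_visit_range = c(1L, 3L),
                       case_fraction = 0.5,
                       signal = planted_signal(15:17, carrier_position = carrier,
                                               penetrance_case = penetrance_case,
                                               penetrance_control = penetrance_control),
                       seed = seed)
  stratified_split(generate_cohort(cfg), seed = seed)
}
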