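# Synthetic classification benchmark: n_subj subjects x 2 sessions,
# m features of which the first n_inform separate the classes.
make_bench <- function(n_subj = 26, m = 18, n_inform = 1, delta = 1.5,
                       seed = 1) {
  with_seed(seed, {
    X <- matrix(rnorm(2 * n_subj * m), 2 * n_subj, m)
    colnames(X) <- paste0("f", seq_len(m))
    y <- rep(c("neg", "pos"), n_subj)
    for (k in seq_len(n_inform))
      X[, k] <- X[, k] + ifelse(y == "pos", delta, -delta)
    list(X = X, y = y, subjects = rep(seq_len(n_subj), each = 2))
  })
}
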