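# Synthetic feature tables with planted batch location/scale effects.
# Features carry distinct natural scales, as radiomic features do; the
# batch shift is additive on every feature.
make_batch_table <- function(n_per_batch = 100, p = 10, shift = 5,
                             scale = 1, label_effect = 0, seed = 1,
                             confound = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_batch
  batch <- rep(c("A", "B"), each = n_per_batch)
  label <- if (confound) as.integer(batch == "B")
           else rep(rep(0:1, length.out = n_per_batch), 2)
  sds <- stats::runif(p, 0.5, 3)
  X <- sapply(seq_len(p), function(j) stats::rnorm(n, sd = sds[j]))
  X[, 1] <- X[, 1] + label_effect * label
  X[batch == "B", ] <- X[batch == "B", ] * scale + shift
  tab <- data.frame(patient_id = sprintf("Q%03d", 1:n), sequence = "T1W",
                    region = "S2", label = label, batch = batch,
                    split = "train", check.names = FALSE)
  for (j in seq_len(p)) tab[[paste0("f", j)]] <- X[, j]
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# Synthetic feature tables for the selection stages.
make_sig_table <- function(n = 60, p = 20, informative = 0,
                           effect = 1, seed = 1, split = "train") {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  if (informative > 0)
    X[, seq_len(informative)] <- X[, seq_len(informative)] + effect * y
  tab <- data.frame(patient_id = sprintf("P%03d", 1:n), sequence = "T1W",
                    region = "S2", label = y, batch = "A", split = split,
                    check.names = FALSE)
  for (j in seq_len(p)) tab[[colnames(X)[j]]] <- X[, j]
  class(tab) <- c("feature_table", "data.frame")
  tab
}
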