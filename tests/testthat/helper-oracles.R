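# Independent oracles, written without reference to the package internals.

# Benjamini-Hochberg step-up by direct application of the definition:
# sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, cap at 1, restore order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# One-component PLS1 on column-autoscaled data, from the closed form:
# the first PLS weight is proportional to X'y; training prediction is the
# least-squares fit of centered y on the single score t = Xw.
pls1_train_predictions <- function(X, y01) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  yc <- y01 - mean(y01)
  w <- drop(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xc %*% w)
  b <- sum(t * yc) / sum(t^2)
  t * b + mean(y01)
}

# small random two-class instance for latent-model tests
random_two_class <- function(n_per = 6, p = 12, shift = 0, seed = 1,
                             n_signal = 3) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(sprintf("s%03d", seq_len(2 * n_per)),
                              sprintf("m%03d", seq_len(p))))
  cols <- seq_len(min(n_signal, p))
  X[seq_len(n_per), cols] <- X[seq_len(n_per), cols] + shift
  list(X = X, labels = rep(c("a", "b"), each = n_per))
}

# tiny abundance fixture: samples x metabolites with optional NAs
tiny_matrix <- function(values, stage = "raw") {
  abundance_matrix(values, stage = stage)
}

named_mat <- function(data, nrow, byrow = TRUE) {
  m <- matrix(data, nrow = nrow, byrow = byrow)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("met_%02d", seq_len(ncol(m)))
  m
}

# minimal metadata for a hand-built two-group design
tiny_meta <- function(sample_ids, dose, timepoint, sex = "M",
                      volume = 1) {
  data.frame(sample_id = sample_ids,
             subject_id = paste0("subj_", sample_ids),
             sex = sex, dose_gy = dose, day = 0L, cohort = 2016L,
             timepoint = timepoint,
             volume_ml = volume)
}
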