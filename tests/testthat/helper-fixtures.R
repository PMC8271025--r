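# Build small complete-design feature tables in code.

# One record per (object, scan, session, feature, sequence); `values` is a
# function(object_id, scan, session, feature) returning the value, so
# tests can encode exact structure (noise-free designs, offsets, ...).
make_feature_table <- function(objects = c("apple1", "kiwi1"),
                               types = sub("[0-9]+$", "", objects),
                               sequences = "T2 map",
                               features = "firstorder_Mean",
                               values = function(o, sc, se, f) 0) {
  grid <- expand.grid(
    object_id = objects, sequence = sequences, scan = 1:2,
    session = radstab::session_labels, feature_name = features,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid$object_type <- types[match(grid$object_id, objects)]
  grid$value <- mapply(values, grid$object_id, grid$scan, grid$session,
                       grid$feature_name)
  tibble::as_tibble(grid[, c("object_id", "object_type", "sequence",
                             "scan", "session", "feature_name", "value")])
}

# Independent CCC oracle: Lin's coefficient written as one minus the ratio
# of the mean squared paired difference to its expectation under an
# independent re-pairing of the empirical marginals.
ccc_oracle <- function(x, y) {
  1 - mean((x - y)^2) / mean(outer(x, y, "-")^2)
}

# Brute-force Mann-Whitney U: count pairs with b > a, ties 1/2.
u_oracle <- function(a, b) {
  cmp <- outer(a, b, function(ai, bj) (bj > ai) + 0.5 * (bj == ai))
  sum(cmp)
}

# ICC oracle from stats::aov mean squares on the long block.
icc_oracle <- function(values, variant) {
  n <- nrow(values); k <- ncol(values)
  d <- data.frame(
    value = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][,
    "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (variant == "consistency_single") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}
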