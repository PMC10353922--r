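# quick constructor for small hand-written visitation fixtures
make_visits <- function(year, day, sex, plant, count = NULL) {
  visitation_dataset(year, day, sex, plant, count)
}

# brute-force label-shuffle sampler of the fixed-margin null: re-pair the
# row (sex) labels of individual visits with their column (plant) labels
shuffle_table <- function(row_margins, col_margins) {
  rows <- rep(seq_along(row_margins), row_margins)
  cols <- rep(seq_along(col_margins), col_margins)
  tab <- table(factor(sample(rows), levels = seq_along(row_margins)),
               factor(cols, levels = seq_along(col_margins)))
  matrix(as.integer(tab), nrow = length(row_margins))
}

# independent Morisita-Horn oracle, written directly from the definition
mh_oracle <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}
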