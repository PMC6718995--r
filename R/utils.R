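# Round half away from zero to `digits` decimals. Base round() uses
# round-half-even, which does not reproduce percentage tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

param_cols <- c("doping", "angle", "force", "pressure", "current")

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s is missing column(s): %s", what,
                         paste(missing, collapse = ", ")),
                 class = "dualpathnet_spec_error")
  }
}
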