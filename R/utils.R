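# internal vectorised row moments (sample variance, denominator n - 1)
row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

row_sds <- function(x) sqrt(row_vars(x))
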