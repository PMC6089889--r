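# internal helpers

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# pattern label (3/4/5) -> mask code (2/3/4) and back
pattern_to_code <- function(p) p - 1L
code_to_pattern <- function(code) code + 1L

assert_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    abort(sprintf("`%s` must be an H x W x 3 array", arg))
  invisible(img)
}

# luminance grayscale (0.299 R + 0.587 G + 0.114 B)
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  assert_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# deterministic seed derivation for sub-tasks, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}
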