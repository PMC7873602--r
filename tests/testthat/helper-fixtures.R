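# Small, fast study conditions for unit tests: compact tumors on a 64 px
# canvas so a phantom renders in ~1 ms. The acceptance suite uses the
# default full-size parameters instead.
small_params <- function(low = list(), high = list(), ...) {
  base_low <- list(
    size_transverse = c(median = 2.4, min = 1.6, max = 3.6),
    size_anteroposterior = c(median = 2.4, min = 1.6, max = 3.6),
    size_craniocaudal = c(median = 2.4, min = 1.6, max = 3.6))
  base_high <- list(
    size_transverse = c(median = 3.0, min = 2.0, max = 4.4),
    size_anteroposterior = c(median = 3.0, min = 2.0, max = 4.4),
    size_craniocaudal = c(median = 3.0, min = 2.0, max = 4.4),
    necrosis_n = 2L)
  default_cohort_params(
    low = utils::modifyList(base_low, low),
    high = utils::modifyList(base_high, high),
    canvas_px = 64L,
    ...
  )
}

disk_mask <- function(n, r, center = (n + 1) / 2) {
  rr <- matrix(seq_len(n) - center, n, n)
  cc <- matrix(seq_len(n) - center, n, n, byrow = TRUE)
  rr^2 + cc^2 <= r^2
}
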