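# Shared fixtures. Expensive simulations are generated once per run and
# cached so independent test files can reuse them.

.fix <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fix[[key]])) .fix[[key]] <- fn()
  .fix[[key]]
}

# Desk-scale campaign: full spatial/spectral geometry, reduced egg count so
# repeated simulations stay fast.
small_cfg <- function(...) {
  synth_config(n_fertile = 40, n_infertile = 30, ...)
}

default_spectra <- function() {
  cached("default", function() simulate_spectra(small_cfg(seed = 7)))
}

strong_spectra <- function() {
  cached("strong", function() {
    simulate_spectra(small_cfg(class_effect_size = 0.3, seed = 11))
  })
}

null_spectra <- function() {
  cached("null", function() {
    simulate_spectra(small_cfg(
      class_effect_size = 0, fertile_transmission_gain = 1, seed = 42
    ))
  })
}

# Quick table builder for algebraic toys (wavelengths default to integers).
toy_table <- function(x, wavelengths = NULL, class = NULL) {
  x <- as.matrix(x)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(x)) * 100 + 400
  if (is.null(class)) class <- rep("fertile", nrow(x))
  spectra_table(x, wavelengths, class)
}

# Two well-separated Gaussian classes in `p` spectral variables.
separated_classes <- function(n_per = 30, p = 8, shift = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * p, 0, sd), n_per),
    matrix(rnorm(n_per * p, shift, sd), n_per)
  )
  toy_table(x, class = rep(c("fertile", "infertile"), each = n_per))
}

mask_iou <- function(a, b) sum(a == 1 & b == 1) / sum(a == 1 | b == 1)
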