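# Small phantom used throughout the statistical tests: same voxel size and
# concentration as the default spec, scaled-down grid so a full curve takes
# well under a second.
small_spec <- function(seed, ...) {
  phantom_spec(shape = c(32, 32, 24), semi_axes_mm = c(55, 45, 35),
               seed = seed, ...)
}

tiny_spec <- function(seed, ...) {
  phantom_spec(shape = c(20, 20, 14), semi_axes_mm = c(34, 28, 20),
               seed = seed, ...)
}

# Hand-built curve object with prescribed (thi, nnuf) rows; nuf is scaled
# so the stored nnuf values are exact.
fixture_curve <- function(thi, nnuf, c_max = 10, mean_conc = 5) {
  nuf <- as.integer(round(nnuf * 100))
  rows <- data.frame(threshold = c_max * (1 - thi), thi = thi,
                     nuf = nuf, nnuf = nuf / max(nuf))
  structure(list(rows = rows, c_max = c_max, mean_conc = mean_conc,
                 grid_size = length(thi), connectivity = 26L,
                 min_size = 1L),
            class = "nnufti")
}

# Deterministic synthetic stand-in for the tumour-free reference group:
# 40 normal quantiles at the published summary (mean 0.623, sd 0.032),
# clamped at the published group maximum 0.68.
synthetic_negative_nthi <- function() {
  s <- reference_summaries()$radtech_neg
  pmin(stats::qnorm((1:s$n - 0.5) / s$n, mean = s$mean, sd = s$sd), s$max)
}
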