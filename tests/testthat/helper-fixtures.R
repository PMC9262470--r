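# Shared fixtures, all generated in code.

# Sinusoidal grating image with the given carrier, values in [0, 1].
makeGrating <- function(h, w, wavelength, orientation, phase = 0) {
  a <- matrix(rep(seq_len(w), each = h), h)
  b <- matrix(rep(seq_len(h), times = w), h)
  0.5 + 0.5 * sin(2 * pi * (a * cos(orientation) + b * sin(orientation)) /
                    wavelength + phase)
}

# Small random RBM with parameters in a moderate range.
randomSmallRBM <- function(m, n, seed) {
  withr::with_seed(seed, newRBM(
    matrix(stats::rnorm(m * n, sd = 0.8), m, n),
    stats::rnorm(m, sd = 0.5),
    stats::rnorm(n, sd = 0.5)))
}

# The four confusion matrices behind the published-style metric table
# (rows = true class, cols = predicted; order cancer, noncancer).
studyConfusions <- function() {
  mk <- function(v) matrix(as.integer(v), 2, 2, byrow = TRUE,
                           dimnames = list(true = c("cancer", "noncancer"),
                                           predicted = c("cancer", "noncancer")))
  list("90:10" = mk(c(9, 1, 0, 4)),
       "80:20" = mk(c(18, 2, 0, 7)),
       "70:30" = mk(c(24, 0, 2, 14)),
       "60:40" = mk(c(28, 2, 1, 22)))
}

# Reference metric cells for the four splits, 2-decimal display values:
# rows cancer / noncancer / Average; columns accuracy, precision, recall, F.
studyMetricTable <- function() {
  list(
    "90:10" = rbind(c(92.86, 100.00, 90.00, 94.74),
                    c(92.86, 80.00, 100.00, 88.89),
                    c(92.86, 90.00, 95.00, 91.81)),
    "80:20" = rbind(c(92.59, 100.00, 90.00, 94.74),
                    c(92.59, 77.78, 100.00, 87.50),
                    c(92.59, 88.89, 95.00, 91.12)),
    "70:30" = rbind(c(95.00, 92.31, 100.00, 96.00),
                    c(95.00, 100.00, 87.50, 93.33),
                    c(95.00, 96.15, 93.75, 94.67)),
    "60:40" = rbind(c(94.34, 96.55, 93.33, 94.92),
                    c(94.34, 91.67, 95.65, 93.62),
                    c(94.34, 94.11, 94.49, 94.27)))
}
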