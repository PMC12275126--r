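# Shared fixtures, built in code.

# A small, well-conditioned synthetic truth: concave with an interior
# stationary point in A and B, flat in D.
concave_spec <- function(noise_sd = 0, seed = NULL) {
  surface_spec(
    c("(Intercept)" = 15, A = 0.5, B = 1, C = 0.2,
      AB = 0.1, A2 = -1, B2 = -1, C2 = -0.5, D2 = -0.2),
    noise_sd = noise_sd, n_center = 5L, seed = seed
  )
}

# Evaluate a surface_spec at coded coordinates (independent of predict()).
spec_value <- function(spec, coded) {
  b <- spec$coefficients
  A <- coded[1]; B <- coded[2]; C <- coded[3]; D <- coded[4]
  b[["(Intercept)"]] + b[["A"]] * A + b[["B"]] * B + b[["C"]] * C + b[["D"]] * D +
    b[["AB"]] * A * B + b[["AC"]] * A * C + b[["AD"]] * A * D +
    b[["BC"]] * B * C + b[["BD"]] * B * D + b[["CD"]] * C * D +
    b[["A2"]] * A^2 + b[["B2"]] * B^2 + b[["C2"]] * C^2 + b[["D2"]] * D^2
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected) / abs(expected), rel_tol)
}
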