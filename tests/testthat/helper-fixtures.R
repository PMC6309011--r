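# shared fixtures for the test suite
std <- preset_params("standard")

# closed-form Erlang CDF at integer shape k: P(X <= x), scale 1
erlang_cdf <- function(x, k) 1 - exp(-x) * sum(x^(0:(k - 1)) / factorial(0:(k - 1)))

# inverse of the fertility function: resources needed for a given net fecundity
fertility_inverse <- function(y, params) {
  -params$c0 * params$F_max * log(1 - sqrt(y / params$F_max))
}
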