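# Shared fixtures, built in code.

# one set on one resource
one_set_config <- function(price = 10, K = 1, U = 1) {
  center_config(
    sets = data.frame(name = "s", price = price, original_limit = 0),
    resources = data.frame(name = "r", ideal_level = K, max_overage = U),
    requirements = list(s = "r")
  )
}

# two sets sharing one resource
two_set_config <- function(prices = c(5, 7), K = 2, U = 0) {
  center_config(
    sets = data.frame(name = c("a", "b"), price = prices,
                      original_limit = c(0, 0)),
    resources = data.frame(name = "r", ideal_level = K, max_overage = U),
    requirements = list(a = "r", b = "r")
  )
}

# a random small instance: n_sets sets, n_res resources, every set on at
# least one resource; used for optimizer cross-checks
random_instance <- function(n_sets = 2, n_res = 2, max_cap = 4,
                            max_price = 20) {
  repeat {
    V <- matrix(rbinom(n_res * n_sets, 1, 0.6), n_res, n_sets)
    if (all(colSums(V) > 0) && all(rowSums(V) > 0)) break
  }
  resources <- data.frame(
    name = paste0("r", seq_len(n_res)),
    ideal_level = sample(1:max_cap, n_res, replace = TRUE),
    max_overage = sample(0:2, n_res, replace = TRUE)
  )
  sets <- data.frame(
    name = paste0("s", seq_len(n_sets)),
    price = sample(seq_len(max_price), n_sets, replace = TRUE),
    original_limit = 0
  )
  config <- center_config(sets, resources, V)
  schedule <- cost_schedule(marginal = c(1, 2, 4, 8, 16, 32))
  list(config = config, schedule = schedule)
}

# independent 2^N enumeration oracle for the show-up distribution
brute_force_pmf <- function(r) {
  N <- length(r)
  pmf <- numeric(N + 1)
  for (mask in 0:(2^N - 1)) {
    shows <- as.integer(intToBits(mask))[seq_len(N)]
    p <- prod(ifelse(shows == 1, 1 - r, r))
    pmf[sum(shows) + 1] <- pmf[sum(shows) + 1] + p
  }
  pmf
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# derived synthetic records used across estimation tests (fixed seed)
synthetic_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- derive_features(generate_bookings(synthetic_spec(seed = 42)))
    cache
  }
})
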