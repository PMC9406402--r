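# Internal numeric/RNG helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded package functions do not perturb the
#' caller's random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Activation function + derivative lookup. The leaky variant has negative
# slope `slope`; "relu" is the literal max(0, t) form.
activation_funs <- function(name = c("leaky_relu", "relu", "linear"),
                            slope = 0.01) {
  name <- match.arg(name)
  switch(name,
    leaky_relu = list(
      f = function(x) x * (x > 0) + slope * x * (x <= 0),
      grad = function(x) (x > 0) + slope * (x <= 0)
    ),
    relu = list(
      f = function(x) x * (x > 0),
      grad = function(x) (x > 0) * 1
    ),
    linear = list(
      f = function(x) x,
      grad = function(x) array(1, dim = dim(x))
    )
  )
}

# Glorot/Xavier uniform initialization, drawn from the current RNG stream.
glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

# Optimizer state over a named list of parameter arrays.
optim_state <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

# One full-batch update step. `method` "adam" uses the Adam update rule;
# "sgd" is plain gradient descent. Returns list(params, state).
optim_step <- function(params, grads, state, lr, method = "adam",
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (method == "adam") {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * g
    }
  }
  list(params = params, state = state)
}

# Add a row vector b to every row of the matrix M.
add_bias <- function(M, b) {
  sweep(M, 2, b, "+")
}
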