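#' Exact GELU activation
#'
#' Gaussian Error Linear Unit, `x * pnorm(x)`: each input is scaled by the
#' probability that a standard normal variate falls below it, a smooth
#' stochastic-regularization analogue of ReLU-plus-dropout.
#'
#' @param x numeric vector/matrix/array.
#' @return object of the same shape.
#' @export
gelu_exact <- function(x) x * stats::pnorm(x)

#' Tanh-approximate GELU activation
#'
#' The widely used fast approximation
#' `0.5 * x * (1 + tanh(sqrt(2/pi) * (x + 0.044715 * x^3)))`; agrees with
#' [gelu_exact()] to about 1e-3 on \[-5, 5\]. This is the default network
#' activation.
#'
#' @param x numeric vector/matrix/array.
#' @return object of the same shape.
#' @export
gelu_approx <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

#' Apply a named activation function
#'
#' @param kind one of `"gelu_approx"`, `"gelu_exact"`, `"relu"`, `"elu"`
#'   (alpha = 1), `"tanh"`.
#' @param x numeric vector/matrix/array.
#' @return activated values, same shape.
#' @export
activation_apply <- function(kind, x) {
  switch(kind,
    gelu_approx = gelu_approx(x),
    gelu_exact = gelu_exact(x),
    relu = pmax(x, 0),
    elu = ifelse(x >= 0, x, expm1(x)),
    tanh = tanh(x),
    stop("unknown activation kind: '", kind, "'"))
}

# Derivative of each activation, evaluated at the pre-activation x.
activation_grad <- function(kind, x) {
  switch(kind,
    gelu_approx = {
      u <- sqrt(2 / pi) * (x + 0.044715 * x^3)
      t <- tanh(u)
      0.5 * (1 + t) + 0.5 * x * (1 - t^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
    },
    gelu_exact = stats::pnorm(x) + x * stats::dnorm(x),
    relu = (x > 0) * 1,
    elu = ifelse(x >= 0, 1, exp(x)),
    tanh = 1 - tanh(x)^2,
    stop("unknown activation kind: '", kind, "'"))
}

activation_kinds <- function() {
  c("gelu_approx", "gelu_exact", "relu", "elu", "tanh")
}
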