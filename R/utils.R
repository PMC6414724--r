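#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom stats rnorm runif rbinom sd quantile predict logLik AIC
#' @importFrom utils head
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Child seeds: stage `index` under a master seed. Keeps every stage
# independently reproducible and all derived seeds below 2^31.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483629L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing with edge renormalisation; sigma in cells
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    n <- length(v)
    out <- stats::filter(c(rep(v[1], half), v, rep(v[n], half)), k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  m1 <- apply(mat, 2L, smooth_1d)
  t(apply(m1, 1L, smooth_1d))
}

logistic <- function(x) 1 / (1 + exp(-x))
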