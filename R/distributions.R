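#' Stochastic duration specifications
#'
#' A `dist_spec` describes one of the duration/delay generators used by the
#' OR-day engine, in the moment-style parameterization common to commercial
#' DES packages (Arena and kin): lognormal durations are given by the
#' arithmetic mean and SD of the variate itself, a shifted exponential by its
#' offset and the mean of the excess, a discrete distribution by cumulative
#' probability/value pairs, and a triangular by min/mode/max.
#'
#' All times are in minutes. Draws are generated by inverse-CDF transform of
#' uniforms, which is what allows the paired-arm design to share identical
#' random inputs (common random numbers): the same uniform always maps to the
#' same duration regardless of which arm consumes it.
#'
#' @param kind one of `"lognormal_mean_sd"`, `"shifted_exponential"`,
#'   `"discrete_cdf"`, `"triangular"`, `"fixed"`.
#' @param params numeric parameter vector, meaning depends on `kind`:
#'   * `lognormal_mean_sd`: `c(mean, sd)` — arithmetic mean and SD of the
#'     variate (NOT the underlying normal's parameters);
#'   * `shifted_exponential`: `c(offset, mean_excess)` — the draw is
#'     `offset + Exp(mean_excess)`;
#'   * `discrete_cdf`: alternating `c(p1, v1, p2, v2, ...)` with strictly
#'     increasing cumulative probabilities ending at 1;
#'   * `triangular`: `c(min, mode, max)`;
#'   * `fixed`: a single value (degenerate distribution).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal_mean_sd", c(72.9, 29.2))   # procedure duration
#' dist_spec("shifted_exponential", c(10, 25.6))   # turnover time
#' dist_spec("discrete_cdf", c(0.5, 5, 1, 15))     # first-patient delay
#' dist_spec("triangular", c(7.5, 15, 22.5))       # end-of-day cleanup
#' @export
dist_spec <- function(kind, params) {
  kind <- match.arg(kind, c("lognormal_mean_sd", "shifted_exponential",
                            "discrete_cdf", "triangular", "fixed"))
  params <- as.numeric(params)
  if (anyNA(params) || any(!is.finite(params)))
    stop("dist_spec: 'params' must be finite numbers", call. = FALSE)
  switch(kind,
    lognormal_mean_sd = {
      if (length(params) != 2L)
        stop("lognormal_mean_sd needs params c(mean, sd)", call. = FALSE)
      if (params[1] <= 0)
        stop("lognormal_mean_sd: mean must be > 0 (got ", params[1], ")",
             call. = FALSE)
      if (params[2] < 0)
        stop("lognormal_mean_sd: sd must be >= 0 (got ", params[2], ")",
             call. = FALSE)
    },
    shifted_exponential = {
      if (length(params) != 2L)
        stop("shifted_exponential needs params c(offset, mean_excess)",
             call. = FALSE)
      if (params[1] < 0)
        stop("shifted_exponential: offset must be >= 0 (got ", params[1], ")",
             call. = FALSE)
      if (params[2] <= 0)
        stop("shifted_exponential: mean_excess must be > 0 (got ",
             params[2], ")", call. = FALSE)
    },
    discrete_cdf = {
      if (length(params) < 2L || length(params) %% 2L != 0L)
        stop("discrete_cdf needs alternating (cum. probability, value) pairs",
             call. = FALSE)
      p <- params[seq(1L, length(params), by = 2L)]
      if (any(p <= 0) || any(p > 1))
        stop("discrete_cdf: cumulative probabilities must lie in (0, 1]",
             call. = FALSE)
      if (any(diff(p) <= 0))
        stop("discrete_cdf: cumulative probabilities must be strictly increasing",
             call. = FALSE)
      if (abs(p[length(p)] - 1) > 1e-12)
        stop("discrete_cdf: final cumulative probability must equal 1 (got ",
             p[length(p)], ")", call. = FALSE)
    },
    triangular = {
      if (length(params) != 3L)
        stop("triangular needs params c(min, mode, max)", call. = FALSE)
      if (!(params[1] <= params[2] && params[2] <= params[3]))
        stop("triangular: need min <= mode <= max (got ",
             paste(params, collapse = ", "), ")", call. = FALSE)
      if (params[1] < 0)
        stop("triangular: min must be >= 0 (got ", params[1], ")",
             call. = FALSE)
    },
    fixed = {
      if (length(params) != 1L)
        stop("fixed needs a single value", call. = FALSE)
      if (params[1] < 0)
        stop("fixed: value must be >= 0 (got ", params[1], ")", call. = FALSE)
    })
  structure(list(kind = kind, params = params), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$kind, "(", paste(x$params, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Underlying normal parameters of a mean/SD-parameterized lognormal
#'
#' Converts the arithmetic mean `m` and SD `s` of a lognormal variate to the
#' `meanlog`/`sdlog` parameters of the underlying normal:
#' `sdlog = sqrt(log(1 + (s/m)^2))`, `meanlog = log(m) - sdlog^2/2`.
#'
#' @param m arithmetic mean of the variate (> 0).
#' @param s arithmetic SD of the variate (>= 0).
#' @return list with elements `meanlog` and `sdlog`.
#' @export
lognormal_moments_to_params <- function(m, s) {
  if (m <= 0) stop("lognormal mean must be > 0", call. = FALSE)
  if (s < 0) stop("lognormal sd must be >= 0", call. = FALSE)
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Inverse-CDF transform of uniforms for a duration specification
#'
#' Maps uniforms on `[0, 1)` through the quantile function of `spec`. This is
#' the deterministic core of [draw_variate()]; exposing it separately lets the
#' engine feed both comparison arms identical uniforms.
#'
#' @param spec a [dist_spec()].
#' @param u numeric vector of uniforms in `[0, 1)`.
#' @return numeric vector of variates, `length(u)`.
#' @export
dist_quantile <- function(spec, u) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$kind,
    lognormal_mean_sd = {
      if (p[2] == 0) rep(p[1], length(u)) else {
        lp <- lognormal_moments_to_params(p[1], p[2])
        stats::qlnorm(u, lp$meanlog, lp$sdlog)
      }
    },
    shifted_exponential = p[1] + stats::qexp(u, rate = 1 / p[2]),
    discrete_cdf = {
      cum <- p[seq(1L, length(p), by = 2L)]
      val <- p[seq(2L, length(p), by = 2L)]
      val[findInterval(u, cum) + 1L]
    },
    triangular = {
      a <- p[1]; b <- p[2]; cc <- p[3]
      if (cc == a) return(rep(a, length(u)))
      fb <- (b - a) / (cc - a)
      ifelse(u < fb,
             a + sqrt(u * (b - a) * (cc - a)),
             cc - sqrt((1 - u) * (cc - b) * (cc - a)))
    },
    fixed = rep(p[1], length(u)))
}

#' Draw random variates from a duration specification
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param streams a [or_streams()] object supplying reproducible uniforms;
#'   if `NULL` the current global RNG is used.
#' @param purpose,replication,day substream key, see [stream_uniforms()].
#' @return numeric vector of `n` variates, in minutes.
#' @examples
#' s <- or_streams(1)
#' draw_variate(dist_spec("triangular", c(7.5, 15, 22.5)), 5, s, "cleanup")
#' @export
draw_variate <- function(spec, n = 1L, streams = NULL, purpose = "draw",
                         replication = 0L, day = 0L) {
  u <- if (is.null(streams)) stats::runif(n)
       else stream_uniforms(streams, purpose, n, replication, day)
  dist_quantile(spec, u)
}

#' Analytic mean and SD of a duration specification
#'
#' Closed-form moments of each supported family; used by the moment-matching
#' checks in the test-suite and handy for sanity-checking configurations.
#'
#' @param spec a [dist_spec()].
#' @return named numeric vector `c(mean =, sd =)`.
#' @export
dist_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$kind,
    lognormal_mean_sd = c(mean = p[1], sd = p[2]),
    shifted_exponential = c(mean = p[1] + p[2], sd = p[2]),
    discrete_cdf = {
      cum <- p[seq(1L, length(p), by = 2L)]
      val <- p[seq(2L, length(p), by = 2L)]
      pr <- diff(c(0, cum))
      m <- sum(pr * val)
      c(mean = m, sd = sqrt(sum(pr * (val - m)^2)))
    },
    triangular = {
      a <- p[1]; b <- p[2]; cc <- p[3]
      c(mean = (a + b + cc) / 3,
        sd = sqrt((a^2 + b^2 + cc^2 - a * b - a * cc - b * cc) / 18))
    },
    fixed = c(mean = p[1], sd = 0))
}

#' Scale a standard deviation by a fixed variability ratio
#'
#' When a mean duration is changed (e.g., longer deep-block procedures), the
#' SD is rescaled so the coefficient of variation of the reference
#' distribution is preserved: `new_mean * reference_sd / reference_mean`.
#'
#' @param new_mean new mean, minutes (> 0).
#' @param reference_mean,reference_sd moments of the reference distribution
#'   (both > 0).
#' @return the rescaled SD in minutes.
#' @examples
#' scaled_sd(145, 72.9, 29.2)  # SD for 145-min deep-block procedures
#' @export
scaled_sd <- function(new_mean, reference_mean, reference_sd) {
  for (nm in c("new_mean", "reference_mean", "reference_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("scaled_sd: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  new_mean * reference_sd / reference_mean
}
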