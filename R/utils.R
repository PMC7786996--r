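# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

# True betas are clamped away from {0,1} before any logit transform.
clamp_beta <- function(p, lo = 0.001, hi = 0.999) pmin(pmax(p, lo), hi)

# All quantiles in the package use linear interpolation between order
# statistics (stats::quantile type 7).
quantile7 <- function(x, probs) unname(stats::quantile(x, probs, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)

# All enrichment tests in the package go through this one Fisher route.
fisher_p <- function(a, b, c, d, alternative = "greater") {
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

# Sample odds ratio ad/bc with the Haldane-Anscombe 0.5 correction when any
# cell is empty; returns c(or, corrected).
odds_ratio_adbc <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0))
    c(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)), 1)
  else c((a * d) / (b * c), 0)
}

# Seeded evaluation that does not leak into the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stop_("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
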