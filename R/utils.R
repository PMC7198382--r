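# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral of y over x (x strictly increasing)
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

stop_mrt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_mrt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) if (!isTRUE(cond)) stop_mrt(fmt, ...)

# set RNG state locally when a seed is supplied, restoring afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "rng_seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# joules per MeV
MEV_TO_J <- 1.602176634e-13

# molar mass of DOTATATE (C65H90N14O18S, g/mol); used by the worked-example
# specific-activity helpers
DOTATATE_MW <- 1435.6
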