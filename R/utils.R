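# Shared helpers: seeded evaluation, per-stage seed derivation, circular
# statistics in degrees.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a deterministic per-stage seed from one global seed
#'
#' A single pipeline seed deterministically maps to distinct seeds per stage
#' name, so any stage can be re-run identically without bookkeeping.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003) * 2011 + (h %% 99991)) %% 2147483647L
}

# Wrap angle (degrees) into [0, 360)
wrap_deg <- function(x) ((x %% 360) + 360) %% 360

# Minimal signed angular difference a - b in (-180, 180]
ang_diff_deg <- function(a, b) {
  d <- wrap_deg(a - b)
  ifelse(d > 180, d - 360, d)
}

# Circular mean of angles in degrees via the resultant vector.
circ_mean_deg <- function(x) {
  rad <- x * pi / 180
  wrap_deg(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
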