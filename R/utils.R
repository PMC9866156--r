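#' @importFrom rlang .data abort warn inform %||% :=
#' @import tibble
NULL

#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline draw their own random numbers. To keep one master
#' seed while decoupling stages, sub-seeds are derived by hashing the stage
#' name and replicate index (FNV-1a over the formatted string), reduced
#' modulo 2^31 - 1 so the result is always a valid 32-bit R seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index integer replicate index (default 0).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  key <- sprintf("%d/%s/%d", as.integer(master), stage, as.integer(index))
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% (2^31 - 1)
  }
  as.integer(h)
}

# Clip scores into [0, 1]; every model family funnels predictions through this.
clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}
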