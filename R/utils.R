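# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream tag
#'
#' All randomness in the package flows from one master seed; independent
#' stages (image substreams, FCM restarts, swarm init, splits) use sub-seeds
#' obtained by stable hashing of the master seed and a tag, so generation
#' order cannot change outputs.
#'
#' @param seed integer master seed.
#' @param ... tags (strings or numbers) identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, keeps products < 2^53 so doubles stay exact
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) {
      v <- utf8ToInt(p)
      sum(v * seq_along(v)) %% m
    } else {
      as.numeric(p) %% m
    }
  }), use.names = FALSE)
  h <- as.numeric(seed) %% m
  for (p in c(parts, 97)) h <- (h * 69069 + p + 1) %% m
  as.integer(h)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) + dr
  cs <- seq_len(ncol(m)) + dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}
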