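# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a fixed RNG seed without disturbing the caller's stream;
# seed = NULL uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Deterministic substream seeds
#'
#' Combines a master seed with a polynomial hash of a string key (for the
#' pipeline: the region id) so each analysis unit draws its Monte-Carlo
#' stream from a seed that depends only on (master seed, key) — results are
#' therefore independent of dataset ordering and any unit can be replayed in
#' isolation. All arithmetic stays below 2^31 (R integers are 32-bit).
#'
#' @param master_seed integer master seed.
#' @param region_id string key naming the substream.
#' @return an integer seed in 1..2147483629.
#' @export
substream_seed <- function(master_seed, region_id) {
  h <- .str_hash(as.character(region_id))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483629 + 1)
}

.str_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 8191 + b) %% 2147483647
  h
}

# short deterministic hash of an R object (for config provenance)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", .str_hash(as.character(s)))
}

NM2_PER_UM2 <- 1e6

# nearest-neighbour distances for an n x 2 coordinate matrix (n >= 2)
nnd_vector <- function(xy) {
  n <- nrow(xy)
  dx <- outer(xy[, 1], xy[, 1], "-")
  dy <- outer(xy[, 2], xy[, 2], "-")
  d2 <- dx * dx + dy * dy
  diag(d2) <- Inf
  j <- max.col(-d2, ties.method = "first")
  sqrt(d2[cbind(seq_len(n), j)])
}
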