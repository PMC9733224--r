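#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom Rcpp sourceCpp
#' @useDynLib netpersist, .registration = TRUE
NULL

# deterministic 32-bit string hash (polynomial rolling, modulo a prime
# below 2^31) used to derive per-stratum seeds from the master seed
hash32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% m
  as.integer(h)
}

#' Derive a reproducible stratum-level seed from a master seed
#'
#' Per-stratum randomness (StARS subsampling, simulation draws) uses seeds
#' derived deterministically from one master seed and a text label, so that
#' strata are independent yet the whole run is reproducible from a single
#' integer.
#'
#' @param master integer master seed.
#' @param label character label (e.g. `"CL_t22"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer(bitwXor(as.integer(master) %% 2147483647L, hash32(label)) %%
               2147483647L)
}

# canonical unordered pair: lexicographically smaller id first
canonical_pair <- function(u, v) {
  swap <- u > v
  tibble(node_u = ifelse(swap, v, u), node_v = ifelse(swap, u, v))
}

# canonical string key for an unordered pair
pair_key <- function(u, v) {
  p <- canonical_pair(u, v)
  paste(p$node_u, p$node_v, sep = "\r")
}
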