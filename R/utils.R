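`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's
#' `.Random.seed` afterwards, so deterministic internals (e.g. the lesion
#' irregularity field) do not disturb user-level random streams.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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

#' FNV-1a hash of an R object
#'
#' 32-bit FNV-1a over the serialized object, returned as an 8-character hex
#' string. Used for provenance stamping of run configurations.
#'
#' The multiply step uses the decomposition 16777619 = 2^24 + 403 so every
#' intermediate stays below 2^53 and the arithmetic is exact in doubles.
#'
#' @param x any serializable R object
#' @return character scalar, 8 hex digits
#' @export
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  bytes <- bytes[-seq_len(14L)]  # drop header (embeds R version numbers)
  two32 <- 2^32
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- ((h %% 2^8) * 2^24 + h * 403) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

#' @keywords internal
xor32 <- function(a, b) {
  # xor of a (double < 2^32) with b (a byte), exact in doubles
  hi <- a %/% 2^16
  lo <- a %% 2^16
  lo <- as.numeric(bitwXor(as.integer(lo), as.integer(b)))
  hi * 2^16 + lo
}

#' @keywords internal
as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  xc <- as.character(x)
  d <- tryCatch(as.Date(xc), error = function(e) rep(NA, length(xc)))
  bad <- is.na(d) & !is.na(xc) & nzchar(xc)
  if (any(bad)) {
    stop(sprintf("malformed %s: %s", what, paste(xc[bad], collapse = ", ")),
         call. = FALSE)
  }
  d
}
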