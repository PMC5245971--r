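#' SHA-1 hash coding
#'
#' A deliberately non-smooth coding scheme: each element of the stimulus is
#' serialized to a canonical decimal string, hashed with SHA-1, and the 20
#' digest bytes are mapped to 20 reals in `[-1, 1]` (`byte / 127.5 - 1`). The
#' representation of a `d`-dimensional stimulus therefore has `20 * d` values.
#' Because cryptographic hashes destroy input structure, representations of
#' arbitrarily similar stimuli are uncorrelated, so similarity structure is
#' unrecoverable from such a code.
#'
#' Serialization uses `sprintf("%.17g", x)`, a round-trip decimal form: equal
#' doubles always hash identically, and any representable change to a value
#' changes its serialization and hence its digest.
#'
#' @param x stimulus vector (finite values only).
#' @return numeric vector of length `20 * length(x)` with entries in
#'   `[-1, 1]`; element `i` of `x` occupies positions `(20i-19):(20i)`.
#' @export
encode_hash <- function(x) {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x))) {
    stop_fmricode("hash coding requires a numeric vector of finite values",
                  "fmricode_invalid_input")
  }
  digests <- lapply(x, function(v) {
    raw <- openssl::sha1(charToRaw(sprintf("%.17g", v)))
    as.integer(raw) / 127.5 - 1
  })
  unlist(digests, use.names = FALSE)
}
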