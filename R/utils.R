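# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a private RNG stream; the caller's RNG state is restored
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

pair_key <- function(compound_id, disease_id) {
  paste(compound_id, disease_id, sep = "\r")
}

# format doubles so that write -> read round-trips bit-exactly
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}
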