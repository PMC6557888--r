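# Internal helpers: seed derivation, input checking.

# Derive a reproducible child seed from a root seed and a text tag, so that
# independent sub-simulations (proteomes, each gel replicate, each spot's
# spectra) consume independent RNG streams. Linear-congruential step in
# double arithmetic; all intermediates stay below 2^53 so the result is
# exact, and the returned value fits a 32-bit integer.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 2147483647
  as.integer((seed %% 2147483647) * 48271 %% 2147483647 + h * 7919) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop(what, " must be a single non-empty residue string", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), STANDARD_RESIDUES)
  if (length(bad) > 0)
    stop("unknown residue(s) in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
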