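# Internal helpers shared across modules.

# Derive a per-stage/per-replicate RNG seed from one user seed. Kept strictly
# below 2^31 - 1 so it is always a valid integer seed.
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stream) == 1L)
  as.integer((abs(as.numeric(seed)) * 1000003 + abs(as.numeric(stream)) * 7919) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# A/T and C/G pairs: strand-ambiguous without allele-frequency information.
is_palindromic <- function(a1, a2) {
  unname(DNA_COMPLEMENT[a1] == a2)
}

is_acgt <- function(x) x %in% c("A", "C", "G", "T")
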