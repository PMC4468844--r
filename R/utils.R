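DNA_BASES <- c("A", "C", "G", "T")

#' Derive a per-stage seed from a run seed
#'
#' Every randomised stage of a run forks its own RNG stream from the run
#' seed and the stage name, so that adding or reordering stages does not
#' perturb the draws of unrelated stages. The derived seed stays below
#' 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 99991L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2039L + h)
}

# character matrix, one column per sequence; all sequences must be equal
# length
.char_matrix <- function(x) {
  L <- nchar(x[1L])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE), nrow = L)
}

# Hamming distance from one sequence to each of a set of equal-length
# sequences (as a .char_matrix)
.hamming_to_matrix <- function(seed_chars, M, cols) {
  colSums(M[, cols, drop = FALSE] != seed_chars)
}

.hamming_pair <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# uniform random DNA sequences
.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  apply(m, 2L, paste, collapse = "")
}

# error condition for statistics that are undefined on the given input
# (e.g. zero eligible clusters), so callers can distinguish it from a
# silent zero
stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("beadphase_undefined", "error", "condition")))
}

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("beadphase_invalid", "error", "condition")))
}
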