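# Small simulated runs shared across test files.

small_reference <- function(n_species = 4, divergence = 0.05, seed = 11) {
  make_reference(n_species, c("16S.1" = 150, "16S.2" = 150),
                 divergence = divergence, seed = seed)
}

small_run <- function(seed = 11, error = 0, n_droplets = 400,
                      n_beads = 6000, reference = small_reference(),
                      ...) {
  cfg <- sim_config(n_beads = n_beads, n_droplets = n_droplets,
                    substitution_error_rate = error, seed = seed, ...)
  simulate_phasing_run(cfg, reference)
}

default_layout <- function(cfg = sim_config(), ...) {
  read_layout(cfg$handle_5p, cfg$handle_3p, cfg$barcode_length, ...)
}

# flip exactly n positions of a sequence (deterministic positions)
flip_bases <- function(seq, pos) {
  other <- c(A = "C", C = "G", G = "T", T = "A")
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- other[ch[pos]]
  paste(ch, collapse = "")
}
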