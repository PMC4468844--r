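#' Poisson loading model for emulsion compartments
#'
#' In an emulsion reaction, barcode oligonucleotides (or genomic
#' fragments) are distributed over beads (or droplets) at a mean rate of
#' `cpb` copies per bead, so the number of molecules a compartment
#' receives is Poisson distributed. This object carries the rate and the
#' bead count and is consumed by [occupancy_probability()],
#' [monoclonal_fraction()], [expected_oligo_count()] and
#' [expected_enriched_beads()].
#'
#' @param cpb copies per bead (the Poisson rate, dimensionless, >= 0).
#' @param n_beads number of beads in the reaction (>= 0).
#' @return an object of class `loading_model`.
#' @examples
#' m <- loading_model(cpb = 0.1, n_beads = 2.4e6)
#' occupancy_probability(m)   # ~0.095, the ~10% enrichment expectation
#' monoclonal_fraction(m)     # ~0.951
#' @export
loading_model <- function(cpb, n_beads = 0) {
  if (!is.numeric(cpb) || length(cpb) != 1L || is.na(cpb) || cpb < 0)
    stop_invalid("'cpb' must be a single non-negative number")
  if (!is.numeric(n_beads) || length(n_beads) != 1L || is.na(n_beads) || n_beads < 0)
    stop_invalid("'n_beads' must be a single non-negative number")
  structure(list(cpb = cpb, n_beads = n_beads), class = "loading_model")
}

.as_loading_model <- function(model) {
  if (inherits(model, "loading_model")) return(model)
  if (is.numeric(model)) return(loading_model(cpb = model))
  stop_invalid("expected a 'loading_model' or a numeric cpb")
}

#' Probability that a compartment receives at least one molecule
#'
#' For K ~ Poisson(cpb), returns P(K >= 1) = 1 - exp(-cpb). This is the
#' expected fraction of beads that carry a barcode oligonucleotide and
#' hence the expected fraction recovered by enrichment: at the standard
#' loading of 0.1 c.p.b. it is 9.52%, i.e. roughly 10% of bead input.
#'
#' @param model a [loading_model()] (or a bare numeric cpb).
#' @return probability in `[0, 1)`.
#' @export
occupancy_probability <- function(model) {
  model <- .as_loading_model(model)
  -expm1(-model$cpb)
}

#' Expected monoclonal fraction among occupied compartments
#'
#' For K ~ Poisson(cpb), returns P(K = 1 | K >= 1) =
#' cpb * exp(-cpb) / (1 - exp(-cpb)): the fraction of occupied
#' compartments founded by exactly one molecule. At 0.1 c.p.b. this is
#' 95.08%, the theoretical monoclonality that observed bead barcoding is
#' compared against. The limit for cpb -> 0+ is 1.
#'
#' @inheritParams occupancy_probability
#' @return probability in `(0, 1]`.
#' @export
monoclonal_fraction <- function(model) {
  model <- .as_loading_model(model)
  if (model$cpb <= 0)
    stop_invalid("'cpb' must be > 0 for the monoclonal fraction")
  model$cpb * exp(-model$cpb) / (-expm1(-model$cpb))
}

#' Expected number of loaded molecules in a reaction
#'
#' Returns `n_beads * cpb`, e.g. 240,000 oligonucleotide molecules for
#' 2.4 million beads at 0.1 c.p.b.
#'
#' @inheritParams occupancy_probability
#' @return expected count.
#' @export
expected_oligo_count <- function(model) {
  model <- .as_loading_model(model)
  model$n_beads * model$cpb
}

#' Expected number of enriched (occupied) beads
#'
#' Returns `n_beads * (1 - exp(-cpb))`; always at most
#' [expected_oligo_count()] since some beads receive several molecules.
#'
#' @inheritParams occupancy_probability
#' @return expected count.
#' @export
expected_enriched_beads <- function(model) {
  model <- .as_loading_model(model)
  model$n_beads * occupancy_probability(model)
}

#' @export
print.loading_model <- function(x, ...) {
  cat(sprintf("Poisson loading model: %.4g c.p.b., %s beads\n",
              x$cpb, format(x$n_beads, big.mark = ",")))
  cat(sprintf("  occupancy (enriched fraction): %.4f\n", occupancy_probability(x)))
  if (x$cpb > 0)
    cat(sprintf("  monoclonal fraction of occupied: %.4f\n", monoclonal_fraction(x)))
  cat(sprintf("  expected molecules: %s\n",
              format(expected_oligo_count(x), big.mark = ",")))
  cat(sprintf("  expected enriched beads: %s\n",
              format(round(expected_enriched_beads(x)), big.mark = ",")))
  invisible(x)
}
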