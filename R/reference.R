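#' Generate a synthetic species reference set
#'
#' Builds the target-region sequences for a small panel of species, the
#' desk-scale stand-in for a panel of known bacterial genomes. For each
#' target region (e.g. the two variable 16S regions "16S.1" and "16S.2")
#' one random ancestral amplicon is drawn; its first `primer_length`
#' bases act as the conserved amplification primer and are shared by all
#' species, while the remaining variable region is mutated independently
#' per species at the given per-base substitution rate. Two species thus
#' differ at an expected fraction 2d(1-d) of variable-region sites.
#' With `n_species = 1` the ancestor is returned unchanged.
#'
#' @param n_species number of species (>= 1).
#' @param target_lengths named integer vector, variable-region length per
#'   target id (excluding the primer prefix).
#' @param divergence per-base substitution probability applied per
#'   species, in (0, 0.5).
#' @param seed integer seed; identical seeds give identical references.
#' @param primer_length length of the conserved primer prefix.
#' @return a `species_reference` data.frame with columns `species_id`,
#'   `target_id`, `sequence`, and attributes `target_primers` (named
#'   character) and `divergence`.
#' @examples
#' ref <- make_reference(4, c("16S.1" = 230, "16S.2" = 230),
#'                       divergence = 0.05, seed = 1)
#' attr(ref, "target_primers")
#' @export
make_reference <- function(n_species,
                           target_lengths = c("16S.1" = 230, "16S.2" = 230),
                           divergence = 0.05, seed = 1, primer_length = 20) {
  if (!is.numeric(n_species) || n_species < 1)
    stop_invalid("'n_species' must be >= 1")
  if (!(divergence > 0 && divergence < 0.5))
    stop_invalid("'divergence' must lie in (0, 0.5)")
  if (is.null(names(target_lengths)) || any(!nzchar(names(target_lengths))))
    stop_invalid("'target_lengths' must be a named vector of target ids")
  set.seed(stage_seed(seed, "reference"))
  species_ids <- sprintf("sp%02d", seq_len(n_species))
  rows <- list()
  primers <- character(0)
  for (t in names(target_lengths)) {
    anc <- .random_dna(1L, primer_length + target_lengths[[t]])
    primers[[t]] <- substr(anc, 1L, primer_length)
    var_anc <- substr(anc, primer_length + 1L, nchar(anc))
    vars <- if (n_species == 1L) var_anc else
      mutate_sequence(rep(var_anc, n_species), divergence)
    rows[[t]] <- data.frame(species_id = species_ids, target_id = t,
                            sequence = paste0(primers[[t]], vars),
                            stringsAsFactors = FALSE)
  }
  ref <- do.call(rbind, rows)
  rownames(ref) <- NULL
  structure(ref, target_primers = primers, divergence = divergence,
            primer_length = primer_length,
            class = c("species_reference", "data.frame"))
}

#' Write / read a species reference as FASTA
#'
#' Headers have the form `species_id|target_id primer_len=<n>`, so the
#' conserved primer prefix can be recovered on read.
#'
#' @param ref a `species_reference`.
#' @param path FASTA file path.
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` returns a `species_reference`.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- sprintf("%s|%s primer_len=%d", ref$species_id, ref$target_id,
                      attr(ref, "primer_length"))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  id <- sub(" .*$", "", hdr)
  plen <- suppressWarnings(as.integer(sub("^.*primer_len=(\\d+).*$", "\\1", hdr)))
  if (anyNA(plen)) plen <- rep(0L, length(x))
  parts <- strsplit(id, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_invalid("reference FASTA headers must be 'species_id|target_id'")
  ref <- data.frame(species_id = vapply(parts, `[`, "", 1L),
                    target_id = vapply(parts, `[`, "", 2L),
                    sequence = as.character(x), stringsAsFactors = FALSE)
  if (anyDuplicated(ref[c("species_id", "target_id")]))
    stop_invalid("duplicate species_id/target_id pair in reference FASTA")
  primers <- vapply(split(seq_len(nrow(ref)), ref$target_id)[unique(ref$target_id)],
                    function(i) substr(ref$sequence[i[1L]], 1L, plen[i[1L]]),
                    character(1))
  structure(ref, target_primers = primers,
            primer_length = plen[1L],
            class = c("species_reference", "data.frame"))
}
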