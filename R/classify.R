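.kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1L), k:L))
}

#' Build a k-mer reference index
#'
#' Indexes every reference target sequence by its set of k-mers. The
#' index backs a desk-scale containment classifier that stands in for
#' alignment of consensus sequences against a database of known
#' bacteria.
#'
#' @param reference a `species_reference` (from [make_reference()] or
#'   [read_reference_fasta()]).
#' @param k k-mer size (>= 4; default 8).
#' @return an object of class `reference_index`.
#' @export
build_reference_index <- function(reference, k = 8) {
  if (k < 4) stop_invalid("'k' must be >= 4")
  if (!nrow(reference)) stop_invalid("empty reference")
  if (anyDuplicated(reference[c("species_id", "target_id")]))
    stop_invalid("duplicate species_id/target_id pair in reference")
  if (any(nchar(reference$sequence) <= k))
    stop_invalid("all reference sequences must be longer than k")
  postings <- lapply(split(seq_len(nrow(reference)), reference$target_id),
                     function(i) {
                       s <- lapply(reference$sequence[i], .kmer_set, k = k)
                       names(s) <- reference$species_id[i]
                       s
                     })
  structure(list(postings = postings, k = k,
                 targets = names(postings),
                 species = sort(unique(reference$species_id))),
            class = "reference_index")
}

#' Classify a consensus sequence against the reference index
#'
#' Scores each reference species by k-mer containment: the fraction of
#' the query's distinct k-mers found in that species' indexed target
#' sequence (a self-hit scores 1). The hit list contains every species
#' scoring within `margin` of the top score (and above zero), ordered by
#' decreasing score then species id; the best call is the top species
#' only when it beats the runner-up by more than `margin`, otherwise
#' `"ambiguous"`.
#'
#' @param consensus query sequence (length >= k).
#' @param index a [build_reference_index()] result.
#' @param target_id which target's references to score against; `NULL`
#'   scores against all targets jointly (max per species).
#' @param margin score margin for hit-list inclusion and ambiguity.
#' @return a `taxon_assignment` list: `best_call`, `hit_list`
#'   (data.frame `species_id`, `score`), `n_hits`, `target_id`.
#' @export
classify_consensus <- function(consensus, index, target_id = NULL,
                               margin = 0.05) {
  stopifnot(inherits(index, "reference_index"))
  km <- .kmer_set(consensus, index$k)
  if (!length(km)) stop_invalid("consensus shorter than k")
  posting_sets <- if (is.null(target_id)) index$postings else {
    if (!target_id %in% index$targets)
      stop_invalid(sprintf("unknown target_id '%s'", target_id))
    index$postings[target_id]
  }
  score <- stats::setNames(numeric(length(index$species)), index$species)
  for (ps in posting_sets)
    for (sp in names(ps))
      score[sp] <- max(score[sp], sum(km %in% ps[[sp]]) / length(km))
  top <- max(score)
  keep <- score > 0 & score >= top - margin
  sp <- names(score)[keep]
  sc <- score[keep]
  ord <- order(-sc, sp, method = "radix")
  hits <- data.frame(species_id = sp[ord], score = unname(sc[ord]),
                     stringsAsFactors = FALSE)
  best <- if (nrow(hits) == 0L) "ambiguous" else {
    runner <- if (nrow(hits) >= 2L) hits$score[2L] else {
      others <- score[names(score) != hits$species_id[1L]]
      if (length(others)) max(others) else 0
    }
    if (hits$score[1L] - runner > margin) hits$species_id[1L] else "ambiguous"
  }
  structure(list(best_call = best, hit_list = hits, n_hits = nrow(hits),
                 target_id = if (is.null(target_id)) NA_character_ else target_id),
            class = "taxon_assignment")
}

#' Tabulate best-call species over assignments
#'
#' Per-target and combined counts of best-call species; ambiguous calls
#' are tallied separately. Reveals e.g. a skewed representation of the
#' reference species in a sample.
#'
#' @param calls data.frame with columns `target_id` and `best_call`.
#' @return data.frame `species`, `target_id`, `n`, plus rows with
#'   `target_id = "combined"`.
#' @export
abundance_table <- function(calls) {
  tab <- as.data.frame(table(species = calls$best_call,
                             target_id = calls$target_id),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  comb <- as.data.frame(table(species = calls$best_call),
                        stringsAsFactors = FALSE)
  names(comb)[2L] <- "n"
  comb$target_id <- "combined"
  out <- rbind(tab[c("species", "target_id", "n")],
               comb[c("species", "target_id", "n")])
  rownames(out) <- NULL
  out
}
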