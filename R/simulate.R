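#' Configuration of a simulated two-emulsion barcoding run
#'
#' Defaults reproduce the study conditions of the bead-barcoding phasing
#' protocol at desk scale: beads loaded with degenerate 15 nt barcode
#' oligonucleotides at 0.1 copies per bead (c.p.b.), droplets pairing one
#' enriched bead with genomic fragments loaded at 0.1 c.p.b. from a
#' skewed four-species mixture, two target regions amplified per
#' fragment, and i.i.d. substitution sequencing errors.
#'
#' @param n_beads beads in the first emulsion.
#' @param barcode_length degenerate barcode length in nt (15-20).
#' @param barcode_cpb barcode oligonucleotide copies per bead.
#' @param n_droplets droplets in the second emulsion (each holds one
#'   enriched bead).
#' @param fragment_cpb genomic fragment copies per droplet.
#' @param species_abundances probability vector over species (sums to 1).
#' @param reads_per_amplicon mean of the Poisson read count per
#'   (fragment, target) amplicon.
#' @param substitution_error_rate per-base substitution probability
#'   applied to every emitted read, in `[0, 1)`.
#' @param handle_5p,handle_3p fixed handle sequences flanking the barcode
#'   on read 1.
#' @param seed integer run seed; all stages fork from it by name.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_beads = 60000, barcode_length = 15,
                       barcode_cpb = 0.1, n_droplets = 5000,
                       fragment_cpb = 0.1,
                       species_abundances = c(0.4, 0.3, 0.2, 0.1),
                       reads_per_amplicon = 20,
                       substitution_error_rate = 0.005,
                       handle_5p = "ACACGACGCTCTTCC",
                       handle_3p = "AGATCGGAAGAGCGT",
                       seed = 1) {
  if (!(barcode_length >= 15 && barcode_length <= 20))
    stop_invalid("'barcode_length' must lie in [15, 20]")
  if (barcode_cpb < 0 || fragment_cpb < 0 || reads_per_amplicon < 0)
    stop_invalid("rates must be non-negative")
  if (!(substitution_error_rate >= 0 && substitution_error_rate < 1))
    stop_invalid("'substitution_error_rate' must lie in [0, 1)")
  if (any(species_abundances < 0) ||
      abs(sum(species_abundances) - 1) > 1e-9)
    stop_invalid("'species_abundances' must be non-negative and sum to 1")
  cfg <- list(n_beads = as.integer(n_beads),
              barcode_length = as.integer(barcode_length),
              barcode_cpb = barcode_cpb,
              n_droplets = as.integer(n_droplets),
              fragment_cpb = fragment_cpb,
              species_abundances = species_abundances,
              reads_per_amplicon = reads_per_amplicon,
              substitution_error_rate = substitution_error_rate,
              handle_5p = handle_5p, handle_3p = handle_3p,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Apply i.i.d. substitution errors to sequences
#'
#' Each base is independently replaced, with probability `rate`, by one
#' of the three other bases chosen uniformly. Length is preserved; there
#' is no indel model (barcode and amplicon comparisons downstream are
#' Hamming-style).
#'
#' @param seqs character vector of A/C/G/T sequences.
#' @param rate per-base substitution probability in `[0, 1)`.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return character vector of mutated sequences.
#' @export
mutate_sequence <- function(seqs, rate, seed = NULL) {
  if (!(rate >= 0 && rate < 1)) stop_invalid("'rate' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (length(seqs) == 0L || rate == 0) return(seqs)
  ch <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(ch)
  flat <- unlist(ch, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    # draw a uniform substitute among the three other bases
    cur <- flat[hit]
    off <- sample.int(3L, length(hit), replace = TRUE)
    idx <- (match(cur, DNA_BASES) - 1L + off) %% 4L + 1L
    flat[hit] <- DNA_BASES[idx]
  }
  grp <- rep.int(seq_along(seqs), lens)
  out <- character(length(seqs))
  nz <- lens > 0L
  out[nz] <- vapply(split(flat, grp), paste, character(1), collapse = "")
  out
}

#' Simulate the first-emulsion bead barcoding library
#'
#' Each bead receives K ~ Poisson(`barcode_cpb`) independent uniformly
#' random barcodes of `barcode_length` nt. Beads with K = 0 are
#' unenriched, K = 1 monoclonal, K >= 2 polyclonal.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_truth` list with elements `beads` (data.frame:
#'   `bead_id`, `n_barcodes`, `status`) and `bead_barcodes` (data.frame:
#'   `bead_id`, `barcode`; one row per barcode on a bead).
#' @export
simulate_bead_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "beads"))
  k <- stats::rpois(cfg$n_beads, cfg$barcode_cpb)
  bead_id <- sprintf("bead%06d", seq_len(cfg$n_beads))
  status <- ifelse(k == 0L, "unenriched",
                   ifelse(k == 1L, "monoclonal", "polyclonal"))
  bcs <- .random_dna(sum(k), cfg$barcode_length)
  truth <- list(
    beads = data.frame(bead_id = bead_id, n_barcodes = k, status = status,
                       stringsAsFactors = FALSE),
    bead_barcodes = data.frame(bead_id = rep.int(bead_id, k), barcode = bcs,
                               stringsAsFactors = FALSE))
  class(truth) <- "sim_truth"
  truth
}

# one barcode per read, chosen uniformly among the bead's barcodes
.draw_read_barcodes <- function(bead_of_read, bead_barcodes) {
  if (!length(bead_of_read)) return(character(0))
  bc_by_bead <- split(bead_barcodes$barcode, bead_barcodes$bead_id)
  nbc <- lengths(bc_by_bead)[bead_of_read]
  pick <- pmax(1L, ceiling(stats::runif(length(bead_of_read)) * nbc))
  unlist(mapply(function(b, i) bc_by_bead[[b]][i], bead_of_read, pick,
                USE.NAMES = FALSE, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Simulate the second-emulsion phasing run
#'
#' Each droplet holds one enriched bead (sampled without replacement
#' from the bead library) and M ~ Poisson(`fragment_cpb`) genomic
#' fragments drawn from `species_abundances`. For every fragment and
#' every target region, a Poisson(`reads_per_amplicon`) number of read
#' pairs is emitted: read 1 is `handle_5p` + bead barcode + `handle_3p`
#' (for polyclonal beads one barcode is chosen uniformly per read), read
#' 2 is the target amplicon of the fragment's species. Substitution
#' errors are applied to both mates. The returned truth records the
#' origin of every read.
#'
#' @param cfg a [sim_config()].
#' @param reference a `species_reference` from [make_reference()] (or
#'   [read_reference_fasta()]). Species order matches
#'   `cfg$species_abundances`.
#' @param truth optionally a pre-simulated bead library `sim_truth`.
#' @return an object of class `phasing_run`: list with `reads`
#'   (data.frame `read_id`, `seq1`, `seq2`), `truth` (completed
#'   `sim_truth` with `droplets`, `fragments`, `reads` tables), `config`
#'   and `reference`.
#' @export
simulate_phasing_run <- function(cfg, reference, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!inherits(reference, "species_reference") || nrow(reference) == 0L)
    stop_invalid("'reference' must be a non-empty species_reference")
  species <- unique(reference$species_id)
  targets <- unique(reference$target_id)
  if (length(cfg$species_abundances) != length(species))
    stop_invalid("'species_abundances' length must equal the number of reference species")
  if (is.null(truth)) truth <- simulate_bead_library(cfg)
  set.seed(stage_seed(cfg$seed, "phasing"))

  enriched <- truth$beads$bead_id[truth$beads$n_barcodes > 0L]
  if (cfg$n_droplets > length(enriched))
    stop_invalid(sprintf("need %d enriched beads for %d droplets, have %d",
                         cfg$n_droplets, cfg$n_droplets, length(enriched)))
  beads_used <- sample(enriched, cfg$n_droplets)
  droplet_id <- sprintf("drop%06d", seq_len(cfg$n_droplets))
  m <- stats::rpois(cfg$n_droplets, cfg$fragment_cpb)
  truth$droplets <- data.frame(droplet_id = droplet_id, bead_id = beads_used,
                               n_fragments = m, stringsAsFactors = FALSE)

  frag_drop <- rep.int(seq_len(cfg$n_droplets), m)
  n_frag <- length(frag_drop)
  frag_species <- if (n_frag)
    sample(species, n_frag, replace = TRUE, prob = cfg$species_abundances)
  else character(0)
  fragment_id <- sprintf("frag%06d", seq_len(n_frag))
  truth$fragments <- data.frame(fragment_id = fragment_id,
                                droplet_id = droplet_id[frag_drop],
                                bead_id = beads_used[frag_drop],
                                species_id = frag_species,
                                stringsAsFactors = FALSE)

  # one amplicon per fragment x target, Poisson read depth each
  amp_frag <- rep(seq_len(n_frag), each = length(targets))
  amp_target <- rep(targets, times = n_frag)
  n_reads <- stats::rpois(length(amp_frag), cfg$reads_per_amplicon)
  ri <- rep.int(seq_along(amp_frag), n_reads)
  n_total <- length(ri)

  ref_key <- paste(reference$species_id, reference$target_id, sep = "\r")
  amp_seq <- reference$sequence[match(
    paste(frag_species[amp_frag], amp_target, sep = "\r"), ref_key)]

  read_id <- sprintf("read%07d", seq_len(n_total))
  bead_of_read <- beads_used[frag_drop[amp_frag[ri]]]
  true_barcode <- .draw_read_barcodes(bead_of_read, truth$bead_barcodes)
  seq1 <- if (n_total) mutate_sequence(
    paste0(cfg$handle_5p, true_barcode, cfg$handle_3p),
    cfg$substitution_error_rate) else character(0)
  seq2 <- mutate_sequence(amp_seq[ri], cfg$substitution_error_rate)

  truth$reads <- data.frame(read_id = read_id,
                            droplet_id = droplet_id[frag_drop[amp_frag[ri]]],
                            bead_id = bead_of_read,
                            fragment_id = fragment_id[amp_frag[ri]],
                            species_id = frag_species[amp_frag[ri]],
                            target_id = amp_target[ri],
                            true_barcode = true_barcode,
                            stringsAsFactors = FALSE)
  structure(list(reads = data.frame(read_id = read_id, seq1 = seq1,
                                    seq2 = seq2, stringsAsFactors = FALSE),
                 truth = truth, config = cfg, reference = reference),
            class = "phasing_run")
}

#' Generate mutually distant well tags
#'
#' Random fixed-length tags with pairwise Hamming distance at least
#' `min_dist`, as required for mismatch-tolerant well demultiplexing
#' (`min_dist` must exceed twice the demultiplexing tolerance).
#'
#' @param n number of tags.
#' @param tag_length tag length in nt (long enough that rejection
#'   sampling can reach `n` mutually distant tags; 12 nt suffices for a
#'   96-well plate at distance 5).
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return character vector of `n` tags.
#' @export
make_well_tags <- function(n, tag_length = 12, min_dist = 5, seed = 1) {
  set.seed(stage_seed(seed, "well_tags"))
  tags <- character(0)
  attempts <- 0L
  while (length(tags) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n)
      stop_invalid("could not generate enough mutually distant well tags")
    cand <- .random_dna(1L, tag_length)
    if (!length(tags) ||
        all(vapply(tags, .hamming_pair, 0L, b = cand) >= min_dist))
      tags <- c(tags, cand)
  }
  tags
}

#' Simulate a bead sorting experiment
#'
#' One enriched bead is sorted into each well; its barcode region is
#' amplified and sequenced, each read carrying the well tag, the 5'
#' handle, one of the bead's barcodes (uniform per read) and the 3'
#' handle. Used to validate bead monoclonality against the Poisson
#' expectation.
#'
#' @param cfg a [sim_config()].
#' @param n_wells number of wells to sort into.
#' @param well_tags optional tag sequences (`length >= n_wells`); default
#'   generated with [make_well_tags()].
#' @param truth optional pre-simulated bead library.
#' @param reads_per_well mean Poisson read count per well.
#' @return an object of class `sorting_run`: list with `reads`
#'   (data.frame `read_id`, `seq1`), `wells` (data.frame `well_id`,
#'   `well_tag`, `bead_id`, `n_barcodes`), `truth`, `config`,
#'   `well_tags`.
#' @export
simulate_sorting_run <- function(cfg, n_wells = 96, well_tags = NULL,
                                 truth = NULL, reads_per_well = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- simulate_bead_library(cfg)
  if (is.null(well_tags)) well_tags <- make_well_tags(n_wells, seed = cfg$seed)
  if (n_wells > length(well_tags))
    stop_invalid("'n_wells' exceeds the number of well tags")
  set.seed(stage_seed(cfg$seed, "sorting"))
  enriched <- truth$beads$bead_id[truth$beads$n_barcodes > 0L]
  if (n_wells > length(enriched))
    stop_invalid("not enough enriched beads to fill the wells")
  beads_used <- sample(enriched, n_wells)
  well_id <- sprintf("well%03d", seq_len(n_wells))
  n_reads <- stats::rpois(n_wells, reads_per_well)
  wi <- rep.int(seq_len(n_wells), n_reads)
  read_id <- sprintf("read%07d", seq_along(wi))
  true_barcode <- .draw_read_barcodes(beads_used[wi], truth$bead_barcodes)
  seq1 <- mutate_sequence(
    paste0(well_tags[wi], cfg$handle_5p, true_barcode, cfg$handle_3p),
    cfg$substitution_error_rate)
  truth$wells <- data.frame(well_id = well_id,
                            well_tag = well_tags[seq_len(n_wells)],
                            bead_id = beads_used,
                            n_barcodes = truth$beads$n_barcodes[
                              match(beads_used, truth$beads$bead_id)],
                            stringsAsFactors = FALSE)
  truth$sorting_reads <- data.frame(read_id = read_id,
                                    well_id = well_id[wi],
                                    bead_id = beads_used[wi],
                                    true_barcode = true_barcode,
                                    stringsAsFactors = FALSE)
  structure(list(reads = data.frame(read_id = read_id, seq1 = seq1,
                                    stringsAsFactors = FALSE),
                 wells = truth$wells, truth = truth, config = cfg,
                 well_tags = well_tags[seq_len(n_wells)]),
            class = "sorting_run")
}

.write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write a simulated run to disk
#'
#' Emits standard 4-line FASTQ (paired, matched order) plus the
#' reference FASTA, the per-read ground truth as TSV and a JSON run
#' manifest, so every downstream stage can be exercised from files.
#'
#' @param run a `phasing_run` or `sorting_run`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  if (inherits(run, "phasing_run")) {
    .write_fastq(run$reads$seq1, run$reads$read_id, file.path(dir, "reads_1.fastq"))
    .write_fastq(run$reads$seq2, run$reads$read_id, file.path(dir, "reads_2.fastq"))
    write_reference_fasta(run$reference, file.path(dir, "reference.fasta"))
    utils::write.table(run$truth$reads, file.path(dir, "truth_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(run, "sorting_run")) {
    .write_fastq(run$reads$seq1, run$reads$read_id, file.path(dir, "reads_1.fastq"))
    utils::write.table(run$truth$sorting_reads, file.path(dir, "truth_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$wells, file.path(dir, "wells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop_invalid("'run' must be a phasing_run or sorting_run")
  manifest <- unclass(cfg)
  manifest$run_class <- class(run)[1L]
  manifest$n_reads <- nrow(run$reads)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param fastq1,fastq2 paths to mate-1 and (optionally) mate-2 FASTQ.
#' @return data.frame with `read_id`, `seq1` and, if `fastq2` is given,
#'   `seq2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2 = NULL) {
  s1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  out <- data.frame(read_id = sub(" .*$", "", names(s1)),
                    seq1 = as.character(s1), stringsAsFactors = FALSE)
  if (!is.null(fastq2)) {
    s2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
    if (length(s2) != length(s1))
      stop_invalid("FASTQ mates differ in read count")
    out$seq2 <- as.character(s2)
  }
  rownames(out) <- NULL
  out
}
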