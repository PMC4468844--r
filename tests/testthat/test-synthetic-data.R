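test_that("mutate_sequence substitutes at the requested rate", {
  expect_equal(mutate_sequence("ACGTACGT", 0), "ACGTACGT")
  expect_error(mutate_sequence("ACGT", 1), class = "beadphase_invalid")
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
             collapse = "")
  m <- mutate_sequence(s, 0.1, seed = 13)
  expect_equal(nchar(m), nchar(s))
  frac <- hamming_distance(s, m) / nchar(s)
  se <- sqrt(0.1 * 0.9 / 1e5)
  expect_lt(abs(frac - 0.1), 3 * se)
  # mutated sequences stay on the DNA alphabet
  expect_true(all(strsplit(m, "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("reference generation is seeded and has the expected divergence", {
  r1 <- make_reference(4, c(a = 200, b = 200), divergence = 0.05, seed = 3)
  r2 <- make_reference(4, c(a = 200, b = 200), divergence = 0.05, seed = 3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_reference_fasta(r1, f1); write_reference_fasta(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_reference_fasta(f1)
  expect_equal(back$sequence, r1$sequence)
  expect_equal(attr(back, "target_primers"), attr(r1, "target_primers"))

  expect_equal(nrow(make_reference(1, c(x = 100), 0.05, seed = 1)), 1)
  expect_error(make_reference(4, c(x = 100), divergence = 0.6),
               class = "beadphase_invalid")

  # two independently mutated copies differ at ~2d(1-d) of variable sites
  plen <- attr(r1, "primer_length")
  d <- 0.05; expd <- 2 * d * (1 - d)
  fr <- c()
  for (t in unique(r1$target_id)) {
    s <- r1$sequence[r1$target_id == t]
    v <- substr(s, plen + 1, nchar(s))
    for (i in 1:3) for (j in (i + 1):4)
      fr <- c(fr, hamming_distance(v[i], v[j]) / nchar(v[i]))
  }
  se <- sqrt(expd * (1 - expd) / (200 * length(fr)))
  expect_lt(abs(mean(fr) - expd), 3 * se * sqrt(length(fr)))
})

test_that("bead library loading follows the Poisson model", {
  cfg0 <- sim_config(n_beads = 500, barcode_cpb = 0, seed = 2)
  expect_true(all(simulate_bead_library(cfg0)$beads$status == "unenriched"))

  cfg <- sim_config(n_beads = 1e5, barcode_cpb = 0.1, seed = 2)
  truth <- simulate_bead_library(cfg)
  k <- truth$beads$n_barcodes
  occ <- 1 - exp(-0.1)
  expect_lt(abs(mean(k >= 1) - occ), 3 * sqrt(occ * (1 - occ) / 1e5))
  mono <- monoclonal_fraction(loading_model(0.1))
  expect_lt(abs(mean(k[k >= 1] == 1) - mono),
            3 * sqrt(mono * (1 - mono) / sum(k >= 1)))
  # one barcode row per loaded molecule, all of configured length
  expect_equal(nrow(truth$bead_barcodes), sum(k))
  expect_true(all(nchar(truth$bead_barcodes$barcode) == cfg$barcode_length))
})

test_that("phasing run emits truth-consistent reads", {
  ref <- small_reference()
  # no fragments -> no reads
  run0 <- simulate_phasing_run(
    sim_config(n_beads = 3000, n_droplets = 100, fragment_cpb = 0, seed = 4),
    ref)
  expect_equal(nrow(run0$reads), 0)

  run <- small_run(seed = 4, error = 0)
  expect_gt(nrow(run$reads), 0)
  # every emitted read appears exactly once in the truth
  expect_identical(sort(run$reads$read_id), sort(run$truth$reads$read_id))
  expect_false(anyDuplicated(run$truth$reads$read_id) > 0)
  # droplets reference existing enriched beads
  expect_true(all(run$truth$droplets$bead_id %in% run$truth$beads$bead_id))
  # with zero error rate read 2 is exactly the reference amplicon
  key <- paste(ref$species_id, ref$target_id)
  expected2 <- ref$sequence[match(
    paste(run$truth$reads$species_id, run$truth$reads$target_id), key)]
  expect_identical(run$reads$seq2, expected2)
  # and read 1 is handles + true barcode
  cfg <- run$config
  expect_identical(run$reads$seq1,
                   paste0(cfg$handle_5p, run$truth$reads$true_barcode,
                          cfg$handle_3p))
  expect_error(simulate_phasing_run(sim_config(n_beads = 10, n_droplets = 50),
                                    ref),
               class = "beadphase_invalid")
})

test_that("droplet fragment loading matches the Poisson model", {
  ref <- small_reference()
  cfg <- sim_config(n_beads = 1.2e5, n_droplets = 1e4, fragment_cpb = 0.1,
                    reads_per_amplicon = 1, seed = 6)
  run <- simulate_phasing_run(cfg, ref)
  m <- run$truth$droplets$n_fragments
  occupied <- m[m >= 1]
  mono <- monoclonal_fraction(loading_model(0.1))
  expect_lt(abs(mean(occupied == 1) - mono),
            3 * sqrt(mono * (1 - mono) / length(occupied)))
  # species composition converges to the configured abundances
  frac <- table(factor(run$truth$fragments$species_id,
                       levels = unique(ref$species_id))) /
    nrow(run$truth$fragments)
  expect_lt(max(abs(as.numeric(frac) - cfg$species_abundances)),
            3 * sqrt(0.4 * 0.6 / nrow(run$truth$fragments)))
})

test_that("identical configs give byte-identical run outputs", {
  ref <- small_reference()
  d1 <- tempfile(); d2 <- tempfile()
  write_run(small_run(seed = 9, error = 0.005, n_droplets = 100,
                      n_beads = 3000, reference = ref), d1)
  write_run(small_run(seed = 9, error = 0.005, n_droplets = 100,
                      n_beads = 3000, reference = ref), d2)
  for (f in c("reads_1.fastq", "reads_2.fastq", "truth_reads.tsv",
              "reference.fasta")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # read pairs written in matched order and re-readable
  rp <- read_fastq_pairs(file.path(d1, "reads_1.fastq"),
                         file.path(d1, "reads_2.fastq"))
  expect_equal(nrow(rp), 0 + length(readLines(file.path(d1, "reads_1.fastq"))) / 4)
})

test_that("sorting runs place one bead per well with per-read barcode choice", {
  cfg <- sim_config(n_beads = 50, barcode_cpb = 5, seed = 3,
                    substitution_error_rate = 0)
  # monoclonal bead: force a single-barcode truth
  truth <- list(beads = data.frame(bead_id = "bead000001", n_barcodes = 1L,
                                   status = "monoclonal"),
                bead_barcodes = data.frame(bead_id = "bead000001",
                                           barcode = strrep("ACGTA", 3)))
  class(truth) <- "sim_truth"
  cfg1 <- sim_config(n_beads = 1, seed = 3, substitution_error_rate = 0)
  run1 <- simulate_sorting_run(cfg1, n_wells = 1, truth = truth,
                               reads_per_well = 60)
  lay <- default_layout(cfg1, offset = nchar(run1$well_tags[1]))
  obs <- extract_barcodes(run1$reads$seq1, lay)
  expect_true(all(obs$barcode == strrep("ACGTA", 3)))

  # two-barcode bead: both barcodes present near 50/50
  truth2 <- list(beads = data.frame(bead_id = "bead000001", n_barcodes = 2L,
                                    status = "polyclonal"),
                 bead_barcodes = data.frame(
                   bead_id = "bead000001",
                   barcode = c(strrep("A", 15), strrep("C", 15))))
  class(truth2) <- "sim_truth"
  run2 <- simulate_sorting_run(cfg1, n_wells = 1, truth = truth2,
                               reads_per_well = 400)
  obs2 <- extract_barcodes(run2$reads$seq1,
                           default_layout(cfg1, offset = nchar(run2$well_tags[1])))
  p <- mean(obs2$barcode == strrep("A", 15))
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(run2$reads)))

  # determinism of sorting FASTQ bytes
  d1 <- tempfile(); d2 <- tempfile()
  write_run(simulate_sorting_run(sim_config(n_beads = 2000, seed = 5),
                                 n_wells = 12), d1)
  write_run(simulate_sorting_run(sim_config(n_beads = 2000, seed = 5),
                                 n_wells = 12), d2)
  expect_identical(readBin(file.path(d1, "reads_1.fastq"), "raw",
                           file.size(file.path(d1, "reads_1.fastq"))),
                   readBin(file.path(d2, "reads_1.fastq"), "raw",
                           file.size(file.path(d2, "reads_1.fastq"))))
})
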