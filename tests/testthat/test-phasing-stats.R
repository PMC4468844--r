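mk_calls <- function(call1, call2) {
  n <- max(length(call1), length(call2))
  call1 <- rep_len(call1, n); call2 <- rep_len(call2, n)
  cl <- sprintf("c%03d", seq_len(n))
  rbind(
    data.frame(cluster_id = cl[!is.na(call1)], target_id = "t1",
               best_call = call1[!is.na(call1)], stringsAsFactors = FALSE),
    data.frame(cluster_id = cl[!is.na(call2)], target_id = "t2",
               best_call = call2[!is.na(call2)], stringsAsFactors = FALSE))
}

test_that("target presence fractions tally single and double recovery", {
  calls <- mk_calls(c("A", "A", NA, NA, NA, NA, NA, "A", "B", "A"),
                    c(NA, NA, "B", "B", "B", "B", "B", "A", "B", "B"))
  fr <- target_presence_fractions(calls, c("t1", "t2"))
  expect_equal(fr$frac_target1_only, 0.2)
  expect_equal(fr$frac_target2_only, 0.5)
  expect_equal(fr$frac_both, 0.3)
  all_both <- target_presence_fractions(mk_calls(rep("A", 4), rep("B", 4)))
  expect_equal(all_both$frac_both, 1.0)
})

test_that("the observed phasing rate is the eligible match fraction", {
  expect_equal(as.numeric(phasing_rate(mk_calls(rep("A", 5), rep("A", 5)))), 1)
  calls <- mk_calls(rep("A", 8), c(rep("A", 6), "B", "B"))
  expect_equal(as.numeric(phasing_rate(calls)), 0.75)
  expect_equal(attr(phasing_rate(calls), "n_eligible"), 8L)
  expect_equal(as.numeric(phasing_rate(mk_calls(rep("A", 4), rep("B", 4)))), 0)
  # ambiguous calls are not eligible
  amb <- mk_calls(c("A", "A", "ambiguous"), c("A", "B", "A"))
  expect_equal(attr(phasing_rate(amb), "n_eligible"), 2L)
  expect_error(phasing_rate(mk_calls(c("A", NA), c(NA, "B"))),
               class = "beadphase_undefined")
})

test_that("the shuffle null matches the analytic collision probability", {
  # all one species: every permutation matches everywhere
  r1 <- random_match_rate(mk_calls(rep("A", 20), rep("A", 20)), 50, seed = 3)
  expect_equal(r1$p_rand, 1)
  expect_equal(r1$se, 0)

  # marginal frequencies p -> sum(p^2)
  set.seed(61)
  sp <- c("A", "B", "C")
  p <- c(0.6, 0.3, 0.1)
  c2 <- sample(sp, 3000, replace = TRUE, prob = p)
  calls <- mk_calls(sample(sp, 3000, replace = TRUE, prob = p), c2)
  rr <- random_match_rate(calls, 100, seed = 5)
  p2hat <- table(factor(c2, sp)) / 3000
  expected <- sum((table(factor(calls$best_call[calls$target_id == "t1"], sp)) / 3000) * p2hat)
  expect_lt(abs(rr$p_rand - expected), 3 * max(rr$se, 1e-4))
  expect_lt(abs(rr$p_rand - analytic_random_match(p)), 0.02)
})

test_that("analytic random match is the sum of squared frequencies", {
  expect_equal(analytic_random_match(rep(0.25, 4)), 0.25)
  expect_equal(analytic_random_match(1), 1)
  expect_equal(analytic_random_match(c(0.5, 0.5)), 0.5)
  expect_error(analytic_random_match(c(0.5, 0.4)),
               class = "beadphase_invalid")
})

test_that("chance correction reproduces the worked example", {
  # printed observed 91.5% and random 11.9% give the printed 90.3%
  expect_lt(abs(100 * corrected_phasing_rate(0.915, 0.119) - 90.3), 0.1)
  expect_equal(corrected_phasing_rate(0.4, 0.4), 0)
  expect_equal(corrected_phasing_rate(1.0, 0.3), 1.0)
  expect_equal(corrected_phasing_rate(0.2, 0.4), 0)  # clamped at zero
  expect_error(corrected_phasing_rate(0.9, 1), class = "beadphase_undefined")
  # no correction needed when chance matching is impossible
  expect_equal(corrected_phasing_rate(0.7, 0), 0.7)
})

test_that("dominant-species removal recomputes the summary on the rest", {
  calls <- mk_calls(c(rep("D", 6), "A", "A", "B", "B"),
                    c(rep("D", 6), "A", "B", "B", "A"))
  res <- remove_dominant_species(calls, n_shuffles = 50, seed = 7)
  expect_equal(res$dominant_species, "D")
  expect_equal(res$n_removed, 6)
  expect_setequal(unique(res$calls$cluster_id),
                  sprintf("c%03d", 7:10))
  expect_equal(res$p_obs, 0.5)  # c007 and c009 match among the 4 left
  expect_error(remove_dominant_species(mk_calls(rep("A", 5), rep("A", 5))),
               class = "beadphase_undefined")
})

test_that("random matching drops toward the minor-species collision rate after removal", {
  set.seed(63)
  sp <- c("dom", "m1", "m2", "m3")
  p <- c(0.7, 0.1, 0.1, 0.1)
  draw <- function() sample(sp, 4000, replace = TRUE, prob = p)
  calls <- mk_calls(draw(), draw())
  res <- remove_dominant_species(calls, n_shuffles = 100, seed = 9)
  # renormalized minor-species mixture is uniform over 3 -> ~1/3
  expect_lt(abs(res$p_rand$p_rand - 1 / 3), 0.02)
  full <- random_match_rate(calls, 100, seed = 9)
  expect_gt(full$p_rand, res$p_rand$p_rand)
})

test_that("hit-list overlap reduction follows the set arithmetic", {
  same <- hitlist_overlap_reduction(list(c("a", "b")), list(c("a", "b")))
  expect_equal(same$mean_reduction, 0)
  disj <- hitlist_overlap_reduction(list(c("a", "b")), list(c("c")))
  expect_equal(disj$mean_reduction, 1)
  ex <- hitlist_overlap_reduction(list(c("s1", "s2", "s3")),
                                  list(c("s2", "s3", "s4")))
  expect_equal(ex$mean_overlap, 2)
  expect_equal(ex$mean_len1, 3)
  expect_equal(ex$mean_reduction, 1 / 3)
  skipped <- hitlist_overlap_reduction(list(c("a"), character(0)),
                                       list(c("a"), c("b")))
  expect_equal(skipped$n_skipped, 1)
})

test_that("depth subsampling reduces to the full run at fraction one", {
  run <- small_run(seed = 65, error = 0.005, n_droplets = 200, n_beads = 5000)
  full <- run_phasing_pipeline(run)
  tab <- depth_subsample(run, fractions = c(0.05, 0.3, 1), seed = 17)
  expect_equal(tab$n_clusters[3], full$summary$n_clusters)
  expect_equal(tab$frac_both[3], full$summary$frac_both)
  # shallower sequencing passes no more clusters through the filters
  expect_true(all(diff(tab$n_clusters) >= 0))
  expect_error(depth_subsample(run, fractions = 0), class = "beadphase_invalid")
})
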