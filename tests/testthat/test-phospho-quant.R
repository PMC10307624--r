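make_meas <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(peptide_id = r[[1]], protein = r[[2]], site_positions = r[[3]],
               run = r[[4]], condition = r[[5]], timepoint = r[[6]],
               replicate = as.integer(r[[7]]),
               intensity = as.numeric(r[[8]]), stringsAsFactors = FALSE)))
}

test_that("peptides with the same site set are summed on the linear scale", {
  m <- make_meas(list("p1", "PROT1", "S15", "r1", "stim", "1h", 1, 10),
                 list("p2", "PROT1", "S15", "r1", "stim", "1h", 1, 12),
                 list("p3", "PROT1", "S15;T20", "r1", "stim", "1h", 1, 8))
  sg <- build_site_groups(m)
  expect_equal(nrow(sg), 2)  # {S15} and {S15,T20} are distinct groups
  one <- sg[sg$site_key == "PROT1_S15", ]
  expect_equal(one$intensity, log2(2^10 + 2^12))
  expect_true("PROT1_S15_T20" %in% sg$site_key)
})

test_that("grouping conserves total linear intensity and is idempotent", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_proteins = 12,
                    missing_prob = 0, seed = 2)
  pr <- generate_protein_set(12, c(60, 90), seed = 2, id_prefix = "P")
  st <- pick_phosphosites(pr, c(2, 3), seed = 3)
  m <- simulate_phospho_experiment(des, NULL, st)
  sg <- build_site_groups(m)
  for (r in unique(m$run)) {
    expect_equal(sum(2^sg$intensity[sg$run == r]),
                 sum(2^m$intensity[m$run == r]), tolerance = 1e-9)
  }
  # idempotence: regrouping the grouped table changes nothing
  m2 <- data.frame(peptide_id = sg$site_key, protein = sg$protein,
                   site_positions = gsub("_", ";", sg$positions),
                   run = sg$run, condition = sg$condition,
                   timepoint = sg$timepoint, replicate = sg$replicate,
                   intensity = sg$intensity)
  sg2 <- build_site_groups(m2)
  expect_equal(sg2$intensity[order(sg2$site_key, sg2$run)],
               sg$intensity[order(sg$site_key, sg$run)], tolerance = 1e-12)
})

test_that("grouping validates positions and handles empty input", {
  expect_equal(nrow(build_site_groups(
    make_meas(list("p", "P1", "S5", "r", "c", "t", 1, 1))[0, ])), 0)
  expect_error(build_site_groups(
    make_meas(list("p", "P1", "X5", "r", "c", "t", 1, 1))), "malformed")
  expect_error(build_site_groups(
    make_meas(list("p", "P1", "S999", "r", "c", "t", 1, 1)),
    proteins = c(P1 = "MKSTY")), "beyond")
})

test_that("median normalization equalizes run medians and is idempotent", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_proteins = 15,
                    missing_prob = 0, seed = 4)
  pr <- generate_protein_set(15, c(60, 90), seed = 4, id_prefix = "P")
  st <- pick_phosphosites(pr, c(2, 3), seed = 5)
  m <- simulate_phospho_experiment(des, NULL, st)
  sg <- build_site_groups(m)
  nm <- equal_median_normalize(sg)
  meds <- tapply(nm$intensity, nm$run, median)
  expect_true(all(abs(meds - meds[1]) < 1e-9))
  nm2 <- equal_median_normalize(nm)
  expect_equal(nm2$intensity, nm$intensity, tolerance = 1e-12)
})

test_that("constructed run offsets are recovered up to a common constant", {
  # identical site values in every run, plus injected offsets {+1, 0, -1}
  base <- c(20, 21, 23, 26)
  runs <- c("r1", "r2", "r3")
  off <- c(r1 = 1, r2 = 0, r3 = -1)
  m <- do.call(rbind, lapply(runs, function(r)
    make_meas(list(paste0("p", 1:4), "P1",
                   c("S5", "T8", "S12", "Y20"), r, "stim", "1h", 1,
                   base + off[[r]]))))
  sg <- build_site_groups(m)
  nm <- equal_median_normalize(sg)
  shifts <- attr(nm, "shifts")
  expect_equal(unname(shifts - shifts["r2"]),
               unname(-off + off["r2"]), tolerance = 1e-12)
  # a single run (already sharing a median) is a fixed point
  one <- sg[sg$run == "r1", ]
  expect_equal(equal_median_normalize(one)$intensity, one$intensity)
})

test_that("normalization rejects a run with no finite values", {
  sg <- build_site_groups(
    make_meas(list("p1", "P1", "S5", "r1", "stim", "1h", 1, 20)))
  sg$intensity <- NaN
  expect_error(equal_median_normalize(sg), "no finite")
})

test_that("differential test computes exact fold changes and edge cases", {
  mk <- function(vals, cond, rep)
    make_meas(list(paste0("p", cond, rep), "P1", "S5",
                   paste0(cond, "_1h_r", rep), cond, "1h", rep, vals))
  m <- rbind(mk(3, "stim", 1), mk(3, "stim", 2), mk(3, "stim", 3),
             mk(1, "US", 1), mk(1, "US", 2), mk(1, "US", 3))
  sg <- build_site_groups(m)
  ct <- default_contrasts(sg, control = "US")
  st <- differential_test(sg, ct)
  expect_equal(st$log2FC, 2)
  expect_lt(st$p, 1e-8)  # unequal means at zero variance: floored, tiny p

  # identical samples: fold change 0, p = 1
  m2 <- rbind(mk(5, "stim", 1), mk(5, "stim", 2),
              mk(5, "US", 1), mk(5, "US", 2))
  st2 <- differential_test(build_site_groups(m2), ct)
  expect_equal(st2$log2FC, 0)
  expect_equal(st2$p, 1)

  expect_error(differential_test(sg, data.frame(
    name = "x", treatment = "nosuch", control = "US", timepoint = "1h")),
    "unknown contrast")
})

test_that("one-sided sites get infinite fold changes and no p value", {
  m <- make_meas(list("p1", "P1", "S5", "stim_1h_r1", "stim", "1h", 1, 20),
                 list("p1", "P1", "S5", "stim_1h_r2", "stim", "1h", 2, 21),
                 list("p2", "P1", "T9", "US_1h_r1", "US", "1h", 1, 18),
                 list("p2", "P1", "T9", "US_1h_r2", "US", "1h", 2, 18.5))
  sg <- build_site_groups(m)
  st <- differential_test(sg, default_contrasts(sg, "US"))
  s5 <- st[st$site_key == "P1_S5", ]
  t9 <- st[st$site_key == "P1_T9", ]
  expect_identical(s5$log2FC, Inf)   # missing control side
  expect_identical(t9$log2FC, -Inf)  # missing treated side
  expect_true(is.na(s5$p) && is.na(t9$p))
})

test_that("null data attain nominal type-I error", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_replicates = 3,
                    n_proteins = 120, sites_per_protein = c(3, 4),
                    noise_sd = 0.3, missing_prob = 0, seed = 101)
  q1 <- quant_chain(des, length_range = c(80, 140))
  des2 <- sim_design(ligands = "stim", timepoints = "1h", n_replicates = 3,
                     n_proteins = 120, sites_per_protein = c(3, 4),
                     noise_sd = 0.3, missing_prob = 0, seed = 202)
  q2 <- quant_chain(des2, length_range = c(80, 140))
  p <- c(q1$site_stats$p, q2$site_stats$p)
  expect_gte(length(p), 800)
  frac <- mean(p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)                    # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))                # hand-evaluated
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(3:80, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("adjusted p never falls below p and respects the step-up order", {
  set.seed(7)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("fold-change collapse picks the lowest-p finite record", {
  base <- data.frame(
    site_key = c("P1_S15", "P1_S15_T20"), protein = "P1",
    positions = c("S15", "S15_T20"), contrast = "stim_1h",
    treatment = "stim", timepoint = "1h", se = 0.1,
    n_treated = 3L, n_control = 3L)
  st <- rbind(cbind(base[1, ], log2FC = 1.2, p = 0.01, adj_p = 0.02),
              cbind(base[2, ], log2FC = -3.0, p = 0.5, adj_p = 0.5))
  fc <- collapse_site_fc(st)
  expect_equal(fc$fc[fc$position == 15], 1.2)  # lowest p wins
  expect_equal(fc$fc[fc$position == 20], -3.0) # only record for T20

  # noninfinite filter: an infinite record never wins, whatever its p
  st2 <- rbind(cbind(base[1, ], log2FC = Inf, p = 0.001, adj_p = 0.001),
               cbind(base[2, ], log2FC = 0.4, p = 0.2, adj_p = 0.2))
  fc2 <- collapse_site_fc(st2)
  expect_equal(fc2$fc[fc2$position == 15], 0.4)

  # all records infinite: site omitted with a notice
  st3 <- cbind(base[1, ], log2FC = Inf, p = NA_real_, adj_p = NA_real_)
  expect_message(fc3 <- collapse_site_fc(st3), "omitted")
  expect_equal(nrow(fc3), 0)

  # single finite record maps to itself
  st4 <- cbind(base[1, ], log2FC = 0.7, p = 0.3, adj_p = 0.3)
  fc4 <- collapse_site_fc(st4)
  expect_equal(fc4[, c("fc", "source_p")],
               data.frame(fc = 0.7, source_p = 0.3))
})

test_that("collapse output is a subset of its input records", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_proteins = 20,
                    missing_prob = 0.1, seed = 61)
  q <- quant_chain(des)
  st <- q$site_stats
  for (i in seq_len(nrow(q$site_fc))) {
    r <- q$site_fc[i, ]
    src <- st[st$site_key == r$source_group & st$contrast == r$contrast, ]
    expect_equal(src$log2FC, r$fc)
    expect_equal(src$p, r$source_p)
  }
})

test_that("changed proteins honour 'significant in at least one timepoint'", {
  toy <- data.frame(
    site_key = paste0("P", 1:5, "_S1"), protein = paste0("P", 1:5),
    positions = "S1", treatment = "stim",
    contrast = rep(c("stim_1h", "stim_3h"), length.out = 5),
    timepoint = rep(c("1h", "3h"), length.out = 5),
    log2FC = 1, se = 0.1, p = 0.01,
    adj_p = c(0.04, 0.2, 0.01, 0.6, 0.9),
    n_treated = 3L, n_control = 3L)
  expect_identical(select_changed_proteins(toy, ligand = "stim"),
                   c("P1", "P3"))
  # a protein significant at one timepoint only is included
  two <- rbind(toy[1, ], transform(toy[1, ], contrast = "stim_3h",
                                   timepoint = "3h", adj_p = 0.2))
  expect_identical(select_changed_proteins(two), "P1")
  none <- transform(toy, adj_p = 0.9)
  expect_identical(select_changed_proteins(none), character(0))
})
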