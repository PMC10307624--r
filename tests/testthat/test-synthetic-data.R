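test_that("protein generation is deterministic, bounded and phosphosite-rich", {
  a <- generate_protein_set(1, c(30, 30), seed = 1)
  b <- generate_protein_set(1, c(30, 30), seed = 1)
  expect_identical(a, b)

  p <- generate_protein_set(50, c(200, 400), seed = 7)
  expect_length(p, 50)
  expect_true(all(nchar(p) >= 200 & nchar(p) <= 400))
  sty <- vapply(strsplit(p, ""), function(x)
    sum(x %in% c("S", "T", "Y")), integer(1))
  expect_true(all(sty >= 3))

  expect_error(generate_protein_set(1, c(10, 10)), "length_range")
})

test_that("design validation rejects degenerate studies", {
  expect_error(sim_design(n_replicates = 1), "n_replicates")
  expect_error(sim_design(noise_sd = 0), "noise_sd")
  expect_error(sim_design(ligands = c("a", "a")), "unique")
  expect_s3_class(sim_design(), "sim_design")
})

test_that("ortholog mutation with zero rates is the identity", {
  seq <- generate_protein_set(1, c(60, 60), seed = 3)[[1]]
  mo <- mutate_ortholog(seq, 0, 0, seed = 5)
  expect_identical(mo$sequence, seq)
  expect_identical(mo$position_map, seq_len(nchar(seq)))
  expect_equal(nrow(mo$edits), 0)
})

test_that("a single deletion shifts downstream positions by one", {
  # deletion of position k: positions < k map to themselves, > k to pos - 1
  seq <- "MKTAYSLEQWRSTHDVKPLN"
  k <- 8L
  src <- strsplit(seq, "")[[1]]
  mut <- paste(src[-k], collapse = "")
  expected <- c(seq_len(k - 1), NA_integer_, seq(k, nchar(seq) - 1))
  # construct via the edit-replay oracle to pin the arithmetic
  rep <- replay_edits(seq, data.frame(op = "del", source_pos = k,
                                      residue = src[k]))
  expect_identical(rep$sequence, mut)
  expect_identical(rep$position_map, expected)
})

test_that("recorded edit scripts replay to the emitted ortholog and map", {
  seqs <- generate_protein_set(10, c(80, 150), seed = 11)
  for (i in seq_along(seqs)) {
    mo <- mutate_ortholog(seqs[[i]], 0.05, 0.02, seed = 100 + i)
    rep <- replay_edits(seqs[[i]], mo$edits)
    expect_identical(rep$sequence, mo$sequence)
    expect_identical(rep$position_map, mo$position_map)
    def <- mo$position_map[!is.na(mo$position_map)]
    expect_true(all(diff(def) > 0))  # strictly increasing where defined
  }
})

test_that("mutation rates outside [0, 0.3] are rejected", {
  expect_error(mutate_ortholog("MKTAYSLEQWRSTHDVKPLN", 0.5, 0), "0.3")
  expect_error(mutate_ortholog("MKTAYSLEQWRSTHDVKPLN", 0, 0.4), "0.3")
})

test_that("simulated measurement tables are seed-deterministic", {
  des <- sim_design(n_proteins = 15, seed = 9)
  pr <- generate_protein_set(15, c(60, 100), seed = 9)
  st <- pick_phosphosites(pr, c(2, 3), seed = 10)
  m1 <- simulate_phospho_experiment(des, NULL, st)
  m2 <- simulate_phospho_experiment(des, NULL, st)
  expect_identical(m1, m2)
})

test_that("null simulation centres per-site fold changes near zero", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_replicates = 3,
                    n_proteins = 25, noise_sd = 0.3, missing_prob = 0,
                    seed = 21)
  q <- quant_chain(des)
  # mean log2FC across contrasts within 3 * noise_sd / sqrt(n)
  bound <- 3 * des$noise_sd / sqrt(des$n_replicates)
  expect_lt(abs(mean(q$site_fc$fc)), bound)
})

test_that("planted kinase shifts are recovered in substrate fold changes", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_replicates = 3,
                    n_proteins = 30, noise_sd = 0.3, missing_prob = 0,
                    seed = 33)
  pr <- generate_protein_set(30, c(60, 120), seed = 33, id_prefix = "P")
  st <- pick_phosphosites(pr, c(2, 4), seed = 40)
  truth <- make_synthetic_truth(st, des, n_kinases = 1,
                                substrates_per_kinase = 10, n_active = 1,
                                delta = 2, seed = 41)
  q <- quant_chain(des, truth, sites = st, proteins = pr)
  sa <- truth$substrate_assignment
  sub_fc <- q$site_fc$fc[paste(q$site_fc$protein, q$site_fc$position) %in%
                           paste(sa$protein, sa$position)]
  expect_gte(mean(sub_fc), 1.5)
  expect_lte(mean(sub_fc), 2.5)
})

test_that("substrate mean fold change converges to delta with replicates", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_replicates = 50,
                    n_proteins = 30, noise_sd = 0.3, missing_prob = 0,
                    seed = 55)
  pr <- generate_protein_set(30, c(60, 120), seed = 55, id_prefix = "P")
  st <- pick_phosphosites(pr, c(2, 4), seed = 56)
  truth <- make_synthetic_truth(st, des, n_kinases = 1,
                                substrates_per_kinase = 10, n_active = 1,
                                delta = 1.5, seed = 57)
  q <- quant_chain(des, truth, sites = st, proteins = pr)
  sa <- truth$substrate_assignment
  # restrict to records collapsed from single-site groups: compound
  # peptides carry the sum of their member shifts by construction
  single <- lengths(regmatches(
    q$site_fc$source_group,
    gregexpr("_[STY][0-9]+", q$site_fc$source_group))) == 1
  fc1 <- q$site_fc[single, ]
  is_sub <- paste(fc1$protein, fc1$position) %in%
    paste(sa$protein, sa$position)
  # background-relative recovery (the pipeline estimand): the common
  # normalization constant cancels between substrate and null sites
  delta_hat <- mean(fc1$fc[is_sub]) - mean(fc1$fc[!is_sub])
  # se of the mean at n = 50 is noise_sd * sqrt(2/50) / sqrt(10) ~ 0.02
  expect_lt(abs(delta_hat - 1.5), 0.15)
})

test_that("a planted kinase losing its substrates to missingness signals", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_replicates = 2,
                    n_proteins = 8, missing_prob = 0.98, seed = 3)
  pr <- generate_protein_set(8, c(60, 80), seed = 3, id_prefix = "P")
  st <- pick_phosphosites(pr, c(2, 2), seed = 4)
  truth <- make_synthetic_truth(st, des, n_kinases = 2,
                                substrates_per_kinase = 2, n_active = 1,
                                seed = 5)
  expect_error(simulate_phospho_experiment(des, truth, st),
               "fewer than 2 measured substrate")
})

test_that("ground-truth and measurement files round-trip losslessly", {
  des <- sim_design(n_proteins = 10, seed = 77)
  study <- synthesize_study(des, n_kinases = 3, substrates_per_kinase = 2,
                            n_active = 1, length_range = c(60, 100))
  d <- withr::local_tempdir()

  write_measurements(study$measurements, file.path(d, "m.tsv"))
  m2 <- read_measurements(file.path(d, "m.tsv"))
  expect_equal(m2, study$measurements, ignore_attr = TRUE)

  write_truth(study$truth, file.path(d, "truth"))
  t2 <- read_truth(file.path(d, "truth"))
  expect_equal(t2$planted_deltas, study$truth$planted_deltas,
               ignore_attr = TRUE)
  expect_equal(t2$substrate_assignment, study$truth$substrate_assignment,
               ignore_attr = TRUE)
  expect_identical(t2$position_maps[names(study$truth$position_maps)],
                   lapply(study$truth$position_maps, as.integer))

  write_fasta(study$proteins_src, file.path(d, "s.faa"))
  expect_identical(read_fasta(file.path(d, "s.faa")), study$proteins_src)

  write_ks_annotation(study$annotation, file.path(d, "ks.tsv"))
  a2 <- read_ks_annotation(file.path(d, "ks.tsv"))
  expect_equal(a2, study$annotation, ignore_attr = TRUE)

  write_gmt(study$terms, file.path(d, "t.gmt"))
  expect_identical(read_gmt(file.path(d, "t.gmt")), study$terms)
})

test_that("linear-scale emission round-trips through the log2 path", {
  des <- sim_design(ligands = "stim", timepoints = "1h", n_proteins = 10,
                    missing_prob = 0, seed = 13)
  pr <- generate_protein_set(10, c(60, 80), seed = 13, id_prefix = "P")
  st <- pick_phosphosites(pr, c(2, 2), seed = 14)
  lin <- simulate_phospho_experiment(des, NULL, st, linear_scale = TRUE)
  log <- simulate_phospho_experiment(des, NULL, st, linear_scale = FALSE)
  sg_lin <- build_site_groups(lin)
  sg_log <- build_site_groups(log)
  expect_equal(sg_lin$intensity, sg_log$intensity, tolerance = 1e-10)
})
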