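#' @useDynLib phosphokin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median p.adjust pnorm rnorm runif sd t.test phyper ave
#' @importFrom stats coef simulate setNames aggregate var pt
#' @importFrom utils head read.delim write.table data
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# sample() treats a length-1 vector as 1:n; this keeps singletons literal
.sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# amino-acid sampling weights with S/T/Y boosted so every protein carries
# candidate phosphosites
.aa_weights <- local({
  w <- rep(1, 20)
  names(w) <- AA20
  w["S"] <- 2.4
  w["T"] <- 2.0
  w["Y"] <- 1.2
  w / sum(w)
})

#' Experimental design for the synthetic phosphoproteomics study
#'
#' Describes a ligand-stimulation time course: each ligand is measured at each
#' timepoint against a time-matched unstimulated control, with `n_replicates`
#' biological replicates per condition/timepoint. Defaults mirror a
#' two-ligand (fibrin, iC3b), two-timepoint (1 h, 3 h) design with n = 3.
#'
#' @param ligands character vector of stimulation condition labels.
#' @param timepoints character vector of timepoint labels.
#' @param n_replicates integer, biological replicates per condition/timepoint
#'   (must be >= 2).
#' @param n_proteins number of proteins to simulate.
#' @param sites_per_protein integer range `c(min, max)` of phosphosites
#'   placed per protein.
#' @param noise_sd log2-intensity standard deviation of replicate noise.
#' @param missing_prob probability that any single measurement is dropped.
#' @param control_label label of the unstimulated control condition.
#' @param seed master seed; stage-level child seeds are derived from it by
#'   fixed offsets.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(ligands = c("fibrin", "iC3b"),
                       timepoints = c("1h", "3h"),
                       n_replicates = 3L,
                       n_proteins = 60L,
                       sites_per_protein = c(2L, 4L),
                       noise_sd = 0.3,
                       missing_prob = 0.1,
                       control_label = "US",
                       seed = 1L) {
  stopifnot(length(ligands) >= 1, length(timepoints) >= 1)
  if (n_replicates < 2)
    stop("n_replicates must be >= 2")
  if (noise_sd <= 0)
    stop("noise_sd must be > 0")
  labs <- c(ligands, control_label)
  if (anyDuplicated(labs) || anyDuplicated(timepoints))
    stop("condition and timepoint labels must be unique")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must be in [0, 1)")
  structure(list(ligands = ligands, timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 n_proteins = as.integer(n_proteins),
                 sites_per_protein = as.integer(sites_per_protein),
                 noise_sd = noise_sd, missing_prob = missing_prob,
                 control_label = control_label, seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a random protein set
#'
#' Sequences are drawn over the 20 standard amino acids with serine,
#' threonine and tyrosine frequencies boosted; every returned protein is
#' guaranteed to contain at least three S/T/Y residues.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range `c(min, max)`; minimum allowed is 30.
#' @param seed integer seed (deterministic output for a fixed seed).
#' @param id_prefix prefix for generated accessions.
#' @return named character vector of sequences.
#' @export
generate_protein_set <- function(n_proteins, length_range = c(200L, 400L),
                                 seed = 1L, id_prefix = "PROT") {
  length_range <- as.integer(rep(length_range, length.out = 2))
  if (min(length_range) < 30)
    stop("length_range must be >= 30 (too short to place sites and indels)")
  set.seed(seed)
  seqs <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    repeat {
      len <- .sample1(seq(length_range[1], length_range[2]))
      aa <- sample(AA20, len, replace = TRUE, prob = .aa_weights)
      if (sum(aa %in% c("S", "T", "Y")) >= 3) break
    }
    seqs[i] <- paste(aa, collapse = "")
  }
  names(seqs) <- sprintf("%s%04d", id_prefix, seq_len(n_proteins))
  seqs
}

#' Mutate a protein into a synthetic ortholog with a recorded position map
#'
#' Applies residue substitutions and single-residue insertions/deletions at
#' the given per-position rates, recording the exact edit script and the
#' true source-to-target position map. Longer gaps arise only from adjacent
#' single-residue indels, which keeps the map bookkeeping exact.
#'
#' @param sequence source amino-acid sequence (character scalar).
#' @param substitution_rate per-position substitution probability, in
#'   `[0, 0.3]`.
#' @param indel_rate per-position indel probability, in `[0, 0.3]`; split
#'   evenly between deletions (at each position) and insertions (at each of
#'   the `L + 1` inter-residue slots).
#' @param seed integer seed.
#' @return list with `sequence` (the ortholog), `position_map` (integer
#'   vector over source positions; `NA` marks a deleted position), and
#'   `edits` (the edit script, one row per operation).
#' @export
mutate_ortholog <- function(sequence, substitution_rate = 0.05,
                            indel_rate = 0.02, seed = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  if (substitution_rate < 0 || substitution_rate > 0.3 ||
      indel_rate < 0 || indel_rate > 0.3)
    stop("substitution_rate and indel_rate must lie in [0, 0.3]")
  set.seed(seed)
  src <- strsplit(sequence, "")[[1]]
  L <- length(src)
  half <- indel_rate / 2
  out <- character(0)
  map <- rep(NA_integer_, L)
  ops <- character(0); pos <- integer(0); res <- character(0)
  add_ins <- function(slot) {
    r <- sample(AA20, 1)
    out <<- c(out, r)
    ops <<- c(ops, "ins"); pos <<- c(pos, slot); res <<- c(res, r)
  }
  if (runif(1) < half) add_ins(0L)
  for (i in seq_len(L)) {
    if (runif(1) < half) {
      ops <- c(ops, "del"); pos <- c(pos, i); res <- c(res, src[i])
    } else {
      r <- src[i]
      if (runif(1) < substitution_rate) {
        r <- sample(setdiff(AA20, src[i]), 1)
        ops <- c(ops, "sub"); pos <- c(pos, i); res <- c(res, r)
      }
      out <- c(out, r)
      map[i] <- length(out)
    }
    if (runif(1) < half) add_ins(i)
  }
  list(sequence = paste(out, collapse = ""),
       position_map = map,
       edits = data.frame(op = ops, source_pos = pos, residue = res,
                          stringsAsFactors = FALSE))
}

#' Pick phosphosites on a protein set
#'
#' Samples S/T/Y positions per protein; the number of sites per protein is
#' uniform over `sites_per_protein`.
#'
#' @param proteins named character vector of sequences.
#' @param sites_per_protein integer range `c(min, max)`.
#' @param seed integer seed.
#' @return data.frame with columns `protein`, `position`, `residue`.
#' @export
pick_phosphosites <- function(proteins, sites_per_protein = c(2L, 4L),
                              seed = 1L) {
  set.seed(seed)
  rows <- lapply(names(proteins), function(id) {
    aa <- strsplit(proteins[[id]], "")[[1]]
    cand <- which(aa %in% c("S", "T", "Y"))
    k <- min(length(cand),
             .sample1(seq(sites_per_protein[1], sites_per_protein[2])))
    p <- sort(sample(cand, k))
    data.frame(protein = id, position = p, residue = aa[p],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plant kinases on phosphosites and record the ground truth
#'
#' Assigns disjoint substrate sets to `n_kinases` kinases and plants a
#' log2 fold-change shift `delta` on the substrates of `n_active` of them,
#' one active condition/timepoint pattern per active kinase (the shift
#' applies in every stimulated condition/timepoint by default).
#'
#' @param sites data.frame from [pick_phosphosites()].
#' @param design a [sim_design()].
#' @param n_kinases number of kinases.
#' @param substrates_per_kinase substrates assigned per kinase (>= 2).
#' @param n_active number of kinases carrying a planted shift.
#' @param delta planted log2 fold-change shift (scalar or vector recycled
#'   over active kinases; signs alternate if scalar).
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: `substrate_assignment`,
#'   `planted_deltas`, and (filled in later) `position_maps`.
#' @export
make_synthetic_truth <- function(sites, design, n_kinases = 10L,
                                 substrates_per_kinase = 5L, n_active = 3L,
                                 delta = 1.5, seed = 1L) {
  if (substrates_per_kinase < 2)
    stop("each kinase needs at least two substrate sites")
  need <- n_kinases * substrates_per_kinase
  if (need > nrow(sites))
    stop("not enough phosphosites to assign ", need, " substrates")
  set.seed(seed)
  idx <- sample(nrow(sites), need)
  kin <- sprintf("KIN%03d", seq_len(n_kinases))
  assign <- sites[idx, , drop = FALSE]
  assign$kinase <- rep(kin, each = substrates_per_kinase)
  rownames(assign) <- NULL
  active <- kin[seq_len(n_active)]
  dl <- rep_len(if (length(delta) == 1)
    delta * rep_len(c(1, -1), n_active) else delta, n_active)
  grid <- expand.grid(condition = design$ligands,
                      timepoint = design$timepoints,
                      stringsAsFactors = FALSE)
  deltas <- do.call(rbind, lapply(seq_along(active), function(i)
    cbind(kinase = active[i], grid, delta = dl[i])))
  structure(list(substrate_assignment =
                   assign[, c("kinase", "protein", "position", "residue")],
                 planted_deltas = deltas,
                 position_maps = list()),
            class = "synthetic_truth")
}

#' Simulate a replicate phosphopeptide measurement table
#'
#' Baseline log2 intensities are Normal(mu_site, noise_sd) per replicate;
#' substrates of planted kinases get their condition-specific mean shifted by
#' the planted delta. A fraction of proteins additionally emit a
#' doubly-phosphorylated peptide (a two-site group), and some site groups are
#' observed as two distinct peptide ions, so that site-group aggregation is
#' exercised. Per-run additive offsets (on log2) are injected so that equal
#' median normalization is nontrivial, and each measurement is dropped
#' independently with `design$missing_prob`.
#'
#' @param design a [sim_design()].
#' @param truth a `synthetic_truth` (or `NULL` for a pure null study).
#' @param sites data.frame from [pick_phosphosites()].
#' @param run_offsets optional named numeric vector of per-run log2 offsets;
#'   defaults to Normal(0, 0.5) draws.
#' @param multi_prob probability that a protein with >= 2 sites also emits a
#'   doubly-phosphorylated peptide.
#' @param second_ion_prob probability that a site group is observed as two
#'   peptide ions within each run.
#' @param linear_scale if `TRUE`, emit linear-scale intensities (2^x) to
#'   exercise the log-transform path downstream.
#' @return data.frame of measurements (one row per peptide ion per run) with
#'   the injected `run_offsets` attached as an attribute.
#' @export
simulate_phospho_experiment <- function(design, truth = NULL, sites,
                                        run_offsets = NULL,
                                        multi_prob = 0.3,
                                        second_ion_prob = 0.25,
                                        linear_scale = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed + 101L)

  conditions <- c(design$ligands, design$control_label)
  runs <- expand.grid(condition = conditions, timepoint = design$timepoints,
                      replicate = seq_len(design$n_replicates),
                      stringsAsFactors = FALSE)
  runs$run <- sprintf("%s_%s_r%d", runs$condition, runs$timepoint,
                      runs$replicate)
  if (is.null(run_offsets)) {
    run_offsets <- stats::setNames(rnorm(nrow(runs), 0, 0.5), runs$run)
  } else {
    if (!all(runs$run %in% names(run_offsets)))
      stop("run_offsets must be named for every run")
    run_offsets <- run_offsets[runs$run]
  }

  # peptide catalogue: every single site, plus some two-site peptides
  peps <- data.frame(protein = sites$protein,
                     positions = as.character(sites$position),
                     residues = sites$residue,
                     stringsAsFactors = FALSE)
  for (id in unique(sites$protein)) {
    s <- sites[sites$protein == id, ]
    if (nrow(s) >= 2 && runif(1) < multi_prob) {
      j <- sort(sample(nrow(s), 2))
      peps <- rbind(peps, data.frame(
        protein = id,
        positions = paste(s$position[j], collapse = ";"),
        residues = paste(s$residue[j], collapse = ";")))
    }
  }
  peps$site_positions <- vapply(seq_len(nrow(peps)), function(i) {
    paste0(strsplit(peps$residues[i], ";")[[1]],
           strsplit(peps$positions[i], ";")[[1]], collapse = ";")
  }, character(1))
  peps$mu <- rnorm(nrow(peps), 25, 1.5)  # log2 abundances, roughly Gaussian
  peps$n_ions <- 1L + (runif(nrow(peps)) < second_ion_prob)

  # per-site shift lookup from planted kinase deltas
  shift <- function(protein, pos_str, condition, timepoint) {
    if (is.null(truth)) return(0)
    pd <- truth$planted_deltas
    pd <- pd[pd$condition == condition & pd$timepoint == timepoint, ,
             drop = FALSE]
    if (!nrow(pd)) return(0)
    pos <- as.integer(strsplit(pos_str, ";")[[1]])
    sa <- truth$substrate_assignment
    hit <- sa[sa$protein == protein & sa$position %in% pos, , drop = FALSE]
    if (!nrow(hit)) return(0)
    sum(pd$delta[match(hit$kinase, pd$kinase)], na.rm = TRUE)
  }

  rows <- list()
  for (i in seq_len(nrow(peps))) {
    n_ions <- peps$n_ions[i]
    for (ion in seq_len(n_ions)) {
      # the second ion of a peptide carries less signal
      mu_ion <- peps$mu[i] - (ion - 1) * 1.5
      d <- vapply(seq_len(nrow(runs)), function(r)
        shift(peps$protein[i], peps$positions[i],
              runs$condition[r], runs$timepoint[r]), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        peptide_id = sprintf("pep_%s_%s_ion%d", peps$protein[i],
                             gsub(";", ".", peps$positions[i]), ion),
        protein = peps$protein[i],
        site_positions = peps$site_positions[i],
        run = runs$run, condition = runs$condition,
        timepoint = runs$timepoint, replicate = runs$replicate,
        intensity = mu_ion + d + run_offsets[runs$run] +
          rnorm(nrow(runs), 0, design$noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL

  if (design$missing_prob > 0)
    meas <- meas[runif(nrow(meas)) >= design$missing_prob, , drop = FALSE]

  if (!is.null(truth)) {
    sa <- truth$substrate_assignment
    for (k in unique(sa$kinase)) {
      sk <- sa[sa$kinase == k, ]
      seen <- 0L
      for (j in seq_len(nrow(sk))) {
        m <- meas[meas$protein == sk$protein[j], ]
        if (any(vapply(strsplit(gsub("[STY]", "", m$site_positions), ";"),
                       function(p) as.character(sk$position[j]) %in% p,
                       logical(1))))
          seen <- seen + 1L
      }
      if (seen < 2L)
        stop("planted kinase ", k, " has fewer than 2 measured substrate ",
             "sites after missingness; lower missing_prob or reseed")
    }
  }

  if (linear_scale) meas$intensity <- 2^meas$intensity
  attr(meas, "run_offsets") <- run_offsets
  attr(meas, "scale") <- if (linear_scale) "linear" else "log2"
  meas
}

#' Generate a complete synthetic study with ground truth
#'
#' Composes the generator stages: source proteins, synthetic orthologs with
#' true position maps, phosphosites, planted kinase truth, the replicate
#' measurement table, a kinase-substrate annotation in target (ortholog)
#' coordinates, an interaction edge table, and a term annotation. Substrate
#' sites are chosen among sites that survive the ortholog mutation, so that
#' planted signal is recoverable after position transfer.
#'
#' @param design a [sim_design()].
#' @param n_kinases,substrates_per_kinase,n_active,delta passed to
#'   [make_synthetic_truth()].
#' @param substitution_rate,indel_rate ortholog mutation rates.
#' @param length_range protein length range.
#' @return list with `proteins_src`, `proteins_tgt`, `pairs`, `sites`,
#'   `truth`, `measurements`, `annotation` (target coordinates), `edges`,
#'   `terms`.
#' @export
synthesize_study <- function(design, n_kinases = 10L,
                             substrates_per_kinase = 5L, n_active = 3L,
                             delta = 1.5, substitution_rate = 0.05,
                             indel_rate = 0.02,
                             length_range = c(200L, 400L)) {
  seed <- design$seed
  src <- generate_protein_set(design$n_proteins, length_range, seed = seed,
                              id_prefix = "MUSP")
  tgt <- character(length(src))
  maps <- vector("list", length(src))
  tgt_ids <- sub("^MUSP", "HUMP", names(src))
  for (i in seq_along(src)) {
    mo <- mutate_ortholog(src[[i]], substitution_rate, indel_rate,
                          seed = seed + 200L + i)
    tgt[i] <- mo$sequence
    maps[[i]] <- mo$position_map
  }
  names(tgt) <- tgt_ids
  names(maps) <- names(src)
  pairs <- data.frame(source_id = names(src), target_id = tgt_ids,
                      stringsAsFactors = FALSE)

  sites <- pick_phosphosites(src, design$sites_per_protein, seed = seed + 7L)
  # restrict substrate candidates to sites that survive the ortholog mapping
  alive <- vapply(seq_len(nrow(sites)), function(i)
    !is.na(maps[[sites$protein[i]]][sites$position[i]]), logical(1))
  truth <- make_synthetic_truth(sites[alive, , drop = FALSE], design,
                                n_kinases, substrates_per_kinase, n_active,
                                delta, seed = seed + 11L)
  truth$position_maps <- maps

  meas <- simulate_phospho_experiment(design, truth, sites)

  # annotation keyed in target-species coordinates, as a curated
  # kinase-substrate resource would be
  sa <- truth$substrate_assignment
  tpos <- vapply(seq_len(nrow(sa)), function(i)
    maps[[sa$protein[i]]][sa$position[i]], integer(1))
  annotation <- data.frame(
    kinase = sa$kinase,
    protein = pairs$target_id[match(sa$protein, pairs$source_id)],
    position = tpos,
    residue = substring(tgt[pairs$target_id[match(sa$protein,
                                                  pairs$source_id)]],
                        tpos, tpos),
    stringsAsFactors = FALSE)

  edges <- simulate_edge_table(truth, names(src), seed = seed + 23L)
  terms <- simulate_term_table(truth, names(src), seed = seed + 29L)

  list(proteins_src = src, proteins_tgt = tgt, pairs = pairs, sites = sites,
       truth = truth, measurements = meas, annotation = annotation,
       edges = edges, terms = terms)
}

#' Simulate a protein-protein interaction edge table
#'
#' Substrate proteins of the same kinase receive high combined scores
#' (functional modules); a sparse random background is added on top.
#'
#' @param truth a `synthetic_truth`.
#' @param proteins character vector of protein accessions (source space).
#' @param background_density fraction of random background pairs scored.
#' @param seed integer seed.
#' @return data.frame with `protein_a`, `protein_b`, `score`.
#' @export
simulate_edge_table <- function(truth, proteins, background_density = 0.05,
                                seed = 1L) {
  set.seed(seed)
  sa <- truth$substrate_assignment
  mod <- lapply(split(unique(sa[, c("kinase", "protein")])$protein,
                      unique(sa[, c("kinase", "protein")])$kinase),
                unique)
  ea <- character(0); eb <- character(0); sc <- numeric(0)
  for (m in mod) {
    if (length(m) < 2) next
    cmb <- utils::combn(sort(m), 2)
    ea <- c(ea, cmb[1, ]); eb <- c(eb, cmb[2, ])
    sc <- c(sc, runif(ncol(cmb), 0.5, 0.95))
  }
  all_cmb <- utils::combn(sort(proteins), 2)
  pick <- runif(ncol(all_cmb)) < background_density
  ea <- c(ea, all_cmb[1, pick]); eb <- c(eb, all_cmb[2, pick])
  sc <- c(sc, runif(sum(pick), 0.05, 0.6))
  e <- data.frame(protein_a = ea, protein_b = eb, score = sc,
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(e[, c("protein_a", "protein_b")]), ]
  rownames(e) <- NULL
  e
}

#' Simulate a term-to-protein annotation
#'
#' One term per kinase covering its substrate proteins (plus random
#' bystanders), and additional purely random terms.
#'
#' @inheritParams simulate_edge_table
#' @param n_random number of random terms.
#' @return named list of character vectors (term -> proteins).
#' @export
simulate_term_table <- function(truth, proteins, n_random = 10L, seed = 1L) {
  set.seed(seed)
  sa <- unique(truth$substrate_assignment[, c("kinase", "protein")])
  terms <- lapply(split(sa$protein, sa$kinase), function(p)
    unique(c(p, sample(proteins, 2))))
  names(terms) <- paste0("MODULE_", names(terms))
  for (i in seq_len(n_random)) {
    terms[[sprintf("RANDOM_%02d", i)]] <-
      sample(proteins, min(length(proteins), .sample1(5:12)))
  }
  terms
}

# ---- writers / readers -----------------------------------------------------

#' Write / read the measurement table
#'
#' Tab-delimited, UTF-8, header row, 1-based residue positions with residue
#' letters (e.g. `S15;T20`).
#' @param measurements measurement data.frame.
#' @param path file path.
#' @export
write_measurements <- function(measurements, path) {
  write.table(measurements, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("peptide_id", "protein", "site_positions", "run", "condition",
            "timepoint", "replicate", "intensity")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("measurement table missing columns: ", paste(miss, collapse = ", "))
  m
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
}

#' Read a protein FASTA into a named character vector
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read a kinase-substrate annotation
#'
#' Three-column TSV: kinase, substrate protein, site (residue letter plus
#' 1-based position, e.g. `S473`).
#' @param annotation data.frame with `kinase`, `protein`, `position`,
#'   `residue`.
#' @param path file path.
#' @export
write_ks_annotation <- function(annotation, path) {
  out <- data.frame(kinase = annotation$kinase, protein = annotation$protein,
                    site = paste0(annotation$residue, annotation$position))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' @rdname write_ks_annotation
#' @export
read_ks_annotation <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("kinase", "protein", "site") %in% names(x)))
    stop("annotation must have columns kinase, protein, site")
  res <- sub("^([A-Z]).*$", "\\1", x$site)
  pos <- as.integer(sub("^[A-Z]", "", x$site))
  if (any(is.na(pos)) || any(pos < 1))
    stop("malformed site strings in annotation")
  data.frame(kinase = x$kinase, protein = x$protein, position = pos,
             residue = res, stringsAsFactors = FALSE)
}

#' Write / read the synthetic ground truth
#'
#' The truth is stored as three TSVs in a directory: planted deltas,
#' substrate assignment, and the per-pair position maps (deleted positions
#' carry an empty target).
#' @param truth a `synthetic_truth`.
#' @param dir directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(truth$planted_deltas, file.path(dir, "planted_deltas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$substrate_assignment, file.path(dir, "substrates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- do.call(rbind, lapply(names(truth$position_maps), function(id) {
    m <- truth$position_maps[[id]]
    data.frame(pair = id, source_pos = seq_along(m), target_pos = m)
  }))
  write.table(pm, file.path(dir, "position_maps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  pm <- read.delim(file.path(dir, "position_maps.tsv"),
                   stringsAsFactors = FALSE)
  maps <- lapply(split(pm, pm$pair), function(d)
    as.integer(d$target_pos[order(d$source_pos)]))
  structure(list(
    planted_deltas = read.delim(file.path(dir, "planted_deltas.tsv"),
                                stringsAsFactors = FALSE),
    substrate_assignment = read.delim(file.path(dir, "substrates.tsv"),
                                      stringsAsFactors = FALSE),
    position_maps = maps), class = "synthetic_truth")
}
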