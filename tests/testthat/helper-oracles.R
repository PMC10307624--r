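# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain recursion, literal formula evaluation,
# exhaustive enumeration.

# exhaustive global-alignment optimum: enumerate every alignment path,
# scoring gaps as open + (L - 1) * extend; feasible for lengths <= 6
brute_force_global_score <- function(a, b, S, open = -10, ext = -0.5) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > length(ac) && j > length(bc)) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc))
      rec(i + 1, j + 1, "d", acc + S[ac[i], bc[j]])
    if (i <= length(ac))
      rec(i + 1, j, "u", acc + if (identical(last, "u")) ext else open)
    if (j <= length(bc))
      rec(i, j + 1, "l", acc + if (identical(last, "l")) ext else open)
  }
  rec(1, 1, "n", 0)
  best
}

# rebuild the mutated ortholog and its position map from the recorded edit
# script (insertion slots and per-position del/sub, in source order)
replay_edits <- function(sequence, edits) {
  src <- strsplit(sequence, "")[[1]]
  ins <- edits[edits$op == "ins", ]
  del <- edits$source_pos[edits$op == "del"]
  sub <- edits[edits$op == "sub", ]
  out <- character(0)
  map <- rep(NA_integer_, length(src))
  for (slot in 0:length(src)) {
    if (slot >= 1 && !(slot %in% del)) {
      r <- src[slot]
      if (slot %in% sub$source_pos) r <- sub$residue[sub$source_pos == slot]
      out <- c(out, r)
      map[slot] <- length(out)
    }
    if (slot %in% ins$source_pos)
      out <- c(out, ins$residue[ins$source_pos == slot])
  }
  list(sequence = paste(out, collapse = ""), position_map = map)
}

# literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(sort(p)[i:m] * m / (i:m)))
  q
}

# exact upper-tail hypergeometric by combinatorial summation
hyper_brute <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# standard BLOSUM62 fetched once for alignment tests
blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                      "G", "H", "I", "L", "K", "M", "F",
                                      "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# one-ligand null or planted study pushed through the quant chain; returns
# the collapsed fold-change table plus the site catalogue and truth
quant_chain <- function(design, truth = NULL, sites = NULL,
                        proteins = NULL, length_range = c(60L, 120L)) {
  if (is.null(proteins))
    proteins <- generate_protein_set(design$n_proteins, length_range,
                                     seed = design$seed, id_prefix = "P")
  if (is.null(sites))
    sites <- pick_phosphosites(proteins, design$sites_per_protein,
                               seed = design$seed + 7L)
  meas <- simulate_phospho_experiment(design, truth, sites)
  sg <- equal_median_normalize(build_site_groups(meas))
  st <- differential_test(sg, default_contrasts(sg,
                                                design$control_label))
  fc <- suppressMessages(collapse_site_fc(st))
  list(proteins = proteins, sites = sites, measurements = meas,
       site_groups = sg, site_stats = st, site_fc = fc)
}

# random kinase-substrate annotation over a site catalogue (source space)
random_annotation <- function(sites, n_kinases, substrates_per_kinase,
                              seed) {
  set.seed(seed)
  idx <- sample(nrow(sites), n_kinases * substrates_per_kinase)
  data.frame(kinase = rep(sprintf("K%03d", seq_len(n_kinases)),
                          each = substrates_per_kinase),
             protein = sites$protein[idx], position = sites$position[idx],
             residue = sites$residue[idx], stringsAsFactors = FALSE)
}
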