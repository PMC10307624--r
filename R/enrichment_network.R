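# Interaction-network assembly over changed phosphoproteins and
# hypergeometric functional enrichment with greedy redundancy pruning.

.canon_edges <- function(edges) {
  if (!all(c("protein_a", "protein_b", "score") %in% names(edges)))
    stop("edge table needs columns protein_a, protein_b, score")
  if (any(!is.finite(edges$score)) || any(edges$score < 0 | edges$score > 1))
    stop("edge scores must lie in [0, 1]")
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  e <- data.frame(protein_a = a, protein_b = b, score = edges$score,
                  stringsAsFactors = FALSE)
  e <- e[e$protein_a != e$protein_b, , drop = FALSE]
  e <- e[order(e$protein_a, e$protein_b, -e$score), ]
  e <- e[!duplicated(e[, c("protein_a", "protein_b")]), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Build the thresholded interaction network over core proteins
#'
#' Induced subgraph on the core proteins, keeping edges with combined score
#' strictly greater than `threshold` (default 0.4). Isolated core proteins
#' are retained as nodes — they still carry phosphorylation states.
#'
#' @param core_proteins character vector (typically from
#'   [select_changed_proteins()]).
#' @param edges data.frame `protein_a`, `protein_b`, `score` in `[0, 1]`.
#' @param threshold strict score cutoff.
#' @return object of class `phospho_network`: `nodes` (with a `core` flag),
#'   `edges`, `threshold`.
#' @export
build_network <- function(core_proteins, edges, threshold = 0.4) {
  e <- .canon_edges(edges)
  core <- sort(unique(core_proteins))
  keep <- e$protein_a %in% core & e$protein_b %in% core &
    e$score > threshold
  kept <- e[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(
    nodes = data.frame(protein = core, core = rep(TRUE, length(core)),
                       stringsAsFactors = FALSE),
    edges = kept,
    threshold = threshold), class = "phospho_network")
}

#' Expand a network with functionally related proteins
#'
#' Adds up to `max_added` non-core proteins, ranked by the summed
#' above-threshold edge score connecting each candidate to the current node
#' set (ties broken lexicographically). Added nodes are flagged as
#' expansion nodes; existing nodes and edges are never removed.
#'
#' @param network a `phospho_network`.
#' @param edges full background edge table.
#' @param max_added maximum number of added nodes (default 10).
#' @return the expanded `phospho_network`.
#' @export
expand_network <- function(network, edges, max_added = 10L) {
  e <- .canon_edges(edges)
  thr <- network$threshold
  cur <- network$nodes$protein
  touch <- e[e$score > thr &
               (xor(e$protein_a %in% cur, e$protein_b %in% cur)), ,
             drop = FALSE]
  cand <- ifelse(touch$protein_a %in% cur, touch$protein_b, touch$protein_a)
  if (!length(cand) || max_added < 1) return(network)
  sums <- tapply(touch$score, cand, sum)
  ord <- order(-sums, names(sums))
  added <- names(sums)[ord][seq_len(min(max_added, length(sums)))]

  network$nodes <- rbind(network$nodes,
                         data.frame(protein = added, core = FALSE,
                                    stringsAsFactors = FALSE))
  allp <- network$nodes$protein
  new_e <- e[e$score > thr & e$protein_a %in% allp & e$protein_b %in% allp, ]
  both <- rbind(network$edges, new_e)
  both <- both[!duplicated(both[, c("protein_a", "protein_b")]), ]
  network$edges <- both[order(both$protein_a, both$protein_b), ]
  rownames(network$edges) <- NULL
  network
}

#' @export
print.phospho_network <- function(x, ...) {
  cat("phospho_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$core), "core ), ", nrow(x$edges),
      "edges with score >", x$threshold, "\n")
  invisible(x)
}

#' Hypergeometric set enrichment
#'
#' Upper-tail hypergeometric test P(X >= k) per term, with BH correction
#' across the tested terms and an FDR filter. Terms with no overlap with
#' the query are skipped. The universe defaults to all detected proteins
#' (the caller supplies it); term members outside the universe are ignored.
#'
#' @param query character vector of proteins; must be contained in
#'   `universe`.
#' @param terms named list of character vectors (term -> members), e.g.
#'   from [read_gmt()].
#' @param universe character vector of background proteins.
#' @param fdr_cutoff keep terms with BH-adjusted p below this (default
#'   0.05); set to 1 to keep all tested terms.
#' @return data.frame `term`, `k` (overlap), `K` (term size in universe),
#'   `n` (query size), `N` (universe size), `p`, `fdr`, `overlap`
#'   (semicolon-joined member genes).
#' @export
hypergeom_enrichment <- function(query, terms, universe, fdr_cutoff = 0.05) {
  query <- unique(query); universe <- unique(universe)
  if (length(setdiff(query, universe)))
    stop("query proteins missing from the universe: ",
         paste(head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), universe)
    ov <- intersect(members, query)
    k <- length(ov); K <- length(members)
    if (k == 0) return(NULL)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0), overlap = character(0)))
  res$fdr <- bh_adjust(res$p)
  if (fdr_cutoff < 1) res <- res[res$fdr < fdr_cutoff, , drop = FALSE]
  res <- res[order(res$fdr, res$p, res$term),
             c("term", "k", "K", "n", "N", "p", "fdr", "overlap")]
  rownames(res) <- NULL
  res
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Remove redundant enrichment terms
#'
#' Greedy pruning: iterate results by ascending FDR (ties by p, then term
#' id) and drop any term whose Jaccard similarity of overlap-gene sets with
#' an already-kept term reaches the cutoff (default 0.5).
#'
#' @param results enrichment table from [hypergeom_enrichment()].
#' @param cutoff Jaccard similarity at or above which a term is redundant.
#' @return the pruned table.
#' @export
remove_redundant_terms <- function(results, cutoff = 0.5) {
  if (!nrow(results)) return(results)
  o <- order(results$fdr, results$p, results$term)
  d <- results[o, , drop = FALSE]
  sets <- strsplit(d$overlap, ";", fixed = TRUE)
  keep <- logical(nrow(d))
  kept_sets <- list()
  for (i in seq_len(nrow(d))) {
    red <- any(vapply(kept_sets, .jaccard, numeric(1), b = sets[[i]]) >=
                 cutoff)
    if (!red) {
      keep[i] <- TRUE
      kept_sets[[length(kept_sets) + 1]] <- sets[[i]]
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach per-timepoint phosphorylation states to network nodes
#'
#' For each node and timepoint, the state is the signed log2 fold change of
#' the significant (BH-adjusted p < `alpha`) site with the largest absolute
#' fold change, or absent (`NA`) when the protein has no significant site
#' at that timepoint — the ring annotation of the network display.
#'
#' @param network a `phospho_network`.
#' @param site_stats `SiteStat` table (restricted to one ligand's
#'   contrasts by the caller).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return the network with one `state_<timepoint>` column per timepoint
#'   added to `nodes`.
#' @export
attach_phospho_states <- function(network, site_stats, alpha = 0.05) {
  tps <- sort(unique(site_stats$timepoint))
  for (tp in tps) {
    d <- site_stats[site_stats$timepoint == tp & !is.na(site_stats$adj_p) &
                      site_stats$adj_p < alpha & is.finite(site_stats$log2FC),
                    , drop = FALSE]
    st <- vapply(network$nodes$protein, function(pr) {
      v <- d$log2FC[d$protein == pr]
      if (!length(v)) NA_real_ else v[which.max(abs(v))]
    }, numeric(1))
    network$nodes[[paste0("state_", tp)]] <- unname(st)
  }
  network
}

#' Export a network as JSON node-link plus a TSV edge list
#'
#' @param network a `phospho_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
write_network <- function(network, dir, prefix = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  tsv_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  jsonlite::write_json(
    list(threshold = network$threshold, nodes = network$nodes,
         links = network$edges),
    json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  write.table(network$edges, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read a GMT term annotation
#'
#' @param path GMT file (term, description, members...).
#' @return named list of member vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write a named list of term members as GMT
#'
#' @param terms named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(tm)
    paste(c(tm, "na", terms[[tm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
}
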