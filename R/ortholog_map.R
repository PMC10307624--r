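# Cross-species phosphosite transfer: affine-gap Needleman-Wunsch global
# alignment (Gotoh) and position mapping along the alignment columns.

.blosum62 <- local({
  e <- new.env()
  function() {
    if (is.null(e$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$m <- e$BLOSUM62
    }
    e$m
  }
})

#' Global protein alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment under a substitution matrix and affine
#' gap model (a gap of length L scores `gap_open + (L - 1) * gap_extend`).
#' The traceback is deterministic: on ties it prefers the diagonal move,
#' then up (gap in the target), then left.
#'
#' @param seq_a,seq_b amino-acid sequences (character scalars; nonempty).
#' @param substitution_matrix scoring matrix with residue dimnames; default
#'   BLOSUM62.
#' @param gap_open,gap_extend gap scores (negative); defaults -10 and -0.5.
#' @param source_id,target_id accession labels stored on the result.
#' @return object of class `ortholog_alignment`: `source_id`, `target_id`,
#'   `aligned_source`, `aligned_target` (gapped strings of equal length),
#'   `score`, and `position_map` (1-based source position to target
#'   position; `NA` where the site falls in a target gap).
#' @export
needleman_wunsch <- function(seq_a, seq_b, substitution_matrix = NULL,
                             gap_open = -10, gap_extend = -0.5,
                             source_id = "a", target_id = "b") {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1, length(seq_b) == 1)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be nonempty")
  S <- substitution_matrix %||% .blosum62()
  ach <- strsplit(seq_a, "")[[1]]
  bch <- strsplit(seq_b, "")[[1]]
  ai <- match(ach, rownames(S))
  bi <- match(bch, colnames(S))
  if (anyNA(ai) || anyNA(bi))
    stop("non-amino-acid characters in input sequences")
  r <- .nw_align_c(ai, bi, S, gap_open, gap_extend)

  moves <- r$moves  # 1 diagonal, 2 up (gap in target), 3 left (gap in source)
  n <- length(ach)
  ga <- character(length(moves)); gb <- ga
  map <- rep(NA_integer_, n)
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    if (moves[k] == 1L) {
      i <- i + 1L; j <- j + 1L
      ga[k] <- ach[i]; gb[k] <- bch[j]
      map[i] <- j
    } else if (moves[k] == 2L) {
      i <- i + 1L
      ga[k] <- ach[i]; gb[k] <- "-"
    } else {
      j <- j + 1L
      ga[k] <- "-"; gb[k] <- bch[j]
    }
  }
  structure(list(source_id = source_id, target_id = target_id,
                 aligned_source = paste(ga, collapse = ""),
                 aligned_target = paste(gb, collapse = ""),
                 score = r$score, position_map = map),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("Global alignment ", x$source_id, " -> ", x$target_id,
      " (score ", format(x$score), ")\n", sep = "")
  w <- min(60, nchar(x$aligned_source))
  cat(substr(x$aligned_source, 1, w), "\n")
  cat(substr(x$aligned_target, 1, w), "\n")
  cat(sum(!is.na(x$position_map)), "of", length(x$position_map),
      "source positions aligned to a target residue\n")
  invisible(x)
}

#' Transfer one site position through an alignment
#'
#' @param alignment an `ortholog_alignment`.
#' @param source_position 1-based position in the source sequence.
#' @return the 1-based target position, or `NA` (unaligned) when the
#'   alignment column holds a target gap.
#' @export
transfer_site_position <- function(alignment, source_position) {
  n <- length(alignment$position_map)
  if (source_position < 1 || source_position > n)
    stop("source_position out of range 1..", n)
  alignment$position_map[source_position]
}

.residue_conserved <- function(src_res, tgt_res) {
  # same phospho-acceptor class: S and T interchangeable, Y only with Y
  tgt_res %in% c("S", "T", "Y") &
    (tgt_res == src_res | (src_res %in% c("S", "T") & tgt_res %in% c("S", "T")))
}

#' Map a site fold-change table onto ortholog coordinates
#'
#' Aligns each source protein to its designated ortholog and re-keys the
#' fold-change table by target protein and position. Sites falling into
#' target gaps are dropped (with a logged count); duplicates arising after
#' mapping are resolved by the lowest-p collapse rule. Sites landing on a
#' residue outside the phospho-acceptor class are retained but flagged
#' `residue_conserved = FALSE` unless `drop_nonconserved = TRUE`.
#'
#' @param site_fc `SiteFC` table from [collapse_site_fc()].
#' @param src_seqs,tgt_seqs named character vectors of sequences.
#' @param pairs data.frame with `source_id`, `target_id` (exactly one
#'   ortholog per source protein).
#' @param drop_nonconserved drop sites whose target residue leaves the
#'   source phospho-acceptor class.
#' @param alignments optional precomputed list of `ortholog_alignment`s
#'   keyed by source id (cache).
#' @param ... scoring arguments passed to [needleman_wunsch()].
#' @return the re-keyed `SiteFC` table with `source_protein`,
#'   `source_position` and `residue_conserved` columns; the alignment cache
#'   is attached as attribute `alignments`.
#' @export
map_sites <- function(site_fc, src_seqs, tgt_seqs, pairs,
                      drop_nonconserved = FALSE, alignments = NULL, ...) {
  need <- unique(site_fc$protein)
  miss <- setdiff(need, pairs$source_id)
  if (length(miss))
    stop("no ortholog pairing for: ", paste(head(miss, 5), collapse = ", "))
  if (length(setdiff(need, names(src_seqs))) ||
      length(setdiff(pairs$target_id[match(need, pairs$source_id)],
                     names(tgt_seqs))))
    stop("protein missing from FASTA input")

  if (is.null(alignments)) alignments <- list()
  for (id in setdiff(need, names(alignments))) {
    tid <- pairs$target_id[match(id, pairs$source_id)]
    alignments[[id]] <- needleman_wunsch(src_seqs[[id]], tgt_seqs[[tid]],
                                         source_id = id, target_id = tid, ...)
  }

  tid <- pairs$target_id[match(site_fc$protein, pairs$source_id)]
  tpos <- vapply(seq_len(nrow(site_fc)), function(i)
    alignments[[site_fc$protein[i]]]$position_map[site_fc$position[i]],
    integer(1))
  keep <- !is.na(tpos)
  if (any(!keep))
    message(sum(!keep), " site(s) fell into target gaps and were dropped")

  d <- site_fc[keep, , drop = FALSE]
  d$source_protein <- d$protein
  d$source_position <- d$position
  d$protein <- tid[keep]
  d$position <- tpos[keep]
  tres <- substring(tgt_seqs[d$protein], d$position, d$position)
  d$target_residue <- unname(tres)
  d$residue_conserved <- .residue_conserved(d$residue, d$target_residue)
  if (drop_nonconserved) d <- d[d$residue_conserved, , drop = FALSE]

  # duplicates after mapping: keep the lowest-p record per target site
  key <- interaction(d$protein, d$position, d$contrast, drop = TRUE)
  d2 <- d; d2$p <- d2$source_p; d2$site_key <- d2$source_group
  ord <- unlist(lapply(split(seq_len(nrow(d2)), key), function(ix)
    ix[.rank_records(d2[ix, , drop = FALSE])[1]]), use.names = FALSE)
  d <- d[sort(ord), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "alignments") <- alignments
  d
}
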