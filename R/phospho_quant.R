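# Phosphosite-group quantification and differential statistics:
# grouping by identical site sets, equal median normalization across runs,
# per-contrast Welch tests with BH correction, and collapse to one finite
# fold change per site.

.parse_sites <- function(site_positions) {
  parts <- strsplit(site_positions, ";", fixed = TRUE)[[1]]
  res <- sub("^([A-Z]).*$", "\\1", parts)
  pos <- suppressWarnings(as.integer(sub("^[A-Z]", "", parts)))
  if (any(is.na(pos)) || !all(res %in% c("S", "T", "Y")))
    stop("malformed site position string: ", site_positions)
  o <- order(pos)
  if (anyDuplicated(pos)) stop("duplicate positions in: ", site_positions)
  data.frame(residue = res[o], position = pos[o], stringsAsFactors = FALSE)
}

.site_key <- function(protein, residues, positions) {
  paste(protein, paste0(residues, positions, collapse = "_"), sep = "_")
}

#' Group peptides into phosphorylation site groups
#'
#' Peptides carrying the same set of phosphorylated sites on the same
#' protein are grouped and quantified together: within each run, their
#' intensities are summed on the linear scale and re-logged. The canonical
#' group key is `PROT_S15_T20` (protein accession plus sorted residue and
#' position labels).
#'
#' @param measurements measurement data.frame (log2 intensities unless
#'   `scale = "linear"`).
#' @param proteins optional named sequences; when supplied, site positions
#'   are validated against protein lengths.
#' @param scale `"log2"` (default) or `"linear"`; linear input is
#'   log2-transformed first. The `scale` attribute of a simulated table is
#'   honoured when present.
#' @return data.frame with one row per site group per run: `site_key`,
#'   `protein`, `positions`, `run`, `condition`, `timepoint`, `replicate`,
#'   `intensity` (log2 of summed linear intensity).
#' @export
build_site_groups <- function(measurements, proteins = NULL, scale = NULL) {
  if (!nrow(measurements)) {
    out <- data.frame(site_key = character(0), protein = character(0),
                      positions = character(0), run = character(0),
                      condition = character(0), timepoint = character(0),
                      replicate = integer(0), intensity = numeric(0))
    return(out)
  }
  if (is.null(scale))
    scale <- attr(measurements, "scale") %||% "log2"
  x <- measurements$intensity
  if (scale == "linear") x <- log2(x)
  if (any(!is.finite(x))) stop("intensities must be finite")

  parsed <- lapply(unique(measurements$site_positions), .parse_sites)
  names(parsed) <- unique(measurements$site_positions)
  canon <- vapply(parsed, function(p)
    paste0(p$residue, p$position, collapse = "_"), character(1))

  if (!is.null(proteins)) {
    for (i in seq_len(nrow(measurements))) {
      p <- parsed[[measurements$site_positions[i]]]
      seq_i <- proteins[[measurements$protein[i]]]
      if (is.null(seq_i))
        stop("protein ", measurements$protein[i], " not in supplied sequences")
      if (any(p$position > nchar(seq_i)))
        stop("site position beyond length of ", measurements$protein[i],
             " (row ", i, ")")
    }
  }

  key <- paste(measurements$protein, canon[measurements$site_positions],
               sep = "_")
  lin <- 2^x
  agg <- stats::aggregate(
    lin,
    by = list(site_key = key, protein = measurements$protein,
              positions = canon[measurements$site_positions],
              run = measurements$run, condition = measurements$condition,
              timepoint = measurements$timepoint,
              replicate = measurements$replicate),
    FUN = sum)
  agg$intensity <- log2(agg$x)
  agg$x <- NULL
  agg <- agg[order(agg$site_key, agg$run), ]
  rownames(agg) <- NULL
  agg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equal median normalization across runs
#'
#' Shifts each run additively on the log2 scale so that every run's median
#' equals the grand median (the median of the pre-normalization run
#' medians). Additive log2 shifts cancel in fold changes, so the choice of
#' common target is immaterial downstream.
#'
#' @param site_groups site-group table from [build_site_groups()].
#' @return the table with normalized intensities; the applied per-run shifts
#'   are attached as attribute `shifts`.
#' @export
equal_median_normalize <- function(site_groups) {
  if (!nrow(site_groups)) return(site_groups)
  meds <- tapply(site_groups$intensity, site_groups$run,
                 function(v) median(v[is.finite(v)]))
  meds <- stats::setNames(as.numeric(meds), names(meds))
  if (any(is.na(meds)))
    stop("run(s) with no finite intensities: ",
         paste(names(meds)[is.na(meds)], collapse = ", "))
  target <- median(meds)
  shifts <- target - meds
  site_groups$intensity <- site_groups$intensity +
    shifts[site_groups$run]
  attr(site_groups, "shifts") <- shifts
  site_groups
}

#' Define treatment-versus-control contrasts
#'
#' Pairs each stimulation condition at each timepoint with its time-matched
#' control; optionally adds stimulation-versus-stimulation contrasts.
#'
#' @param site_groups a site-group table (used for its condition/timepoint
#'   labels).
#' @param control label of the control condition.
#' @param between_ligands if `TRUE`, also contrast each pair of stimulated
#'   conditions at the same timepoint.
#' @return data.frame with columns `name`, `treatment`, `control`,
#'   `timepoint`.
#' @export
default_contrasts <- function(site_groups, control = "US",
                              between_ligands = FALSE) {
  conds <- setdiff(unique(site_groups$condition), control)
  tps <- unique(site_groups$timepoint)
  out <- expand.grid(treatment = conds, timepoint = tps,
                     stringsAsFactors = FALSE)
  out$control <- control
  out$name <- paste(out$treatment, out$timepoint, sep = "_")
  if (between_ligands && length(conds) >= 2) {
    cmb <- utils::combn(conds, 2)
    extra <- do.call(rbind, lapply(tps, function(tp)
      data.frame(treatment = cmb[1, ], timepoint = tp, control = cmb[2, ],
                 name = paste(cmb[1, ], "vs", cmb[2, ], tp, sep = "_"))))
    out <- rbind(out, extra)
  }
  out[, c("name", "treatment", "control", "timepoint")]
}

# Welch p with a variance floor, used when t.test would degenerate
# (zero-variance groups at n = 2-3)
.floored_welch_p <- function(x, y, floor = 1e-8) {
  if (abs(mean(x) - mean(y)) < 1e-12) return(1)
  v1 <- max(stats::var(x), floor); v2 <- max(stats::var(y), floor)
  n1 <- length(x); n2 <- length(y)
  se <- sqrt(v1 / n1 + v2 / n2)
  tt <- (mean(x) - mean(y)) / se
  df <- se^4 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  2 * stats::pt(-abs(tt), df)
}

#' Per-contrast differential testing of site groups
#'
#' For each site group and contrast, the log2 fold change is the mean
#' treated minus the mean control intensity; p values come from a two-sided
#' two-sample t test (Welch by default), with Benjamini-Hochberg correction
#' applied per contrast over the defined p values. Site groups observed on
#' only one side get an infinite log2FC and an undefined p. Groups with a
#' single replicate on a side get a fold change but no p value. When both
#' groups are constant, p is 1 for equal means and otherwise computed with a
#' variance floor of 1e-8.
#'
#' @param site_groups normalized site-group table.
#' @param contrasts data.frame from [default_contrasts()].
#' @param var_equal use the pooled-variance (classical Student) test instead
#'   of Welch.
#' @return `SiteStat` data.frame: `site_key`, `protein`, `positions`,
#'   `contrast`, `treatment`, `timepoint`, `log2FC`, `se`, `p`, `adj_p`,
#'   `n_treated`, `n_control`.
#' @export
differential_test <- function(site_groups, contrasts, var_equal = FALSE) {
  need <- unique(c(contrasts$treatment, contrasts$control))
  missing_cond <- setdiff(need, unique(site_groups$condition))
  if (length(missing_cond))
    stop("unknown contrast condition(s): ",
         paste(missing_cond, collapse = ", "))

  out <- list()
  for (ci in seq_len(nrow(contrasts))) {
    tp <- contrasts$timepoint[ci]
    trt <- site_groups[site_groups$condition == contrasts$treatment[ci] &
                         site_groups$timepoint == tp, ]
    ctl <- site_groups[site_groups$condition == contrasts$control[ci] &
                         site_groups$timepoint == tp, ]
    keys <- sort(unique(c(trt$site_key, ctl$site_key)))
    tv <- split(trt$intensity, factor(trt$site_key, levels = keys))
    cv <- split(ctl$intensity, factor(ctl$site_key, levels = keys))
    rows <- lapply(keys, function(k) {
      x <- tv[[k]]; y <- cv[[k]]
      n1 <- length(x); n2 <- length(y)
      if (n1 == 0 && n2 == 0) return(NULL)
      if (n1 == 0 || n2 == 0) {
        fc <- if (n2 == 0) Inf else -Inf
        return(data.frame(site_key = k, log2FC = fc, se = NA_real_,
                          p = NA_real_, n_treated = n1, n_control = n2))
      }
      fc <- mean(x) - mean(y)
      if (n1 < 2 || n2 < 2) {
        p <- NA_real_; se <- NA_real_
      } else {
        se <- sqrt(max(stats::var(x), 0) / n1 + max(stats::var(y), 0) / n2)
        p <- tryCatch(
          stats::t.test(x, y, var.equal = var_equal)$p.value,
          error = function(e) .floored_welch_p(x, y))
        if (!is.finite(p)) p <- .floored_welch_p(x, y)
      }
      data.frame(site_key = k, log2FC = fc, se = se, p = p,
                 n_treated = n1, n_control = n2)
    })
    d <- do.call(rbind, rows)
    if (is.null(d) || !nrow(d)) next
    d$adj_p <- NA_real_
    ok <- !is.na(d$p)
    d$adj_p[ok] <- bh_adjust(d$p[ok])
    d$contrast <- contrasts$name[ci]
    d$treatment <- contrasts$treatment[ci]
    d$timepoint <- tp
    out[[ci]] <- d
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  lk <- unique(site_groups[, c("site_key", "protein", "positions")])
  res <- merge(res, lk, by = "site_key", sort = FALSE)
  res <- res[order(res$contrast, res$site_key),
             c("site_key", "protein", "positions", "contrast", "treatment",
               "timepoint", "log2FC", "se", "p", "adj_p", "n_treated",
               "n_control")]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

.rank_records <- function(d) {
  # lowest p first; NA p last; ties by larger |fc|, then lexicographic key
  order(is.na(d$p), d$p, -abs(d$fc), d$site_key)
}

#' Collapse to a single fold change per phosphosite
#'
#' Each individual site may carry several (FC, p) records: one per site
#' group containing it, per contrast. Records with infinite fold changes are
#' dropped; among the rest the record with the lowest p value wins, with
#' ties broken by larger absolute fold change and then lexicographic group
#' key. Sites with only infinite records are omitted with a logged notice.
#'
#' @param site_stats `SiteStat` table from [differential_test()].
#' @return `SiteFC` data.frame: `protein`, `position`, `residue`,
#'   `contrast`, `treatment`, `timepoint`, `fc`, `source_p`,
#'   `source_adj_p`, `source_group`.
#' @export
collapse_site_fc <- function(site_stats) {
  if (is.null(site_stats) || !nrow(site_stats))
    return(data.frame(protein = character(0), position = integer(0),
                      residue = character(0), contrast = character(0),
                      treatment = character(0), timepoint = character(0),
                      fc = numeric(0), source_p = numeric(0),
                      source_adj_p = numeric(0), source_group = character(0)))
  expand <- lapply(seq_len(nrow(site_stats)), function(i) {
    parts <- strsplit(site_stats$positions[i], "_", fixed = TRUE)[[1]]
    data.frame(protein = site_stats$protein[i],
               position = as.integer(sub("^[A-Z]", "", parts)),
               residue = sub("^([A-Z]).*$", "\\1", parts),
               contrast = site_stats$contrast[i],
               treatment = site_stats$treatment[i],
               timepoint = site_stats$timepoint[i],
               fc = site_stats$log2FC[i], p = site_stats$p[i],
               adj_p = site_stats$adj_p[i],
               site_key = site_stats$site_key[i],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, expand)
  n_sites <- nrow(unique(d[, c("protein", "position", "contrast")]))
  d <- d[is.finite(d$fc), , drop = FALSE]
  if (nrow(d)) {
    grp <- interaction(d$protein, d$position, d$contrast, drop = TRUE)
    picked <- do.call(rbind, lapply(split(d, grp), function(g)
      g[.rank_records(g)[1], , drop = FALSE]))
  } else {
    picked <- d
  }
  dropped <- n_sites - nrow(picked)
  if (dropped > 0)
    message(dropped, " site/contrast record(s) had only infinite fold ",
            "changes and were omitted")
  picked <- picked[order(picked$contrast, picked$protein, picked$position), ]
  out <- data.frame(protein = picked$protein, position = picked$position,
                    residue = picked$residue, contrast = picked$contrast,
                    treatment = picked$treatment,
                    timepoint = picked$timepoint, fc = picked$fc,
                    source_p = picked$p, source_adj_p = picked$adj_p,
                    source_group = picked$site_key,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select proteins with changed phosphorylation state
#'
#' A protein qualifies when at least one of its site groups is significant
#' (BH-adjusted p below `fdr`) in at least one timepoint of the given
#' ligand.
#'
#' @param site_stats `SiteStat` table.
#' @param ligand stimulation condition to restrict to (`NULL` = any).
#' @param fdr adjusted-p threshold (default 0.05).
#' @return character vector of protein accessions.
#' @export
select_changed_proteins <- function(site_stats, ligand = NULL, fdr = 0.05) {
  d <- site_stats
  if (!is.null(ligand)) d <- d[d$treatment == ligand, , drop = FALSE]
  hit <- !is.na(d$adj_p) & d$adj_p < fdr
  sort(unique(d$protein[hit]))
}
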