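# Kinase activity inference: a substrate-set z statistic against the
# sample-wide fold-change background (KSEA-style). For kinase substrates
# with mean log2FC M, background mean u and background sd s over all n
# measured sites, z = (M - u) / (s / sqrt(m)) with a two-tailed normal p.

#' Fold-change background of a contrast
#'
#' Mean and sample standard deviation (ddof 1) of all finite collapsed site
#' fold changes in one contrast — the distribution substrate sets are
#' compared against.
#'
#' @param site_fc `SiteFC` table.
#' @param contrast contrast name.
#' @return object of class `fc_background` with `u`, `sd`, `n_total`.
#' @export
compute_background <- function(site_fc, contrast) {
  x <- site_fc$fc[site_fc$contrast == contrast & is.finite(site_fc$fc)]
  if (length(x) < 2)
    stop("fewer than 2 finite fold changes in contrast ", contrast)
  s <- sd(x)
  if (s == 0)
    stop("degenerate background: all fold changes equal in ", contrast)
  structure(list(u = mean(x), sd = s, n_total = length(x)),
            class = "fc_background")
}

# substrate fold changes of one kinase in one contrast; multiply-
# phosphorylated site groups contribute once per group
.substrate_fcs <- function(kinase, site_fc, annotation, contrast) {
  sub <- annotation[annotation$kinase == kinase, , drop = FALSE]
  d <- site_fc[site_fc$contrast == contrast & is.finite(site_fc$fc), ,
               drop = FALSE]
  hit <- d[paste(d$protein, d$position) %in%
             paste(sub$protein, sub$position), , drop = FALSE]
  if ("source_group" %in% names(hit))
    hit <- hit[!duplicated(hit$source_group), , drop = FALSE]
  hit
}

#' z statistic for one kinase in one contrast
#'
#' @param kinase kinase identifier.
#' @param site_fc `SiteFC` table (one coordinate space with `annotation`).
#' @param background an `fc_background` for the contrast.
#' @param annotation kinase-substrate table (`kinase`, `protein`,
#'   `position`).
#' @param contrast contrast name.
#' @param min_substrates minimum measured substrate sites (default 2);
#'   kinases below the floor return `NULL` with a logged reason.
#' @param se_mode `"background"` (default): se = background sd / sqrt(m);
#'   `"substrate"`: se = sd of the substrate fold changes / sqrt(m).
#' @return one-row data.frame (`kinase`, `contrast`, `m`, `M`, `u`, `se`,
#'   `z`, `p`) or `NULL`.
#' @export
kinase_z <- function(kinase, site_fc, background, annotation, contrast,
                     min_substrates = 2L,
                     se_mode = c("background", "substrate")) {
  se_mode <- match.arg(se_mode)
  hit <- .substrate_fcs(kinase, site_fc, annotation, contrast)
  m <- nrow(hit)
  if (m < min_substrates) {
    message("kinase ", kinase, " skipped in ", contrast, ": ", m,
            " measured substrate site(s) < ", min_substrates)
    return(NULL)
  }
  M <- mean(hit$fc)
  s <- if (se_mode == "background") background$sd else sd(hit$fc)
  se <- s / sqrt(m)
  z <- (M - background$u) / se
  data.frame(kinase = kinase, contrast = contrast, m = m, M = M,
             u = background$u, se = se, z = z,
             p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Infer kinase activities across contrasts
#'
#' The package's central estimator. For every kinase with at least
#' `min_substrates` measured substrate sites in a contrast, computes the
#' substrate-set z statistic against that contrast's fold-change background
#' and a two-tailed normal p value. Kinases below the substrate floor are
#' omitted, not zero-filled. For each pair of treatments sharing a
#' timepoint, per-kinase z differences are recorded as contrast deltas (the
#' differentially-regulated-kinase display).
#'
#' @param site_fc `SiteFC` table, in the same coordinate space as
#'   `annotation` (i.e. after ortholog mapping when annotation is in the
#'   target species).
#' @param annotation kinase-substrate table (`kinase`, `protein`,
#'   `position`).
#' @param contrasts contrast names to analyse (default: all in `site_fc`).
#' @param min_substrates substrate floor (default 2).
#' @param alpha significance level for the `significant` flag (raw p,
#'   matching an unadjusted z-test cutoff; a BH-adjusted column `adj_p` is
#'   also emitted).
#' @param se_mode see [kinase_z()].
#' @param exclude_substrates_from_background if `TRUE`, each kinase's
#'   background excludes its own substrates.
#' @return object of class `kinase_activity` (a data.frame with one row per
#'   kinase/contrast: `kinase`, `contrast`, `m`, `M`, `u`, `se`, `z`, `p`,
#'   `adj_p`, `significant`), with the backgrounds and the contrast-delta
#'   table attached as attributes.
#' @seealso [coef.kinase_activity()], [plot.kinase_activity()],
#'   [contrast_deltas()]
#' @export
infer_activities <- function(site_fc, annotation, contrasts = NULL,
                             min_substrates = 2L, alpha = 0.05,
                             se_mode = c("background", "substrate"),
                             exclude_substrates_from_background = FALSE) {
  se_mode <- match.arg(se_mode)
  if (!nrow(annotation)) stop("empty kinase-substrate annotation")
  if (is.null(contrasts)) contrasts <- unique(site_fc$contrast)
  miss <- setdiff(contrasts, unique(site_fc$contrast))
  if (length(miss))
    stop("contrast(s) absent from fold-change table: ",
         paste(miss, collapse = ", "))

  kinases <- unique(annotation$kinase)
  backgrounds <- lapply(stats::setNames(contrasts, contrasts),
                        function(ct) compute_background(site_fc, ct))
  rows <- list()
  for (ct in contrasts) {
    for (k in kinases) {
      bg <- backgrounds[[ct]]
      if (exclude_substrates_from_background) {
        sub <- annotation[annotation$kinase == k, ]
        rest <- site_fc[site_fc$contrast == ct & is.finite(site_fc$fc) &
                          !(paste(site_fc$protein, site_fc$position) %in%
                              paste(sub$protein, sub$position)), ]
        if (nrow(rest) >= 2 && sd(rest$fc) > 0)
          bg <- structure(list(u = mean(rest$fc), sd = sd(rest$fc),
                               n_total = nrow(rest)),
                          class = "fc_background")
      }
      r <- suppressMessages(
        kinase_z(k, site_fc, bg, annotation, ct, min_substrates, se_mode))
      if (!is.null(r)) rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) {
    message("no kinase reached the substrate floor of ", min_substrates)
    res <- data.frame(kinase = character(0), contrast = character(0),
                      m = integer(0), M = numeric(0), u = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0),
                      adj_p = numeric(0), significant = logical(0))
  } else {
    res <- do.call(rbind, rows)
    res$adj_p <- ave(res$p, res$contrast, FUN = bh_adjust)
    res$significant <- res$p < alpha
  }

  # z differences between treatments sharing a timepoint
  deltas <- NULL
  if ("timepoint" %in% names(site_fc) && nrow(res)) {
    ct_tp <- unique(site_fc[, c("contrast", "treatment", "timepoint")])
    ct_tp <- ct_tp[ct_tp$contrast %in% contrasts, ]
    dl <- list()
    for (tp in unique(ct_tp$timepoint)) {
      cc <- ct_tp[ct_tp$timepoint == tp, ]
      if (nrow(cc) < 2) next
      cmb <- utils::combn(nrow(cc), 2)
      for (q in seq_len(ncol(cmb))) {
        a <- cc$contrast[cmb[1, q]]; b <- cc$contrast[cmb[2, q]]
        za <- res[res$contrast == a, c("kinase", "z")]
        zb <- res[res$contrast == b, c("kinase", "z")]
        both <- merge(za, zb, by = "kinase", suffixes = c("_a", "_b"))
        if (!nrow(both)) next
        dl[[length(dl) + 1]] <- data.frame(
          timepoint = tp, contrast_a = a, contrast_b = b,
          kinase = both$kinase, z_delta = both$z_a - both$z_b)
      }
    }
    if (length(dl)) deltas <- do.call(rbind, dl)
  }

  structure(res, class = c("kinase_activity", "data.frame"),
            alpha = alpha, min_substrates = min_substrates,
            se_mode = se_mode, backgrounds = backgrounds,
            contrast_deltas = deltas)
}

#' Contrast deltas of a kinase-activity fit
#'
#' Per-kinase z differences between treatments sharing a timepoint.
#' @param object a `kinase_activity` object.
#' @export
contrast_deltas <- function(object) attr(object, "contrast_deltas")

#' @export
print.kinase_activity <- function(x, ...) {
  cat("Kinase activities:", length(unique(x$kinase)), "kinase(s) across",
      length(unique(x$contrast)), "contrast(s)\n")
  cat("substrate floor m >=", attr(x, "min_substrates"),
      "; significance: p <", attr(x, "alpha"), "(two-tailed z test)\n")
  ord <- order(-abs(x$z))
  print.data.frame(head(as.data.frame(x)[ord, ], 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.kinase_activity <- function(object, ...) {
  by_ct <- split(as.data.frame(object), object$contrast)
  out <- do.call(rbind, lapply(names(by_ct), function(ct) {
    d <- by_ct[[ct]]
    data.frame(contrast = ct, kinases = nrow(d),
               significant = sum(d$significant),
               top_kinase = d$kinase[which.max(abs(d$z))],
               top_z = d$z[which.max(abs(d$z))])
  }))
  structure(out, class = c("summary.kinase_activity", "data.frame"))
}

#' Extract the z-score matrix of a fit
#'
#' @param object a `kinase_activity` object.
#' @param ... ignored.
#' @return numeric matrix, kinases by contrasts (NA where a kinase misses
#'   the substrate floor in a contrast).
#' @export
coef.kinase_activity <- function(object, ...) {
  kin <- sort(unique(object$kinase))
  cts <- unique(object$contrast)
  m <- matrix(NA_real_, length(kin), length(cts),
              dimnames = list(kin, cts))
  m[cbind(match(object$kinase, kin), match(object$contrast, cts))] <-
    object$z
  m
}

#' Dot plot of inferred kinase activities
#'
#' One panel row of z scores per contrast; kinases passing the significance
#' cutoff are filled, others grey (non-significant kinases de-emphasised).
#'
#' @param x a `kinase_activity` object.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.kinase_activity <- function(x, ...) {
  z <- coef(x)
  sig <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  sig[cbind(match(x$kinase, rownames(z)), match(x$contrast, colnames(z)))] <-
    x$significant
  op <- graphics::par(mfrow = c(1, ncol(z)), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(op))
  for (ct in colnames(z)) {
    ok <- !is.na(z[, ct])
    graphics::dotchart(z[ok, ct], labels = rownames(z)[ok],
                       color = ifelse(sig[ok, ct], "firebrick", "grey50"),
                       xlab = "z", main = ct, pch = 19, ...)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' @export
simulate.kinase_activity <- function(object, nsim = 1, seed = NULL, ...) {
  # draws of M under the fitted null (background) for each kinase/contrast
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, rnorm(nrow(object), object$u, object$se), simplify = FALSE)
}
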