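#' Cross-region / cross-sample variance decomposition
#'
#' Separates the two sources of spread in a multi-sample ROI table:
#' `sd_across_regions` is the mean, over samples, of the standard deviation
#' of that sample's 92 ROI values (how much the myelin profile varies along
#' the callosum); `sd_across_samples` is the mean, over ROIs, of the
#' standard deviation of that ROI's values across samples (how much
#' samples disagree at a fixed location). A regional pattern is considered
#' reproducible when the first clearly exceeds the second. Standard
#' deviations use the unbiased (n-1) estimator.
#'
#' @param table a [roi_sample_table()]; typically on the rescaled 1-7 scale
#'   so both SDs are in the reported arbitrary units, but any consistent
#'   units work.
#' @param modality which modality to decompose; may be omitted when the
#'   table holds a single modality with two or more samples.
#' @return list of class `variance_decomposition` with `sd_across_regions`,
#'   `sd_across_samples`, `n_samples`, `n_rois`, `modality`.
#' @export
variance_decomposition <- function(table, modality = NULL) {
  if (!inherits(table, "roi_sample_table"))
    stop_callomap("table must be a roi_sample_table", "callomap_input_error")
  if (is.null(modality)) {
    counts <- tapply(table$sample, table$modality,
                     function(s) length(unique(s)))
    multi <- names(counts)[counts >= 2]
    if (length(multi) != 1)
      stop_callomap("specify `modality`: table has no unique multi-sample modality",
                    "callomap_input_error")
    modality <- multi
  }
  sub <- table[table$modality == modality, ]
  if (nrow(sub) == 0)
    stop_callomap(sprintf("modality %s not in table", modality),
                  "callomap_lookup_error")
  wide <- matrix(NA_real_, nrow = length(unique(sub$sample)),
                 ncol = length(unique(sub$roi)),
                 dimnames = list(unique(sub$sample), sort(unique(sub$roi))))
  for (i in seq_len(nrow(sub)))
    wide[as.character(sub$sample[i]), as.character(sub$roi[i])] <- sub$value[i]
  n_samples <- nrow(wide); n_rois <- ncol(wide)
  if (n_samples < 2)
    stop_callomap("sd_across_samples is undefined for a single sample",
                  "callomap_input_error")
  if (n_rois < 2)
    stop_callomap("sd_across_regions is undefined for fewer than 2 ROIs",
                  "callomap_input_error")
  structure(list(sd_across_regions = mean(apply(wide, 1, sd)),
                 sd_across_samples = mean(apply(wide, 2, sd)),
                 n_samples = n_samples, n_rois = n_rois, modality = modality),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<variance_decomposition> %s (%d samples x %d ROIs)\n",
                     "  SD across regions: %.3f\n  SD across samples: %.3f\n"),
              x$modality, x$n_samples, x$n_rois,
              x$sd_across_regions, x$sd_across_samples))
  invisible(x)
}

#' Pearson correlation between two ROI vectors
#'
#' Product-moment correlation with a two-sided p-value from the exact t
#' transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom, the
#' standard inference for Pearson's r. A seeded permutation test (null
#' distribution of r under random pairing) is available as a robustness
#' check.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param pair optional character length-2 naming the two modalities.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm,perm_seed permutation count and seed for
#'   `method = "permutation"`.
#' @return list of class `roi_correlation`: `pair`, `r`, `r_squared`,
#'   `p_two_sided`, `n`, `method`.
#' @export
roi_pearson <- function(x, y, pair = c("x", "y"), method = c("t", "permutation"),
                        n_perm = 10000, perm_seed = 1L) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < length(x))
    warning(sprintf("%d incomplete ROI pairs dropped", length(x) - sum(keep)))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n)
    stop_callomap("x and y must have equal length", "callomap_input_error")
  if (n < 3)
    stop_callomap("need at least 3 complete pairs", "callomap_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_callomap("correlation undefined for a constant input", "callomap_input_error")
  r <- cor(x, y)
  if (method == "t") {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    set.seed(perm_seed)
    r_null <- replicate(n_perm, cor(x, sample(y)))
    p <- (1 + sum(abs(r_null) >= abs(r))) / (n_perm + 1)
  }
  structure(list(pair = pair, r = r, r_squared = r * r,
                 p_two_sided = p, n = n, method = method),
            class = "roi_correlation")
}

#' @export
print.roi_correlation <- function(x, ...) {
  cat(sprintf("<roi_correlation> %s vs %s: r = %.3f, r^2 = %.3f, p = %.3g (n = %d, %s)\n",
              x$pair[1], x$pair[2], x$r, x$r_squared, x$p_two_sided, x$n, x$method))
  invisible(x)
}

# Per-ROI means of one modality, averaging across its samples.
modality_roi_means <- function(table, modality) {
  sub <- table[table$modality == modality, ]
  if (nrow(sub) == 0)
    stop_callomap(sprintf("modality %s not in table", modality),
                  "callomap_lookup_error")
  means <- tapply(sub$value, sub$roi, mean)
  means[order(as.integer(names(means)))]
}

#' Pairwise correlations between modalities over the 92 ROIs
#'
#' For each requested pair, averages multi-sample modalities across their
#' samples per ROI (as done for the three histological samples) and
#' computes the Pearson correlation of the two 92-ROI vectors.
#'
#' @param table a [roi_sample_table()].
#' @param pairs list of character length-2 vectors, or strings `"A:B"`.
#' @param ... passed to [roi_pearson()] (e.g. `method`).
#' @return data.frame with one row per pair: `modality_a`, `modality_b`,
#'   `r`, `r_squared`, `p_two_sided`, `n`.
#' @export
correlate_all <- function(table, pairs, ...) {
  if (!inherits(table, "roi_sample_table"))
    stop_callomap("table must be a roi_sample_table", "callomap_input_error")
  pairs <- lapply(pairs, function(p) {
    if (is.character(p) && length(p) == 1) p <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(p) != 2)
      stop_callomap("each pair must name two modalities", "callomap_config_error")
    p
  })
  rows <- lapply(pairs, function(p) {
    res <- roi_pearson(modality_roi_means(table, p[1]),
                       modality_roi_means(table, p[2]), pair = p, ...)
    data.frame(modality_a = p[1], modality_b = p[2], r = res$r,
               r_squared = res$r_squared, p_two_sided = res$p_two_sided,
               n = res$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scatter plot of one modality pair over the 92 ROIs
#'
#' @param table a rescaled [roi_sample_table()].
#' @param pair character length-2 modality names.
#' @param file optional PNG path.
#' @return the [roi_pearson()] result, invisibly.
#' @export
plot_correlation <- function(table, pair, file = NULL) {
  x <- modality_roi_means(table, pair[1])
  y <- modality_roi_means(table, pair[2])
  res <- roi_pearson(x, y, pair = pair)
  if (!is.null(file)) {
    png(file, width = 600, height = 600)
    on.exit(dev.off())
  }
  plot(x, y, pch = 19, col = "#00000088",
       xlab = paste(pair[1], "(a.u., 1-7)"), ylab = paste(pair[2], "(a.u., 1-7)"),
       main = sprintf("%s vs %s: r = %.2f, r2 = %.2f, p = %.2g",
                      pair[1], pair[2], res$r, res$r_squared, res$p_two_sided))
  abline(stats::lm(y ~ x), col = "firebrick", lwd = 2)
  invisible(res)
}
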