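#' Per-sample genus relative abundances
#'
#' Converts a samples x genera count matrix to percentages of the total
#' classified sequences per sample; every retained row sums to 100.
#' Samples with zero total counts are dropped with a warning.
#'
#' @param counts Matrix or data.frame of non-negative integer counts,
#'   rows = samples, columns = genera.
#' @return Numeric matrix of percentages with the same dimnames (minus
#'   any dropped samples).
#' @examples
#' relative_abundance(rbind(s1 = c(Geobacter = 30, Other = 70)))
#' @export
relative_abundance <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0)) {
    stop("counts must be a non-negative numeric matrix", call. = FALSE)
  }
  if (ncol(m) < 1) stop("at least one genus column is required", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " sample(s) with zero total counts",
            call. = FALSE)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 1, tot, "/") * 100
}

#' Exact one-sided permutation test on a difference of means
#'
#' Enumerates every assignment of the pooled observations into groups of
#' the observed sizes and computes the achieved significance level of
#' `mean(x) - mean(y)` against the permutation distribution (one-sided,
#' greater).  With three replicates per side there are exactly
#' `choose(6, 3) = 20` assignments, so the smallest attainable p-value is
#' 0.05.  If all observations are identical the p-value is 1.
#'
#' @param x,y Numeric vectors with at least two observations each.
#' @return The permutation p-value.
#' @examples
#' perm_test_greater(c(30, 32, 31), c(2, 3, 2))  # 0.05
#' @export
perm_test_greater <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two replicates per group", call. = FALSE)
  }
  pooled <- c(x, y)
  n <- length(x)
  ncomb <- choose(length(pooled), n)
  if (ncomb > 1e5) {
    stop("too many group assignments to enumerate exactly (",
         ncomb, ")", call. = FALSE)
  }
  obs <- mean(x) - mean(y)
  idx <- utils::combn(length(pooled), n)
  diffs <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  # tolerance absorbs floating-point ties with the observed statistic
  mean(diffs >= obs - 1e-9)
}

#' Screen genera for 13C assimilation
#'
#' For each genus, tests whether its relative abundance in the heavy
#' fractions of the labeled (13C) treatment exceeds that of the parallel
#' unlabeled (12C) treatment, using the exact one-sided permutation test
#' on the difference of means.  A genus is flagged as a putative
#' assimilator when `p <= alpha` and the labeled mean is strictly larger.
#' No multiple-testing correction is applied by default (per-genus
#' significance mirrors the usual reporting convention for these
#' screens); Benjamini-Hochberg adjustment is available via `p_adjust`.
#'
#' @param labeled,unlabeled Matrices of per-sample relative abundances
#'   (percent), rows = replicate fraction samples, columns = genera.
#'   Columns are aligned by name; a genus absent from one side counts as
#'   zeros there.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust "none" (default) or "BH".
#' @return A data.frame with one row per genus: `genus`,
#'   `mean_rel_labeled`, `mean_rel_unlabeled`, `p_value`, `p_adjusted`,
#'   `assimilator`.
#' @examples
#' lab <- cbind(Geobacter = c(30, 32, 31), Bacillus = c(2, 2, 3))
#' unl <- cbind(Geobacter = c(2, 3, 2), Bacillus = c(2, 3, 2))
#' assimilator_screen(lab, unl)
#' @export
assimilator_screen <- function(labeled, unlabeled, alpha = 0.05,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  labeled <- as.matrix(labeled)
  unlabeled <- as.matrix(unlabeled)
  if (nrow(labeled) < 2 || nrow(unlabeled) < 2) {
    stop("need at least two replicate samples per treatment", call. = FALSE)
  }
  genera <- union(colnames(labeled), colnames(unlabeled))
  if (is.null(genera)) stop("genus columns must be named", call. = FALSE)
  col_or_zero <- function(m, g) if (g %in% colnames(m)) m[, g] else
    rep(0, nrow(m))
  res <- lapply(genera, function(g) {
    x <- col_or_zero(labeled, g)
    y <- col_or_zero(unlabeled, g)
    data.frame(genus = g,
               mean_rel_labeled = mean(x),
               mean_rel_unlabeled = mean(y),
               p_value = perm_test_greater(x, y),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- if (p_adjust == "BH") {
    stats::p.adjust(res$p_value, method = "BH")
  } else {
    res$p_value
  }
  res$assimilator <- res$p_adjusted <= alpha &
    res$mean_rel_labeled > res$mean_rel_unlabeled
  res
}

#' Net proportional change in relative abundance
#'
#' Difference, in percentage points, between a genus's mean relative
#' abundance under an iron amendment and under the unamended control.
#' Negative values indicate depletion.
#'
#' @param mean_treatment,mean_control Mean relative abundances in percent,
#'   each in `[0, 100]`.
#' @return Percentage points, `mean_treatment - mean_control`.
#' @examples
#' net_change(31, 2.4)  # 28.6
#' @export
net_change <- function(mean_treatment, mean_control) {
  if (any(mean_treatment < 0 | mean_treatment > 100) ||
      any(mean_control < 0 | mean_control > 100)) {
    stop("relative abundances must lie in [0, 100]", call. = FALSE)
  }
  mean_treatment - mean_control
}

#' Fold change in relative abundance versus a control
#'
#' Ratio of treatment to control mean relative abundance.  A zero control
#' makes the ratio undefined; if `pseudo_count` is supplied (typically
#' half the smallest nonzero relative abundance in the table) it is added
#' to both sides instead and the result is flagged via the
#' `"pseudo_count"` attribute.
#'
#' @param mean_treatment,mean_control Mean relative abundances, percent.
#' @param pseudo_count Optional fallback added to both numerator and
#'   denominator when the control is zero.
#' @return The fold change (ratio).
#' @examples
#' fold_change(31, 2.4)  # ~12.9
#' @export
fold_change <- function(mean_treatment, mean_control, pseudo_count = NULL) {
  if (any(mean_treatment < 0) || any(mean_control < 0)) {
    stop("relative abundances must be non-negative", call. = FALSE)
  }
  zero <- mean_control == 0
  if (any(zero)) {
    if (is.null(pseudo_count)) {
      stop("fold change undefined for a zero control; supply `pseudo_count`",
           call. = FALSE)
    }
    fc <- (mean_treatment + pseudo_count) / (mean_control + pseudo_count)
    fc[!zero] <- mean_treatment[!zero] / mean_control[!zero]
    attr(fc, "pseudo_count") <- pseudo_count
    return(fc)
  }
  mean_treatment / mean_control
}

#' Half the minimum nonzero relative abundance
#'
#' Convenience pseudo-count for [fold_change()] with zero controls.
#'
#' @param rel Matrix or vector of relative abundances.
#' @return Half the smallest strictly positive value.
#' @export
half_min_nonzero <- function(rel) {
  v <- rel[rel > 0]
  if (length(v) == 0) stop("no nonzero abundances", call. = FALSE)
  min(v) / 2
}

#' Reference list of putative dissimilatory iron-reducing genera
#'
#' Genera flagged in published reviews of dissimilatory Fe(III)-reducing
#' bacteria, used in place of a functional marker gene (none exists for
#' iron reduction).  Covers the taxa recurrently recovered from paddy
#' soils and freshwater sediments.
#'
#' @return A data.frame with columns `genus` and `citation`.
#' @examples
#' iron_reducer_genera()$genus
#' @export
iron_reducer_genera <- function() {
  data.frame(
    genus = c("Geobacter", "Geothrix", "Desulfobulbus", "Clostridium",
              "Anaeromyxobacter", "Desulfovibrio", "Desulfosporosinus",
              "Dechloromonas", "Pseudomonas", "Desulfitobacterium",
              "Acidiphilium"),
    citation = "published reviews of dissimilatory Fe(III)-reducing taxa",
    stringsAsFactors = FALSE
  )
}

#' Restrict a taxon table to putative iron reducers
#'
#' Keeps only the genus columns present in the reference list; counts are
#' passed through unchanged.  An empty intersection returns a zero-column
#' table with a warning.
#'
#' @param counts Samples x genera count (or abundance) matrix/data.frame
#'   with genus column names.
#' @param reference A data.frame with a `genus` column, or a character
#'   vector of genus names; default [iron_reducer_genera()].
#' @return The column subset of `counts`, same class as the input matrix.
#' @examples
#' tab <- cbind(Geobacter = c(5, 8), Methanosarcina = c(3, 1))
#' filter_iron_reducers(tab)
#' @export
filter_iron_reducers <- function(counts, reference = iron_reducer_genera()) {
  genera <- if (is.data.frame(reference)) reference$genus else reference
  keep <- intersect(colnames(counts), genera)
  if (length(keep) == 0) {
    warning("no reference genera present in the table", call. = FALSE)
  }
  counts[, keep, drop = FALSE]
}

#' Most abundant genera in a relative-abundance table
#'
#' Rank preselection used before significance screening: keeps the `n`
#' genera with the highest mean relative abundance.
#'
#' @param rel Samples x genera relative-abundance matrix.
#' @param n Number of genera to keep (default 10).
#' @return Character vector of genus names, most abundant first.
#' @export
top_genera <- function(rel, n = 10) {
  mu <- colMeans(as.matrix(rel))
  names(sort(mu, decreasing = TRUE))[seq_len(min(n, length(mu)))]
}
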