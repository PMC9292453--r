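.mrd_classes <- c("POS", "PNQ", "NEG")

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Construct a 3x3 paired-classification table
#'
#' @param counts 3x3 non-negative integer matrix; rows are ddPCR classes,
#'   columns Q-RT-PCR classes, both in the order POS, PNQ, NEG.
#' @return A list of class `"crosstab_result"` with `counts` and `n_total`.
#' @export
crosstab_result <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("'counts' must be a 3x3 matrix of non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ddPCR = .mrd_classes, QRTPCR = .mrd_classes)
  structure(list(counts = counts, n_total = sum(counts)),
            class = "crosstab_result")
}

#' Cross-tabulate paired MRD classifications
#'
#' @param qrtpcr_class,ddpcr_class Paired class vectors; values must be
#'   POS, PNQ or NEG.
#' @return A `"crosstab_result"`; rows ddPCR, columns Q-RT-PCR, both ordered
#'   POS, PNQ, NEG. Empty input gives an all-zero table.
#' @export
mrd_crosstab <- function(qrtpcr_class, ddpcr_class) {
  if (length(qrtpcr_class) != length(ddpcr_class)) {
    stop("class vectors must have equal length", call. = FALSE)
  }
  bad <- unique(c(qrtpcr_class, ddpcr_class))
  bad <- bad[!bad %in% .mrd_classes]
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(ddpcr_class, .mrd_classes),
               factor(qrtpcr_class, .mrd_classes))
  crosstab_result(unclass(tab))
}

#' Overall concordance between the paired methods
#'
#' Percentage of samples receiving the same class from both methods (the
#' diagonal of the cross-table). Both a one-decimal figure
#' (half-away-from-zero rounding) and a nearest-integer figure are reported,
#' as both conventions are common.
#'
#' @param ct A `"crosstab_result"` with `n_total > 0`.
#' @return A list: `percent` (exact), `percent_1dp`, `percent_nearest_int`,
#'   `n_concordant`, `n_total`.
#' @export
overall_concordance <- function(ct) {
  stopifnot(inherits(ct, "crosstab_result"))
  if (ct$n_total == 0) stop("empty cross-table: concordance undefined", call. = FALSE)
  d <- sum(diag(ct$counts))
  pct <- 100 * d / ct$n_total
  list(percent = pct,
       percent_1dp = round_half_up(pct, 1),
       percent_nearest_int = round_half_up(pct, 0),
       n_concordant = d, n_total = ct$n_total)
}

#' Recovery of quantifiability by ddPCR
#'
#' Among samples the comparator could not quantify (Q-RT-PCR PNQ or NEG),
#' the percentage that ddPCR calls positive and quantifiable.
#'
#' @param ct A `"crosstab_result"`.
#' @return A list: `percent`, `percent_1dp`, `percent_nearest_int`,
#'   `n_recovered`, `n_not_quantifiable`.
#' @export
quantifiability_recovery <- function(ct) {
  stopifnot(inherits(ct, "crosstab_result"))
  denom <- sum(ct$counts[, c("PNQ", "NEG")])
  if (denom == 0) stop("no non-quantifiable comparator samples: recovery undefined",
                       call. = FALSE)
  num <- sum(ct$counts["POS", c("PNQ", "NEG")])
  pct <- 100 * num / denom
  list(percent = pct,
       percent_1dp = round_half_up(pct, 1),
       percent_nearest_int = round_half_up(pct, 0),
       n_recovered = num, n_not_quantifiable = denom)
}

#' Exact paired test on quantifiable-versus-not
#'
#' Collapses the 3x3 table to quantifiable (POS) versus not (PNQ or NEG)
#' and tests whether the two paired methods disagree symmetrically — an
#' exact McNemar-type test on the discordant counts `b` (quantifiable by
#' ddPCR only) and `c` (quantifiable by Q-RT-PCR only): two-sided
#' `p = min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' `b + c = 0` gives `p = 1`. A continuity-corrected chi-square variant is
#' available as a secondary option.
#'
#' @param ct A `"crosstab_result"`, or `NULL` when `b`/`c` are given
#'   directly.
#' @param b,c Discordant counts, derived from `ct` when supplied.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return A list with `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_exact <- function(ct = NULL, b = NULL, c = NULL,
                          method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (!is.null(ct)) {
    stopifnot(inherits(ct, "crosstab_result"))
    b <- sum(ct$counts["POS", c("PNQ", "NEG")])
    c <- sum(ct$counts[c("PNQ", "NEG"), "POS"])
  }
  if (is.null(b) || is.null(c) || b < 0 || c < 0) {
    stop("need a cross-table or non-negative discordant counts b, c", call. = FALSE)
  }
  nd <- b + c
  p <- if (nd == 0) {
    1
  } else if (method == "exact") {
    min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
  } else {
    stat <- (abs(b - c) - 1)^2 / nd
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p_value = p, b = b, c = c, method = method)
}

#' Pearson correlation of paired quantitative MRD values
#'
#' Sample product-moment correlation of the paired Q-RT-PCR and ddPCR
#' ratios. For dual-transcript samples the default pairing policy is one
#' pair per transcript (see [reference_diagnostic_table()]).
#'
#' @param x,y Paired numeric vectors, at least 3 pairs, each with nonzero
#'   variance.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in one coordinate: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}
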