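#' Construct a replicate-positivity table
#'
#' @param label Dilution labels (fractions), unique, one per point.
#' @param n_replicates,n_positive Replicate counts per point;
#'   `0 <= n_positive <= n_replicates`.
#' @param extra Optional data frame of extra per-point columns.
#' @return A data frame of class `"positivity_table"` ordered from the least
#'   dilute (largest label) to the most dilute point, with
#'   `fraction_positive`.
#' @export
positivity_table <- function(label, n_replicates, n_positive, extra = NULL) {
  if (anyDuplicated(label)) stop("dilution labels must be unique", call. = FALSE)
  if (any(n_positive < 0) || any(n_positive > n_replicates)) {
    stop("need 0 <= n_positive <= n_replicates", call. = FALSE)
  }
  tab <- data.frame(label = label,
                    n_replicates = as.integer(n_replicates),
                    n_positive = as.integer(n_positive))
  if (!is.null(extra)) tab <- cbind(tab, extra)
  tab <- tab[order(tab$label, decreasing = TRUE), , drop = FALSE]
  tab$fraction_positive <- tab$n_positive / tab$n_replicates
  rownames(tab) <- NULL
  class(tab) <- c("positivity_table", "data.frame")
  tab
}

#' Replicate positivity by dilution point
#'
#' Scores each replicate well of a dilution experiment positive when its
#' positive-droplet count reaches the detection threshold of the rules
#' (default: a single positive droplet), and tabulates the positive fraction
#' per dilution point, ordered from the least to the most dilute point.
#'
#' @param experiment A `"dilution_experiment"` from
#'   [simulate_lod_experiment()] (wells assumed QC-filtered).
#' @param rules A [classification_rules()]; only
#'   `min_positive_droplets_detected` is used.
#' @return A `"positivity_table"` with a `copies_per_well` column.
#' @export
positivity_by_dilution <- function(experiment, rules = classification_rules()) {
  if (!inherits(experiment, "dilution_experiment") ||
      length(experiment$points) == 0) {
    stop("empty or invalid dilution experiment", call. = FALSE)
  }
  lab <- vapply(experiment$points, function(p) p$label, 0)
  m <- vapply(experiment$points, function(p) p$copies_per_well, 0)
  nrep <- vapply(experiment$points, function(p) nrow(p$wells), 0L)
  npos <- vapply(experiment$points, function(p) {
    sum(p$wells$k_positive >= rules$min_positive_droplets_detected)
  }, 0L)
  positivity_table(lab, nrep, npos, extra = data.frame(copies_per_well = m))
}

#' Maximum sensitivity from a positivity table
#'
#' The assay's maximum sensitivity is the most dilute point such that it and
#' every less-dilute point reach the required positive-replicate fraction
#' (default 75%) — the rule applies cumulatively from the least dilute point
#' down, so an isolated positive point beyond a failing one does not count.
#'
#' @param table A `"positivity_table"`.
#' @param min_fraction Required positive-replicate fraction (default 0.75).
#' @return The qualifying dilution label, or `NA` when no point qualifies.
#' @export
max_sensitivity <- function(table, min_fraction = 0.75) {
  if (!inherits(table, "positivity_table") || nrow(table) == 0) {
    stop("empty or invalid positivity table", call. = FALSE)
  }
  ok <- table$fraction_positive >= min_fraction
  run <- cumprod(ok) == 1  # TRUE prefix from the least dilute point
  if (!any(run)) return(NA_real_)
  table$label[max(which(run))]
}

#' Specificity summary over background wells
#'
#' Counts false-positive replicates among background wells (NTCs,
#' healthy-donor pools, Ph-negative controls): a replicate is a false
#' positive when it contains any positive droplet.
#'
#' @param wells Droplet-well data frame containing only background roles.
#' @return A list with `n_replicates_tested`, `n_false_positive` and
#'   `specificity` (fraction of clean replicates).
#' @export
specificity_summary <- function(wells) {
  wells <- validate_wells(wells)
  if (nrow(wells) == 0) stop("no background wells supplied", call. = FALSE)
  bg <- c("NTC", "healthy_donor", "ph_negative_control")
  if (any(!wells$role %in% bg)) {
    stop("non-background wells in input: ",
         paste(unique(wells$role[!wells$role %in% bg]), collapse = ", "),
         call. = FALSE)
  }
  n_fp <- sum(wells$k_positive > 0)
  list(n_replicates_tested = nrow(wells),
       n_false_positive = n_fp,
       specificity = 1 - n_fp / nrow(wells))
}

#' Reproducibility of paired concentration estimates
#'
#' Two estimates of the same sample are called reproducible when they fall
#' within the same logarithm, operationalised as
#' `|log10(a) - log10(b)| < 1`. The strict log-difference reading is used
#' rather than same-integer-decade, which would call (9.9, 10.1)
#' irreproducible. Pairs where both members are zero are reproducible;
#' pairs where exactly one member is zero are reported as a separate
#' `discordant_detection` category, since no log distance exists.
#'
#' @param a,b Paired non-negative concentration estimates (copies/µl).
#' @return A list with the per-pair data frame (`category` one of
#'   `reproducible`, `not_reproducible`, `discordant_detection`) and summary
#'   fractions.
#' @export
reproducibility_check <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0) {
    stop("need equal-length, non-empty paired estimates", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) stop("concentrations must be >= 0", call. = FALSE)
  dlog <- abs(log10(a) - log10(b))
  category <- ifelse(
    a == 0 & b == 0, "reproducible",
    ifelse(xor(a == 0, b == 0), "discordant_detection",
           ifelse(dlog < 1, "reproducible", "not_reproducible"))
  )
  pairs <- data.frame(a = a, b = b,
                      delta_log10 = ifelse(a > 0 & b > 0, dlog, NA_real_),
                      category = category)
  list(
    pairs = pairs,
    n_pairs = nrow(pairs),
    fraction_reproducible = mean(category == "reproducible"),
    n_discordant_detection = sum(category == "discordant_detection")
  )
}
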