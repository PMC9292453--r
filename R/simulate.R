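# All generators route randomness through an explicit seed (carried in the
# config or passed per call) and restore the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for synthetic droplet data
#'
#' Parameters of the droplet-level generative model used throughout the
#' synthetic-data functions. Droplets per well vary as a rounded Gaussian
#' truncated at 1 (real runs only bound the count from below, via QC);
#' template molecules partition into droplets at random, so at reaction
#' concentration `C` copies/µl a droplet of volume `droplet_volume` µl is
#' positive with probability `1 - exp(-C * droplet_volume)`. The
#' `partitioned_fraction` is the fraction of a reaction's template molecules
#' that end up in read droplets (droplet generation and reading never capture
#' the whole reaction); `rain_rate` flips negative droplets positive
#' independently to emulate false-positive rain. Fluorescence amplitudes are
#' drawn from two Gaussian clusters that are separable by construction.
#'
#' @param n_droplets_mean,n_droplets_sd Accepted droplets per well
#'   (default 20000 +/- 1500).
#' @param droplet_volume Droplet volume, µl (default `8.5e-4` = 0.85 nL).
#' @param partitioned_fraction Fraction of reaction template molecules that
#'   land in read droplets, in (0, 1] (default 0.8).
#' @param rain_rate Per-droplet false-positive probability in \[0, 1)
#'   (default 0; clean NTC/donor backgrounds).
#' @param amplitude_neg_mean,amplitude_neg_sd,amplitude_pos_mean,amplitude_pos_sd
#'   Fluorescence cluster parameters (a.u.); the positive centre must sit at
#'   least 6 negative SDs above the negative centre.
#' @param seed Integer seed; every generator drawing from this config is
#'   reproducible from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_droplets_mean = 20000, n_droplets_sd = 1500,
                       droplet_volume = 8.5e-4, partitioned_fraction = 0.8,
                       rain_rate = 0,
                       amplitude_neg_mean = 1000, amplitude_neg_sd = 50,
                       amplitude_pos_mean = 8000, amplitude_pos_sd = 300,
                       seed = NULL) {
  if (droplet_volume <= 0) stop("droplet_volume must be positive", call. = FALSE)
  if (rain_rate < 0 || rain_rate >= 1) stop("rain_rate must be in [0, 1)", call. = FALSE)
  if (partitioned_fraction <= 0 || partitioned_fraction > 1) {
    stop("partitioned_fraction must be in (0, 1]", call. = FALSE)
  }
  if (amplitude_pos_mean <= amplitude_neg_mean + 6 * amplitude_neg_sd) {
    stop("amplitude clusters not separable: need pos_mean > neg_mean + 6*neg_sd",
         call. = FALSE)
  }
  structure(
    list(n_droplets_mean = n_droplets_mean, n_droplets_sd = n_droplets_sd,
         droplet_volume = droplet_volume,
         partitioned_fraction = partitioned_fraction,
         rain_rate = rain_rate,
         amplitude_neg_mean = amplitude_neg_mean,
         amplitude_neg_sd = amplitude_neg_sd,
         amplitude_pos_mean = amplitude_pos_mean,
         amplitude_pos_sd = amplitude_pos_sd,
         seed = seed),
    class = "sim_config"
  )
}

# droplets per well: rounded Gaussian truncated at >= 1
draw_n_droplets <- function(n, config) {
  k <- pmax(1L, as.integer(round(stats::rnorm(n, config$n_droplets_mean,
                                              config$n_droplets_sd))))
  k
}

# one well's counts at a given per-droplet positive probability
draw_well_counts <- function(p, config) {
  n <- draw_n_droplets(1L, config)
  p_eff <- p + (1 - p) * config$rain_rate
  k <- stats::rbinom(1L, n, p_eff)
  c(n = n, k = k)
}

#' Simulate one droplet well
#'
#' Draws a well's accepted-droplet count, makes each droplet positive
#' independently with the Poisson-occupancy probability
#' `1 - exp(-concentration * droplet_volume)` (plus rain), and optionally
#' attaches per-droplet fluorescence amplitudes drawn from the two clusters.
#'
#' @param concentration Template concentration in copies/µl of reaction;
#'   must be non-negative.
#' @param config A [sim_config()].
#' @param role,target,well_id,sample_id,replicate_group Well metadata.
#' @param with_amplitudes Attach per-droplet amplitudes (attribute
#'   `"amplitudes"`, a named list keyed by `well_id`)?
#' @param seed Overrides `config$seed` for this call.
#' @return A one-row droplet-well data frame (see [validate_wells()]).
#' @export
simulate_well <- function(concentration, config = sim_config(),
                          role = "sample", target = "p190",
                          well_id = "A01", sample_id = well_id,
                          replicate_group = sample_id,
                          with_amplitudes = FALSE,
                          seed = config$seed) {
  if (is.na(concentration) || concentration < 0) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  local_seed(seed, {
    p <- -expm1(-concentration * config$droplet_volume)
    nk <- draw_well_counts(p, config)
    well <- data.frame(
      well_id = well_id, sample_id = sample_id, target = target, role = role,
      replicate_group = replicate_group,
      n_accepted = nk[["n"]], k_positive = nk[["k"]]
    )
    well <- validate_wells(well)
    if (with_amplitudes) {
      amp <- c(
        stats::rnorm(nk[["k"]], config$amplitude_pos_mean, config$amplitude_pos_sd),
        stats::rnorm(nk[["n"]] - nk[["k"]], config$amplitude_neg_mean,
                     config$amplitude_neg_sd)
      )
      attr(well, "amplitudes") <- stats::setNames(list(sample(amp)), well_id)
    }
    well
  })
}

#' Simulate a batch of replicate wells at one concentration
#'
#' Vectorised counterpart of [simulate_well()] without amplitudes: draws
#' `n_wells` wells at the same concentration in one pass. Used by the
#' Monte-Carlo validation studies where thousands of wells are needed.
#'
#' @inheritParams simulate_well
#' @param n_wells Number of replicate wells.
#' @return A droplet-well data frame with `n_wells` rows.
#' @export
simulate_wells <- function(concentration, n_wells, config = sim_config(),
                           role = "sample", target = "p190",
                           sample_id = "S1", replicate_group = sample_id,
                           seed = config$seed) {
  if (is.na(concentration) || concentration < 0) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  if (n_wells < 1) stop("need at least one well", call. = FALSE)
  local_seed(seed, {
    p <- -expm1(-concentration * config$droplet_volume)
    p_eff <- p + (1 - p) * config$rain_rate
    n <- draw_n_droplets(n_wells, config)
    k <- stats::rbinom(n_wells, n, p_eff)
    validate_wells(data.frame(
      well_id = sprintf("W%04d", seq_len(n_wells)),
      sample_id = sample_id, target = target, role = role,
      replicate_group = replicate_group,
      n_accepted = n, k_positive = k
    ))
  })
}

#' Simulate a serial dilution series
#'
#' Generates replicate groups of wells at `base_concentration * factor` for
#' each dilution factor, recording the nominal factor and concentration in
#' extra metadata columns.
#'
#' @param base_concentration Undiluted concentration, copies/µl (> 0).
#' @param dilution_factors Strictly decreasing factors in (0, 1].
#' @param replicates_per_point Wells per dilution point.
#' @param config A [sim_config()].
#' @param target Transcript target for the wells.
#' @param seed Overrides `config$seed`.
#' @return A droplet-well data frame with extra columns `nominal_factor` and
#'   `nominal_concentration`; `replicate_group` identifies the dilution point.
#' @export
simulate_dilution_series <- function(base_concentration, dilution_factors,
                                     replicates_per_point = 2,
                                     config = sim_config(), target = "p190",
                                     seed = config$seed) {
  if (length(dilution_factors) == 0) stop("no dilution factors", call. = FALSE)
  if (any(dilution_factors <= 0 | dilution_factors > 1)) {
    stop("dilution factors must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(dilution_factors), strictly = TRUE)) {
    stop("dilution factors must be strictly decreasing", call. = FALSE)
  }
  if (base_concentration <= 0) stop("base_concentration must be positive", call. = FALSE)

  local_seed(seed, {
    rows <- list()
    for (i in seq_along(dilution_factors)) {
      f <- dilution_factors[i]
      conc <- base_concentration * f
      p <- -expm1(-conc * config$droplet_volume)
      group <- format(f, scientific = TRUE)
      for (r in seq_len(replicates_per_point)) {
        nk <- draw_well_counts(p, config)
        rows[[length(rows) + 1L]] <- data.frame(
          well_id = sprintf("D%02dR%02d", i, r),
          sample_id = sprintf("dil_%s", group),
          target = target, role = "sample",
          replicate_group = group,
          n_accepted = nk[["n"]], k_positive = nk[["k"]],
          nominal_factor = f, nominal_concentration = conc
        )
      }
    }
    validate_wells(do.call(rbind, rows))
  })
}

#' Default limit-of-detection escalation design
#'
#' The replicate-escalation design used for LOD assessment: five dilution
#' labels with 2, 6, 8, 12 and 14 replicates. Two copies-per-well mappings
#' are carried: `"proportional"` (10, 5, 1, 0.5, 0.1 copies — follows the
#' dilution-label arithmetic relative to the 10-copy standard point) and
#' `"stated"` (10, 5, 2, 1, 0.5 — the copy counts as quoted in the assay
#' write-up). The proportional mapping is the simulator default; see the
#' methods vignette for the discrepancy between the two.
#'
#' @param copies One of `"proportional"` or `"stated"`.
#' @return A list with `labels`, `replicates`, `copies_per_well`.
#' @export
lod_default_design <- function(copies = c("proportional", "stated")) {
  copies <- match.arg(copies)
  list(
    labels = c(1e-4, 5e-5, 1e-5, 5e-6, 1e-6),
    replicates = c(2L, 6L, 8L, 12L, 14L),
    copies_per_well = switch(copies,
      proportional = c(10, 5, 1, 0.5, 0.1),
      stated = c(10, 5, 2, 1, 0.5)
    )
  )
}

#' Simulate a limit-of-detection replicate-escalation experiment
#'
#' For each dilution point with expected `m` template molecules per well, a
#' replicate well receives `Poisson(m)` molecules, of which
#' `Binomial(., partitioned_fraction)` land in read droplets; the positive
#' droplet count is the number of distinct droplets those molecules occupy,
#' plus any rain. With `partitioned_fraction = 1` and no rain a replicate is
#' positive (>= 1 positive droplet) with probability `1 - exp(-m)`.
#'
#' @param copies_per_well Expected molecules per well at each point.
#' @param replicates Replicate wells per point; same length.
#' @param config A [sim_config()].
#' @param labels Dilution labels (fractions), one per point; defaults to the
#'   escalation-design labels when lengths match, else the copy numbers.
#' @param target Transcript target.
#' @param seed Overrides `config$seed`.
#' @return A list of class `"dilution_experiment"`: `points` (each with
#'   `label`, `copies_per_well`, `wells`) and `design_name`.
#' @export
simulate_lod_experiment <- function(copies_per_well = lod_default_design()$copies_per_well,
                                    replicates = lod_default_design()$replicates,
                                    config = sim_config(),
                                    labels = NULL, target = "p190",
                                    seed = config$seed) {
  if (length(copies_per_well) != length(replicates)) {
    stop("copies_per_well and replicates must have equal length", call. = FALSE)
  }
  if (any(copies_per_well < 0)) stop("copies per well must be >= 0", call. = FALSE)
  if (any(replicates < 1)) stop("each point needs >= 1 replicate", call. = FALSE)
  if (is.null(labels)) {
    d <- lod_default_design()
    labels <- if (length(copies_per_well) == length(d$labels)) d$labels
              else copies_per_well
  }
  if (anyDuplicated(labels)) stop("dilution labels must be unique", call. = FALSE)

  local_seed(seed, {
    points <- vector("list", length(copies_per_well))
    for (i in seq_along(copies_per_well)) {
      m <- copies_per_well[i]
      nr <- replicates[i]
      n <- draw_n_droplets(nr, config)
      n_mol <- stats::rpois(nr, m)
      landed <- stats::rbinom(nr, n_mol, config$partitioned_fraction)
      # distinct droplets occupied by the landed molecules
      k <- integer(nr)
      for (r in which(landed > 0)) {
        k[r] <- length(unique(sample.int(n[r], landed[r], replace = TRUE)))
      }
      if (config$rain_rate > 0) {
        k <- k + stats::rbinom(nr, n - k, config$rain_rate)
      }
      wells <- validate_wells(data.frame(
        well_id = sprintf("L%02dR%02d", i, seq_len(nr)),
        sample_id = sprintf("lod_point_%02d", i),
        target = target, role = "sample",
        replicate_group = sprintf("point_%02d", i),
        n_accepted = n, k_positive = k
      ))
      points[[i]] <- list(label = labels[i], copies_per_well = m, wells = wells)
    }
    structure(list(points = points, design_name = "replicate_escalation"),
              class = "dilution_experiment")
  })
}

#' Cohort specification for paired-method simulation
#'
#' Describes a follow-up cohort of MRD samples with a mixture of true
#' residual-disease levels and a simple generative model for the comparator
#' Q-RT-PCR call: samples at or above `qrtpcr_quant_limit` (MRD ratio,
#' percent scale) are quantifiable (POS); below it the target is detected —
#' hence PNQ — with probability `1 - exp(-eff * copies_sampled)` where
#' `copies_sampled` is the expected number of target copies in a
#' `qrtpcr_input_volume`-µl reaction, and otherwise the sample is NEG.
#'
#' @param n_samples Number of follow-up samples.
#' @param class_mix Named proportions over true levels
#'   `high` (ratio 1–100%), `low` (0.01–1%), `trace` (0.0005–0.01%, i.e.
#'   between typical detection and quantification limits) and `zero`
#'   (no disease); must sum to 1.
#' @param qrtpcr_quant_limit Quantification limit of the comparator on the
#'   percent ratio scale (default 0.01, i.e. a 1e-4 fraction).
#' @param qrtpcr_detect_prob_per_copy Per-copy detection efficiency of the
#'   comparator below its quantification limit (default 1: any sampled copy
#'   amplifies).
#' @param qrtpcr_input_volume Comparator reaction volume, µl (default 20).
#' @param control_concentration_meanlog,control_concentration_sdlog
#'   Log-normal parameters for the control-gene concentration, copies/µl.
#' @param wells_per_sample ddPCR replicate wells per gene per sample
#'   (default 3, triplicate).
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_samples = 88,
                        class_mix = c(high = 0.12, low = 0.30,
                                      trace = 0.35, zero = 0.23),
                        qrtpcr_quant_limit = 0.01,
                        qrtpcr_detect_prob_per_copy = 1,
                        qrtpcr_input_volume = 20,
                        control_concentration_meanlog = log(200),
                        control_concentration_sdlog = 0.4,
                        wells_per_sample = 3,
                        seed = NULL) {
  if (n_samples < 0) stop("n_samples must be >= 0", call. = FALSE)
  lv <- c("high", "low", "trace", "zero")
  if (!setequal(names(class_mix), lv)) {
    stop("class_mix needs exactly the levels high, low, trace, zero", call. = FALSE)
  }
  if (any(class_mix < 0)) stop("class_mix proportions must be non-negative", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples), class_mix = class_mix[lv],
         qrtpcr_quant_limit = qrtpcr_quant_limit,
         qrtpcr_detect_prob_per_copy = qrtpcr_detect_prob_per_copy,
         qrtpcr_input_volume = qrtpcr_input_volume,
         control_concentration_meanlog = control_concentration_meanlog,
         control_concentration_sdlog = control_concentration_sdlog,
         wells_per_sample = as.integer(wells_per_sample),
         seed = seed),
    class = "cohort_spec"
  )
}

# true MRD ratio (percent) for one sample of a given level
draw_true_ratio <- function(level) {
  switch(level,
    high = 10^stats::runif(1, 0, 2),
    low = 10^stats::runif(1, -2, 0),
    trace = 10^stats::runif(1, log10(5e-4), -2),
    zero = 0
  )
}

#' Simulate a paired Q-RT-PCR / ddPCR follow-up cohort
#'
#' For each sample: a true MRD level is drawn from `class_mix`, the
#' control-gene concentration from its log-normal, and the target
#' concentration as `ratio/100 * control`. The comparator class follows the
#' threshold/detection model in [cohort_spec()]; ddPCR wells (target plus
#' control, `wells_per_sample` replicates each) come from the droplet
#' generator and are analysed downstream with [quantify_wells()].
#'
#' @param spec A [cohort_spec()].
#' @param config A [sim_config()].
#' @param seed Overrides `spec$seed`.
#' @return A list of class `"mrd_cohort"`: `samples` (per-sample truth and
#'   Q-RT-PCR class) and `wells` (droplet-well data frame for all samples).
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = sim_config(),
                            seed = spec$seed) {
  local_seed(seed, {
    n <- spec$n_samples
    samples <- data.frame(
      sample_id = sprintf("FU%03d", seq_len(n)),
      true_level = if (n) sample(names(spec$class_mix), n, replace = TRUE,
                                 prob = spec$class_mix) else character(0),
      stringsAsFactors = FALSE
    )
    samples$true_ratio <- vapply(samples$true_level, draw_true_ratio, 0)
    samples$control_concentration <- stats::rlnorm(
      n, spec$control_concentration_meanlog, spec$control_concentration_sdlog
    )
    samples$target_concentration <-
      samples$true_ratio / 100 * samples$control_concentration

    # comparator call
    copies_sampled <- samples$target_concentration * spec$qrtpcr_input_volume
    p_detect <- -expm1(-spec$qrtpcr_detect_prob_per_copy * copies_sampled)
    detected <- stats::runif(n) < p_detect
    samples$qrtpcr_class <- ifelse(
      samples$true_ratio >= spec$qrtpcr_quant_limit, "POS",
      ifelse(samples$true_ratio > 0 & detected, "PNQ", "NEG")
    )

    rows <- list()
    for (i in seq_len(n)) {
      for (gene in c("p190", "control_ABL1")) {
        conc <- if (gene == "control_ABL1") samples$control_concentration[i]
                else samples$target_concentration[i]
        p <- -expm1(-conc * config$droplet_volume)
        for (r in seq_len(spec$wells_per_sample)) {
          nk <- draw_well_counts(p, config)
          rows[[length(rows) + 1L]] <- data.frame(
            well_id = sprintf("%s_%s_R%d", samples$sample_id[i],
                              sub("control_", "", gene), r),
            sample_id = samples$sample_id[i],
            target = gene, role = "sample",
            replicate_group = sprintf("%s_%s", samples$sample_id[i], gene),
            n_accepted = nk[["n"]], k_positive = nk[["k"]]
          )
        }
      }
    }
    wells <- if (length(rows)) validate_wells(do.call(rbind, rows)) else
      validate_wells(data.frame(well_id = character(0),
                                sample_id = character(0),
                                target = character(0), role = character(0),
                                replicate_group = character(0),
                                n_accepted = integer(0),
                                k_positive = integer(0)))
    structure(list(samples = samples, wells = wells), class = "mrd_cohort")
  })
}
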