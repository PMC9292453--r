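#' Parameterised MRD interpretation rules
#'
#' Thresholds for assigning POS / PNQ / NEG calls to merged droplet counts,
#' in the spirit of the EuroMRD consensus interpretation of digital PCR MRD
#' results. All thresholds are exposed because laboratory guidelines evolve;
#' the defaults encode common digital-PCR practice: at least one positive
#' partition to call the target detected, at least three merged positive
#' partitions to call it quantifiable, and an optional floor on the
#' control-gene concentration below which a sample is not evaluable.
#'
#' @param min_positive_droplets_quantifiable Merged positive droplets needed
#'   for a quantifiable (POS) call (default 3).
#' @param min_positive_droplets_detected Merged positive droplets needed to
#'   call the target detected at all (default 1).
#' @param min_control_copies Floor on the control-gene concentration
#'   (copies/µl) for an evaluable sample (default 0 = no floor).
#' @param max_background_positive Positive droplets tolerated across all
#'   background wells (NTC, healthy donor, Ph-negative) for a valid run
#'   (default 0). A nonzero setting triggers a warning: classification
#'   thresholds assume a clean background and should be re-derived if
#'   background positivity is tolerated.
#'
#' @return A list of class `"classification_rules"`.
#' @export
classification_rules <- function(min_positive_droplets_quantifiable = 3,
                                 min_positive_droplets_detected = 1,
                                 min_control_copies = 0,
                                 max_background_positive = 0) {
  if (min_positive_droplets_detected > min_positive_droplets_quantifiable) {
    stop("detection threshold cannot exceed the quantifiability threshold",
         call. = FALSE)
  }
  if (min_positive_droplets_detected < 0 || min_control_copies < 0 ||
      max_background_positive < 0) {
    stop("rule thresholds must be non-negative", call. = FALSE)
  }
  if (max_background_positive > 0) {
    warning("max_background_positive > 0: classification thresholds assume ",
            "a clean background and should be re-derived", call. = FALSE)
  }
  structure(
    list(
      min_positive_droplets_quantifiable =
        as.integer(min_positive_droplets_quantifiable),
      min_positive_droplets_detected =
        as.integer(min_positive_droplets_detected),
      min_control_copies = min_control_copies,
      max_background_positive = as.integer(max_background_positive)
    ),
    class = "classification_rules"
  )
}

#' Read classification rules from a YAML file
#'
#' @param path YAML file holding any of the four [classification_rules()]
#'   keys; missing keys take their defaults.
#' @return A `"classification_rules"` object.
#' @export
read_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(classification_rules))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown rule keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(classification_rules, cfg)
}

#' Validate a run against its controls
#'
#' A run is valid when (i) the background wells — NTCs, healthy-donor pools
#' and Ph-negative controls — together show no more than
#' `max_background_positive` positive droplets, and (ii) every
#' plasmid-standard positive-control well shows at least one positive
#' droplet. Invalid runs must block downstream classification: background
#' positivity signals contamination, a blank plasmid standard signals
#' reaction failure.
#'
#' @param wells Droplet-well data frame for the run; must contain at least
#'   one NTC well.
#' @param rules A [classification_rules()] object.
#'
#' @return A list of class `"run_validation"` with `valid`,
#'   `ntc_positive_droplets`, `donor_positive_droplets`,
#'   `phneg_positive_droplets`, `plasmid_controls_positive` and `messages`.
#' @export
validate_run <- function(wells, rules = classification_rules()) {
  wells <- validate_wells(wells)
  if (!any(wells$role == "NTC")) {
    stop("run contains no NTC well: cannot validate", call. = FALSE)
  }
  msgs <- character(0)

  k_role <- function(role) {
    w <- wells[wells$role == role, , drop = FALSE]
    sum(w$k_positive)
  }
  ntc_k <- k_role("NTC")
  donor_k <- k_role("healthy_donor")
  phneg_k <- k_role("ph_negative_control")
  background_k <- ntc_k + donor_k + phneg_k

  if (background_k > rules$max_background_positive) {
    bad <- wells[wells$role %in% c("NTC", "healthy_donor", "ph_negative_control") &
                   wells$k_positive > 0, , drop = FALSE]
    msgs <- c(msgs, sprintf(
      "background positivity: %d positive droplet(s) in well(s) %s",
      background_k, paste(bad$well_id, collapse = ", ")
    ))
  }

  plasmid <- wells[wells$role == "plasmid_standard", , drop = FALSE]
  plasmid_ok <- nrow(plasmid) == 0 || all(plasmid$k_positive >= 1)
  if (!plasmid_ok) {
    blank <- plasmid$well_id[plasmid$k_positive == 0]
    msgs <- c(msgs, sprintf("positive control failed: plasmid well(s) %s negative",
                            paste(blank, collapse = ", ")))
  }

  structure(
    list(
      valid = background_k <= rules$max_background_positive && plasmid_ok,
      ntc_positive_droplets = ntc_k,
      donor_positive_droplets = donor_k,
      phneg_positive_droplets = phneg_k,
      plasmid_controls_positive = plasmid_ok,
      messages = msgs
    ),
    class = "run_validation"
  )
}

#' Classify a measurement as POS, PNQ or NEG
#'
#' Deterministic call from merged target droplet counts under
#' [classification_rules()]: NEG when fewer than
#' `min_positive_droplets_detected` merged target-positive droplets; PNQ when
#' the target is detected but has fewer than
#' `min_positive_droplets_quantifiable` positives, or when the control gene
#' falls below `min_control_copies`; POS otherwise. A sample whose control
#' gene is inadequate and whose target is undetected cannot be called
#' negative with confidence — it is returned as NEG with `evaluable = FALSE`,
#' a distinct not-evaluable annotation rather than a silent NEG.
#'
#' @param k_target Merged positive droplet count for the fusion transcript.
#' @param control_concentration Control-gene concentration in copies/µl.
#' @param control_ok Logical: control gene quantified adequately (finite,
#'   positive, QC-passed)?
#' @param rules A [classification_rules()] object.
#'
#' @return A list with `class` (`"POS"`, `"PNQ"` or `"NEG"`) and `evaluable`.
#' @export
classify_mrd <- function(k_target, control_concentration, control_ok = TRUE,
                         rules = classification_rules()) {
  stopifnot(length(k_target) == 1, k_target >= 0)
  detected <- k_target >= rules$min_positive_droplets_detected
  if (!control_ok || !is.finite(control_concentration)) {
    # control inadequate: a detected target still reports, an undetected one
    # is NEG-not-evaluable
    if (!detected) return(list(class = "NEG", evaluable = FALSE))
    # detected but no ratio can be formed: at best non-quantifiable
    return(list(class = "PNQ", evaluable = FALSE))
  }
  if (!detected) return(list(class = "NEG", evaluable = TRUE))
  if (k_target < rules$min_positive_droplets_quantifiable ||
      control_concentration < rules$min_control_copies) {
    return(list(class = "PNQ", evaluable = TRUE))
  }
  list(class = "POS", evaluable = TRUE)
}
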