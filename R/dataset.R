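#' Single-scan PET dataset
#'
#' Container for one dynamic scan: the frame schedule, regional TACs, the
#' metabolite-corrected tracer plasma input and whole-blood curve, the
#' measured tracer plasma free fraction, the injection time on the absolute
#' study clock, and the scan role.
#'
#' @param frames A [frame_schedule()] (times relative to this scan's
#'   injection).
#' @param tacs Named list of numeric vectors (one per region), each of length
#'   `nrow(frames)`, in Bq/cm^3.
#' @param plasma [sampled_curve()] of parent (metabolite-corrected) tracer
#'   plasma, absolute clock.
#' @param whole_blood [sampled_curve()] of whole-blood radioactivity,
#'   absolute clock.
#' @param fP Tracer plasma free fraction measured for this scan.
#' @param injection_time Injection time, absolute minutes.
#' @param role `"displacement"` or `"post-dose"`.
#' @param total_plasma,parent_fraction Optional uncorrected plasma and parent
#'   fraction curves (kept for provenance; `plasma` is what the model uses).
#' @return Object of class `scan_data`.
#' @export
scan_data <- function(frames, tacs, plasma, whole_blood, fP,
                      injection_time = 0,
                      role = c("displacement", "post-dose"),
                      total_plasma = NULL, parent_fraction = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(frames, "frame_schedule"),
            inherits(plasma, "sampled_curve"),
            inherits(whole_blood, "sampled_curve"),
            is.list(tacs), length(tacs) > 0, !is.null(names(tacs)))
  bad <- names(tacs)[vapply(tacs, length, 1L) != nrow(frames)]
  if (length(bad))
    stop("TAC length does not match the frame count for region(s): ",
         paste(bad, collapse = ", "))
  if (!is.numeric(fP) || fP <= 0 || fP > 1)
    stop("fP must lie in (0, 1]")
  structure(list(frames = frames, tacs = tacs, plasma = plasma,
                 whole_blood = whole_blood, fP = fP,
                 injection_time = injection_time, role = role,
                 total_plasma = total_plasma,
                 parent_fraction = parent_fraction),
            class = "scan_data")
}

#' Paired displacement + post-dose subject dataset
#'
#' Combines the two scans of one subject with the drug plasma samples and
#' dose metadata on a single absolute study clock (displacement injection at
#' t = 0).
#'
#' @param disp,post [scan_data()] objects (roles `"displacement"` and
#'   `"post-dose"`).
#' @param drug_input [sampled_curve()] of drug plasma concentration (nmol/L),
#'   absolute clock.
#' @param dose List with elements `drug` ("LEV"/"BRV"), `dose_mg`,
#'   `infusion_start` and `infusion_duration` (minutes, absolute clock).
#' @param constants [fixed_constants()] for the drug.
#' @param truth Optional [kinetic_parameters()] (or named list of them, one
#'   per region) recording the generating ground truth of a synthetic
#'   dataset.
#' @param id Subject identifier.
#' @return Object of class `subject_dataset`.
#' @export
subject_dataset <- function(disp, post, drug_input, dose, constants,
                            truth = NULL, id = "subject") {
  stopifnot(inherits(disp, "scan_data"), inherits(post, "scan_data"),
            inherits(drug_input, "sampled_curve"),
            inherits(constants, "fixed_constants"))
  if (disp$role != "displacement" || post$role != "post-dose")
    stop("scan roles must be displacement (disp) and post-dose (post)")
  need <- c("drug", "dose_mg", "infusion_start", "infusion_duration")
  if (!all(need %in% names(dose)))
    stop("dose must contain: ", paste(need, collapse = ", "))
  if (!setequal(names(disp$tacs), names(post$tacs)))
    stop("the two scans must cover the same regions")
  structure(list(disp = disp, post = post, drug_input = drug_input,
                 dose = dose, constants = constants, truth = truth, id = id),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset '%s': %s %g mg, regions: %s\n", x$id,
              x$dose$drug, x$dose$dose_mg,
              paste(names(x$disp$tacs), collapse = ", ")))
  cat(sprintf("  scans at t = %g and %g min; infusion at %g min\n",
              x$disp$injection_time, x$post$injection_time,
              x$dose$infusion_start))
  invisible(x)
}

#' Timeline implied by a subject dataset
#'
#' @param dataset A [subject_dataset()].
#' @return A [study_timeline()].
#' @export
dataset_timeline <- function(dataset) {
  stopifnot(inherits(dataset, "subject_dataset"))
  fr <- dataset$disp$frames
  study_timeline(
    inj_disp = dataset$disp$injection_time,
    inj_post = dataset$post$injection_time,
    scan_duration = max(fr$start + fr$duration),
    infusion_start = dataset$dose$infusion_start,
    infusion_duration = dataset$dose$infusion_duration)
}
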