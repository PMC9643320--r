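#' Read / write a sampled curve as CSV
#'
#' One file per curve with columns `time_min`, `value`, `units`, `kind`
#' (times in minutes on the absolute study clock).
#'
#' @param curve A [sampled_curve()].
#' @param file CSV path.
#' @param zero_before Boundary policy for the read curve; `NULL` uses the
#'   kind's default (zero before the first sample for drug plasma).
#' @return `write_curve()`: `file` invisibly; `read_curve()`: a
#'   [sampled_curve()].
#' @export
write_curve <- function(curve, file) {
  stopifnot(inherits(curve, "sampled_curve"))
  write_curve_csv(curve, file)
  invisible(file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file, zero_before = NULL) {
  read_curve_csv(file, zero_before = zero_before)
}

write_curve_csv <- function(curve, file) {
  write.csv(data.frame(time_min = curve$times, value = curve$values,
                       units = curve$units, kind = curve$kind),
            file, row.names = FALSE)
}

read_curve_csv <- function(file, zero_before = NULL) {
  if (!file.exists(file)) stop("missing curve file: ", file)
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_min", "value", "units", "kind")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("curve file ", basename(file), " lacks column(s): ",
         paste(miss, collapse = ", "))
  kind <- d$kind[1L]
  if (is.null(zero_before)) zero_before <- kind == "drug-plasma"
  sampled_curve(d$time_min, d$value, kind = kind, units = d$units[1L],
                zero_before = zero_before)
}

#' Write / read a subject dataset directory
#'
#' Serializes a [subject_dataset()] to a fixed plain-CSV/JSON layout:
#' `dose.json`, `constants.json`, `drug_plasma.csv`, optional `truth.json`,
#' and per scan (`scan_displacement/`, `scan_postdose/`) `scan.json`,
#' `frames.csv` (start_min, duration_min), one `tac_<region>.csv` per region
#' and one CSV per curve (time_min, value, units, kind). All times are
#' minutes on the absolute study clock (displacement injection at t = 0).
#' `read_dataset()` validates the layout and reports the specific missing
#' file or malformed column.
#'
#' @param dataset A [subject_dataset()].
#' @param dir Dataset directory.
#' @return `write_dataset()`: `dir` invisibly. `read_dataset()`: a
#'   [subject_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(dataset$dose, file.path(dir, "dose.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(unclass(dataset$constants), id = dataset$id),
                       file.path(dir, "constants.json"),
                       auto_unbox = TRUE, digits = NA)
  write_curve_csv(dataset$drug_input, file.path(dir, "drug_plasma.csv"))
  if (!is.null(dataset$truth)) {
    tr <- lapply(dataset$truth, function(p)
      c(p[c("K1_disp", "K1_post", "VT", "fND", "K1D", "fP_disp", "fP_post")],
        drug = p$constants$drug))
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (scan in c("disp", "post")) {
    sd <- dataset[[scan]]
    sdir <- file.path(dir, if (scan == "disp") "scan_displacement"
                           else "scan_postdose")
    dir.create(sdir, showWarnings = FALSE)
    jsonlite::write_json(list(injection_time = sd$injection_time,
                              fP = sd$fP, role = sd$role),
                         file.path(sdir, "scan.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(start_min = sd$frames$start,
                         duration_min = sd$frames$duration),
              file.path(sdir, "frames.csv"), row.names = FALSE)
    for (rg in names(sd$tacs))
      write.csv(data.frame(start_min = sd$frames$start,
                           duration_min = sd$frames$duration,
                           value = as.numeric(sd$tacs[[rg]]),
                           units = "Bq/cm3"),
                file.path(sdir, paste0("tac_", rg, ".csv")),
                row.names = FALSE)
    write_curve_csv(sd$plasma, file.path(sdir, "plasma.csv"))
    write_curve_csv(sd$whole_blood, file.path(sdir, "whole_blood.csv"))
    if (!is.null(sd$total_plasma))
      write_curve_csv(sd$total_plasma, file.path(sdir, "total_plasma.csv"))
    if (!is.null(sd$parent_fraction))
      write_curve_csv(sd$parent_fraction,
                      file.path(sdir, "parent_fraction.csv"))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  need_file <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing dataset file: ", p)
    p
  }
  dose <- jsonlite::read_json(need_file("dose.json"), simplifyVector = TRUE)
  cst <- jsonlite::read_json(need_file("constants.json"),
                             simplifyVector = TRUE)
  constants <- fixed_constants(cst$drug, KD = cst$KD, koff = cst$koff,
                               vB = cst$vB, fPD = cst$fPD, KDD = cst$KDD,
                               fNDD = cst$fNDD, koffD = cst$koffD)
  drug_input <- read_curve_csv(need_file("drug_plasma.csv"))

  read_scan <- function(sub, role) {
    sdir <- file.path(dir, sub)
    if (!dir.exists(sdir)) stop("missing scan directory: ", sdir)
    meta <- jsonlite::read_json(need_file(file.path(sub, "scan.json")),
                                simplifyVector = TRUE)
    fr <- read.csv(need_file(file.path(sub, "frames.csv")))
    if (!all(c("start_min", "duration_min") %in% names(fr)))
      stop("frames.csv in ", sub, " must have columns start_min, duration_min")
    frames <- frame_schedule(fr$start_min, fr$duration_min)
    tac_files <- list.files(sdir, pattern = "^tac_.*\\.csv$")
    if (!length(tac_files)) stop("no tac_<region>.csv files in ", sdir)
    tacs <- list()
    for (f in tac_files) {
      d <- read.csv(file.path(sdir, f))
      if (!"value" %in% names(d))
        stop("TAC file ", f, " lacks a 'value' column")
      if (nrow(d) != nrow(frames))
        stop("TAC file ", f, " has ", nrow(d), " rows for ",
             nrow(frames), " frames")
      tacs[[sub("^tac_(.*)\\.csv$", "\\1", f)]] <- d$value
    }
    pf_f <- file.path(sdir, "parent_fraction.csv")
    tp_f <- file.path(sdir, "total_plasma.csv")
    scan_data(frames, tacs,
              plasma = read_curve_csv(need_file(file.path(sub, "plasma.csv")),
                                      zero_before = TRUE),
              whole_blood = read_curve_csv(
                need_file(file.path(sub, "whole_blood.csv")),
                zero_before = TRUE),
              fP = meta$fP, injection_time = meta$injection_time,
              role = role,
              total_plasma = if (file.exists(tp_f))
                read_curve_csv(tp_f, zero_before = TRUE),
              parent_fraction = if (file.exists(pf_f)) read_curve_csv(pf_f))
  }

  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- lapply(tr, function(p)
      kinetic_parameters(p$K1_disp, p$K1_post, p$VT, p$fND, p$K1D,
                         p$fP_disp, p$fP_post, constants = constants))
  }
  subject_dataset(read_scan("scan_displacement", "displacement"),
                  read_scan("scan_postdose", "post-dose"),
                  drug_input, as.list(dose), constants, truth = truth,
                  id = if (!is.null(cst$id)) cst$id else basename(dir))
}

#' Tabulate fit results and write them with a diagnostics sidecar
#'
#' @param fits A list of [fit_joint()] results.
#' @return `fit_results_table()`: one row per fit x parameter with estimate
#'   (in reported units: `K1D` in uL/cm^3/min), rSE, SS, n and convergence.
#' @export
fit_results_table <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    est <- f$estimates
    rep_units <- ifelse(names(est) == "K1D", 1000, 1)
    data.frame(dataset = f$dataset_id, drug = f$fixed$drug,
               region = f$region, config = f$config$id,
               param = names(est), estimate = unname(est * rep_units),
               rse_pct = unname(f$rse), SS = f$SS, n = f$n,
               converged = f$converged, row.names = NULL)
  }))
}

#' @rdname fit_results_table
#' @param dir Output directory (`estimates.csv` + `diagnostics.json`).
#' @export
write_results <- function(fits, dir) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(fit_results_table(fits), file.path(dir, "estimates.csv"),
            row.names = FALSE)
  diag <- lapply(fits, function(f)
    list(dataset = f$dataset_id, region = f$region, config = f$config$id,
         SS = f$SS, n = f$n, converged = f$converged, info = f$info,
         message = f$message, at_bound = as.list(setNames(
           as.logical(f$at_bound), names(f$estimates))),
         singular_se = f$singular))
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
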