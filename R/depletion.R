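#' Percent peptide depletion from raw signals
#'
#' Core signal model of the assay. A well's raw signal (absorbance at 405 nm
#' for the thiol probe, fluorescence Ex 485 / Em 528 for the amine probe) is
#' normalised against three reference controls measured in the same run:
#' `a` (peptide + solvent + probe: the maximum signal), `b` (peptide +
#' solvent, no probe: the blank) and `c` (peptide + test chemical, no probe:
#' the chemical's optical interference). Depletion is
#' \deqn{\left[1 - \frac{reading - C}{A - B}\right] \times 100}
#' returned unclamped, so values below 0 or above 100 are preserved for audit.
#'
#' @param reading mean raw signal of the test-chemical (or control) wells.
#' @param a,b,c mean raw signals of reference controls A, B and C.
#' @return signed percent depletion (vectorised over `reading` and `c`).
#' @examples
#' percent_depletion(1.2, a = 2.0, b = 0.2, c = 0.3)  # 50
#' @export
percent_depletion <- function(reading, a, b, c) {
  vals <- c(reading, a, b, c)
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    stop("signals must be finite numbers", call. = FALSE)
  }
  if (any(a <= b)) {
    stop("invalid run: reference A must exceed reference B ",
         "(zero or negative dynamic range)", call. = FALSE)
  }
  (1 - (reading - c) / (a - b)) * 100
}

#' Clamp a signed depletion value to the reportable 0--100 range
#'
#' Negative depletion is reported as 0% and depletion above the maximum as
#' 100%.
#'
#' @param raw signed percent depletion.
#' @return value in \[0, 100\].
#' @export
clamp_depletion <- function(raw) {
  if (!is.numeric(raw) || !all(is.finite(raw))) {
    stop("depletion must be finite", call. = FALSE)
  }
  pmin(100, pmax(0, raw))
}

#' Construct a plate run
#'
#' Container for one experimental run of one peptide assay: raw signals for
#' reference controls A and B, the negative and positive control chemicals
#' (with their own interference controls), and each test chemical's wells
#' paired with its interference control C. Replicate wells are kept as raw
#' vectors; [run_depletion()] averages them.
#'
#' @param peptide `"cysteine"` or `"lysine"`.
#' @param ref_a,ref_b numeric vectors of replicate signals for controls A, B.
#' @param nc,pc replicate signals for the negative / positive control wells.
#' @param tc named list of numeric vectors, one per test substance.
#' @param ref_c named list of interference-control signals; names must cover
#'   `names(tc)`.
#' @param nc_ref_c,pc_ref_c interference controls for NC / PC wells; default
#'   to the blank B (a non-interfering control is indistinguishable from it).
#' @param signal_kind label for the readout, kept as metadata.
#' @return an object of class `plate_run`.
#' @export
plate_run <- function(peptide = c("cysteine", "lysine"),
                      ref_a, ref_b, nc, pc, tc, ref_c,
                      nc_ref_c = ref_b, pc_ref_c = ref_b,
                      signal_kind = if (peptide == "cysteine")
                        "absorbance_405nm" else "fluorescence_485_528") {
  peptide <- match.arg(peptide)
  stopifnot(is.list(tc), is.list(ref_c))
  if (length(ref_a) == 0L || length(ref_b) == 0L) {
    stop("reference controls A and B must be non-empty", call. = FALSE)
  }
  if (is.null(names(tc)) || any(!nzchar(names(tc)))) {
    stop("test-chemical wells must be named by substance", call. = FALSE)
  }
  orphans <- setdiff(names(tc), names(ref_c))
  if (length(orphans)) {
    stop("missing reference control C for substance: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  sig <- c(ref_a, ref_b, nc, pc, unlist(tc), unlist(ref_c))
  if (!all(is.finite(sig)) || any(sig < 0)) {
    stop("all signals must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(peptide = peptide, signal_kind = signal_kind,
         ref_a = ref_a, ref_b = ref_b, nc = nc, pc = pc,
         tc = tc, ref_c = ref_c,
         nc_ref_c = nc_ref_c, pc_ref_c = pc_ref_c),
    class = "plate_run"
  )
}

#' Compute per-substance depletion for one plate run
#'
#' Replicate wells are averaged within the run for every role, then each
#' substance's depletion is computed with its own interference control C.
#' Run quality is checked on the control chemicals: the run is flagged
#' invalid when the clamped negative-control depletion exceeds `nc_max_pct`
#' or the positive-control depletion falls below `pc_min_pct`. No published
#' acceptance band exists for these controls, so both bounds are explicit,
#' configurable arguments.
#'
#' @param run a [plate_run()].
#' @param nc_max_pct maximum tolerated clamped NC depletion (default 10).
#' @param pc_min_pct minimum required PC depletion (default 50).
#' @return tibble with columns `substance`, `raw_pct`, `clamped_pct`; the
#'   run-level QC summary (`nc_pct`, `pc_pct`, `valid`) is attached as
#'   attribute `"qc"`.
#' @export
run_depletion <- function(run, nc_max_pct = 10, pc_min_pct = 50) {
  stopifnot(inherits(run, "plate_run"))
  a <- mean(run$ref_a)
  b <- mean(run$ref_b)
  raw <- vapply(names(run$tc), function(id) {
    percent_depletion(mean(run$tc[[id]]), a, b, mean(run$ref_c[[id]]))
  }, numeric(1))
  nc_pct <- percent_depletion(mean(run$nc), a, b, mean(run$nc_ref_c))
  pc_pct <- percent_depletion(mean(run$pc), a, b, mean(run$pc_ref_c))
  valid <- clamp_depletion(nc_pct) <= nc_max_pct && pc_pct >= pc_min_pct
  out <- tibble::tibble(
    substance = names(run$tc),
    raw_pct = unname(raw),
    clamped_pct = clamp_depletion(unname(raw))
  )
  attr(out, "qc") <- list(nc_pct = nc_pct, pc_pct = pc_pct, valid = valid)
  out
}

#' Aggregate per-run depletion values across independent experiments
#'
#' Reported depletion is the arithmetic mean of at least `n_min` independent
#' runs. Signed per-run values are averaged first and the mean is clamped
#' once afterwards; the signed mean is retained for audit. Per-run clamping
#' before averaging is available via `clamp_per_run` for sensitivity
#' analysis.
#'
#' @param per_run_values signed percent depletion, one value per run.
#' @param n_min minimum number of independent runs (default 3).
#' @param clamp_per_run clamp each run's value before averaging.
#' @return list with `raw` (signed mean), `clamped`, and `n`.
#' @export
aggregate_runs <- function(per_run_values, n_min = 3, clamp_per_run = FALSE) {
  if (length(per_run_values) < n_min) {
    stop("insufficient replication: ", length(per_run_values), " run(s), ",
         n_min, " required", call. = FALSE)
  }
  if (clamp_per_run) per_run_values <- clamp_depletion(per_run_values)
  m <- mean(per_run_values)
  list(raw = m, clamped = clamp_depletion(m), n = length(per_run_values))
}

#' Assemble a depletion profile for one chemical
#'
#' Combines cross-run cysteine (and optionally lysine) depletion into the
#' profile used by the prediction models: clamped per-peptide percentages and
#' their unweighted arithmetic mean, with the unclamped signed values
#' retained.
#'
#' @param raw_cys_pct signed cysteine percent depletion (after run
#'   aggregation).
#' @param raw_lys_pct optional signed lysine percent depletion.
#' @return list of class `depletion_profile` with elements `cys_pct`,
#'   `lys_pct`, `mean_pct`, `raw_cys_pct`, `raw_lys_pct`.
#' @export
depletion_profile <- function(raw_cys_pct, raw_lys_pct = NULL) {
  cys <- clamp_depletion(raw_cys_pct)
  lys <- if (is.null(raw_lys_pct)) NULL else clamp_depletion(raw_lys_pct)
  structure(
    list(cys_pct = cys, lys_pct = lys,
         mean_pct = if (is.null(lys)) NULL else (cys + lys) / 2,
         raw_cys_pct = raw_cys_pct,
         raw_lys_pct = raw_lys_pct),
    class = "depletion_profile"
  )
}

#' Read raw plate runs from CSV
#'
#' Schema: `run_id,peptide,role,substance_id,replicate,signal` with role in
#' A, B, C, NC, PC, TC; C rows carry the substance they control for (the
#' special ids `NC` and `PC` attach interference controls to the control
#' chemicals). One [plate_run()] is built per `run_id` and peptide.
#'
#' @param path CSV path.
#' @return named list of `plate_run` objects (`<run_id>.<peptide>`).
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("run_id", "peptide", "role", "substance_id", "replicate",
                "signal")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(df[, c("run_id", "peptide")])
  runs <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$run_id == keys$run_id[i] & df$peptide == keys$peptide[i], ]
    grab <- function(role) sub$signal[sub$role == role]
    tc_rows <- sub[sub$role == "TC", ]
    c_rows <- sub[sub$role == "C", ]
    tc <- split(tc_rows$signal, tc_rows$substance_id)
    cc <- split(c_rows$signal, c_rows$substance_id)
    plate_run(
      peptide = keys$peptide[i],
      ref_a = grab("A"), ref_b = grab("B"),
      nc = grab("NC"), pc = grab("PC"),
      tc = tc,
      ref_c = cc[setdiff(names(cc), c("NC", "PC"))],
      nc_ref_c = if ("NC" %in% names(cc)) cc$NC else grab("B"),
      pc_ref_c = if ("PC" %in% names(cc)) cc$PC else grab("B")
    )
  })
  names(runs) <- paste(keys$run_id, keys$peptide, sep = ".")
  runs
}

#' Write plate runs to CSV
#'
#' Inverse of [read_plate_csv()]; used by the simulator to emit text plates.
#'
#' @param runs named list of [plate_run()] objects (`<run_id>.<peptide>`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(runs, path) {
  rows <- lapply(names(runs), function(key) {
    run <- runs[[key]]
    run_id <- sub("\\.[a-z]+$", "", key)
    role_rows <- function(role, sig, substance = "") {
      data.frame(run_id = run_id, peptide = run$peptide, role = role,
                 substance_id = substance, replicate = seq_along(sig),
                 signal = sig)
    }
    do.call(rbind, c(
      list(role_rows("A", run$ref_a), role_rows("B", run$ref_b),
           role_rows("NC", run$nc), role_rows("PC", run$pc),
           role_rows("C", run$nc_ref_c, "NC"),
           role_rows("C", run$pc_ref_c, "PC")),
      lapply(names(run$tc), function(id) role_rows("TC", run$tc[[id]], id)),
      lapply(names(run$ref_c), function(id) role_rows("C", run$ref_c[[id]], id))
    ))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
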