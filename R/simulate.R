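#' Simulate raw plate runs from known depletion targets
#'
#' Inverts the depletion equation to emit raw well signals: for a chemical
#' with true depletion d, the test-chemical well reads
#' C + (1 - d/100) * (A - B) plus Gaussian instrument noise on the signal
#' scale (the plate reader measures absorbance or fluorescence, not
#' depletion; depletion-scale noise follows by propagation). Control wells
#' are noised the same way. With `noise_sd = 0`, [run_depletion()] recovers
#' each target exactly, which is the round-trip invariant the simulator
#' exists to provide.
#'
#' @param targets named numeric vector of true percent depletion in
#'   \[0, 100\], one per substance.
#' @param a_signal,b_signal baseline magnitudes of reference controls A and B
#'   (defaults mimic an absorbance readout spanning 0.2--2.0 AU).
#' @param c_signal_range interval from which each substance's interference
#'   control C is drawn uniformly.
#' @param nc_target,pc_target true depletion of the negative / positive
#'   control chemical.
#' @param noise_sd standard deviation of the signal-scale Gaussian noise.
#' @param n_replicates wells per chemical within a run (default 2).
#' @param n_runs independent runs (default 3).
#' @param peptide assay peptide label.
#' @param seed integer seed; identical seeds give identical runs.
#' @return named list of [plate_run()] objects (`run<i>.<peptide>`).
#' @export
simulate_plate <- function(targets,
                           a_signal = 2.0, b_signal = 0.2,
                           c_signal_range = c(0.25, 0.45),
                           nc_target = 2, pc_target = 85,
                           noise_sd = 0, n_replicates = 2, n_runs = 3,
                           peptide = c("cysteine", "lysine"),
                           seed = NULL) {
  peptide <- match.arg(peptide)
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("targets must be named by substance", call. = FALSE)
  }
  if (any(targets < 0 | targets > 100)) {
    stop("targets must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(a_signal > b_signal, noise_sd >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  span <- a_signal - b_signal
  noisy <- function(mu) pmax(0, mu + stats::rnorm(n_replicates, 0, noise_sd))
  runs <- lapply(seq_len(n_runs), function(i) {
    c_mu <- stats::runif(length(targets), c_signal_range[1], c_signal_range[2])
    names(c_mu) <- names(targets)
    nc_c <- stats::runif(1, c_signal_range[1], c_signal_range[2])
    pc_c <- stats::runif(1, c_signal_range[1], c_signal_range[2])
    plate_run(
      peptide = peptide,
      ref_a = noisy(a_signal), ref_b = noisy(b_signal),
      nc = noisy(nc_c + (1 - nc_target / 100) * span),
      pc = noisy(pc_c + (1 - pc_target / 100) * span),
      tc = stats::setNames(lapply(names(targets), function(id)
        noisy(c_mu[[id]] + (1 - targets[[id]] / 100) * span)),
        names(targets)),
      ref_c = lapply(c_mu, noisy),
      nc_ref_c = noisy(nc_c), pc_ref_c = noisy(pc_c)
    )
  })
  names(runs) <- paste0("run", seq_len(n_runs), ".", peptide)
  runs
}

#' Simulate a labeled class-conditional depletion population
#'
#' Draws depletion scores for sensitizers and non-sensitizers from Gaussian
#' class-conditional distributions truncated to \[0, 100\] (truncation, not
#' rejection, mirroring the assay's clamping semantics). The defaults --
#' sensitizers N(60, 15), non-sensitizers N(5, 5) -- emulate a strongly but
#' imperfectly separated reactive/unreactive mixture for threshold-recovery
#' testing.
#'
#' @param n_sensitizers,n_nonsensitizers class sizes (>= 1).
#' @param sens_mean,sens_sd,non_mean,non_sd Gaussian parameters on the
#'   percent-depletion scale.
#' @param seed integer seed.
#' @return tibble with columns `id`, `label`, `depletion`.
#' @seealso [normal_optimal_threshold()] for the analytic Youden optimum of
#'   the untruncated model.
#' @export
simulate_population <- function(n_sensitizers = 200, n_nonsensitizers = 200,
                                sens_mean = 60, sens_sd = 15,
                                non_mean = 5, non_sd = 5,
                                seed = NULL) {
  stopifnot(n_sensitizers >= 1, n_nonsensitizers >= 1,
            sens_sd >= 0, non_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, m, s) clamp_depletion(stats::rnorm(n, m, s))
  tibble::tibble(
    id = seq_len(n_sensitizers + n_nonsensitizers),
    label = rep(hazard_levels, c(n_sensitizers, n_nonsensitizers)),
    depletion = c(draw(n_sensitizers, sens_mean, sens_sd),
                  draw(n_nonsensitizers, non_mean, non_sd))
  )
}

#' Analytic Youden-optimal threshold for two Gaussian classes
#'
#' Youden's J = TPR(t) - FPR(t) is stationary where the two class densities
#' are equal, so the population optimum is the density crossing between the
#' class means: the root of a quadratic for unequal variances, the midpoint
#' weighted by variances in closed form. Used as the independent oracle for
#' threshold-recovery tests on simulated populations.
#'
#' @param non_mean,non_sd non-sensitizer distribution parameters.
#' @param sens_mean,sens_sd sensitizer distribution parameters.
#' @return the crossing point between the two means.
#' @export
normal_optimal_threshold <- function(non_mean, non_sd, sens_mean, sens_sd) {
  stopifnot(sens_mean > non_mean)
  if (isTRUE(all.equal(non_sd, sens_sd))) {
    return((non_mean + sens_mean) / 2)
  }
  # f0(t) = f1(t)  =>  quadratic in t
  a <- 1 / sens_sd^2 - 1 / non_sd^2
  b <- 2 * (non_mean / non_sd^2 - sens_mean / sens_sd^2)
  cc <- sens_mean^2 / sens_sd^2 - non_mean^2 / non_sd^2 +
    2 * log(sens_sd / non_sd)
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  inside <- roots[roots > non_mean & roots < sens_mean]
  if (length(inside) != 1L) stop("no unique crossing between the means")
  inside
}
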