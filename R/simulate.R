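#' Scan protocol: count budget, contamination fractions, repeats
#'
#' Study conditions for the synthetic acquisitions: an expected
#' true-coincidence budget of 100,000 counts with uniform randoms and
#' scatter contamination fields of 60\% and 20\% of the trues, and 50
#' Monte-Carlo realizations.
#'
#' @param total_counts Expected total true-coincidence counts (default 1e5).
#' @param random_fraction Uniform randoms as a fraction of the trues
#'   (default 0.60).
#' @param scatter_fraction Uniform scatter as a fraction of the trues
#'   (default 0.20).
#' @param n_realizations Number of Monte-Carlo realizations (default 50).
#' @param seed Integer base RNG seed (default 0).
#' @return A `scan_protocol`.
#' @export
scan_protocol <- function(total_counts = 1e5, random_fraction = 0.60,
                          scatter_fraction = 0.20, n_realizations = 50L,
                          seed = 0L) {
  if (total_counts <= 0) stop("total_counts must be positive")
  if (random_fraction < 0 || random_fraction > 1)
    stop("random_fraction must be in [0, 1]")
  if (scatter_fraction < 0 || scatter_fraction > 1)
    stop("scatter_fraction must be in [0, 1]")
  structure(list(total_counts = total_counts,
                 random_fraction = random_fraction,
                 scatter_fraction = scatter_fraction,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "scan_protocol")
}

# derived RNG seed for one realization; kept well below 2^31
realization_seed <- function(seed, realization) {
  (as.integer(seed) %% 100000L) * 20011L + as.integer(realization) * 7919L
}

#' Simulate one prompt/delayed acquisition
#'
#' The true mean is `t = s * D x` with the scale `s` chosen so that
#' `sum(t) = total_counts`; the randoms and scatter means are uniform fields
#' summing to `random_fraction * sum(t)` and `scatter_fraction * sum(t)`.
#' The prompt window collects `Poisson(t + r + c)` and the delayed window
#' (the randoms estimate) collects `Poisson(r)`.  Deterministic given
#' `(proto$seed, realization)`.
#'
#' @param x True activity ([activity_image()] or vector).
#' @param D A `system_matrix` (the exact projector used as the physics).
#' @param proto A [scan_protocol()].
#' @param realization 0-based realization index (`< n_realizations`).
#' @return List with `prompt` and `delayed` [sinogram()]s plus `scale` (the
#'   activity-to-counts factor `s`), `trues_mean`, `randoms_mean`,
#'   `scatter_mean`.
#' @export
simulate_scan <- function(x, D, proto, realization = 0L) {
  stopifnot(inherits(proto, "scan_protocol"))
  geom <- if (inherits(D, "system_matrix")) D$geometry else NULL
  proj <- forward_project(D, x)
  tot <- sum(proj)
  if (tot <= 0) stop("D %*% x is identically zero; cannot scale to counts")
  if (realization < 0 || realization >= proto$n_realizations)
    stop("realization index out of range")
  s <- proto$total_counts / tot
  trues <- s * proj
  m <- length(trues)
  randoms <- rep(proto$random_fraction * proto$total_counts / m, m)
  scatter <- rep(proto$scatter_fraction * proto$total_counts / m, m)
  set.seed(realization_seed(proto$seed, realization))
  prompt <- stats::rpois(m, trues + randoms + scatter)
  delayed <- stats::rpois(m, randoms)
  list(prompt = sinogram(prompt, geom, "prompt"),
       delayed = sinogram(delayed, geom, "delayed"),
       scale = s, trues_mean = trues, randoms_mean = randoms,
       scatter_mean = scatter)
}

#' Correct a prompt sinogram for randoms and scatter
#'
#' Subtracts the delayed-window counts (the randoms estimate) and the known
#' uniform scatter mean from the prompt counts:
#' `y = prompt - delayed - scatter_mean`.  The result may contain negative
#' bins; they are retained for the least-squares reconstructors (MLEM clips
#' its input to zero itself).
#'
#' The corrected sinogram carries the plug-in variance estimate
#' `max(prompt + delayed, 1)`: the variance of the difference of the two
#' independent Poisson windows.  (Weighting by `1 / max(y, 1)` instead would
#' overweight near-zero corrected bins -- whose true variance is dominated
#' by the subtracted contamination -- by an order of magnitude, which
#' destabilizes every weighted least-squares reconstruction at realistic
#' randoms fractions.)
#'
#' @param prompt Prompt [sinogram()].
#' @param delayed Delayed [sinogram()].
#' @param proto The [scan_protocol()] (supplies the known scatter mean).
#' @return A corrected [sinogram()].
#' @export
correct_sinogram <- function(prompt, delayed, proto) {
  stopifnot(inherits(prompt, "sinogram"), inherits(delayed, "sinogram"),
            inherits(proto, "scan_protocol"))
  if (prompt$kind != "prompt" || delayed$kind != "delayed")
    stop("kind mismatch: need a prompt and a delayed sinogram")
  if (!identical(unclass(prompt$geometry), unclass(delayed$geometry)))
    stop("geometry mismatch")
  m <- prompt$geometry$m
  scatter <- proto$scatter_fraction * proto$total_counts / m
  sinogram(prompt$values - delayed$values - scatter, prompt$geometry,
           "corrected",
           variance = pmax(prompt$values + delayed$values, 1))
}
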