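#' End-to-end T1/endothelial analysis of one simulated animal
#'
#' Convenience wrapper chaining the full endothelial-function pipeline on
#' synthetic data for a single animal: phantom construction, noisy
#' multi-angle baseline series, noisy dynamic post-injection series with
#' the group-dependent T1 response, baseline VFA map fit, and the
#' myocardial percent T1-change course.
#'
#' @param resp a [group_response_spec()]; defaults to the control
#'   phenotype.
#' @param snr image signal-to-noise ratio (default 30).
#' @param seed integer seed for this animal.
#' @param spec a [phantom_spec()].
#' @param protocol an [spgr_protocol()].
#' @return A [delta_t1_course()] object with the generator `truth`
#'   data.frame attached as attribute `"truth"`.
#' @export
simulate_endothelial_animal <- function(resp = group_response_spec("control"),
                                        snr = 30, seed = 1L,
                                        spec = phantom_spec(),
                                        protocol = spgr_protocol()) {
  ph <- make_phantom(spec, seed = seed)
  pre <- simulate_vfa_series(ph, protocol, snr = snr, seed = seed)
  dyn <- simulate_lname_response(ph, protocol, resp, snr = snr, seed = seed)
  pre_map <- fit_t1_map(pre)
  course <- delta_t1_course(pre_map, dyn$series)
  attr(course, "truth") <- dyn$truth
  course
}

#' Simulated endothelial-function cohort
#'
#' Runs [simulate_endothelial_animal()] for `n` animals with seeds
#' `base_seed + 1..n` and aggregates the recovered percent T1-change
#' courses.
#'
#' @param n number of animals.
#' @param resp a [group_response_spec()].
#' @param snr image signal-to-noise ratio.
#' @param base_seed integer; animal i uses seed `base_seed + i`.
#' @inheritParams simulate_endothelial_animal
#' @return List with `courses` (per animal), `times_min`, `delta_mat`
#'   (animals x time points), `mean_course` (cohort mean percent change),
#'   `cumulative` (per-animal cumulative delta-T1, %·min).
#' @export
simulate_endothelial_cohort <- function(n = 6, resp = group_response_spec("control"),
                                        snr = 30, base_seed = 0L,
                                        spec = phantom_spec(),
                                        protocol = spgr_protocol()) {
  stop_if(!is_count(n) || n < 1, "'n' must be a positive integer")
  courses <- lapply(seq_len(n), function(i)
    simulate_endothelial_animal(resp, snr = snr, seed = base_seed + i,
                                spec = spec, protocol = protocol))
  delta_mat <- do.call(rbind, lapply(courses, `[[`, "delta_t1_pct"))
  list(courses = courses,
       times_min = courses[[1]]$times_min,
       delta_mat = delta_mat,
       mean_course = colMeans(delta_mat),
       cumulative = vapply(courses, cumulative_delta_t1, numeric(1)))
}
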