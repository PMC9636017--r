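#' Pipeline parameters
#'
#' All tunable parameters of the docking/rebuilding procedure, under their
#' conventional names. Values not overridden keep their defaults.
#'
#' @param ... name = value overrides of the defaults listed below.
#' @return A named list of class `dr_params`.
#' @details Defaults:
#' * `plddt_threshold` 70 — minimum (smoothed) confidence kept by trimming.
#' * `maximum_domains` 3 — upper bound on docked domains.
#' * `minimum_domain_length` 10 — minimum residues per domain; also the
#'   smoothing window for confidence/density profiles.
#' * `ssm_search_min_cc` 0.3 — if secondary-structure docking reaches this
#'   correlation, the correlation search is skipped.
#' * `minimum_docking_cc` 0.15 — placements below this are discarded and
#'   the scoring bonus block is gated on it.
#' * `acceptable_docking_cc` 0.5 — "lowest cc" bonus threshold.
#' * `allowed_fraction_overlapping` 0.1 — overlap bonus threshold.
#' * `overlap_ca_ca_distance` 3 A — CA-CA distance counting as overlap.
#' * `maximum_connectivity_deviation` 15 A — slack (plus twice the
#'   resolution) beyond the spannable distance before the -200 penalty.
#' * `match_distance_high` 5 A — paired-CA agreement bound in SSM.
#' * `ok_brute_force_cc` 0.25 — minimum cc for an SSM placement.
#' * `shift_field_distance` 10 A — morphing distance scale.
#' * `iterative_refine_start_resolution` 6 A, `iterative_refine_step` 1 A.
#' * `n_window` 6 — window size for windowed morphing.
#' * `ca_distance` 3.8 A — end-deviation bound for external fragments.
#' * `cc_sd_ratio` 3 — density-outlier threshold ratio.
#' * `mask_radius` 2.5 A — map-model correlation mask radius.
#' * `rotation_count` 300 — rotations sampled by the correlation search
#'   (quasi-uniform, roughly 24-degree spacing).
#' * `top_k_placements` 5 — placements per domain entering combination
#'   scoring.
#' * `domain_join_distance` 12 A — proximity clustering merge distance.
#' * `convergence_rmsd` 0.3 A — early-stop threshold between cycles.
#' @export
dr_params <- function(...) {
  p <- list(
    plddt_threshold = 70,
    maximum_domains = 3,
    minimum_domain_length = 10,
    ssm_search_min_cc = 0.3,
    minimum_docking_cc = 0.15,
    acceptable_docking_cc = 0.5,
    allowed_fraction_overlapping = 0.1,
    overlap_ca_ca_distance = 3,
    maximum_connectivity_deviation = 15,
    match_distance_high = 5,
    ok_brute_force_cc = 0.25,
    shift_field_distance = 10,
    iterative_refine_start_resolution = 6,
    iterative_refine_step = 1,
    n_window = 6,
    ca_distance = 3.8,
    cc_sd_ratio = 3,
    mask_radius = 2.5,
    rotation_count = 300,
    top_k_placements = 5,
    domain_join_distance = 12,
    convergence_rmsd = 0.3)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "dr_params")
}

#' Read a flat key=value parameter file
#' @param path text file of `name = value` lines (# comments allowed).
#' @return A `dr_params`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=")
  vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  do.call(dr_params, vals)
}
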