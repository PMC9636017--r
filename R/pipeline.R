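# The per-cycle dock-and-rebuild procedure and the iterative loop with a
# pluggable predictor. One cycle = trim/split -> dock domains -> morph the
# full model onto the docked domains -> refine -> rebuild poor segments ->
# assemble the best parts.

#' Run one dock-and-rebuild cycle
#'
#' Stages, in order: (1) confidence normalization, trimming and splitting
#' into compact domains; (2) per-domain docking (secondary-structure
#' matching first; when its best correlation stays below
#' `ssm_search_min_cc` the exhaustive correlation search runs), placement
#' expansion across domains/symmetry, and combination selection by the
#' empirical score; (3) shift-field morphing of the full model onto the
#' docked domains, followed by restrained real-space refinement; (4)
#' detection of poorly fitting segments and candidate generation by every
#' rebuilding strategy; (5) assembly of the best per-segment candidates
#' and final refinement.
#'
#' @param predicted_model `dr_model` with confidence in the B-value field.
#' @param map A `dr_map`.
#' @param resolution nominal map resolution, Angstrom.
#' @param params A [dr_params()].
#' @param external_model optional externally built `dr_model`.
#' @param symmetry_ops optional list of `dr_transform`.
#' @param reference optional `dr_model` for progress metrics only (never
#'   used in any computation that shapes the result).
#' @param seed RNG seed (default 0).
#' @return List of class `dr_cycle_result`: `docked_morphed_model`,
#'   `rebuilt_model`, `placement_combo`, `plan`, `metrics`, `log`.
#' @export
run_cycle <- function(predicted_model, map, resolution,
                      params = dr_params(), external_model = NULL,
                      symmetry_ops = NULL, reference = NULL, seed = 0) {
  log <- list(params = unclass(params), seed = seed, stages = character(0))
  note <- function(msg) log$stages <<- c(log$stages, msg)
  # stage 1: trim and split
  profile <- normalize_confidence(predicted_model$confidence)
  trimmed <- trim_low_confidence(predicted_model, profile,
                                 threshold = params$plddt_threshold,
                                 window = params$minimum_domain_length)
  note(sprintf("trim: kept %d/%d residues", model_nres(trimmed),
               model_nres(predicted_model)))
  dset <- split_into_domains(
    trimmed, maximum_domains = params$maximum_domains,
    minimum_domain_length = params$minimum_domain_length,
    join_distance = params$domain_join_distance)
  domains <- lapply(seq_along(dset$domains), function(i)
    domain_model(trimmed, dset, i))
  note(sprintf("split: %d domain(s) of %s residues", length(domains),
               paste(vapply(domains, model_nres, 0L), collapse = "/")))
  # stage 2: dock each domain
  map_sses <- detect_sse_from_map(map, resolution)
  note(sprintf("map SSEs: %d", length(map_sses)))
  placements <- vector("list", length(domains))
  for (i in seq_along(domains)) {
    id <- paste0("domain", i)
    pl <- dock_domain(domains[[i]], map, resolution, params, id, map_sses)
    note(sprintf("%s: %s dock (%d placements)", id,
                 attr(pl, "mode") %||% "no", length(pl)))
    placements[[i]] <- pl
  }
  placements <- expand_placements(placements, domains, map, resolution,
                                  symmetry_ops, params)
  combo <- select_placements(placements, domains, resolution, params)
  note(sprintf("combo: score %.2f, %d/%d placed", combo$score,
               sum(!vapply(combo$placements, is.null, TRUE)), length(domains)))
  if (all(vapply(combo$placements, is.null, TRUE))) {
    stop("docking failed: no domain could be placed (",
         attr(combo, "diagnostic") %||% "no acceptable placement", ")")
  }
  # stage 3: morph the full model onto the docked domains, then refine
  docked <- list()
  for (i in seq_along(domains)) {
    if (is.null(combo$placements[[i]])) next
    docked[[length(docked) + 1L]] <-
      model_transform(domains[[i]], combo$placements[[i]]$transform)
  }
  field <- build_field_from_docked(predicted_model, docked,
                                   distance = params$shift_field_distance)
  morphed <- morph_model(predicted_model, field)
  refined <- simple_real_space_refine(morphed, map, resolution,
                                      reference = morphed)
  cc_docked <- model_cc(refined, map, resolution, params)
  note(sprintf("morph+refine: cc %.3f", cc_docked))
  # stage 4: find poor segments, generate candidates
  plan <- identify_poor_segments(refined, map,
                                 window = params$minimum_domain_length,
                                 plddt_threshold = params$plddt_threshold,
                                 sd_ratio = params$cc_sd_ratio)
  candidates <- generate_candidates(refined, map, plan, resolution,
                                    external_model, params, seed = seed)
  note(sprintf("rebuild: %d candidate model(s) [%s]", length(candidates),
               paste(vapply(candidates, function(x) x$strategy, ""),
                     collapse = ", ")))
  # stage 5: assemble the best parts
  assembly <- assemble_best_segments(candidates, plan, map, resolution,
                                     params)
  rebuilt <- assembly$model
  cc_rebuilt <- model_cc(rebuilt, map, resolution, params)
  note(sprintf("assembled: cc %.3f", cc_rebuilt))
  metrics <- list(cc_docked_morphed = cc_docked, cc_rebuilt = cc_rebuilt)
  if (!is.null(reference)) {
    metrics$fraction_matched_input <-
      chain_comparison(reference, predicted_model)$fraction_matched
    metrics$fraction_matched_rebuilt <-
      chain_comparison(reference, rebuilt)$fraction_matched
  }
  structure(list(docked_morphed_model = refined, rebuilt_model = rebuilt,
                 placement_combo = combo, plan = plan,
                 choices = assembly$choices, metrics = metrics, log = log),
            class = "dr_cycle_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_cc <- function(model, map, resolution, params = dr_params()) {
  tryCatch(suppressWarnings(
    map_model_cc(map_crop(map, model_coords(model), 6), model, resolution,
                 params$mask_radius)$cc),
    error = function(e) NA_real_)
}

#' @export
print.dr_cycle_result <- function(x, ...) {
  cat("<dr_cycle_result>\n")
  for (s in x$log$stages) cat(" ", s, "\n")
  invisible(x)
}

#' Deterministic stand-in for a structure-prediction engine
#'
#' Satisfies the predictor contract (sequence + optional template model ->
#' predicted model with per-residue confidence) for testing the iterative
#' loop without any inference engine. With a template it returns the
#' template with seeded coordinate jitter (sigma 0.3 A per atom) and
#' confidence nudged toward 90; without a template it returns the
#' configured initial prediction.
#'
#' @param initial_prediction the `dr_model` to return on the first call
#'   (no template).
#' @param jitter_sd coordinate jitter, Angstrom (default 0.3).
#' @return A predictor `function(sequence, template = NULL, seed = 0)`.
#' @export
stub_predictor <- function(initial_prediction, jitter_sd = 0.3) {
  force(initial_prediction); force(jitter_sd)
  function(sequence, template = NULL, seed = 0) {
    if (is.null(template)) return(initial_prediction)
    if (!identical(paste(model_sequence(template), collapse = ""),
                   paste(sequence, collapse = "")))
      stop("template sequence does not match the requested sequence")
    with_seed(seed, {
      xyz <- model_coords(template)
      out <- model_set_coords(template,
                              xyz + matrix(stats::rnorm(length(xyz), 0,
                                                        jitter_sd),
                                           nrow(xyz), 3))
      out$confidence <- pmin(98, 0.5 * out$confidence + 0.5 * 90)
      out$atoms$b <- out$confidence[match(out$atoms$resno, model_resno(out))]
      out
    })
  }
}

#' Iterative prediction and rebuilding
#'
#' Cycle 1 feeds the predictor's template-free model to [run_cycle()];
#' later cycles re-predict with the previous cycle's rebuilt model as the
#' template and rebuild again. Iteration stops early when consecutive
#' rebuilt models agree within `convergence_rmsd`. Two labelled outputs
#' are kept: the last predictor output (the prediction informed by the
#' map) and the last rebuilt model (the overall final model).
#'
#' @param predictor function(sequence, template, seed) -> `dr_model`, e.g.
#'   from [stub_predictor()].
#' @param sequence character vector of one-letter residue codes.
#' @param map A `dr_map`.
#' @param resolution Angstrom.
#' @param params A [dr_params()].
#' @param n_cycles maximum cycles (default 4).
#' @param external_model,symmetry_ops,reference passed to [run_cycle()].
#' @param seed RNG seed (default 0).
#' @return List of class `dr_iterative_result`: `cycles` (list of
#'   `dr_cycle_result`), `final_prediction`, `final_model`.
#' @export
run_iterative <- function(predictor, sequence, map, resolution,
                          params = dr_params(), n_cycles = 4,
                          external_model = NULL, symmetry_ops = NULL,
                          reference = NULL, seed = 0) {
  cycles <- list()
  template <- NULL
  prediction <- NULL
  prev_rebuilt <- NULL
  for (cyc in seq_len(n_cycles)) {
    prediction <- tryCatch(
      predictor(sequence, template, seed = seed + cyc),
      error = function(e) stop("predictor failed at cycle ", cyc, ": ",
                               conditionMessage(e)))
    res <- run_cycle(prediction, map, resolution, params, external_model,
                     symmetry_ops, reference, seed = seed + cyc)
    res$cycle_index <- cyc
    cycles[[cyc]] <- res
    template <- res$rebuilt_model
    if (!is.null(prev_rebuilt)) {
      ca1 <- model_ca(prev_rebuilt); ca2 <- model_ca(res$rebuilt_model)
      shared <- stats::complete.cases(ca1) & stats::complete.cases(ca2)
      drms <- sqrt(mean(rowSums((ca1[shared, , drop = FALSE] -
                                 ca2[shared, , drop = FALSE])^2)))
      if (drms < params$convergence_rmsd) break
    }
    prev_rebuilt <- res$rebuilt_model
  }
  structure(list(cycles = cycles, final_prediction = prediction,
                 final_model = cycles[[length(cycles)]]$rebuilt_model),
            class = "dr_iterative_result")
}

#' @export
print.dr_iterative_result <- function(x, ...) {
  cat(sprintf("<dr_iterative_result> %d cycle(s)\n", length(x$cycles)))
  for (cyc in x$cycles)
    cat(sprintf("  cycle %d: cc %.3f -> %.3f\n", cyc$cycle_index,
                cyc$metrics$cc_docked_morphed, cyc$metrics$cc_rebuilt))
  invisible(x)
}
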