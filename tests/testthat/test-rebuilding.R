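# Poor-segment detection, the rebuilding strategies and assembly.

test_that("poor-segment detection flags displacement and low confidence", {
  fx <- fixture_single_domain(1)
  plan0 <- identify_poor_segments(fx$truth, fx$map)
  expect_equal(sum(plan0$segments$label == "rebuild"), 0L)

  # 10 central residues displaced out of density
  ca <- model_ca(fx$truth)
  bad <- 18:27
  moved <- model_set_ca(fx$truth, bad - 1L,
                        sweep(ca[bad, , drop = FALSE], 2, -c(0, 14, 0)))
  plan1 <- identify_poor_segments(moved, fx$map)
  reb <- plan1$segments[plan1$segments$label == "rebuild", ]
  expect_gte(nrow(reb), 1)
  expect_lte(min(reb$start), 17 + 5)
  expect_gte(max(reb$end), 28 - 5)

  # a confidence dip alone triggers rebuilding even with perfect density
  conf <- rep(95, model_nres(fx$truth))
  conf[20:35] <- 40
  plan2 <- identify_poor_segments(fx$truth, fx$map, confidence = conf)
  reb2 <- plan2$segments[plan2$segments$label == "rebuild", ]
  expect_equal(nrow(reb2), 1L)
  expect_lte(abs(reb2$start - 19), 5)
  expect_lte(abs(reb2$end - 35), 5)
  expect_match(reb2$reason, "low_confidence")
})

test_that("segments tile the model with adjacent labels merged", {
  for (seed in 1:10) {
    fx <- fixture_two_domain(seed)
    plan <- identify_poor_segments(fx$predicted, fx$map)
    segs <- plan$segments
    expect_equal(segs$start[1], 0L)
    expect_equal(segs$end[nrow(segs)], plan$n)
    if (nrow(segs) > 1) {
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
      expect_true(all(segs$label[-1] != segs$label[-nrow(segs)]))
    }
  }
})

test_that("widest-path retracing follows the strongest channel", {
  # straight tube of uniform density
  tube <- array(0, c(20, 9, 9)); tube[3:18, 5, 5] <- 1
  tm <- map_new(tube, 1, c(0, 0, 0))
  tr <- retrace_loop(tm, c(2, 4, 4), c(17, 4, 4), 4)
  expect_equal(attr(tr, "path_min"), 1)
  expect_lt(max(abs(tr[, 2:3] - 4)), 1)
  # two channels with different minima: the wider (0.8) one wins
  g <- array(0, c(14, 9, 5))
  g[2:13, 2, 3] <- 0.8; g[7, 2, 3] <- 0.8       # top channel
  g[2:13, 7, 3] <- 1;   g[7, 7, 3] <- 0.3       # stronger but pinched
  g[2, 2:7, 3] <- 1; g[13, 2:7, 3] <- 1         # connect the ends
  gm <- map_new(g, 1, c(0, 0, 0))
  tr2 <- retrace_loop(gm, c(1, 4, 2), c(12, 4, 2), 5)
  expect_equal(attr(tr2, "path_min"), 0.8)
  # disjoint islands fail
  isl <- array(0, c(12, 5, 5)); isl[2:4, 3, 3] <- 1; isl[9:11, 3, 3] <- 1
  expect_null(retrace_loop(map_new(isl, 1, c(0, 0, 0)),
                           c(2, 2, 2), c(9, 2, 2), 3))
})

test_that("retracing matches the bottleneck oracle on random grids", {
  set.seed(17)
  for (k in 1:30) {
    d <- sample(5:10, 3, replace = TRUE)
    g <- array(round(runif(prod(d)), 2), d)
    g[g < 0.15] <- 0
    s <- c(1, 1, 1); e <- d
    g[1, 1, 1] <- max(g[1, 1, 1], 0.5); g[d[1], d[2], d[3]] <-
      max(g[d[1], d[2], d[3]], 0.5)
    m <- map_new(g, 1, c(0, 0, 0))
    got <- retrace_loop(m, c(0, 0, 0), (d - 1), 3)
    want <- widest_path_oracle(g, s, e)
    if (is.na(want)) expect_null(got)
    else expect_equal(attr(got, "path_min"), want, tolerance = 1e-12)
  }
})

test_that("loop fitting closes onto the anchors and prefers density", {
  fx <- fixture_single_domain(2)
  seg <- c(13, 15)                     # the short internal loop
  out <- fit_loop(fx$truth, fx$map, seg, 3, n_candidates = 150, seed = 1)
  expect_false(is.null(out))
  ca <- model_ca(out)
  steps <- sqrt(rowSums(diff(ca[12:17, ])^2))
  expect_true(all(steps > 2 & steps < 5.6))
  dens <- mean(interpolate_density(fx$map, ca[14:15, ]))
  expect_gt(dens, 0.15)
  # infeasible span fails cleanly
  stretched <- model_set_ca(fx$truth, 16L,
                            matrix(model_ca(fx$truth)[17, ] + c(0, 60, 0),
                                   1, 3))
  expect_null(fit_loop(stretched, fx$map, c(13, 16), 3, seed = 1))
  # determinism under a fixed seed
  out2 <- fit_loop(fx$truth, fx$map, seg, 3, n_candidates = 150, seed = 1)
  expect_identical(model_coords(out), model_coords(out2))
})

test_that("external fragments splice only when their ends connect", {
  fx <- fixture_single_domain(3)
  seg <- c(12, 16)
  # external model containing the truth: qualifies and restores the loop
  noisy <- fx$truth
  ca <- model_ca(noisy)
  noisy <- model_set_ca(noisy, 13:14,
                        sweep(ca[14:15, , drop = FALSE], 2, -c(0, 6, 0)))
  spliced <- splice_external_fragment(noisy, seg, fx$truth, fx$map)
  expect_false(is.null(spliced))
  expect_lt(max(abs(model_ca(spliced)[13:16, ] - ca[13:16, ])), 1e-9)
  # fragment ends 5 A away from the flanks: rejected
  shifted <- model_set_coords(fx$truth,
                              sweep(model_coords(fx$truth), 2, -c(0, 0, 5)))
  expect_null(splice_external_fragment(noisy, seg, shifted, fx$map))
  expect_null(splice_external_fragment(noisy, seg, NULL, fx$map))
})

test_that("restrained refinement recovers small offsets and guards cc", {
  fx <- fixture_single_domain(3)
  m0 <- simple_real_space_refine(fx$truth, fx$map, 3)
  expect_lt(max(abs(model_ca(m0) - model_ca(fx$truth))), 0.15)
  off <- model_set_coords(fx$truth,
                          sweep(model_coords(fx$truth), 2, -c(1, 0, 0)))
  m1 <- simple_real_space_refine(off, fx$map, 3)
  expect_lt(sqrt(mean(rowSums((model_ca(m1) - model_ca(fx$truth))^2))), 0.5)
  zm <- map_new(array(0, dim(fx$map$grid)), 1, fx$map$origin)
  m2 <- simple_real_space_refine(fx$truth, zm, 3)
  expect_true(isTRUE(attr(m2, "refine_flag")))
  expect_equal(model_coords(m2), model_coords(fx$truth))
})

test_that("iterative-resolution refinement widens the capture basin", {
  fx <- fixture_single_domain(3)
  # already-optimal model barely moves
  m0 <- iterative_resolution_refine(fx$truth, fx$map, 3)
  cc0 <- map_model_cc(fx$map, fx$truth, 3)$cc
  cc1 <- map_model_cc(fx$map, m0, 3)$cc
  expect_lt(abs(cc1 - cc0), 1e-2)
  # 2 A offset recovered through the 6 -> 3 A schedule
  off <- model_set_coords(fx$truth,
                          sweep(model_coords(fx$truth), 2, -c(2, 0, 0)))
  m2 <- iterative_resolution_refine(off, fx$map, 3)
  expect_lt(sqrt(mean(rowSums((model_ca(m2) - model_ca(fx$truth))^2))), 0.6)
  # start = resolution collapses to a single pass
  m3 <- iterative_resolution_refine(off, fx$map, 3, start = 3)
  expect_s3_class(m3, "dr_model")
  expect_error(iterative_resolution_refine(fx$truth, fx$map, 7, start = 6))
})

test_that("candidate generation covers the strategies and keeps residues", {
  fx <- fixture_two_domain(2)
  res <- trim_low_confidence(fx$predicted)
  # a plan with no rebuild segments returns the refined input only
  plan0 <- identify_poor_segments(fx$truth, fx$map)
  cands0 <- generate_candidates(fx$truth, fx$map, plan0, 3)
  expect_length(cands0, 1)
  expect_equal(cands0[[1]]$strategy, "refined_input")
  # with rebuild segments, multiple strategies produce full-length models
  plan <- identify_poor_segments(fx$predicted, fx$map)
  if (sum(plan$segments$label == "rebuild") > 0) {
    cands <- generate_candidates(fx$predicted, fx$map, plan, 3, seed = 1)
    expect_gte(length(cands), 2)
    for (cand in cands) {
      expect_equal(model_resno(cand$model), model_resno(fx$predicted))
      expect_length(cand$per_segment_cc, nrow(plan$segments))
    }
    # no external model was supplied, so that strategy is absent
    expect_false("external" %in% vapply(cands, function(x) x$strategy, ""))
  }
})

test_that("assembly picks the best candidate per segment deterministically", {
  fx <- fixture_single_domain(5)
  plan <- structure(list(segments = data.frame(
    start = c(0L, 20L), end = c(20L, 44L),
    label = c("rebuild", "rebuild"), reason = "low_density"),
    n = 44L), class = "dr_segment_plan")
  good <- fx$truth
  set.seed(44)
  bad1 <- model_set_coords(fx$truth,
                           model_coords(fx$truth) + matrix(rnorm(528, 0, 3),
                                                           176, 3))
  c1 <- list(model = good, strategy = "fit_loop",
             per_segment_cc = dockrebuild:::segment_ccs(good, fx$map, plan, 3))
  c2 <- list(model = bad1, strategy = "retrace",
             per_segment_cc = dockrebuild:::segment_ccs(bad1, fx$map, plan, 3))
  out <- assemble_best_segments(list(c2, c1), plan, fx$map, 3, refine = FALSE)
  expect_equal(out$choices$strategy, c("fit_loop", "fit_loop"))
  expect_equal(model_coords(out$pre_model), model_coords(good),
               ignore_attr = TRUE)
  # ties break toward the earlier candidate in the list
  out2 <- assemble_best_segments(list(c1, c1), plan, fx$map, 3, refine = FALSE)
  expect_equal(out2$choices$cc, c1$per_segment_cc, tolerance = 1e-12)
  # single candidate assembles to itself
  out3 <- assemble_best_segments(list(c1), plan, fx$map, 3, refine = FALSE)
  expect_equal(model_coords(out3$model), model_coords(good),
               ignore_attr = TRUE)
})
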