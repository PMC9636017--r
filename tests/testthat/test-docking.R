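# SSE detection, SSM and correlation docking, rigid-body refinement,
# placement expansion and the empirical combination score.

test_that("model SSE detection recognizes canonical geometry", {
  helix <- make_toy_fold(fixture_spec(
    data.frame(element = "helix", length = 12), seed = 1))
  ss <- detect_sse_from_model(helix)
  expect_length(ss, 1)
  expect_equal(ss[[1]]$kind, "helix")
  expect_equal(nrow(ss[[1]]$ca), 12)

  strand <- make_toy_fold(fixture_spec(
    data.frame(element = "strand", length = 6), seed = 1))
  ss2 <- detect_sse_from_model(strand)
  expect_length(ss2, 1)
  expect_equal(ss2[[1]]$kind, "strand")

  # seeded random coil: rejected by the geometric filters
  set.seed(8)
  walk <- matrix(0, 15, 3)
  for (i in 2:15) {
    step <- rnorm(3); walk[i, ] <- walk[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
  }
  coil <- model_new(data.frame(resno = 1:15, resname = "GLY", atom = "CA",
                               element = "C", x = walk[, 1], y = walk[, 2],
                               z = walk[, 3], b = 50))
  expect_length(detect_sse_from_model(coil), 0)
})

test_that("map SSE detection finds isolated rods and ignores noise", {
  helix <- make_toy_fold(fixture_spec(
    data.frame(element = "helix", length = 14), seed = 1))
  map <- make_synthetic_map(helix, 3)
  ss <- detect_sse_from_map(map, 3)
  expect_gte(length(ss), 1)
  expect_equal(ss[[1]]$kind, "helix")
  # axis direction within 10 degrees and position within 2 A of truth (z)
  tr <- ss[[1]]$ca
  fit <- prcomp(tr)$rotation[, 1]
  expect_gt(abs(fit[3]), cos(10 * pi / 180))
  expect_lt(max(abs(colMeans(tr)[1:2] - colMeans(model_ca(helix))[1:2])), 2)

  # two parallel helices 10 A apart
  h2 <- helix
  h2$atoms$x <- h2$atoms$x + 10
  h2$atoms$resno <- h2$atoms$resno + 50L
  pair <- model_bind(list(helix, h2))
  ss2 <- detect_sse_from_map(make_synthetic_map(pair, 3), 3)
  expect_gte(sum(vapply(ss2, function(s) s$kind, "") == "helix"), 2)

  # pure noise map yields nothing
  set.seed(12)
  noise <- map_new(array(rnorm(35^3), c(35, 35, 35)), 1)
  expect_length(detect_sse_from_map(noise, 3), 0)
})

test_that("SSM docking recovers rigid transforms on clean two-helix maps", {
  m <- two_helix_model()
  map <- make_synthetic_map(m, 3)
  sses <- detect_sse_from_map(map, 3)
  expect_gte(length(sses), 2)
  # identity case
  pl0 <- ssm_dock(m, sses, map, 3)
  expect_gte(length(pl0), 1)
  ca <- model_ca(m)
  rms0 <- sqrt(mean(rowSums((transform_apply(pl0[[1]]$transform, ca) - ca)^2)))
  expect_lte(rms0, 0.5)
  # transform recovery over seeded trials
  ok <- 0
  for (seed in 1:3) {
    set.seed(seed)
    tr <- random_transform(max_angle = 1.2, max_shift = 6)
    pert <- model_transform(m, transform_invert(tr))
    pl <- ssm_dock(pert, sses, map, 3)
    if (length(pl) == 0) next
    moved <- transform_apply(pl[[1]]$transform, model_ca(pert))
    if (sqrt(mean(rowSums((moved - ca)^2))) <= 1.5) ok <- ok + 1
  }
  expect_gte(ok, 2)
  # a helix-only domain cannot match a strand-only target set
  strand_sse <- list(dockrebuild:::sse_new(
    "strand", cbind(seq(0, 33, by = 3.3), 0, 0)))
  expect_length(ssm_dock(m, strand_sse, map, 3), 0)
  # fewer than 2 SSEs signals not-applicable
  single <- make_toy_fold(fixture_spec(
    data.frame(element = "helix", length = 12), seed = 1))
  expect_null(ssm_dock(single, sses, map, 3))
})

test_that("correlation docking recovers a pure translation within a voxel", {
  m <- two_helix_model()
  t_true <- c(6, -4, 3)
  moved <- model_set_coords(m, sweep(model_coords(m), 2, -t_true))
  map <- make_synthetic_map(moved, 3)
  pl <- correlation_dock(m, map, 3)
  expect_gte(length(pl), 1)
  got <- pl[[1]]$transform
  ca <- model_ca(m)
  err <- sqrt(mean(rowSums((transform_apply(got, ca) -
                              sweep(ca, 2, -t_true))^2)))
  expect_lte(err, 1.0)
  expect_gte(pl[[1]]$cc, 0.8)
  # zero map gives no placements; an oversized domain errors
  zmap <- map_new(array(0, c(42, 42, 42)), 1, c(-18, -18, -18))
  expect_length(correlation_dock(m, zmap, 3), 0)
  tiny <- map_new(array(1, c(4, 4, 4)), 1)
  expect_error(correlation_dock(m, tiny, 3), "too small")
})

test_that("rigid-body refinement polishes small errors and flags dead starts", {
  m <- two_helix_model()
  map <- make_synthetic_map(m, 3)
  ca <- model_ca(m)
  pert <- transform_about_center(c(0, 0, 1), 3 * pi / 180, colMeans(ca),
                                 c(1, 0, 0))
  ref <- rigid_body_refine(m, map, 3, pert)
  expect_lte(sqrt(mean(rowSums((transform_apply(ref$transform, ca) - ca)^2))),
             0.5)
  # exact start: cc cannot decrease, transform stays put
  ref0 <- rigid_body_refine(m, map, 3, transform_identity())
  expect_gte(ref0$cc,
             map_model_cc(map, m, 3)$cc - 1e-6)
  expect_lte(sqrt(mean(rowSums((transform_apply(ref0$transform, ca) - ca)^2))),
             0.2)
  # start far from any density: no improvement, flagged
  far <- transform_new(diag(3), c(500, 500, 500))
  reff <- rigid_body_refine(m, map, 3, far)
  expect_false(reff$improved)
})

test_that("placement expansion shares transforms and applies symmetry", {
  m <- two_helix_model()
  map <- make_synthetic_map(m, 3)
  d1 <- model_subset(m, 0:11)
  d2 <- model_subset(m, 12:23)
  tr <- transform_identity()
  pl <- list(list(dockrebuild:::placement_new("d1", tr, 0.9, "correlation")),
             list())
  ex <- expand_placements(pl, list(d1, d2), map, 3)
  expect_gte(length(ex[[2]]), 1)          # d2 borrowed d1's transform
  expect_equal(ex[[2]][[1]]$source, "reused")
  # identity symmetry op adds nothing after dedup
  ex2 <- expand_placements(pl, list(d1, d2), map, 3,
                           symmetry_ops = list(transform_identity()))
  expect_equal(length(ex2[[1]]), 1L)
  # a C2 operator doubles a placement, related by the operator
  c2 <- transform_about_center(c(0, 0, 1), pi, c(0, 0, 0))
  ex3 <- expand_placements(list(list(dockrebuild:::placement_new(
    "d1", tr, 0.9, "correlation"))), list(d1), map, 3,
    symmetry_ops = list(c2))
  expect_equal(length(ex3[[1]]), 2L)
  t_new <- ex3[[1]][[2]]$transform
  expect_lt(max(abs(t_new$rotation - c2$rotation)), 1e-6)
})

test_that("symmetry operator files parse as 3x4 row-major matrices", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 0 0 0 1 0 0 0 0 1 0",
               "-1 0 0 5 0 -1 0 0 0 0 1 0"), tf)
  ops <- load_symmetry_ops(tf)
  expect_length(ops, 2)
  expect_equal(ops[[1]]$rotation, diag(3))
  expect_equal(ops[[2]]$translation, c(5, 0, 0))
  writeLines("1 2 3", tf)
  expect_error(load_symmetry_ops(tf), "12 numbers")
})

test_that("the combination score reproduces hand-evaluated rule cases", {
  # two domains in sequence, spatially adjacent, identical transforms
  mk <- function(resno, xs) model_new(data.frame(
    resno = resno, resname = "ALA", atom = "CA", element = "C",
    x = xs, y = 0, z = 0, b = 80))
  d1 <- mk(1:8, seq(0, by = 3.8, length.out = 8))
  d2 <- mk(11:18, seq(38, by = 3.8, length.out = 8))
  id <- transform_identity()
  p1 <- dockrebuild:::placement_new("d1", id, 0.6, "correlation")
  p2 <- dockrebuild:::placement_new("d2", id, 0.7, "correlation")
  combo <- score_placement_combo(list(p1, p2), list(d1, d2), 3)
  # bonuses 5 x 200; adjustments +0.6 +0.65; nothing subtracted
  expect_equal(combo$score, 1001.25, tolerance = 1e-9)
  expect_equal(sum(combo$breakdown), combo$score, tolerance = 1e-12)

  # a single low-cc placement earns no bonus block
  p_low <- dockrebuild:::placement_new("d1", id, 0.10, "correlation")
  combo2 <- score_placement_combo(list(p_low, NULL), list(d1, d2), 3)
  expect_equal(combo2$score, 0.2, tolerance = 1e-9)

  # domains placed far beyond the spannable distance get the -200 penalty
  far <- transform_new(diag(3), c(200, 0, 0))
  p2f <- dockrebuild:::placement_new("d2", far, 0.7, "correlation")
  combo3 <- score_placement_combo(list(p1, p2f), list(d1, d2), 3)
  expect_equal(unname(combo3$breakdown["penalty_connectivity"]), -200)
})

test_that("placement selection is optimal on small instances", {
  mk <- function(resno, xs) model_new(data.frame(
    resno = resno, resname = "ALA", atom = "CA", element = "C",
    x = xs, y = 0, z = 0, b = 80))
  d1 <- mk(1:8, seq(0, by = 3.8, length.out = 8))
  d2 <- mk(11:18, seq(38, by = 3.8, length.out = 8))
  id <- transform_identity()
  truth1 <- dockrebuild:::placement_new("d1", id, 0.8, "correlation")
  decoy1 <- dockrebuild:::placement_new("d1", transform_new(diag(3), c(40, 0, 0)),
                                        0.5, "correlation")
  truth2 <- dockrebuild:::placement_new("d2", id, 0.75, "correlation")
  decoy2 <- dockrebuild:::placement_new("d2", transform_new(diag(3), c(-40, 0, 0)),
                                        0.45, "correlation")
  best <- select_placements(list(list(truth1, decoy1), list(truth2, decoy2)),
                            list(d1, d2), 3)
  expect_equal(best$placements[[1]]$cc, 0.8)
  expect_equal(best$placements[[2]]$cc, 0.75)
  # single domain, single placement
  one <- select_placements(list(list(truth1)), list(d1), 3)
  expect_equal(one$placements[[1]]$cc, 0.8)
  # no placements anywhere: all-unplaced combo with diagnostic
  none <- select_placements(list(list(), list()), list(d1, d2), 3)
  expect_true(all(vapply(none$placements, is.null, TRUE)))
  expect_match(attr(none, "diagnostic"), "no domain")
})

test_that("overlap-avoiding combinations beat higher-cc overlapping ones", {
  mk <- function(resno, xs, y = 0) model_new(data.frame(
    resno = resno, resname = "ALA", atom = "CA", element = "C",
    x = xs, y = y, z = 0, b = 80))
  d1 <- mk(1:10, seq(0, by = 3.8, length.out = 10))
  d2 <- mk(21:30, seq(0, by = 3.8, length.out = 10))
  id <- transform_identity()
  up <- transform_new(diag(3), c(0, 20, 0))
  # overlapping pair: both at the same place, high cc
  ov1 <- dockrebuild:::placement_new("d1", id, 0.9, "correlation")
  ov2 <- dockrebuild:::placement_new("d2", id, 0.88, "correlation")
  # separated alternative for d2: lower cc but no overlap
  sep2 <- dockrebuild:::placement_new("d2", up, 0.6, "correlation")
  best <- select_placements(list(list(ov1), list(ov2, sep2)),
                            list(d1, d2), 3)
  expect_equal(best$placements[[2]]$cc, 0.6)
  expect_equal(unname(best$breakdown["bonus_low_overlap"]), 200)
})

test_that("beam search agrees with exhaustive enumeration", {
  set.seed(99)
  for (rep in 1:5) {
    case <- random_combo_case()
    lists <- lapply(seq_along(case$domains), function(i) {
      k <- sample(0:3, 1)
      lapply(seq_len(k), function(j)
        dockrebuild:::placement_new(paste0("d", i), random_transform(),
                                    runif(1, 0, 0.9), "correlation"))
    })
    ex <- select_placements(lists, case$domains, case$resolution,
                            max_exhaustive = 1e6)
    bm <- select_placements(lists, case$domains, case$resolution,
                            max_exhaustive = 1)
    expect_equal(bm$score, ex$score, tolerance = 1e-9)
  }
})
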