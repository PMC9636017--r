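# Shift-field morphing: evaluation, field construction, whole-model and
# windowed morphs, grafting.

test_that("shift-field evaluation: normalization, symmetry, oracle", {
  f1 <- shift_field(matrix(c(3, 4, 5), 1), matrix(c(1, -2, 0.5), 1))
  expect_equal(as.numeric(evaluate_shift_field(f1, c(90, -40, 7))),
               c(1, -2, 0.5))
  # constant vectors give the constant everywhere
  f2 <- shift_field(matrix(rnorm(30), 10), matrix(rep(c(2, 0, -1), each = 10), 10))
  expect_equal(as.numeric(evaluate_shift_field(f2, c(5, 5, 5))), c(2, 0, -1))
  # equidistant point between two anchors averages their vectors
  f3 <- shift_field(rbind(c(-1, 0, 0), c(1, 0, 0)),
                    rbind(c(1, 0, 0), c(0, 3, 0)))
  expect_equal(as.numeric(evaluate_shift_field(f3, c(0, 9, 2))),
               c(0.5, 1.5, 0))
  # brute-force oracle
  set.seed(77)
  for (k in 1:40) {
    na <- sample(2:12, 1)
    anchors <- matrix(rnorm(3 * na, sd = 15), na)
    vectors <- matrix(rnorm(3 * na), na)
    D <- runif(1, 3, 20)
    fld <- shift_field(anchors, vectors, D)
    pts <- matrix(rnorm(15, sd = 15), 5)
    got <- evaluate_shift_field(fld, pts)
    for (p in 1:5) {
      w <- exp(-colSums((t(anchors) - pts[p, ])^2) / D^2)
      expect_lt(max(abs(got[p, ] - colSums(vectors * w) / sum(w))), 1e-12)
    }
  }
})

test_that("field construction from docked domains follows the CA pairing", {
  fx <- fixture_single_domain(1)
  m <- fx$truth
  fld0 <- build_field_from_docked(m, list(m))
  expect_equal(max(abs(fld0$vectors)), 0)
  t_shift <- c(3, -1, 2)
  moved <- model_set_coords(m, sweep(model_coords(m), 2, -t_shift))
  fld1 <- build_field_from_docked(m, list(moved))
  expect_equal(nrow(fld1$anchors), model_nres(m))
  expect_lt(max(abs(sweep(fld1$vectors, 2, t_shift))), 1e-12)
  # two domains under different transforms give two vector populations
  d1 <- model_subset(m, 0:19); d2 <- model_subset(m, 20:43)
  m1 <- model_set_coords(d1, sweep(model_coords(d1), 2, -c(5, 0, 0)))
  m2 <- model_set_coords(d2, sweep(model_coords(d2), 2, -c(0, 0, -7)))
  fld2 <- build_field_from_docked(m, list(m1, m2))
  expect_lt(max(abs(sweep(fld2$vectors[1:20, ], 2, c(5, 0, 0)))), 1e-12)
  expect_lt(max(abs(sweep(fld2$vectors[21:44, ], 2, c(0, 0, -7)))), 1e-12)
  # residue mismatch errors
  bad <- d1; bad$atoms$resno <- bad$atoms$resno + 500L
  expect_error(build_field_from_docked(m, list(bad)), "not present")
})

test_that("morphing with uniform/zero fields is rigid/identity", {
  fx <- fixture_single_domain(2)
  m <- fx$truth
  n <- model_nres(m)
  fldz <- shift_field(model_ca(m), matrix(0, n, 3))
  expect_equal(model_coords(morph_model(m, fldz)), model_coords(m))
  fldt <- shift_field(model_ca(m), matrix(rep(c(1, 2, -3), each = n), n))
  mt <- morph_model(m, fldt)
  expect_lt(max(abs(sweep(model_coords(mt) - model_coords(m), 2,
                          c(1, 2, -3)))), 1e-9)
  # bond lengths exactly preserved under a uniform field
  d0 <- sqrt(rowSums(diff(model_ca(m))^2))
  d1 <- sqrt(rowSums(diff(model_ca(mt))^2))
  expect_lt(max(abs(d1 - d0)), 1e-9)
  # topology, numbering, confidence untouched
  expect_equal(model_resno(mt), model_resno(m))
  expect_equal(mt$confidence, m$confidence)
})

test_that("a whole-model rigid dock morphs onto the docked pose", {
  fx <- fixture_single_domain(3)
  m <- fx$truth
  set.seed(5)
  tr <- random_transform(max_angle = 0.4, max_shift = 5)
  docked <- model_transform(m, tr)
  fld <- build_field_from_docked(m, list(docked))
  morphed <- morph_model(m, fld)
  # a Gaussian-weighted field reproduces a rotation only up to a small
  # residual rigid component, so compare after superposition
  ca_m <- model_ca(morphed); ca_d <- model_ca(docked)
  aligned <- transform_apply(kabsch(ca_m, ca_d), ca_m)
  expect_lt(sqrt(mean(rowSums((aligned - ca_d)^2))), 0.3)
  # re-anchoring and morphing again converges onto the docked pose
  rms <- numeric(4)
  cur <- m
  for (it in 1:4) {
    fld_i <- shift_field(model_ca(cur), model_ca(docked) - model_ca(cur), 10)
    cur <- morph_model(cur, fld_i)
    rms[it] <- sqrt(mean(rowSums((model_ca(cur) - model_ca(docked))^2)))
  }
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[4], 0.25)
})

test_that("two-domain morph hits both docked poses and keeps the linker sane", {
  spec <- fixture_spec(data.frame(element = c("helix", "loop", "helix"),
                                  length = c(12, 16, 12)),
                       domains = c(1L, 0L, 2L), seed = 6)
  m <- make_toy_fold(spec)
  d1 <- model_subset(m, 0:11); d2 <- model_subset(m, 28:39)
  t2 <- transform_about_center(c(0, 0, 1), 10 * pi / 180,
                               colMeans(model_ca(d2)), c(4, 1, 0))
  docked <- list(d1, model_transform(d2, t2))
  fld <- build_field_from_docked(m, docked)
  morphed <- morph_model(m, fld)
  expect_lt(sqrt(mean(rowSums((model_ca(morphed)[1:12, ] -
                                 model_ca(d1))^2))), 0.5)
  expect_lt(sqrt(mean(rowSums((model_ca(morphed)[29:40, ] -
                                 model_ca(docked[[2]]))^2))), 0.5)
  # the linker deforms smoothly: consecutive-CA steps grow by no more
  # than the largest anchor shift (no chain tearing)
  steps <- sqrt(rowSums(diff(model_ca(morphed))^2))
  orig <- sqrt(rowSums(diff(model_ca(m))^2))
  max_shift <- max(sqrt(rowSums(fld$vectors^2)))
  expect_lt(max(steps), max(orig) + max_shift)
})

test_that("grafting is exact for rigid flank motions and smooth otherwise", {
  fx <- fixture_single_domain(4)
  m <- fx$truth
  ca <- model_ca(m)
  seg <- c(14, 30)
  lp <- 14:16; rp <- 27:29
  # identity graft
  g0 <- graft_segment(m, seg, ca[lp + 1, ], ca[rp + 1, ])
  expect_lt(max(abs(model_ca(g0) - ca)), 1e-9)
  # both flanks translated by t -> whole segment translated by t
  t_shift <- c(2, -1, 1)
  g1 <- graft_segment(m, seg, sweep(ca[lp + 1, ], 2, -t_shift),
                      sweep(ca[rp + 1, ], 2, -t_shift))
  moved <- model_ca(g1) - ca
  expect_lt(max(abs(sweep(moved[15:30, ], 2, t_shift))), 1e-9)
  expect_lt(max(abs(moved[-(15:30), ])), 1e-12)
  # different end translations interpolate monotonically along a
  # straight chain (anchor distances are monotone there)
  line <- model_new(data.frame(resno = 1:20, resname = "ALA", atom = "CA",
                               element = "C",
                               x = seq(0, by = 3.8, length.out = 20),
                               y = 0, z = 0, b = 80))
  lca <- model_ca(line)
  g2 <- graft_segment(line, c(2, 18), lca[3:5, ],
                      sweep(lca[16:18, ], 2, -c(0, 6, 0)))
  disp <- (model_ca(g2) - lca)[3:18, 2]
  expect_true(all(diff(disp) > -1e-9))
  expect_error(graft_segment(m, seg, NULL, ca[rp + 1, ]), "flank")
})

test_that("windowed morphing is a fixed point in matching density and
           improves an offset segment", {
  fx <- fixture_single_domain(5)
  m <- fx$truth
  w0 <- window_morph(m, fx$map, c(10, 30), resolution = 3)
  expect_lt(max(abs(model_ca(w0) - model_ca(m))), 0.35)
  # uniformly offset segment: mean CA density must not decrease
  ca <- model_ca(m)
  seg <- 12:27
  off <- ca; off[seg + 1, ] <- sweep(off[seg + 1, , drop = FALSE], 2,
                                     -c(2, 0, 0))
  m_off <- model_set_ca(m, seq_len(model_nres(m)) - 1L, off)
  before <- mean(interpolate_density(fx$map, model_ca(m_off)[seg + 1, ]))
  w1 <- window_morph(m_off, fx$map, c(12, 28), resolution = 3)
  after <- mean(interpolate_density(fx$map, model_ca(w1)[seg + 1, ]))
  expect_gte(after, before)
  # oversized window falls back to a single whole-segment pass
  w2 <- window_morph(m, fx$map, c(18, 22), n_window = 50, resolution = 3)
  expect_equal(model_nres(w2), model_nres(m))
})
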