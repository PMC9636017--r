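# Confidence normalization, smoothing, trimming, domain splitting.

test_that("confidence scale is detected and validated", {
  p <- normalize_confidence(c(0.9, 0.5))
  expect_equal(p$values, c(90, 50))
  expect_equal(p$source_scale, "0-1")
  p2 <- normalize_confidence(c(90, 50))
  expect_equal(p2$values, c(90, 50))
  expect_equal(p2$source_scale, "0-100")
  expect_error(normalize_confidence(c(150, 20)), "not a confidence")
})

test_that("profile smoothing is a truncated centered running mean", {
  expect_equal(smooth_profile(rep(7, 20), 10), rep(7, 20))
  expect_equal(smooth_profile(1:5, 1), 1:5)
  v <- rep(0, 21); v[11] <- 100
  s <- smooth_profile(v, 10)
  expect_equal(s[11], 10)            # full window of 10 residues
  expect_equal(s[1], 0)
  # truncation at the ends: window shrinks to what exists
  expect_equal(smooth_profile(c(10, 0, 0, 0), 10),
               c(10 / 4, 10 / 4, 10 / 4, 10 / 4))
})

test_that("trimming removes residues below the smoothed threshold", {
  fx <- fixture_single_domain(1)
  m <- fx$truth                       # confidence 90 everywhere
  expect_equal(model_nres(trim_low_confidence(m)), model_nres(m))
  expect_equal(model_nres(trim_low_confidence(m, threshold = 0)),
               model_nres(m))
  prof <- c(rep(90, 10), rep(50, 10))
  m20 <- model_subset(m, 0:19)
  trimmed <- trim_low_confidence(m20, prof, threshold = 70, window = 1)
  expect_equal(model_resno(trimmed), model_resno(m20)[1:10])
  err <- tryCatch(trim_low_confidence(m20, rep(10, 20)),
                  error = function(e) e)
  expect_match(conditionMessage(err), "all residues removed")
  expect_equal(err$max_smoothed_confidence, 10)
})

test_that("raising the threshold never increases retained residues", {
  fx <- fixture_two_domain(5)
  m <- fx$predicted
  kept <- vapply(c(0, 30, 50, 70, 90), function(thr) {
    tryCatch(model_nres(trim_low_confidence(m, threshold = thr)),
             error = function(e) 0L)
  }, 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("proximity splitting separates well-separated rigid bodies", {
  # two helices laid out ~45 A apart with the trimmed linker removed
  spec <- fixture_spec(data.frame(element = c("helix", "loop", "helix"),
                                  length = c(12, 14, 12)),
                       domains = c(1L, 0L, 2L), seed = 2)
  m <- make_toy_fold(spec)
  trimmed <- model_subset(m, c(0:11, 26:37))   # drop the linker
  ds <- split_into_domains(trimmed, maximum_domains = 3)
  expect_equal(length(ds$domains), 2L)
  expect_equal(ds$domains[[1]]$positions, 0:11)
  expect_equal(ds$domains[[2]]$positions, 12:23)
  # single compact unit stays one domain
  single <- fixture_single_domain(1)
  ds1 <- split_into_domains(single$truth)
  expect_equal(length(ds1$domains), 1L)
  expect_equal(length(ds1$domains[[1]]$positions), model_nres(single$truth))
  # parameter degeneracy
  ds2 <- split_into_domains(trimmed, maximum_domains = 1)
  expect_equal(length(ds2$domains), 1L)
})

test_that("domain sets exactly partition the retained residues", {
  for (seed in 1:25) {
    fx <- fixture_two_domain(seed)
    trimmed <- tryCatch(trim_low_confidence(fx$predicted),
                        error = function(e) NULL)
    if (is.null(trimmed)) next
    ds <- split_into_domains(trimmed)
    pos <- sort(unlist(lapply(ds$domains, function(d) d$positions)))
    expect_equal(pos, 0:(model_nres(trimmed) - 1L))
    expect_equal(anyDuplicated(pos), 0L)
    # intervals reproduce the positions
    for (d in ds$domains) {
      from_iv <- unlist(apply(d$intervals, 1,
                              function(r) seq(r[1], r[2] - 1L)))
      expect_equal(sort(from_iv), sort(d$positions))
    }
  }
})

test_that("PAE-based splitting follows the error-matrix block structure", {
  spec <- fixture_spec(data.frame(element = c("helix", "loop", "helix"),
                                  length = c(12, 14, 12)),
                       domains = c(1L, 0L, 2L), seed = 2)
  m <- make_toy_fold(spec)
  trimmed <- model_subset(m, c(0:11, 26:37))
  n <- 24
  pae <- matrix(20, n, n)
  pae[1:12, 1:12] <- 2; pae[13:24, 13:24] <- 2
  diag(pae) <- 0
  ds <- split_into_domains(trimmed, method = "pae", pae = pae)
  expect_equal(length(ds$domains), 2L)
  expect_equal(ds$domains[[1]]$positions, 0:11)
  # a uniformly confident matrix joins everything
  ds2 <- split_into_domains(trimmed, method = "pae",
                            pae = matrix(1, n, n))
  expect_equal(length(ds2$domains), 1L)
})

test_that("PAE JSON in the common dialect is parsed", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(predicted_aligned_error =
                                     matrix(c(0, 3, 3, 0), 2, 2))), tf)
  pae <- load_pae(tf)
  expect_equal(dim(pae), c(2L, 2L))
  expect_equal(pae[1, 2], 3)
})

test_that("short models yield a single domain with a warning", {
  fx <- fixture_single_domain(1)
  small <- model_subset(fx$truth, 0:4)
  expect_warning(ds <- split_into_domains(small), "shorter")
  expect_equal(length(ds$domains), 1L)
})
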