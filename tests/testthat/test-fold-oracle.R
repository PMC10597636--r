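test_that("energy model defaults, overrides and validation behave", {
  m <- build_energy_model()
  expect_equal(m$pair_energies$CG, -3.0)
  expect_equal(m$pair_energies$AU, -2.0)
  expect_equal(m$pair_energies$GU, -1.0)
  expect_equal(m$RT, 0.6163)
  expect_equal(m$min_hairpin, 3L)
  m2 <- build_energy_model(RT = 1.0)
  expect_equal(m2$RT, 1.0)
  expect_equal(m2$pair_energies$CG, -3.0)
  # any pair of real bases may be declared; non-bases may not
  expect_silent(build_energy_model(pair_energies = list(AG = -0.5)))
  expect_error(build_energy_model(pair_energies = list(AX = -0.5)),
               "two bases")
  expect_error(build_energy_model(RT = -1), "RT")
})

test_that("energy model files round-trip through the key=value format", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  writeLines(c("# comment", "pair.GC=-2.5", "pair.AU=-1.5", "stack_bonus=-0.4",
               "min_hairpin=4", "RT=0.7"), path)
  m <- read_energy_model(path)
  expect_equal(m$pair_energies$CG, -2.5)
  expect_equal(m$stack_bonus, -0.4)
  expect_equal(m$min_hairpin, 4L)
  expect_equal(m$RT, 0.7)
  writeLines("pair.GC=-2.5=x", path)
  expect_error(read_energy_model(path), "malformed")
})

test_that("degenerate ensembles collapse to the open chain", {
  polyA <- seq_record("a", strrep("A", 20))
  expect_equal(constrained_partition(polyA, W = 100L)$log_z, 0)
  prof <- accessibility_profile(polyA, oracle_config(l_a = 5, W = 100))
  expect_length(prof$values, 16L)
  expect_identical(prof$values, rep(0, 16))
  # a span cap at or below the hairpin minimum forbids every pair
  s <- seq_record("s", "GCGCAAAGCGCAAAGC")
  expect_equal(constrained_partition(s, W = 3L)$log_z, 0)
  p2 <- accessibility_profile(s, oracle_config(l_a = 4, W = 3))
  expect_identical(p2$values, rep(0, 13))
})

test_that("dynamic program equals exhaustive enumeration on worked examples", {
  cfg <- oracle_config(l_a = 4, W = 9)
  s <- seq_record("ex", "GGGAAAUCCC")
  dp <- accessibility_profile(s, cfg)
  bf <- brute_force_accessibility(s, cfg)
  expect_lt(max(abs(dp$values - bf$values)), 1e-6)
  part <- constrained_partition(s, W = 9L)
  m <- build_energy_model()
  res <- strsplit(s$seq, "")[[1]]
  zbrute <- sum(vapply(enumerate_structures(s, m, 9L), function(st)
    exp(-accessfold:::structure_energy(st, res, m) / m$RT), 0))
  expect_lt(abs(part$log_z - log(zbrute)) / abs(log(zbrute)), 1e-9)

  s2 <- seq_record("gc", "GCGCAAAGCGC")
  cfg2 <- oracle_config(l_a = 3, W = 10)
  expect_lt(max(abs(accessibility_profile(s2, cfg2)$values -
                    brute_force_accessibility(s2, cfg2)$values)), 1e-6)
})

test_that("hand-counted structure enumeration", {
  # GAAAC with min hairpin 3: the open chain and the single G-C pair
  st <- enumerate_structures(seq_record("x", "GAAAC"))
  expect_length(st, 2L)
  expect_identical(sort(vapply(st, nrow, 0L)), c(0L, 1L))
  expect_error(enumerate_structures(random_seq(19)), "18")
  expect_error(brute_force_accessibility(random_seq(19), oracle_config(3, 5)),
               "18")
})

test_that("DP matches brute force across random sequences and models", {
  set.seed(31)
  for (i in 1:60) {
    s <- random_seq(sample(8:14, 1), paste0("r", i))
    cfg <- oracle_config(l_a = sample(2:5, 1), W = sample(c(4, 7, 12), 1))
    m <- build_energy_model(stack_bonus = sample(c(0, -0.8), 1))
    dp <- accessibility_profile(s, cfg, m)
    bf <- brute_force_accessibility(s, cfg, m)
    expect_lt(max(abs(dp$values - bf$values)), 1e-6)
  }
})

test_that("profiles are nonnegative and monotone in the window length", {
  set.seed(47)
  for (i in 1:8) {
    s <- random_seq(sample(40:60, 1), paste0("m", i))
    prev <- NULL
    for (la in c(3, 6, 9, 12)) {
      p <- accessibility_profile(s, oracle_config(la, 25))
      expect_true(all(p$values >= -1e-9))
      if (!is.null(prev)) {
        k <- length(p$values)
        expect_true(all(p$values - prev[seq_len(k)] >= -1e-6))
      }
      prev <- p$values
    }
  }
})

test_that("a span of at least N-1 reproduces the unconstrained ensemble", {
  set.seed(59)
  for (i in 1:5) {
    n <- sample(30:45, 1)
    s <- random_seq(n, paste0("u", i))
    m <- build_energy_model(stack_bonus = if (i %% 2) 0 else -0.6)
    ref <- mccaskill_unconstrained(s, m, l_a = 6)
    dp <- accessibility_profile(s, oracle_config(6, n - 1L), m)
    expect_lt(max(abs(dp$values - ref)), 1e-9 * max(1, max(abs(ref))))
  }
})

test_that("reversal mirrors the profile when the energy is pairwise", {
  set.seed(61)
  for (i in 1:6) {
    s <- random_seq(sample(30:60, 1), "f")
    r <- seq_record("r", paste(rev(strsplit(s$seq, "")[[1]]), collapse = ""))
    cfg <- oracle_config(l_a = 7, W = 30)
    pf <- accessibility_profile(s, cfg)
    pr <- accessibility_profile(r, cfg)
    expect_lt(max(abs(rev(pr$values) - pf$values)), 1e-9)
  }
})

test_that("structured 440-base sequences fold without numerical sentinels", {
  ds <- generate_dataset(6, "structured",
                         sampler_params(len_min = 400, len_max = 440),
                         seed = 77)
  for (rec in ds$records) {
    p <- accessibility_profile(rec, oracle_config(35, 100))
    expect_true(all(is.finite(p$values)))
    expect_true(all(p$values >= -1e-9))
    expect_length(p$values, rec$n - 34L)
  }
})

test_that("label_dataset preserves order, skips short sequences, resumes", {
  expect_length(label_dataset(list(), oracle_config(5, 10))$profiles, 0L)
  set.seed(3)
  seqs <- c(lapply(1:5, function(i) random_seq(40, paste0("s", i))),
            list(random_seq(20, "short")))
  cfg <- oracle_config(35, 50)
  expect_warning(lab <- label_dataset(seqs, cfg), "short")
  expect_length(lab$profiles, 5L)
  expect_identical(lab$n_skipped, 1L)
  expect_identical(vapply(lab$profiles, `[[`, "", "id"), paste0("s", 1:5))
  expect_true(all(vapply(lab$profiles, function(p) length(p$values), 0L) == 6L))
  # resume: previously computed profiles are reused verbatim
  lab2 <- suppressWarnings(label_dataset(seqs, cfg, done = lab))
  expect_identical(lab2$profiles, lab$profiles)
})
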