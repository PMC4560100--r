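# superposition, transform decomposition, TM-score, displacement profiles

test_that("superposing coordinates onto themselves is the identity", {
  set.seed(11)
  m <- matrix(rnorm(60, sd = 8), 20, 3)
  fit <- superpose(m, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-8)
})

test_that("a known rotation plus shift is recovered exactly", {
  set.seed(12)
  m <- matrix(rnorm(45, sd = 10), 15, 3)
  tf <- rotation_about(c(0, 0, 1), 90)
  tf$translation <- tf$translation + c(1, 2, 3)
  moved <- apply_transform(m, tf)
  fit <- superpose(moved, m)
  expect_lt(fit$rmsd, 1e-9)
  back <- invert_transform(tf)
  expect_equal(fit$transform$rotation, back$rotation, tolerance = 1e-8)
  expect_equal(fit$transform$translation, back$translation, tolerance = 1e-8)
})

test_that("superposition RMSD matches an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(13)
  a <- matrix(rnorm(90, sd = 9), 30, 3)
  b <- a + matrix(rnorm(90, sd = 1.5), 30, 3)
  ours <- superpose(b, a)$rmsd
  theirs <- bio3d::fit.xyz(fixed = as.numeric(t(a)), mobile = as.numeric(t(b)),
                           fixed.inds = 1:90, mobile.inds = 1:90)
  ref_rmsd <- bio3d::rmsd(as.numeric(t(a)), theirs)
  expect_equal(ours, ref_rmsd, tolerance = 1e-4)
})

test_that("superpose RMSD is invariant under rigid pre-transforms", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rnorm(60, sd = 7), 20, 3)
    b <- a + matrix(rnorm(60, sd = 2), 20, 3)
    base <- superpose(b, a)$rmsd
    g <- rotation_about(rnorm(3), runif(1, 10, 170), center = rnorm(3, sd = 5))
    moved <- superpose(apply_transform(b, g), apply_transform(a, g))$rmsd
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
  expect_error(superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)), "mismatch")
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "3")
})

test_that("decomposition reads off constructed rotations", {
  id <- decompose_transform(rigid_transform())
  expect_equal(id$angle_deg, 0)
  expect_equal(as.numeric(id$displacement), c(0, 0, 0))

  d <- decompose_transform(rotation_about(c(1, 0, 0), 40))
  expect_equal(d$angle_deg, 40, tolerance = 1e-8)
  expect_equal(abs(d$axis), c(1, 0, 0), tolerance = 1e-8)
  expect_equal(as.numeric(d$displacement), c(0, 0, 0), tolerance = 1e-8)
  # in-plane axis is 90 degrees from the membrane normal
  expect_equal(d$axis_membrane_angle_deg, 90, tolerance = 1e-6)
})

test_that("decompose after compose is the identity on axis and angle", {
  for (seed in 1:8) {
    set.seed(seed)
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 1, 179)
    d <- decompose_transform(rotation_about(ax, ang))
    expect_equal(d$angle_deg, ang, tolerance = 1e-6)
    expect_equal(abs(sum(d$axis * ax)), 1, tolerance = 1e-6)
  }
  # near-180 branch uses the symmetric part
  d180 <- decompose_transform(rotation_about(c(0, 1, 0), 180))
  expect_equal(d180$angle_deg, 180, tolerance = 1e-6)
  expect_equal(abs(d180$axis), c(0, 1, 0), tolerance = 1e-6)
})

test_that("centroid displacement is reported in the membrane frame", {
  tf <- rigid_transform(diag(3), c(3.9, 2.8, 16.4))
  d <- decompose_transform(tf, membrane_frame(), centroid = c(5, -2, 7))
  expect_equal(as.numeric(d$displacement), c(3.9, 2.8, 16.4))
  # flipped normal flips the reported normal component
  d2 <- decompose_transform(tf, membrane_frame(normal = c(0, 0, -1)),
                            centroid = c(0, 0, 0))
  expect_equal(unname(d2$displacement["dz"]), -16.4)
})

test_that("TM-score is 1 for identity and scales with l_norm", {
  set.seed(21)
  m <- matrix(rnorm(90, sd = 10), 30, 3)
  expect_equal(as.numeric(tm_score(m, m)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(tm_score(m, m, l_norm = 60)), 0.5, tolerance = 1e-9)
  expect_error(tm_score(m, m, l_norm = 10), "l_norm")
  expect_error(tm_score(m[1:2, ], m[1:2, ]), "3")
})

test_that("pairs displaced by exactly d0 score one half", {
  # alternating +/- d0 shifts along z in a sign-cancelling pattern keep the
  # optimal superposition at the identity, so every pair sits at d0
  n <- 32
  l_norm <- n
  d0 <- max(0.5, 1.24 * (l_norm - 15)^(1 / 3) - 1.8)
  th <- 2 * pi * (seq_len(n) - 1) / n
  ref <- cbind(40 * cos(th), 40 * sin(th), 0)
  signs <- rep(c(1, -1, -1, 1), n / 4)
  mob <- ref + cbind(0, 0, signs * d0)
  expect_equal(as.numeric(tm_score(mob, ref, optimize = FALSE)), 0.5,
               tolerance = 1e-9)
  # the TM-optimal pose can only improve on the least-squares pose
  expect_gte(as.numeric(tm_score(mob, ref)), 0.5 - 1e-9)
})

test_that("TM-score search matches an exhaustive subset oracle on tiny toys", {
  exhaustive_tm <- function(mob, ref, l_norm) {
    n <- nrow(ref)
    d0 <- swapsmith:::tm_d0(l_norm)
    best <- -Inf
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) < 3) next
      fit <- tryCatch(superpose(mob[idx, , drop = FALSE], ref[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      mt <- apply_transform(mob, fit$transform)
      sc <- sum(1 / (1 + rowSums((mt - ref)^2) / d0^2)) / l_norm
      best <- max(best, sc)
    }
    best
  }
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(6:8, 1)
    ref <- matrix(rnorm(3 * n, sd = 4), n, 3)
    mob <- ref + matrix(rnorm(3 * n, sd = 1.2), n, 3)
    ours <- as.numeric(tm_score(mob, ref))
    oracle <- exhaustive_tm(mob, ref, n)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("TM-score does not increase as noise is added", {
  set.seed(31)
  ref <- matrix(rnorm(120, sd = 10), 40, 3)
  mean_tm <- function(sigma) {
    mean(vapply(1:5, function(k) {
      set.seed(100 + k)
      as.numeric(tm_score(ref + matrix(rnorm(120, sd = sigma), 40, 3), ref))
    }, numeric(1)))
  }
  tms <- vapply(c(0, 0.5, 1.5, 4), mean_tm, numeric(1))
  expect_true(all(diff(tms) <= 1e-9))
  expect_true(all(tms <= 1 + 1e-12))
})

test_that("displacement profiles localise a constructed domain shift", {
  toy <- symmetric_toy(5)
  s <- toy$structure
  shifted <- s
  in_trans <- swapsmith:::in_ranges(s$chain_id, s$res_seq, toy$domains$transport)
  shifted$z[in_trans] <- shifted$z[in_trans] + 5
  prof <- displacement_profile(shifted, s, toy$domains$scaffold)
  scaf <- prof$displacement_A[swapsmith:::in_ranges(prof$chain_id, prof$res_seq,
                                                    toy$domains$scaffold)]
  trans <- prof$displacement_A[swapsmith:::in_ranges(prof$chain_id, prof$res_seq,
                                                     toy$domains$transport)]
  expect_lt(max(scaf), 1e-6)
  expect_equal(unname(trans), rep(5, length(trans)), tolerance = 1e-6)
  # self comparison is all zeros
  self <- displacement_profile(s, s, toy$domains$scaffold)
  expect_lt(max(self$displacement_A), 1e-9)
})
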