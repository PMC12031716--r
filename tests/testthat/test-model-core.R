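test_that("event table fixes the eight outcome bindings", {
  ev <- event_table()
  expect_equal(ev$event, paste0("E", 1:8))
  expect_equal(ev$attention, c(rep("T", 4), rep("~T", 4)))
  expect_equal(ev$light, c("L", "L", "~L", "~L", rep("off", 4)))
  expect_equal(ev$choice, c("A", "A", "B", "B", "A", "A", "B", "B"))
  expect_equal(ev$outcome, rep(c("O1", "O2"), 4))
})

test_that("event probabilities follow the trial tree", {
  p <- model_params(rep(0.2, 8), rep(0, 8), u1 = 1, u2 = 0)
  expect_equal(unname(event_probabilities(1, p)),
               c(0.5, 0, 0, 0.5, 0, 0, 0, 0))

  p2 <- model_params(rep(0.2, 8), rep(0, 8), u1 = 0.7, u2 = 0.4)
  expect_equal(unname(event_probabilities(0.6, p2)),
               c(0.21, 0.09, 0.12, 0.18, 0.14, 0.06, 0.08, 0.12),
               tolerance = 1e-15)
  expect_equal(sum(event_probabilities(0.6, p2)), 1, tolerance = 1e-12)
})

test_that("event probabilities are a distribution across the parameter cube", {
  grid <- seq(0, 1, length.out = 11)
  for (x in grid) for (u1 in grid[c(1, 4, 8, 11)]) for (u2 in grid[c(2, 6, 11)]) {
    p <- model_params(rep(0.5, 8), rep(0, 8), u1, u2)
    probs <- event_probabilities(x, p)
    expect_true(all(probs >= 0))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("validation errors name the offending field", {
  expect_error(model_params(rep(0, 8), rep(0, 8)), "theta")
  expect_error(model_params(rep(1, 8), rep(0, 8)), "theta")
  expect_error(model_params(rep(0.5, 8), rep(-0.1, 8)), "lam")
  expect_error(model_params(rep(0.5, 8), rep(0, 8), u1 = 1.2), "u1")
  p <- model_params(rep(0.5, 8), rep(0, 8))
  expect_error(event_probabilities(1.5, p), "x")
  expect_error(apply_operator(9, 0.5, p), "k")
  expect_error(apply_operator(1, -0.2, p), "x")
})

test_that("learning operators are the stated affine maps", {
  p <- model_params(rep(0.8, 8), rep(0.25, 8))
  expect_equal(apply_operator(1, 0.5, p), 0.45)
  # lambda_k is each operator's fixed point
  q <- model_params(seq(0.1, 0.8, by = 0.1), seq(0, 0.7, by = 0.1))
  for (k in 1:8)
    expect_equal(apply_operator(k, q$lam[k], q), q$lam[k])
  # reflex-extinction regime: P_k x = theta_k x
  z <- make_special_case(model_params(rep(0.2, 8), runif(8)), "all_zero")
  for (k in 1:8)
    expect_equal(apply_operator(k, 0.5, z), 0.1)
})

test_that("operators map [0,1] into [0,1] for random valid parameters", {
  set.seed(11)
  for (i in 1:200) {
    p <- sample_params()
    x <- runif(1)
    y <- apply_operator(sample(8, 1), x, p)
    expect_gte(y, 0)
    expect_lte(y, 1)
  }
})

test_that("special-case constructors overwrite the limit points only", {
  base <- model_params(seq(0.1, 0.8, by = 0.1), runif(8), 0.3, 0.9)
  expect_equal(make_special_case(base, "all_zero")$lam, rep(0, 8))
  expect_equal(make_special_case(base, "all_one")$lam, rep(1, 8))
  cl <- make_special_case(base, "common_lambda", lam_value = 0.3)
  expect_equal(cl$lam, rep(0.3, 8))
  expect_equal(cl$theta, base$theta)
  expect_equal(c(cl$u1, cl$u2), c(base$u1, base$u2))
  expect_identical(make_special_case(base, "general"), base)
  expect_error(make_special_case(base, "common_lambda"), "lam_value")
})

test_that("parameter sampler is deterministic and respects invariants", {
  expect_identical(sample_params(seed = 7), sample_params(seed = 7))
  set.seed(21)
  for (i in 1:1000) {
    p <- sample_params()
    expect_silent(validate_params(p))
    expect_true(all(p$theta > 0 & p$theta < 1))
  }
  pc <- rand_contraction_params(5)
  expect_lt(contraction_constants(pc)$K1, 1)
  expect_error(
    sample_params(seed = 1, require_contraction = TRUE,
                  theta_range = c(0.6, 0.9), max_draws = 50),
    "narrower")
})

test_that("contraction constants match their closed-form collapses", {
  p <- model_params(rep(0.2, 8), rep(0, 8))
  d <- contraction_constants(p)
  expect_equal(d$K1, 0.8)
  expect_equal(d$K3, 0.8)
  p2 <- make_special_case(p, "common_lambda", 0.5)
  expect_equal(contraction_constants(p2)$K1, 1.6)

  # common theta/lambda collapse identities over random draws
  set.seed(31)
  for (i in 1:50) {
    th <- runif(1, 0.01, 0.99)
    lm <- runif(1)
    p <- model_params(rep(th, 8), rep(lm, 8), runif(1), runif(1))
    d <- contraction_constants(p)
    expect_equal(d$K1, 2 * (2 * th + (1 - th) * lm), tolerance = 1e-12)
    expect_equal(d$K3, 4 * th, tolerance = 1e-12)
  }
})

test_that("K3 equals K1 at zero limit points; K3 <= K1 in general", {
  set.seed(41)
  for (i in 1:100) {
    p <- sample_params()
    d <- contraction_constants(p)
    expect_lte(d$K3, d$K1 + 1e-15)
    pz <- make_special_case(p, "all_zero")
    dz <- contraction_constants(pz)
    expect_equal(dz$K1, dz$K3, tolerance = 1e-14)
    expect_equal(dz$K3, d$K3, tolerance = 1e-14)
  }
})

test_that("K2 variants differ by the theta3/theta7 term and need a common lambda", {
  p <- model_params(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
                    rep(0.4, 8), 0.3, 0.6)
  d_printed <- contraction_constants(p, "as_printed")
  d_fixed <- contraction_constants(p, "typo_corrected")
  expect_true(d_printed$K2_applicable)
  expect_true(d_printed$K2_as_printed)
  expect_true(d_fixed$typo_corrected)
  # as printed the third pair is theta3 + theta3; corrected, theta3 + theta7
  lam <- 0.4
  expect_equal(d_fixed$K2 - d_printed$K2,
               p$u2 * (1 - lam / 2) * (p$theta[7] - p$theta[3]),
               tolerance = 1e-14)
  # K1/K3/K4 do not depend on the variant
  expect_equal(d_printed$K1, d_fixed$K1)
  expect_equal(d_printed$K4, d_fixed$K4)

  uneq <- model_params(rep(0.2, 8), c(rep(0.4, 7), 0.5))
  d <- contraction_constants(uneq)
  expect_false(d$K2_applicable)
  expect_true(is.na(d$K2))
})

test_that("K4 exceeds 2 for valid parameters (as-stated formula)", {
  set.seed(51)
  for (i in 1:200) {
    d <- contraction_constants(sample_params())
    expect_gt(d$K4, 2)
    expect_equal(d$K4, 2 + d$K3, tolerance = 1e-14)
  }
})

test_that("parameter sets round-trip through flat configs and files", {
  p <- model_params(seq(0.1, 0.8, by = 0.1), seq(0, 0.7, by = 0.1),
                    0.25, 0.75)
  cfg <- params_to_config(p)
  expect_named(cfg, c(paste0("theta", 1:8), paste0("lambda", 1:8),
                      "u1", "u2"))
  expect_equal(params_from_config(cfg), p)

  expect_error(params_from_config(c(cfg, list(theta9 = 0.5))), "theta9")
  expect_error(params_from_config(cfg[-1]), "missing")

  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_equal(read_params(f), p, tolerance = 1e-9)
    unlink(f)
  }
})
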