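test_that("classic Vector Model matches hand-computed cases", {
  expect_equal(vector_model(c(3, 3), 1), 6)          # collinear vectors add
  expect_equal(vector_model(c(3, 3), -1), 0)         # opposed vectors cancel
  expect_equal(vector_model(c(3, 3), -0.129), sqrt(9 + 9 - 0.258 * 9))
  expect_equal(vector_model(c(3, 3), -0.129), 3.9595, tolerance = 1e-4)
  # a full symmetric matrix with one shared value is equivalent to the scalar
  m <- matrix(-0.129, 3, 3)
  expect_equal(vector_model(c(1, 2, 3), m), vector_model(c(1, 2, 3), -0.129))
})

test_that("classic Vector Model validates its interaction input", {
  expect_error(vector_model(c(3, -1), 1), class = "odormix_domain_error")
  expect_error(vector_model(c(3, 3), 1.5), class = "odormix_config_error")
  m <- matrix(0, 2, 2); m[1, 2] <- 0.5; m[2, 1] <- -0.5
  expect_error(vector_model(c(1, 1), m), "symmetric",
               class = "odormix_config_error")
  m2 <- matrix(NA_real_, 2, 2)
  expect_error(vector_model(c(1, 1), m2), "missing",
               class = "odormix_config_error")
  expect_error(vector_model(c(1, 1, 1), matrix(0, 2, 2)),
               class = "odormix_config_error")
})

test_that("modified Vector Model reproduces tabulated binary/ternary cells", {
  expect_equal(round_half_up(modified_vector_model(c(3.36, 3.54)), 1), 4.9)
  expect_equal(round_half_up(modified_vector_model(c(2.34, 3.54, 2.80)), 1),
               4.7)
  # quaternary direct evaluation (the tabulated 5.5 reflects intermediate
  # rounding; see the methods vignette)
  expect_equal(
    round_half_up(modified_vector_model(c(4.24, 2.20, 3.83, 2.15)), 2),
    5.63)
  # single component reduces to the individual law
  for (x in c(0.5, 1.9, 4.2)) {
    expect_equal(modified_vector_model(x), 1.07 * x)
  }
  expect_error(modified_vector_model(numeric(0)),
               class = "odormix_domain_error")
})

test_that("generalized quadratic form equals the literal n-specific formulas", {
  withr::local_seed(4711)
  for (i in 1:100) {
    x2 <- runif(2, 0.1, 5)
    x3 <- runif(3, 0.1, 5)
    x4 <- runif(4, 0.1, 5)
    expect_equal(modified_vector_model(x2), oracle_mvm2(x2[1], x2[2]),
                 tolerance = 1e-12)
    expect_equal(modified_vector_model(x3),
                 oracle_mvm3(x3[1], x3[2], x3[3]), tolerance = 1e-12)
    expect_equal(modified_vector_model(x4),
                 oracle_mvm4(x4[1], x4[2], x4[3], x4[4]), tolerance = 1e-12)
  }
})

test_that("strongest-component and summation baselines match hand values", {
  expect_equal(round_half_up(strongest_component_model(c(3.54, 2.20, 3.83)), 1),
               4.1)
  expect_equal(round_half_up(strongest_component_model(c(3.36, 3.54)), 1), 3.8)
  expect_equal(strongest_component_model(2.5), 1.07 * 2.5)
  expect_equal(strongest_component_model(-1), 0)  # sub-threshold clamps
  expect_equal(summation_model(c(3, 3), k = 1), 6)
  expect_equal(summation_model(0), 0)
  expect_equal(summation_model(c(3.36, 3.54)), 1.07 * 6.90)
  expect_equal(summation_model(c(3, -2), k = 1), 3)  # negatives contribute 0
  expect_error(strongest_component_model(numeric(0)),
               class = "odormix_domain_error")
  expect_error(summation_model(numeric(0)), class = "odormix_domain_error")
})

test_that("all models are invariant under component reordering", {
  withr::local_seed(99)
  for (i in 1:25) {
    x <- runif(sample(2:5, 1), 0.2, 4.5)
    p <- sample(length(x))
    expect_equal(modified_vector_model(x), modified_vector_model(x[p]))
    expect_equal(strongest_component_model(x),
                 strongest_component_model(x[p]))
    expect_equal(summation_model(x), summation_model(x[p]))
    expect_equal(vector_model(x, -0.2), vector_model(x[p], -0.2))
  }
})

test_that("models coincide for a single supra-threshold component", {
  for (x in seq(0, 4, by = 0.5)) {
    expect_equal(modified_vector_model(x), strongest_component_model(x))
    expect_equal(modified_vector_model(x), summation_model(x))
  }
})

test_that("counteraction keeps mixture OI strictly below the summation", {
  withr::local_seed(7)
  for (i in 1:50) {
    x <- runif(sample(2:4, 1), 0.3, 4.5)
    ca <- runif(1, -0.9, 0.99)
    # strongly negative cos(alpha) may clamp to 0, which still sits below
    # the summation
    mv <- suppressWarnings(modified_vector_model(x, cos_alpha = ca))
    expect_lt(mv, summation_model(x))
  }
})

test_that("equal-intensity binary mixtures reproduce the beta relation", {
  # with cos(alpha) = 2 beta^2 - 1, OI_mix = beta * (OI_a + OI_b) exactly
  for (beta in seq(0.1, 1, by = 0.1)) {
    ca <- 2 * beta^2 - 1
    for (x in c(0.7, 2.2, 4.5)) {
      expect_equal(modified_vector_model(c(x, x), cos_alpha = ca),
                   beta * (2 * 1.07 * x), tolerance = 1e-9)
    }
  }
})

test_that("radicand sign boundary sits at nine equal components", {
  # n - 0.129 n (n-1) > 0 iff n <= 8 for equal components
  x8 <- rep(2, 8)
  expect_no_warning(v8 <- modified_vector_model(x8))
  expect_gt(v8, 0)
  expect_warning(v9 <- modified_vector_model(rep(2, 9)),
                 class = "odormix_clamp_warning")
  expect_equal(v9, 0)
})

test_that("pairwise cos(alpha) recovery inverts the binary Vector Model", {
  withr::local_seed(11)
  for (i in 1:20) {
    oi <- runif(2, 0.5, 5)
    ca <- runif(1, -0.6, 1)
    mix <- vector_model(oi, ca)
    expect_equal(cos_alpha_from_pair(mix, oi[1], oi[2]), ca,
                 tolerance = 1e-10)
  }
  expect_error(cos_alpha_from_pair(10, 1, 1), class = "odormix_domain_error")
  expect_error(cos_alpha_from_pair(1, 0, 1), class = "odormix_domain_error")
})

test_that("predict_oi resolves lnOAV from either input encoding", {
  reg <- aromatic_odorants()
  via_ln <- tibble::tibble(sample_id = "m1", component = c("T", "S"),
                           ln_oav = c(log(2), log(4)))
  via_conc <- tibble::tibble(sample_id = "m1", component = c("T", "S"),
                             concentration_mg_m3 = c(2 * 1.43, 4 * 0.19))
  p1 <- predict_oi(via_ln, model = "mvm")
  p2 <- predict_oi(via_conc, model = "mvm", registry = reg)
  expect_equal(p1$predicted_oi, p2$predicted_oi, tolerance = 1e-12)
  # both encodings together must agree
  bad <- tibble::tibble(sample_id = "m1", component = "T",
                        concentration_mg_m3 = 2 * 1.43, ln_oav = 5)
  expect_error(predict_oi(bad, registry = reg),
               class = "odormix_validation_error")
  # concentration without a registry is a configuration error
  expect_error(predict_oi(via_conc, model = "mvm"),
               class = "odormix_config_error")
})

test_that("sub-threshold policy drops, keeps or refuses as asked", {
  s <- tibble::tibble(sample_id = "m", component = c("a", "b", "c"),
                      ln_oav = c(2, 3, -0.5))
  p_drop <- predict_oi(s, model = "mvm", subthreshold = "drop")
  expect_equal(p_drop$predicted_oi, modified_vector_model(c(2, 3)))
  expect_equal(p_drop$n_dropped, 1L)
  expect_match(p_drop$warnings, "sub-threshold")
  p_keep <- predict_oi(s, model = "mvm", subthreshold = "keep")
  expect_equal(p_keep$predicted_oi, modified_vector_model(c(2, 3, -0.5)))
  expect_error(predict_oi(s, model = "mvm", subthreshold = "error"),
               class = "odormix_domain_error")
})

test_that("zero-concentration and fully-dropped samples degrade gracefully", {
  reg <- aromatic_odorants()
  s <- tibble::tibble(sample_id = "m", component = c("T", "E"),
                      concentration_mg_m3 = c(0, 0.45 * 2))
  p <- predict_oi(s, registry = reg)
  expect_equal(p$n_dropped, 1L)
  expect_match(p$warnings, "undefined lnOAV")
  expect_equal(p$predicted_oi, modified_vector_model(log(2)))

  all_sub <- tibble::tibble(sample_id = "m", component = c("a", "b"),
                            ln_oav = c(-1, -2))
  p0 <- predict_oi(all_sub)
  expect_equal(p0$predicted_oi, 0)
  expect_match(p0$warnings, "all components dropped")

  dup <- tibble::tibble(sample_id = "m", component = c("a", "a"),
                        ln_oav = c(1, 2))
  expect_error(predict_oi(dup), class = "odormix_validation_error")
})

test_that("sample at threshold predicts zero OI", {
  s <- tibble::tibble(sample_id = "m", component = "T", ln_oav = 0)
  for (m in c("mvm", "scm", "sum")) {
    expect_equal(predict_oi(s, model = m)$predicted_oi, 0)
  }
})

test_that("classic model through predict_oi uses named interaction matrices", {
  s <- tibble::tibble(sample_id = "m", component = c("T", "E"),
                      ln_oav = c(2, 3))
  inter <- matrix(-0.129, 2, 2, dimnames = list(c("E", "T"), c("E", "T")))
  p <- predict_oi(s, model = "vm", interactions = inter)
  expect_equal(p$predicted_oi, modified_vector_model(c(2, 3)))
  expect_error(predict_oi(s, model = "vm"), class = "odormix_config_error")
  unnamed <- matrix(-0.129, 2, 2)
  expect_error(predict_oi(s, model = "vm", interactions = unnamed),
               class = "odormix_config_error")
})
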