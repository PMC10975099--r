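test_that("hand-evaluated count matrices give the expected kappa", {
  # 26 unanimous not-found rows + 26 rows split between levels 0 and 2
  m <- rbind(
    matrix(rep(c(2, 0, 0, 0, 0), 26), ncol = 5, byrow = TRUE),
    matrix(rep(c(1, 0, 1, 0, 0), 26), ncol = 5, byrow = TRUE)
  )
  fk <- fleiss_kappa(m)
  expect_equal(fk$p_bar, 0.5)
  expect_equal(fk$p_bar_e, 0.625)
  expect_equal(fk$kappa, -1 / 3)
  expect_equal(round(fk$kappa, 4), -0.3333)
  expect_false(fk$degenerate)
  expect_identical(fk$band, "poor")

  fk2 <- fleiss_kappa(rbind(c(2, 0, 0, 0, 0), c(0, 2, 0, 0, 0)))
  expect_equal(fk2$p_bar, 1)
  expect_equal(unname(fk2$level_proportions), c(0.5, 0.5, 0, 0, 0))
  expect_equal(fk2$p_bar_e, 0.5)
  expect_equal(fk2$kappa, 1)
  expect_false(fk2$degenerate)

  fk3 <- fleiss_kappa(rbind(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0)))
  expect_equal(fk3$p_bar, 0)
  expect_equal(fk3$p_bar_e, 0.5)
  expect_equal(fk3$kappa, -1)
  expect_identical(fk3$band, "poor")
})

test_that("all ratings in one level is the degenerate kappa = 1 case", {
  m <- matrix(rep(c(2, 0, 0, 0, 0), 10), ncol = 5, byrow = TRUE)
  fk <- fleiss_kappa(m)
  expect_true(fk$degenerate)
  expect_equal(fk$kappa, 1)
  expect_identical(fk$band, "perfect")
  expect_equal(fk$p_bar, 1)
  expect_equal(fk$p_bar_e, 1)
})

test_that("malformed count matrices are rejected with the offending row", {
  expect_error(fleiss_kappa(matrix(numeric(0), ncol = 5)),
               class = "ddic_domain_error")
  bad <- rbind(c(2, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  expect_error(fleiss_kappa(bad), class = "ddic_malformed_error")
  expect_error(fleiss_kappa(bad), "Row 2")
  expect_error(fleiss_kappa(rbind(c(-1, 3, 0, 0, 0), c(2, 0, 0, 0, 0))),
               class = "ddic_domain_error")
})

test_that("engine matches a naive transcription on random matrices", {
  set.seed(42)
  for (rep in 1:300) {
    N <- sample(1:20, 1)
    n <- sample(2:3, 1)
    m <- random_counts(N, n)
    fk <- fleiss_kappa(m)
    oracle <- naive_fleiss(m)
    expect_equal(fk$p_bar, oracle$p_bar, tolerance = 1e-12)
    expect_equal(fk$p_bar_e, oracle$p_e, tolerance = 1e-12)
    if (!fk$degenerate) {
      expect_equal(fk$kappa, oracle$kappa, tolerance = 1e-12)
    } else {
      expect_true(is.na(oracle$kappa))
    }
  }
})

test_that("with two raters every per-pair agreement is 0 or 1", {
  set.seed(7)
  for (rep in 1:50) {
    m <- random_counts(sample(1:20, 1), 2)
    fk <- fleiss_kappa(m)
    expect_true(all(fk$pair_agreements %in% c(0, 1)))
  }
})

test_that("kappa is 1 iff every pair agrees, and disagreement lowers P-bar", {
  agree <- rbind(c(2, 0, 0, 0, 0), c(0, 0, 2, 0, 0), c(0, 0, 0, 2, 0))
  fk <- fleiss_kappa(agree)
  expect_equal(fk$kappa, 1)
  expect_true(all(fk$pair_agreements == 1))
  worse <- fleiss_kappa(rbind(agree, c(1, 1, 0, 0, 0)))
  expect_lt(worse$p_bar, fk$p_bar)
  expect_lt(worse$kappa, 1)
})

test_that("within-category restriction equals the generic engine", {
  f <- fixture_c07_c04()
  drugs <- f$catalog$drug_id
  # rate only 3 of the pairs; the remaining universe is imputed mutual 0
  r <- make_ratings(c(0L, 0L, 0L), c(0L, 0L, 2L))
  r$drug_u <- rep(c("C07_001", "C07_002", "C07_003"), 2)
  r$drug_v <- rep(c("C07_004", "C07_005", "C07_006"), 2)
  sub <- sprintf("C07_%03d", 1:6)
  fk <- kappa_within_category(r, sub)
  expect_equal(fk$n_universe, choose(6, 2))
  expect_equal(fk$n_imputed, choose(6, 2) - 3L)
  # oracle: the explicitly assembled matrix
  m <- rbind(
    matrix(rep(c(2, 0, 0, 0, 0), 14), ncol = 5, byrow = TRUE),
    c(1, 0, 1, 0, 0)
  )
  expect_equal(fk$kappa, fleiss_kappa(m)$kappa, tolerance = 1e-15)
  expect_equal(fk$p_bar, fleiss_kappa(m)$p_bar, tolerance = 1e-15)
})

test_that("within-category guards endpoints and duplicates", {
  r <- make_ratings(0L, 0L)
  expect_error(kappa_within_category(r, c("dA001")),
               class = "ddic_domain_error")
  expect_error(kappa_within_category(r, c("dA001", "other")),
               class = "ddic_domain_error")
  dup <- dplyr::bind_rows(r, r[1, ])
  expect_error(kappa_within_category(dup, c("dA001", "dB001")),
               class = "ddic_malformed_error")
})

test_that("between-sets kappa equals the generic engine on the product", {
  f <- fixture_c07_c04()
  set_x <- sprintf("C07_%03d", 1:13)
  set_y <- sprintf("C04_%03d", 1:4)
  fk <- kappa_between_sets(f$ratings, set_x, set_y)
  expect_equal(fk$kappa, -1 / 3)
  expect_equal(round(fk$kappa, 3), -0.333)
  expect_identical(fk$band, "poor")
  expect_equal(fk$n_universe, 52L)
  expect_equal(fk$n_imputed, 0L)
  expect_equal(fk$kappa, fleiss_kappa(ratings_to_counts(f$ratings))$kappa)

  one <- tibble::tibble(drug_u = c("x1", "x1"), drug_v = c("y1", "y1"),
                        rater = c("a", "b"), code = c(3L, 3L))
  fk1 <- kappa_between_sets(one, "x1", "y1")
  expect_true(fk1$degenerate)
  expect_equal(fk1$kappa, 1)
})

test_that("between-sets rejects overlapping sets and non-spanning pairs", {
  r <- make_ratings(0L, 1L)
  expect_error(kappa_between_sets(r, c("dA001", "z"), c("dB001", "z")),
               class = "ddic_domain_error")
  expect_error(kappa_between_sets(r, c("dA001", "dB001"), "z"),
               class = "ddic_domain_error")
})

test_that("Landis-Koch banding uses kappa rounded to two decimals", {
  expect_identical(classify_band(0.655), "substantial")
  expect_identical(classify_band(0.203), "slight")   # rounds to 0.20
  expect_identical(classify_band(0.212), "fair")     # rounds to 0.21
  expect_identical(classify_band(-0.333), "poor")
  expect_identical(classify_band(1), "perfect")
  expect_identical(classify_band(0.9999), "almost_perfect")
  expect_identical(classify_band(-0.004), "slight")  # rounds to 0.00
  expect_identical(classify_band(0.405), "moderate") # half-up to 0.41
  expect_error(classify_band(1.5), class = "ddic_domain_error")
})

test_that("every kappa in [-1, 1] maps to exactly one band", {
  grid <- seq(-1, 1, length.out = 10001)
  bands <- classify_band(grid)
  expect_true(all(bands %in% band_levels()))
  # published range endpoints land inside the band bearing their label
  expect_true(all(classify_band(c(0.632, 0.655, 0.614, 0.801)) == "substantial"))
  expect_true(all(classify_band(c(0.221, 0.352, 0.212, 0.345)) == "fair"))
  expect_true(all(classify_band(c(0.035, 0.179, 0.068, 0.203)) == "slight"))
  expect_true(all(classify_band(c(0.427, 0.566, 0.420, 0.532)) == "moderate"))
  expect_true(all(classify_band(c(0.911, 0.978)) == "almost_perfect"))
  expect_identical(classify_band(1.0), "perfect")
})

test_that("tidy and glance expose the diagnostic fields", {
  fk <- fleiss_kappa(rbind(c(2, 0, 0, 0, 0), c(1, 0, 1, 0, 0)))
  td <- tidy(fk)
  expect_identical(td$level, 0:4)
  expect_equal(sum(td$proportion), 1)
  gl <- glance(fk)
  expect_identical(names(gl),
                   c("kappa", "p_bar", "p_bar_e", "n_pairs", "n_raters",
                     "band", "degenerate"))
  expect_equal(gl$kappa, (fk$p_bar - fk$p_bar_e) / (1 - fk$p_bar_e))
})
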