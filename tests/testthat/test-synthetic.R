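test_that("generator_spec validates its invariants", {
  expect_s3_class(generator_spec(), "generator_spec")
  expect_error(generator_spec(marginal = c(0.5, 0.5, 0.5, 0, 0)),
               class = "ddic_validation_error")
  expect_error(generator_spec(agreement = 1.2), class = "ddic_validation_error")
  expect_error(generator_spec(kernel = c(`0` = 1)), class = "ddic_validation_error")
  expect_error(generator_spec(kernel = c(`5` = 1)), class = "ddic_validation_error")
  expect_error(generator_spec(c_sizes = c(C01 = 0)), class = "ddic_validation_error")
})

test_that("the default catalog reproduces the study's subcategory sizes", {
  catalog <- synthetic_catalog(generator_spec())
  sizes <- subcategory_sizes(catalog)
  c_sizes <- sizes$n_drugs[sizes$category == "C"]
  names(c_sizes) <- sizes$subcategory[sizes$category == "C"]
  expect_equal(c_sizes[c("C01", "C02", "C03", "C04", "C07", "C08", "C09", "C10")],
               c(C01 = 46L, C02 = 11L, C03 = 15L, C04 = 4L, C07 = 13L,
                 C08 = 11L, C09 = 19L, C10 = 18L))
  expect_equal(sum(c_sizes), 137L)
  expect_equal(sum(sizes$n_drugs[sizes$category == "O"]), 189L)
})

test_that("identical seeds give byte-identical tables", {
  spec <- generator_spec(c_sizes = c(C01 = 6, C04 = 4),
                         o_sizes = c(A02 = 5), seed = 123)
  d1 <- generate_ratings(spec)
  d2 <- generate_ratings(spec)
  expect_identical(d1$catalog, d2$catalog)
  expect_identical(d1$ratings, d2$ratings)
  d3 <- generate_ratings(generator_spec(c_sizes = c(C01 = 6, C04 = 4),
                                        o_sizes = c(A02 = 5), seed = 124))
  expect_false(identical(d1$ratings, d3$ratings))
})

test_that("full agreement probability yields pure agreement and kappa 1", {
  spec <- generator_spec(c_sizes = c(C01 = 8, C04 = 6),
                         o_sizes = c(A02 = 2), agreement = 1, seed = 2)
  d <- generate_ratings(spec, universe = "within_C")
  rep <- stratify(d$ratings)
  expect_equal(rep$strata$pct[rep$strata$stratum == "agreement"], 100)
  fk <- fleiss_kappa(ratings_to_counts(d$ratings))
  expect_equal(fk$kappa, 1)
})

test_that("marginals and agreement fraction are recovered within 3 SE", {
  # ~10k pairs is enough for the 3-standard-error bound to bite
  spec <- generator_spec(
    c_sizes = c(C01 = 100, C02 = 101), o_sizes = c(A02 = 2),
    marginal = c(0.5, 0.1, 0.2, 0.15, 0.05), agreement = 0.65, seed = 77
  )
  d <- generate_ratings(spec, universe = "within_C")
  wide <- tidyr::pivot_wider(d$ratings, names_from = "rater",
                             values_from = "code")
  N <- nrow(wide)
  expect_equal(N, choose(201, 2))
  for (j in 0:4) {
    p <- spec$marginal[j + 1]
    se <- sqrt(p * (1 - p) / N)
    expect_lt(abs(mean(wide$edic_a == j) - p), 3 * se + 1e-12)
  }
  # kernel forbids offset 0, so empirical agreement ~ a
  a_hat <- mean(wide$edic_a == wide$edic_b)
  se_a <- sqrt(spec$agreement * (1 - spec$agreement) / N)
  expect_lt(abs(a_hat - spec$agreement), 3 * se_a)
})

test_that("disagreeing second ratings stay on-scale and differ from the first", {
  spec <- generator_spec(c_sizes = c(C01 = 40, C02 = 41),
                         o_sizes = c(A02 = 2),
                         marginal = c(0.2, 0.2, 0.2, 0.2, 0.2),
                         agreement = 0, seed = 31)
  d <- generate_ratings(spec, universe = "within_C")
  wide <- tidyr::pivot_wider(d$ratings, names_from = "rater",
                             values_from = "code")
  expect_true(all(wide$edic_b >= 0 & wide$edic_b <= 4))
  expect_true(all(wide$edic_a != wide$edic_b))
})

test_that("the default preset has the expected study-shape signature", {
  d <- generate_ratings(generator_spec(seed = 4), universe = "within_C")
  rep <- stratify(d$ratings)
  agree_pct <- rep$strata$pct[rep$strata$stratum == "agreement"]
  expect_gt(agree_pct, 72)
  expect_lt(agree_pct, 86)
  nf_share <- rep$by_level$pct[rep$by_level$level == 0]
  expect_gt(nf_share, 88)
})

test_that("fixture expectations are recomputable from the fixture ratings", {
  f <- fixture_c07_c04()
  fk <- fleiss_kappa(ratings_to_counts(f$ratings))
  expect_equal(fk$kappa, f$expected$kappa)
  expect_equal(fk$p_bar, f$expected$p_bar)
  expect_equal(fk$p_bar_e, f$expected$p_bar_e)
  rep <- stratify(f$ratings)
  expect_equal(rep$strata$count[rep$strata$stratum == "agreement"],
               f$expected$strata[["agreement"]])
  expect_equal(rep$strata$count[rep$strata$stratum == "mild_disagreement"],
               f$expected$strata[["mild_disagreement"]])

  pm <- fixture_perfect_agreement("mixed")
  fkm <- fleiss_kappa(ratings_to_counts(pm$ratings))
  expect_equal(fkm$kappa, 1)
  expect_false(fkm$degenerate)
  pz <- fixture_perfect_agreement("all_zero")
  fkz <- fleiss_kappa(ratings_to_counts(pz$ratings))
  expect_equal(fkz$kappa, 1)
  expect_true(fkz$degenerate)
  # appending one disagreeing pair drops kappa below 1 in both variants
  extra <- tibble::tibble(drug_u = c("C02_001", "C02_001"),
                          drug_v = c("zB01_001", "zB01_001"),
                          rater = c("edic_a", "edic_b"), code = c(0L, 2L))
  for (fx in list(pm, pz)) {
    fk2 <- fleiss_kappa(ratings_to_counts(dplyr::bind_rows(fx$ratings, extra)))
    expect_lt(fk2$kappa, 1)
  }
})
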