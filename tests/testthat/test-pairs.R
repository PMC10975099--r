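test_that("pair enumeration reproduces the study's combinatorics", {
  catalog <- paper_sized_catalog()
  expect_equal(nrow(enumerate_within_pairs(catalog, "C")), 9316L)
  expect_equal(nrow(enumerate_cross_subcategory_pairs(catalog, "C")), 7658L)
  expect_equal(nrow(enumerate_category_product(catalog, "C", "O")), 25893L)
  c10 <- subcategory_sizes(catalog)
  expect_equal(c10$n_drugs[c10$subcategory == "C10"] *
                 c10$n_drugs[c10$subcategory == "C04"], 72L)
})

test_that("pair-count identity: within = cross-subcategory + same-subcategory", {
  catalog <- paper_sized_catalog()
  sizes <- subcategory_sizes(catalog, "C")$n_drugs
  expect_equal(9316L, 7658L + sum(choose(sizes, 2)))
  # and on an arbitrary smaller catalog
  spec <- generator_spec(c_sizes = c(C01 = 5, C03 = 3, C08 = 7),
                         o_sizes = c(A02 = 2), seed = 3)
  cat2 <- synthetic_catalog(spec)
  w <- nrow(enumerate_within_pairs(cat2, "C"))
  x <- nrow(enumerate_cross_subcategory_pairs(cat2, "C"))
  expect_equal(w, x + sum(choose(c(5, 3, 7), 2)))
})

test_that("degenerate catalogs enumerate correctly", {
  small <- as_drug_catalog(tibble::tibble(
    drug_id = c("C01_1", "C01_2"), category = "C",
    primary_subcategory = "C01"
  ))
  expect_equal(nrow(enumerate_within_pairs(small, "C")), 1L)
  expect_equal(nrow(enumerate_cross_subcategory_pairs(small, "C")), 0L)
  one <- small[1, ]
  expect_equal(nrow(enumerate_within_pairs(as_drug_catalog(one), "C")), 0L)
  two_sub <- as_drug_catalog(tibble::tibble(
    drug_id = sprintf("d%d", 1:4), category = "C",
    primary_subcategory = c("C01", "C01", "C02", "C02")
  ))
  expect_equal(nrow(enumerate_cross_subcategory_pairs(two_sub, "C")), 4L)
})

test_that("catalog validation rejects duplicates and mismatches", {
  expect_error(as_drug_catalog(tibble::tibble(
    drug_id = c("a", "a"), category = "C", primary_subcategory = "C01"
  )), class = "ddic_malformed_error")
  expect_error(as_drug_catalog(tibble::tibble(
    drug_id = "a", category = "O", primary_subcategory = "C01"
  )), class = "ddic_malformed_error")
  expect_error(as_drug_catalog(tibble::tibble(
    drug_id = "a", category = "X", primary_subcategory = "C01"
  )), class = "ddic_malformed_error")
})

test_that("kappa matrix cells equal independent between-set calls", {
  spec <- generator_spec(
    c_sizes = c(C01 = 4, C04 = 3, C07 = 5),
    o_sizes = c(A02 = 3, B01 = 4),
    marginal = c(0.6, 0.1, 0.15, 0.1, 0.05), agreement = 0.6, seed = 21
  )
  d <- generate_ratings(spec)
  km <- build_kappa_matrix(d$catalog, d$ratings, mode = "within_C")
  expect_equal(nrow(km$cells), choose(3, 2))
  sub_of <- stats::setNames(d$catalog$primary_subcategory, d$catalog$drug_id)
  for (i in seq_len(nrow(km$cells))) {
    sx <- km$cells$subcat_x[i]; sy <- km$cells$subcat_y[i]
    dx <- d$catalog$drug_id[d$catalog$primary_subcategory == sx]
    dy <- d$catalog$drug_id[d$catalog$primary_subcategory == sy]
    keep <- (sub_of[d$ratings$drug_u] == sx & sub_of[d$ratings$drug_v] == sy) |
            (sub_of[d$ratings$drug_u] == sy & sub_of[d$ratings$drug_v] == sx)
    fk <- kappa_between_sets(d$ratings[keep, ], dx, dy)
    expect_equal(km$cells$kappa[i], fk$kappa)
    expect_equal(km$cells$n_pairs[i], fk$n_universe)
  }
  kco <- build_kappa_matrix(d$catalog, d$ratings, mode = "C_cross_O")
  expect_equal(nrow(kco$cells), 3L * 2L)
})

test_that("within-category kappa matrix is symmetric as a dense matrix", {
  spec <- generator_spec(c_sizes = c(C01 = 4, C04 = 3, C07 = 5),
                         o_sizes = c(A02 = 2), agreement = 0.7, seed = 5)
  d <- generate_ratings(spec, universe = "within_C")
  m <- as.matrix(build_kappa_matrix(d$catalog, d$ratings, mode = "within_C"))
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))
})

test_that("the worked-example cell appears in the matrix with kappa -1/3", {
  f <- fixture_c07_c04()
  km <- build_kappa_matrix(f$catalog, f$ratings, mode = "within_C")
  cell <- km$cells[km$cells$subcat_x == "C04" & km$cells$subcat_y == "C07", ]
  expect_equal(cell$kappa, -1 / 3)
  expect_identical(cell$band, "poor")
  expect_equal(cell$n_pairs, 52L)
})

test_that("band table sorts monotonically by kappa", {
  spec <- generator_spec(c_sizes = c(C01 = 4, C02 = 3, C04 = 3, C07 = 4),
                         o_sizes = c(A02 = 2), agreement = 0.5, seed = 9)
  d <- generate_ratings(spec, universe = "within_C")
  km <- build_kappa_matrix(d$catalog, d$ratings, mode = "within_C")
  bt <- kappa_band_table(km)
  expect_true(all(diff(bt$kappa) <= 0))
  expect_identical(bt$band, classify_band(bt$kappa))
})

test_that("run_pipeline produces a conserved, deterministic bundle", {
  spec <- generator_spec(
    c_sizes = c(C01 = 5, C04 = 3, C07 = 4),
    o_sizes = c(A02 = 3, B01 = 3),
    agreement = 0.75, seed = 13
  )
  d <- generate_ratings(spec)
  b1 <- run_pipeline(d$catalog, d$ratings)
  b2 <- run_pipeline(d$catalog, d$ratings)
  expect_identical(
    jsonlite::toJSON(ddiconcord:::bundle_to_list(b1), auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(ddiconcord:::bundle_to_list(b2), auto_unbox = TRUE, digits = NA)
  )
  # section totals satisfy the conservation invariants
  n_cross <- nrow(enumerate_cross_subcategory_pairs(d$catalog, "C"))
  expect_equal(sum(b1$reports$within_C$strata$count), n_cross)
  n_prod <- nrow(enumerate_category_product(d$catalog, "C", "O"))
  expect_equal(sum(b1$reports$C_cross_O$strata$count), n_prod)
  expect_equal(sum(b1$sixway$within_C$count), n_cross)
  ov <- b1$overall
  expect_equal(ov$n_pairs[ov$analysis == "within_C_all_pairs"],
               nrow(enumerate_within_pairs(d$catalog, "C")))
  expect_equal(ov$n_pairs[ov$analysis == "C_cross_O_full_product"], n_prod)
})

test_that("run_pipeline names unknown drugs in its error", {
  f <- fixture_c07_c04()
  bad <- f$ratings
  bad$drug_u[1] <- "ghost_drug"
  bad$drug_u[53] <- "ghost_drug"  # same pair, second rater
  expect_error(run_pipeline(f$catalog, bad), "ghost_drug",
               class = "ddic_domain_error")
})
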