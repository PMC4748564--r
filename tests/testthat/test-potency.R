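test_that("dual Tanimoto handles the worked pairs and degenerate vectors", {
  expect_equal(tanimoto_present(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto_absent(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  x <- c(1, 0, 1, 1)
  expect_equal(tanimoto_present(x, x), 1)
  expect_equal(tanimoto_present(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto_absent(c(0, 0, 1), c(0, 0, 1)), 1)
  expect_equal(tanimoto_absent(c(0, 1), c(1, 0)), 0)

  z <- tanimoto_present(c(0, 0), c(0, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  o <- tanimoto_absent(c(1, 1), c(1, 1))
  expect_equal(as.numeric(o), 0)
  expect_true(attr(o, "degenerate"))

  expect_error(tanimoto_present(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(tanimoto_present(c(1, 2), c(1, 0)), "binary")
})

test_that("both similarities are symmetric and ts0 is ts1 on complements", {
  set.seed(303)
  for (k in 1:200) {
    n <- sample(4:24, 1)
    x <- rbinom(n, 1, runif(1))
    y <- rbinom(n, 1, runif(1))
    expect_identical(tanimoto_present(x, y), tanimoto_present(y, x))
    expect_identical(tanimoto_absent(x, y), tanimoto_absent(y, x))
    expect_identical(as.numeric(tanimoto_absent(x, y)),
                     as.numeric(tanimoto_present(1 - x, 1 - y)))
  }
})

test_that("nearest similarities match exhaustive enumeration", {
  set.seed(404)
  for (k in 1:50) {
    n_ref <- sample(4:20, 1)
    n_bit <- sample(4:16, 1)
    refs <- random_dataset(ceiling(n_ref / 2), floor(n_ref / 2), n_bit,
                           p = runif(1, 0.2, 0.8))
    q <- rbinom(n_bit, 1, 0.5)
    got <- nearest_similarities(q, refs)
    want <- brute_nearest(q, refs$matrix, refs$labels)
    expect_equal(got$ha_ts1, want$ha_ts1)
    expect_equal(got$ha_ts0, want$ha_ts0)
    expect_equal(got$hn_ts1, want$hn_ts1)
    expect_equal(got$hn_ts0, want$hn_ts0)
    expect_equal(got$potency, want$potency)
  }
})

test_that("identity and symmetric reference sets behave as expected", {
  m <- rbind(A1 = c(1, 0, 1, 0), A2 = c(0, 1, 1, 1), I1 = c(0, 0, 0, 1))
  colnames(m) <- paste0("F", 1:4)
  refs <- labeled_dataset(m, c("active", "active", "inactive"))
  q <- c(1, 0, 1, 0)
  res <- nearest_similarities(q, refs)
  expect_equal(res$ha_ts1, 1)
  expect_equal(res$nearest_active_id, "A1")

  # one active and one inactive both equal to the query: potency 0
  m2 <- rbind(A = c(1, 1, 0), I = c(1, 1, 0))
  colnames(m2) <- paste0("F", 1:3)
  refs2 <- labeled_dataset(m2, c("active", "inactive"))
  expect_equal(nearest_similarities(c(1, 1, 0), refs2)$potency, 0)
})

test_that("exclusion removes self-matches and empty classes error", {
  set.seed(11)
  refs <- random_dataset(5, 5, 12)
  q <- refs$matrix["m1", ]
  with_self <- nearest_similarities(q, refs)
  expect_equal(with_self$ha_ts1, 1)
  without <- nearest_similarities(q, refs, exclude_id = "m1")
  expect_lte(without$ha_ts1, 1)
  expect_false(identical(without$nearest_active_id, "m1"))

  one_act <- subset_molecules(refs, c("m1", "m6", "m7"))
  expect_error(nearest_similarities(q, one_act, exclude_id = "m1"),
               "no active")
})

test_that("potency arithmetic, bounds and label-swap antisymmetry hold", {
  expect_equal(potency(1.0, 0.8, 0.4, 0.3), 0.6)
  expect_equal(potency(0.3, 0.9, 0.3, 0.9), 0)
  expect_equal(potency(0, 0, 1, 1), -1)
  expect_error(potency(1.2, 0, 0, 0), "\\[0, 1\\]")

  set.seed(505)
  for (k in 1:50) {
    refs <- random_dataset(4, 4, 10)
    swapped <- labeled_dataset(refs$matrix,
                               ifelse(refs$labels == "active",
                                      "inactive", "active"))
    q <- rbinom(10, 1, 0.5)
    a <- nearest_similarities(q, refs)$potency
    b <- nearest_similarities(q, swapped)$potency
    expect_equal(a, -b)
    expect_gte(a, -1); expect_lte(a, 1)
  }
})

test_that("threshold classification calls the boundary inactive", {
  expect_equal(as.character(classify_potency(0.6)), "active")
  expect_equal(as.character(classify_potency(0)), "inactive")
  expect_equal(as.character(classify_potency(-0.2, threshold = -0.3)),
               "active")
})
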