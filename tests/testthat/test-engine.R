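# Scheme generation, scoring, standardisation, preselection, final draw.

test_that("scheme counting is an exact binomial coefficient", {
  expect_identical(count_schemes(14, 7), 3432)
  expect_identical(count_schemes(15, 5), 3003)
  expect_identical(count_schemes(4, 2), 6)
  expect_identical(count_schemes(9, 0), 1)
  expect_identical(count_schemes(9, 9), 1)
  expect_identical(count_schemes(30, 15), choose(30, 15))
  expect_error(count_schemes(4, 5), class = "ccr_bad_spec")
})

test_that("sampled schemes respect arm sizes, pre-assignments and the seed", {
  tab <- synth_dataset(profile = "tds1-like", seed = 3)
  cfg <- generation_config(allocation_ratio = 0.5, n_schemes = 500, seed = 9)
  ss <- generate_schemes(tab, cfg)
  expect_true(all(rowSums(ss$labels == "A") == 7))
  expect_true(all(ss$labels %in% c("A", "B")))
  expect_false(any(duplicated(apply(ss$labels, 1, paste, collapse = ""))))
  # identical config -> identical set
  ss2 <- generate_schemes(tab, cfg)
  expect_identical(ss$labels, ss2$labels)

  # two units pre-assigned to A: every scheme honours them with 5 more As
  tab$fixed[1:2] <- "A"
  ssf <- generate_schemes(tab, cfg)
  expect_true(all(ssf$labels[, 1:2] == "A"))
  expect_true(all(rowSums(ssf$labels[, -(1:2)] == "A") == 5))
  expect_equal(ssf$coverage$n_possible, count_schemes(12, 5))

  # over-committed arm is refused
  tab$fixed <- c(rep("A", 8), rep("", 6))
  expect_error(generate_schemes(tab, cfg), class = "ccr_capacity")
})

test_that("allocation ratio one third on 15 units gives a 5:10 split", {
  tab <- synth_dataset(profile = "tds2-like", seed = 3)
  ss <- generate_schemes(tab, generation_config(allocation_ratio = 1 / 3,
                                                n_schemes = 50, seed = 1))
  expect_true(all(rowSums(ss$labels == "A") == 5))
  expect_equal(ss$coverage$n_possible, 3003)
})

test_that("enumeration yields all distinct schemes in a fixed order and respects the cap", {
  tab <- unit_table(ids = paste0("u", 1:4),
                    values = data.frame(x = c(1, 2, 3, 4)),
                    variables = list(variable_spec("x", "integer")))
  cfg <- generation_config(allocation_ratio = 0.5, mode = "enumerate")
  ss <- generate_schemes(tab, cfg)
  expect_equal(nrow(ss$labels), 6)
  expect_equal(ss$coverage$fraction, 1)
  expect_false(any(duplicated(apply(ss$labels, 1, paste, collapse = ""))))
  # lexicographic in the positions of A: first scheme is AABB, last BBAA
  expect_equal(unname(ss$labels[1, ]), c("A", "A", "B", "B"))
  expect_equal(unname(ss$labels[6, ]), c("B", "B", "A", "A"))
  cfg_cap <- generation_config(allocation_ratio = 0.5, mode = "enumerate",
                               enumeration_cap = 5)
  expect_error(generate_schemes(tab, cfg_cap), class = "ccr_cap_exceeded")
})

test_that("totals are the weighted sum of contributions (isolation, additivity, linearity)", {
  tab <- small_table()
  ss <- generate_schemes(tab, generation_config(0.5, mode = "enumerate"))
  ss <- score_schemes(ss, tab)
  expect_equal(ss$totals, as.numeric(rowSums(ss$contributions)))

  w_iso <- c(bin = 0, cat = 1, int = 0, con = 0)
  ss_iso <- score_schemes(ss, tab, weights = w_iso)
  expect_equal(ss_iso$totals, unname(ss_iso$contributions[, "cat"]))

  w_dbl <- c(bin = 2, cat = 1, int = 1, con = 1)
  ss_dbl <- score_schemes(ss, tab, weights = w_dbl)
  expect_equal(ss_dbl$totals,
               ss$totals + unname(ss$contributions[, "bin"]),
               tolerance = 1e-12)
})

test_that("mirror schemes score identically under equal arm sizes", {
  tab <- small_table()
  ss <- generate_schemes(tab, generation_config(0.5, mode = "enumerate"))
  ss <- score_schemes(ss, tab)
  keys <- apply(ss$labels, 1, paste, collapse = "")
  mirror <- apply(ss$labels, 1, function(r)
    paste(ifelse(r == "A", "B", "A"), collapse = ""))
  pair <- match(mirror, keys)
  expect_false(anyNA(pair))
  expect_equal(ss$contributions, ss$contributions[pair, ], tolerance = 1e-10)
})

test_that("standardising weights scales each variable's range to [0, 1] and preserves order", {
  tab <- small_table()
  ss <- score_schemes(generate_schemes(tab, generation_config(0.5, mode = "enumerate")), tab)
  w <- standardize_weights(ss)
  ss_std <- score_schemes(ss, tab, weights = w)
  std <- sweep(ss_std$contributions, 2, w, `*`)
  expect_equal(unname(apply(std, 2, max)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(std >= 0 & std <= 1 + 1e-12))
  # positive scaling is order-preserving: sorting by the raw contribution
  # leaves the standardised contribution nondecreasing
  for (v in colnames(std))
    expect_false(is.unsorted(std[order(ss$contributions[, v]), v]))

  # a constant variable gets weight 0, with a warning
  tabc <- unit_table(ids = paste0("u", 1:6),
                     values = data.frame(flat = rep(1, 6), x = c(1:5, 9)),
                     variables = list(variable_spec("flat", "integer", "Eucl"),
                                      variable_spec("x", "continuous", "AbCDF")))
  ssc <- suppressWarnings(
    score_schemes(generate_schemes(tabc, generation_config(0.5, mode = "enumerate")), tabc))
  expect_warning(wc <- standardize_weights(ssc), class = "ccr_degenerate")
  expect_equal(unname(wc["flat"]), 0)
})

test_that("preselection picks the best-ranked schemes under each criterion", {
  tab <- small_table()
  ss <- score_schemes(generate_schemes(tab, generation_config(0.5, mode = "enumerate")), tab)
  n <- length(ss$totals)

  expect_equal(length(preselect(ss, "proportion", 1)$selected), n)
  expect_equal(length(preselect(ss, "proportion", 0.1)$selected), ceiling(0.1 * n))

  p10 <- preselect(ss, "count", 10)
  expect_equal(length(p10$selected), 10)
  worst_in <- max(ss$totals[p10$selected])
  expect_true(all(ss$totals[-p10$selected] >= worst_in - 1e-12))

  pmin <- preselect(ss, "max_imbalance", min(ss$totals))
  expect_true(length(pmin$selected) >= 1)
  expect_true(all(ss$totals[pmin$selected] == min(ss$totals)))
  expect_error(preselect(ss, "max_imbalance", min(ss$totals) - 1e-6),
               class = "ccr_empty_selection")
  expect_error(preselect(ss, "proportion", 0), class = "ccr_bad_spec")
})

test_that("the final draw is reproducible and uniform over the preselection", {
  tab <- small_table()
  ss <- score_schemes(generate_schemes(tab, generation_config(0.5, mode = "enumerate")), tab)
  p1 <- preselect(ss, "count", 1)
  expect_equal(choose_final(p1, seed = 5)$scheme_id, p1$selected[1])

  p4 <- preselect(ss, "count", 4)
  expect_equal(choose_final(p4, seed = 123)$scheme_id,
               choose_final(p4, seed = 123)$scheme_id)
  expect_error(choose_final(p4), class = "ccr_bad_spec")

  draws <- vapply(1:10000, function(s) choose_final(p4, seed = s)$scheme_id, 0L)
  freq <- as.numeric(table(factor(draws, levels = p4$selected))) / 10000
  expect_true(all(freq >= 0.23 & freq <= 0.27))
})

test_that("the imbalance ECDF steps through the distinct totals and ends at one", {
  tab <- small_table()
  ss <- score_schemes(generate_schemes(tab, generation_config(0.5, mode = "enumerate")), tab)
  e <- imbalance_ecdf(ss)
  expect_true(all(diff(e$total) > 0))
  expect_true(all(diff(e$cum_fraction) > 0))
  expect_equal(e$cum_fraction[nrow(e)], 1)
  expect_equal(sum(e$count), length(ss$totals))
  expect_equal(nrow(e), length(unique(ss$totals)))
})

test_that("sampling the small fixture heavily recovers the full enumeration", {
  tab <- small_table()
  full <- score_schemes(generate_schemes(tab, generation_config(0.5, mode = "enumerate")), tab)
  samp <- score_schemes(
    generate_schemes(tab, generation_config(0.5, n_schemes = 2000, seed = 2)), tab)
  expect_lte(samp$coverage$n_unique, full$coverage$n_possible)
  # 2000 draws over 70 schemes: coupon-collector-complete with high probability
  expect_equal(sort(unique(samp$totals)), sort(unique(full$totals)),
               tolerance = 1e-12)
})
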