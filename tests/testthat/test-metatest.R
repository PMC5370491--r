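mk_metadata <- function() {
  data.frame(
    species = rep(c("a", "b", "c", "d"), each = 1),
    individual = paste0(c("a", "b", "c", "d"), "1"),
    technician = c("t1", "t1", "t2", "t2"),
    entry_date = as.Date(c("2011-01-10", "2011-02-19", "2011-01-10",
                           "2011-03-01")),
    shipment_date = as.Date(c("2011-04-10", "2011-04-10", "2011-04-10",
                              "2011-09-27")),
    center = c("SC1", "SC1", "SC2", "SC1"),
    flowcell = c("F1", "F1", "F9", "F3"),
    lane = c(1, 2, 1, 1), stringsAsFactors = FALSE)
}

test_that("pair predictors: overlap arithmetic and shipment semantics", {
  md <- mk_metadata()
  pred <- pair_predictors(md)
  pick <- function(x, y, col)
    pred[pred$species1 == x & pred$species2 == y, col]
  # overlapping periods [Jan10, Apr10] and [Feb19, Apr10] -> 50 days
  expect_equal(pick("a", "b", "lab_overlap"), 50)
  # disjoint periods give zero
  md2 <- md
  md2$entry_date[4] <- as.Date("2011-05-01")
  expect_equal(pair_predictors(md2)[3, "lab_overlap"], 0)
  # same date but different centers is not a shared shipment
  expect_false(pick("a", "c", "same_shipment"))
  expect_true(pick("a", "b", "same_shipment"))
  expect_true(pick("a", "b", "same_flowcell"))
  expect_false(pick("a", "b", "same_lane"))
  # nesting: same_lane implies same_flowcell implies same_shipment
  expect_true(all(with(pred, !same_lane %in% TRUE |
                         same_flowcell %in% TRUE)))
  expect_true(all(with(pred, !same_flowcell %in% TRUE | same_shipment)))
})

test_that("periods example from the generic overlap definition", {
  md <- data.frame(
    species = c("x", "y"), individual = c("x1", "y1"),
    technician = "t1",
    entry_date = as.Date(c("2011-01-10", "2011-02-19")),
    shipment_date = as.Date(c("2011-04-10", "2011-06-09")),
    center = "SC1", stringsAsFactors = FALSE)
  # [day 10, day 100] vs [day 50, day 150] -> 50
  expect_equal(pair_predictors(md)$lab_overlap, 50)
})

mk_M <- function(m) {
  structure(list(m = m, reads = abs(m), min_reads = 1,
                 p = sum(m == 1, na.rm = TRUE) / sum(!is.na(m))),
            class = "contamination_matrix")
}

test_that("observed statistic averages predictor values over contaminated cells", {
  md <- mk_metadata()
  pred <- pair_predictors(md)
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- NA_integer_
  m["a", "b"] <- 1L  # same shipment
  m["c", "d"] <- 1L  # different shipment
  m["d", "a"] <- 1L  # different shipment
  M <- mk_M(m)
  expect_equal(observed_statistic(M, pred, "same_shipment")$observed,
               1 / 3)
  expect_equal(observed_statistic(M, pred, "same_technician")$observed,
               2 / 3)
  expect_error(observed_statistic(mk_M(matrix(0L, 2, 2,
                                              dimnames = list(c("a", "b"),
                                                              c("a", "b")))),
                                  pred, "same_shipment"),
               "no contaminated pairs")
})

test_that("unconditional randomisation preserves missingness and the mean", {
  md <- mk_metadata()
  pred <- pair_predictors(md)
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- NA_integer_
  m["a", "c"] <- NA_integer_
  m["a", "b"] <- m["b", "a"] <- m["c", "d"] <- 1L
  M <- mk_M(m)
  n1 <- randomize_unconditional(M, pred, "same_shipment", reps = 500,
                                seed = 31)
  n2 <- randomize_unconditional(M, pred, "same_shipment", reps = 500,
                                seed = 31)
  expect_identical(n1, n2)  # seeded reproducibility
  expect_equal(length(n1), 500)
  # Bernoulli mean: expected ones per replicate = p * non-missing cells
  set.seed(31)
  draws <- matrix(rbinom(500 * sum(!is.na(m)), 1, M$p), 500)
  expect_equal(mean(rowSums(draws)), M$p * sum(!is.na(m)),
               tolerance = 0.15)
})

test_that("conditional randomisation respects stratum probabilities", {
  md <- mk_metadata()
  pred <- pair_predictors(md)
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- NA_integer_
  # ones only on the same-shipment pair (a, b)
  m["a", "b"] <- m["b", "a"] <- 1L
  M <- mk_M(m)
  nc <- randomize_conditional(M, pred, "same_technician",
                              condition_on = "same_shipment",
                              reps = 400, seed = 7)
  ps <- attr(nc, "stratum_probs")
  # stratum without observed ones stays empty -> all replicates drawn
  # from the same-shipment stratum where same_technician is always 1
  expect_equal(unname(ps[["|0"]]), 0)
  expect_true(all(nc[!is.na(nc)] == 1))
})

test_that("empirical p-values use the add-one estimator", {
  nulls <- 1:1000 / 1000
  expect_equal(empirical_pvalue(2, nulls), 1 / 1001)
  expect_equal(empirical_pvalue(0, nulls), 1)
  expect_equal(empirical_pvalue(0, nulls, tail = "lower"), 1 / 1001)
  expect_lt(abs(empirical_pvalue(0.5, nulls) - 0.5), 0.01)
})

test_that("stratified probability grid reproduces printed-count arithmetic", {
  # disjoint tiers realising cumulative counts 451 >= 247 >= 159
  mk <- function(center, lab, n, k)
    data.frame(center = center, lab = lab,
               connected = rep(c(TRUE, FALSE), c(k, n - k)))
  pairs <- rbind(
    mk("-", "-", 3368, 3), mk("-", "+", 360, 0),
    mk("+", "-", 204, 11), mk("+", "+", 24, 0),
    mk("++", "-", 88, 9), mk("++", "+", 18, 3),
    mk("+++", "-", 159, 69), mk("+++", "+", 86, 49))
  tab <- pair_probability_table(pairs, cumulative = TRUE)
  g <- function(center, lab)
    tab[tab$center == center & tab$lab == lab, ]
  expect_equal(g("+", "-")$n_pairs, 451)
  expect_equal(g("+", "-")$n_connected, 89)
  expect_equal(round(g("+", "-")$probability, 2), 0.20)
  expect_equal(round(g("-", "-")$probability, 5), 0.00089)
  expect_equal(round(g("++", "-")$probability, 2), 0.32)
  expect_equal(round(g("+++", "-")$probability, 2), 0.43)
  # nested tier totals are monotone
  expect_true(g("+++", "-")$n_pairs <= g("++", "-")$n_pairs)
  expect_true(g("++", "-")$n_pairs <= g("+", "-")$n_pairs)
  # empty cells print NA
  tab0 <- pair_probability_table(mk("+", "-", 5, 0))
  expect_true(is.na(tab0[tab0$center == "+++" & tab0$lab == "+",
                         "probability"]))
})

test_that("one-species-per-stratum subsampling is seeded and exhaustive", {
  md <- simulate_metadata(n_species = 25, n_technicians = 3, seed = 5)
  s1 <- subsample_one_per_stratum(md, seed = 2)
  s2 <- subsample_one_per_stratum(md, seed = 2)
  expect_identical(s1, s2)
  # each retained stratum contributes exactly one species
  sub <- md[md$species %in% s1, ]
  st <- unique(sub[, c("species", "technician", "shipment_date")])
  expect_false(any(duplicated(paste(st$technician, st$shipment_date))))
  # single-stratum input keeps exactly one species
  md1 <- md
  md1$technician <- "t1"
  md1$shipment_date <- md1$shipment_date[1]
  expect_length(subsample_one_per_stratum(md1, seed = 2), 1)
})
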