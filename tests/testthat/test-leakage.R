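test_that("error matrix is the row-normalised h_mono table", {
  rec <- data.frame(
    species = "s", individual = "i", contig = "c", pos = 1:4,
    major = "A", minor = c("C", "C", "G", "T"),
    class = "monoallelic", z = NA_character_, r_z = NA_integer_,
    stringsAsFactors = FALSE)
  em <- error_matrix(rec)
  expect_equal(em$P["A", "C"], 0.5)
  expect_equal(em$P["A", "G"], 0.25)
  expect_equal(em$P["A", "T"], 0.25)
  expect_equal(sum(em$P["A", ]), 1)
  expect_true(all(em$undefined[c("C", "G", "T")]))
  # all-undefined input is a hard error
  expect_error(error_matrix(rec[0, ]), "undefined")
})

test_that("uniform simulated errors give near-uniform off-diagonals", {
  rec <- simulate_error_records(1e5, seed = 7)
  em <- error_matrix(rec)
  offdiag <- em$P[row(em$P) != col(em$P)]
  expect_true(all(abs(offdiag - 1 / 3) < 0.02))
})

test_that("q_obs, q_exp and lambda reproduce the fictive example", {
  rec <- extract_homo_quartets(fictive_quartets())
  qo <- q_observed(rec)
  expect_equal(qo$h_bi, 3)
  expect_equal(qo$q_obs, 2 / 3)
  em <- error_matrix(rec)
  qe <- q_expected(rec, em)
  # P(A,C) = P(A,G) = 1/2 from the two monoallelic records; z = C, T, T
  expect_equal(qe$q_exp, (0.5 + 0 + 0) / 3)
  expect_equal(lambda_index(qo$q_obs, qe$q_exp), 3)
})

test_that("q_exp equals the mean of P(a, z) over records (Eq. identity)", {
  sim <- simulate_quartet_dataset(n_positions = 4000, gamma = 0.1,
                                  seed = 5)
  rec <- extract_homo_quartets(sim$quartets)
  em <- error_matrix(rec)
  qe <- q_expected(rec, em)
  bi <- rec[rec$class == "biallelic" & !is.na(rec$z), ]
  bi <- bi[!em$undefined[match(bi$major, c("A", "C", "G", "T"))], ]
  direct <- mean(em$P[cbind(match(bi$major, c("A", "C", "G", "T")),
                            match(bi$z, c("A", "C", "G", "T")))])
  expect_equal(qe$q_exp, direct, tolerance = 1e-12)
})

test_that("lambda edge cases and sign behaviour", {
  expect_equal(lambda_index(1 / 3, 1 / 3), 0)
  expect_equal(lambda_index(2 / 3, 1 / 3), 1)
  expect_error(lambda_index(0.5, 0), "positive")
  # leakage drives lambda above zero
  sim <- simulate_quartet_dataset(n_positions = 4000, gamma = 0.1,
                                  seed = 11)
  rec <- extract_homo_quartets(sim$quartets)
  em <- error_matrix(rec)
  lam <- lambda_index(q_observed(rec)$q_obs, q_expected(rec, em)$q_exp)
  expect_gt(lam, 0.5)
})

test_that("lambda increases with the generating leakage rate", {
  lams <- sapply(c(0, 0.05, 0.1), function(g) {
    sim <- simulate_quartet_dataset(n_positions = 4000, gamma = g,
                                    seed = 13)
    rec <- extract_homo_quartets(sim$quartets)
    em <- error_matrix(rec)
    lambda_index(q_observed(rec)$q_obs, q_expected(rec, em)$q_exp)
  })
  expect_true(all(diff(lams) > 0))
})

test_that("between-group lambda-prime keeps only within-group-monoallelic sites", {
  q <- fictive_quartets()
  groups <- c(ind1 = "g1", ind2 = "g1", ind3 = "g2", ind4 = "g2")
  res <- suppressWarnings(lambda_between_groups(q, groups))
  # pos 3 and 4 are not monoallelic within ind1's group; only pos 5 is
  expect_equal(res$h, 1)
  expect_equal(res$q_obs, 1)
  # a single group makes the statistic undefined
  expect_error(lambda_between_groups(q, setNames(rep("g1", 4),
                                                 names(groups))),
               "single group")
})

test_that("within-group leakage leaves lambda-prime near zero while lambda is high", {
  # two cohorts on a shared reference, simulated independently: leakage
  # exists only within cohorts, so between-shipment leakage is absent
  simA <- simulate_quartet_dataset(n_individuals = 4, n_positions = 6000,
                                   gamma = 0.15, seed = 17,
                                   species = "sp")
  simB <- simulate_quartet_dataset(n_individuals = 4, gamma = 0.15,
                                   seed = 18, species = "sp",
                                   cds = simA$truth$cds)
  qB <- simB$quartets
  qB$individual <- sub("ind0", "ind1", qB$individual)
  q <- rbind(simA$quartets, qB)
  groups <- setNames(rep(c("g1", "g2"), each = 4),
                     c(unique(simA$quartets$individual),
                       unique(qB$individual)))
  rec <- extract_homo_quartets(q)
  em <- error_matrix(rec)
  lam <- lambda_index(q_observed(rec)$q_obs, q_expected(rec, em)$q_exp)
  lp <- lambda_between_groups(q, groups)
  expect_gt(lam, 0.1)
  expect_lt(abs(lp$lambda_prime), 0.1)
  expect_lt(lp$lambda_prime, lam / 2)
})

test_that("error-class summary pools strand-ambiguous classes", {
  rec <- data.frame(
    species = "s", individual = "i", contig = "c", pos = 1:6,
    major = c("A", "T", "A", "C", "G", "C"),
    minor = c("C", "G", "G", "T", "A", "G"),
    class = "monoallelic", z = NA_character_, r_z = NA_integer_,
    stringsAsFactors = FALSE)
  s <- error_class_summary(error_matrix(rec))
  expect_equal(unname(s$class_counts[["AC_TG"]]), 2)  # A->C pooled with T->G
  expect_equal(unname(s$class_counts[["AG_TC"]]), 1)
  expect_equal(unname(s$class_counts[["GA_CT"]]), 2)  # G->A pooled with C->T
  expect_equal(unname(s$class_counts[["CG_GC"]]), 1)
  expect_equal(sum(s$class_counts), 6)
})

test_that("ts/tv ratio is 0.5 under uniform error and flagged infinite without transversions", {
  s <- error_class_summary(error_matrix(simulate_error_records(1e5,
                                                               seed = 2)))
  expect_lt(abs(s$ts_tv_ratio - 0.5), 0.02)
  expect_false(s$ts_tv_infinite)
  # all-transition law
  law <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  law["A", "G"] <- law["G", "A"] <- law["C", "T"] <- law["T", "C"] <- 1
  s2 <- error_class_summary(error_matrix(
    simulate_error_records(2000, error_law = law, seed = 3)))
  expect_true(is.infinite(s2$ts_tv_ratio))
  expect_true(s2$ts_tv_infinite)
})

test_that("per-species leakage report carries counts and the min-h_bi rule", {
  sim <- simulate_quartet_dataset(n_positions = 3000, gamma = 0.05,
                                  seed = 23)
  rep_ <- leakage_report(sim$quartets, min_hbi = 50)
  expect_equal(nrow(rep_), 1)
  expect_gt(rep_$h_bi, 50)
  expect_false(is.na(rep_$lambda))
  rep2 <- leakage_report(sim$quartets, min_hbi = 1e6)
  expect_true(is.na(rep2$lambda))
  # JSON round trip
  f <- tempfile(fileext = ".json")
  write_leakage_json(rep_, f)
  js <- jsonlite::read_json(f)
  expect_equal(js[[1]]$species, rep_$species[1])
  expect_equal(js[[1]]$h_bi, rep_$h_bi[1])
})
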