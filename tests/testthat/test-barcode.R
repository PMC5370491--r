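test_that("pairwise divergence: identity, single differences, species minimum", {
  p <- barcode_panel(c(strrep("ACGT", 10),
                       strrep("ACGT", 10),
                       paste0("T", substr(strrep("ACGT", 10), 2, 40))),
                     id = c("a1", "a2", "b1"),
                     species = c("spA", "spA", "spB"))
  d <- pairwise_divergence(p)
  expect_equal(d$D["spA", "spA"], 0)
  expect_equal(d$D["spA", "spB"], 1 / 40)
  expect_equal(d$D, t(d$D))
  # species with multiple sequences: pair value is the minimum
  p2 <- barcode_panel(c(strrep("A", 40), strrep("C", 40), strrep("A", 40)),
                      species = c("spA", "spA", "spB"))
  expect_equal(pairwise_divergence(p2)$D["spA", "spB"], 0)
})

test_that("divergence agrees with ape's raw pairwise-deletion distance", {
  set.seed(8)
  seqs <- replicate(6, random_seq(60))
  p <- barcode_panel(seqs, species = sprintf("sp%d", 1:6))
  D <- pairwise_divergence(p)$D
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  names(bin) <- sprintf("sp%d", 1:6)
  Dape <- as.matrix(ape::dist.dna(bin, model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(D[rownames(Dape), colnames(Dape)]), unname(Dape),
               tolerance = 1e-12)
})

test_that("ambiguous bases reduce the comparable-site count", {
  s1 <- paste0(strrep("N", 25), strrep("A", 15))  # 15 comparable < 50%
  s2 <- strrep("A", 40)
  p <- barcode_panel(c(s1, s2), species = c("spA", "spB"))
  d <- pairwise_divergence(p)
  expect_equal(d$D["spA", "spB"], 0)
  expect_true(d$unreliable["spA", "spB"])
})

test_that("diagnostic mask uses a strict threshold and the 10% variant", {
  p <- barcode_panel(c(strrep("A", 100),
                       paste0(strrep("C", 4), strrep("A", 96)),
                       paste0(strrep("C", 7), strrep("A", 93))),
                     species = c("s1", "s2", "s3"))
  d <- pairwise_divergence(p)
  m5 <- diagnostic_mask(d, 0.05)
  expect_false(m5["s1", "s2"])   # 4% divergent: non-diagnostic
  expect_true(m5["s1", "s3"])    # 7%: diagnostic
  m10 <- diagnostic_mask(d, 0.10)
  expect_false(m10["s1", "s3"])  # flips in [0.05, 0.10)
  # exactly at the threshold counts as diagnostic (strict "<")
  p2 <- barcode_panel(c(strrep("A", 100),
                        paste0(strrep("C", 5), strrep("A", 95))),
                      species = c("x", "y"))
  expect_true(diagnostic_mask(pairwise_divergence(p2), 0.05)["x", "y"])
})

test_that("read mapping finds exact substrings and honours the tolerance", {
  set.seed(2)
  refs <- replicate(5, random_seq(120))
  p <- barcode_panel(refs, species = sprintf("sp%d", 1:5))
  read <- substr(refs[3], 31, 80)
  h <- map_read(read, p)
  expect_equal(h$species, "sp3")
  expect_equal(h$mismatches, 0)
  # reverse strand
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(read, "")[[1]]),
                                     collapse = ""))
  h2 <- map_read(rc, p)
  expect_equal(h2$species, "sp3")
  expect_equal(h2$strand, "-")
  # three mismatches exceed the tolerance of 2 (length > 50)
  long <- substr(refs[2], 1, 75)
  mutated <- long
  substr(mutated, 1, 1) <- "N"; substr(mutated, 30, 30) <- "N"
  substr(mutated, 60, 60) <- "N"
  expect_null(map_read(mutated, p))
  # short reads are skipped
  expect_null(map_read(substr(refs[1], 1, 20), p))
})

test_that("mapper agrees with the brute-force all-offset oracle", {
  set.seed(5)
  refs <- replicate(20, random_seq(120))
  p <- barcode_panel(refs, species = sprintf("sp%02d", 1:20))
  for (k in 1:40) {
    src <- sample(20, 1)
    read <- substr(refs[src], 20, 69)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(50, nmut)
      ch <- strsplit(read, "")[[1]]
      ch[at] <- sapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1))
      read <- paste(ch, collapse = "")
    }
    oracle <- oracle_best_mismatch(read, refs, 1)
    h <- map_read(read, p)
    if (all(is.na(oracle))) {
      expect_null(h)
    } else {
      best <- min(oracle, na.rm = TRUE)
      expect_equal(h$mismatches, best)
      expect_setequal(h$tie_set, which(oracle == best))
    }
  }
  # forced tie: identical references -> uniform seeded choice
  pt <- barcode_panel(c(refs[1], refs[1]), species = c("a", "b"))
  set.seed(42)
  ht <- map_read(substr(refs[1], 1, 50), pt)
  expect_setequal(ht$tie_set, 1:2)
})

test_that("sample screening accounts prevalences and the divergence rule", {
  set.seed(77)
  r_exp <- random_seq(120)
  # close relative: 3 substitutions (2.5%) inside the first 50 bases so
  # reads from there separate the two species
  ch <- strsplit(r_exp, "")[[1]]
  for (at in c(5, 15, 25))
    ch[at] <- setdiff(c("A", "C", "G", "T"), ch[at])[1]
  r_close <- paste(ch, collapse = "")
  refs <- c(r_exp, r_close, random_seq(120))
  p <- barcode_panel(refs, species = c("exp", "close", "far"))
  d <- pairwise_divergence(p)
  mask <- diagnostic_mask(d)
  expect_false(mask["exp", "close"])  # 2.5% divergent
  reads <- c(substr(refs[1], 1, 50),            # expected hit
             substr(refs[1], 3, 52),            # expected hit
             substr(refs[3], 10, 59),           # unexpected (diagnostic)
             substr(refs[2], 1, 40))            # too short, skipped
  set.seed(9)
  ht <- screen_sample(reads, p, "exp", mask, total_reads = 2e6)
  expect_equal(ht$expected_hits, 2L)
  expect_equal(ht$unexpected_hits, 1L)
  expect_equal(ht$expected_prevalence, 1)      # 2 hits / 2M reads * 1e6
  expect_equal(ht$unexpected_prevalence, 0.5)
  expect_false(ht$dubious)
  # 10 expected hits in 2 million reads -> prevalence 5 per million
  ht2 <- screen_sample(rep(substr(refs[1], 1, 50), 10), p, "exp", mask,
                       total_reads = 2e6)
  expect_equal(ht2$expected_prevalence, 5)
  # hits to a close species attest nothing
  ht3 <- screen_sample(substr(refs[2], 1, 50), p, "exp", mask,
                       total_reads = 1e6)
  expect_equal(ht3$unexpected_hits, 0L)
  expect_equal(ht3$nondiagnostic_hits, 1L)
  # unexpected/expected ratio > 1 flags the sample
  ht4 <- screen_sample(rep(substr(refs[3], 1, 50), 3), p, "exp", mask,
                       total_reads = 1e6)
  expect_true(ht4$dubious)
  expect_error(screen_sample(reads, p, "exp", mask, total_reads = 0),
               "zero total reads")
})

test_that("contamination matrix honours min_reads and the mask", {
  mk_ht <- function(sp, hits) {
    structure(list(species_hits = hits, expected_species = sp),
              class = "hit_table")
  }
  mask <- matrix(TRUE, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  mask["b", "c"] <- mask["c", "b"] <- FALSE
  diag(mask) <- FALSE
  hts <- list(mk_ht("a", c(a = 100L, b = 1L, c = 0L)),
              mk_ht("b", c(a = 5L, b = 200L, c = 7L)),
              mk_ht("c", c(a = 0L, b = 0L, c = 50L)))
  M1 <- build_contamination_matrix(hts, mask, min_reads = 1)
  expect_equal(M1$m["b", "a"], 1L)      # single read suffices
  expect_equal(M1$m["a", "b"], 1L)
  expect_true(is.na(M1$m["c", "b"]))    # non-diagnostic pair masked
  expect_true(is.na(M1$m["a", "a"]))
  expect_equal(M1$p, 2 / 4)
  M10 <- build_contamination_matrix(hts, mask, min_reads = 10)
  expect_equal(M10$m["b", "a"], 0L)     # below the ten-read bar
  expect_equal(M10$p, 0)
})

test_that("clean simulated samples yield no unexpected diagnostic hits", {
  exp0 <- simulate_barcode_experiment(n_species = 8, n_close_pairs = 1,
                                      reads_per_sample = 60,
                                      error_rate = 0,
                                      scenario = list(link = "none"),
                                      seed = 14)
  mask <- diagnostic_mask(pairwise_divergence(exp0$panel))
  set.seed(1)
  hts <- lapply(exp0$samples, function(s)
    screen_sample(s$reads, exp0$panel, s$species, mask,
                  total_reads = s$total_reads))
  expect_true(all(vapply(hts, `[[`, 0L, "unexpected_hits") == 0L))
})
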