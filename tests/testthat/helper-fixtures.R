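# Shared fixtures and independent oracles, built in code.

# A fictive dataset of four individuals and five positions. Individual
# ind1 carries a homo-quartet at every position. pos 1-2 are
# monoallelic; pos 3-5 are biallelic; at pos 3 the ind1 minor state (G)
# differs from the other segregating allele (C), at pos 4 and 5 it
# matches (T), so q_obs = 2/3.
fictive_quartets <- function() {
  rows <- list(
    # pos 1: monoallelic A, ind1 error C
    c(1, 1, 45, 1, 0, 0), c(2, 1, 50, 0, 0, 0),
    c(3, 1, 50, 0, 0, 0), c(4, 1, 50, 0, 0, 0),
    # pos 2: monoallelic A, ind1 error G
    c(1, 2, 45, 0, 1, 0), c(2, 2, 50, 0, 0, 0),
    c(3, 2, 50, 0, 0, 0), c(4, 2, 50, 0, 0, 0),
    # pos 3: biallelic A/C, ind1 minor G (third base)
    c(1, 3, 45, 0, 1, 0), c(2, 3, 25, 25, 0, 0),
    c(3, 3, 0, 50, 0, 0), c(4, 3, 50, 0, 0, 0),
    # pos 4: biallelic A/T, ind1 minor T = z
    c(1, 4, 44, 0, 0, 1), c(2, 4, 30, 0, 0, 28),
    c(3, 4, 0, 0, 0, 55), c(4, 4, 60, 0, 0, 0),
    # pos 5: biallelic A/T, ind1 minor T = z
    c(1, 5, 44, 0, 0, 1), c(2, 5, 50, 0, 0, 0),
    c(3, 5, 25, 0, 0, 30), c(4, 5, 0, 0, 0, 60))
  m <- do.call(rbind, rows)
  data.frame(species = "fict", individual = sprintf("ind%d", m[, 1]),
             contig = "c1", pos = m[, 2], nA = m[, 3], nC = m[, 4],
             nG = m[, 5], nT = m[, 6], stringsAsFactors = FALSE)
}

# brute-force quartet probability: enumerate ordered genotype pairs
# (f_y f_z each; heterozygotes arise twice, giving the factor 2) and
# all 4^r read-call sequences
oracle_quartet_prob <- function(counts, f, eps_ts, eps_tv, gamma = 0,
                                fprime = NULL) {
  r <- sum(counts)
  tot <- 0
  for (y in 1:4) for (z in 1:4) {
    w <- f[y] * f[z]
    if (w == 0) next
    p <- suppressWarnings(
      read_state_probs(c(BASES[y], BASES[z]), eps_ts, eps_tv, gamma,
                       fprime))
    if (r == 0) { tot <- tot + w; next }
    seqs <- as.matrix(expand.grid(rep(list(1:4), r)))
    pr <- apply(seqs, 1, function(s) {
      cnt <- tabulate(s, 4)
      if (all(cnt == counts)) prod(p[s]) else 0
    })
    tot <- tot + w * sum(pr)
  }
  tot
}

# brute-force read mapper: best mismatch count per reference over all
# offsets and both strands, integer-coded comparison
oracle_best_mismatch <- function(read, refs, max_mismatch) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  L <- nchar(read)
  vapply(refs, function(ref) {
    best <- Inf
    for (s in c(read, rc(read))) {
      sv <- strsplit(s, "")[[1]]
      rv <- strsplit(ref, "")[[1]]
      for (o in 0:(nchar(ref) - L)) {
        mm <- sum(sv != rv[(o + 1):(o + L)])
        if (mm < best) best <- mm
      }
    }
    if (best <= max_mismatch) best else NA_real_
  }, 0, USE.NAMES = FALSE)
}

# random ACGT sequence
random_seq <- function(n) paste(sample(BASES <- c("A", "C", "G", "T"),
                                       n, replace = TRUE), collapse = "")
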