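# Seeded generators for every input the toolkit consumes, with logged
# ground truth. Leakage is simulated at the read level: a leaked read
# copies the state of one of the *other* individuals' native reads and
# then passes through the error channel again, mirroring the
# read-frequency formulation of the genotype model.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# draw a coding sequence (no stop codons) of length L (multiple of 3)
.random_cds <- function(L) {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  paste(sample(codons, L / 3, replace = TRUE), collapse = "")
}

# vectorised error channel: given true-state indices (1..4) draw called
# states under the ts/tv emission matrix, n[i] reads each; returns an
# N x 4 count matrix
.emit_counts <- function(state, n, E) {
  out <- matrix(0L, length(n), 4)
  for (w in 1:4) {
    sel <- state == w & n > 0
    if (!any(sel)) next
    ns <- n[sel]
    p <- E[w, ]
    # chain of binomials = multinomial draw, vectorised over cells
    left <- ns
    pr <- 1
    cnt <- matrix(0L, length(ns), 4)
    for (x in 1:4) {
      px <- if (pr > 0) min(1, p[x] / pr) else 0
      cnt[, x] <- rbinom(length(ns), left, px)
      left <- left - cnt[, x]
      pr <- pr - p[x]
    }
    out[sel, ] <- out[sel, ] + cnt
  }
  out
}

#' Simulate a quartet dataset with known genotypes and leakage
#'
#' Generates Hardy–Weinberg genotypes over a random coding sequence,
#' then per-read emission with class-specific error rates and, with
#' probability `gamma` per read, replacement by a read state copied from
#' a uniformly chosen native read of the other individuals (contaminant
#' reads pass through the error channel again). Positions are biallelic
#' with probability `prop_polymorphic`; the minor-allele frequency
#' follows the folded neutral-like law (weight proportional to 1/i for
#' minor-allele count i).
#'
#' @param n_individuals number of diploid individuals (>= 2 when
#'   `gamma > 0`).
#' @param n_positions number of positions (rounded up to a codon
#'   multiple).
#' @param coverage mean per-individual coverage (Poisson).
#' @param eps_ts,eps_tv per-read error rates by substitution class.
#' @param gamma per-read leakage probability.
#' @param prop_polymorphic fraction of positions carrying a segregating
#'   alternative allele.
#' @param inbreeding_f probability that an individual's genotype at a
#'   polymorphic position is drawn as fully inbred (homozygote by
#'   descent).
#' @param species species label written into the table.
#' @param cds optional reference coding sequence to simulate on (length
#'   a multiple of 3); overrides `n_positions`. Lets several cohorts
#'   share one reference.
#' @param seed integer seed; same seed, same output.
#' @return list with `quartets` (quartet table), `truth` (list: `cds`,
#'   `genotypes` — position x individual matrix of two-letter strings,
#'   `alt_allele`, `poly_pos`, `leaked` — position x individual leaked
#'   read counts, `params`, `seed`).
#' @export
simulate_quartet_dataset <- function(n_individuals = 6,
                                     n_positions = 20000,
                                     coverage = 60,
                                     eps_ts = 0.003, eps_tv = 0.001,
                                     gamma = 0,
                                     prop_polymorphic = 0.3,
                                     inbreeding_f = 0,
                                     species = "simsp", cds = NULL,
                                     seed = 1) {
  stopifnot(gamma >= 0, gamma <= 1, prop_polymorphic >= 0,
            prop_polymorphic <= 1)
  if (gamma > 0 && n_individuals < 2)
    stop("gamma > 0 requires at least 2 individuals (no leakage source)")
  set.seed(seed)
  if (is.null(cds)) {
    L <- 3 * ceiling(n_positions / 3)
    cds <- .random_cds(L)
  } else {
    if (nchar(cds) %% 3 != 0)
      stop("supplied cds length must be a multiple of 3")
    L <- nchar(cds)
  }
  ref <- base_index(strsplit(cds, "")[[1]])
  E <- error_emission_matrix(eps_ts, eps_tv)

  n_poly <- round(prop_polymorphic * L)
  poly <- sort(sample.int(L, n_poly))
  alt <- rep(NA_integer_, L)
  alt[poly] <- vapply(ref[poly],
                      function(b) sample(setdiff(1:4, b), 1), 0L)
  # folded MAF law: minor count i in 1..n_individuals with weight 1/i
  i_cnt <- sample.int(n_individuals, n_poly, replace = TRUE,
                      prob = 1 / seq_len(n_individuals))
  p_alt <- rep(0, L)
  p_alt[poly] <- i_cnt / (2 * n_individuals)

  # genotypes: number of alt copies per (position, individual)
  nI <- n_individuals
  galt <- matrix(0L, L, nI)
  if (n_poly > 0) {
    p <- matrix(p_alt[poly], n_poly, nI)
    inbred <- matrix(runif(n_poly * nI) < inbreeding_f, n_poly, nI)
    hw <- matrix(rbinom(n_poly * nI, 2, p), n_poly, nI)
    ib <- matrix(2L * rbinom(n_poly * nI, 1, p), n_poly, nI)
    galt[poly, ] <- ifelse(inbred, ib, hw)
  }

  cov <- matrix(rpois(L * nI, coverage), L, nI)
  n_leak <- matrix(rbinom(L * nI, cov, gamma), L, nI)
  n_own <- cov - n_leak

  counts <- array(0L, c(L, nI, 4))
  native <- array(0L, c(L, nI, 4))  # pre-leak reads, the leak source pool
  refm <- matrix(ref, L, nI)
  altm <- matrix(ifelse(is.na(alt), ref, alt), L, nI)
  for (ind in seq_len(nI)) {
    # own reads: pick gametic allele, then error channel
    n_alt_reads <- rbinom(L, n_own[, ind], galt[, ind] / 2)
    n_ref_reads <- n_own[, ind] - n_alt_reads
    cc <- .emit_counts(refm[, ind], n_ref_reads, E) +
      .emit_counts(altm[, ind], n_alt_reads, E)
    native[, ind, ] <- cc
    counts[, ind, ] <- counts[, ind, ] + cc
  }
  if (any(n_leak > 0)) {
    tot_native <- vapply(1:4, function(x) rowSums(native[, , x,
                                                         drop = FALSE]),
                         numeric(L))
    for (ind in seq_len(nI)) {
      if (all(n_leak[, ind] == 0)) next
      pool <- tot_native - native[, ind, ]
      ps <- rowSums(pool)
      # source state of each leaked read ~ pool frequencies
      left <- n_leak[, ind]
      pr <- rep(1, L)
      for (w in 1:4) {
        px <- ifelse(ps > 0, pool[, w] / ifelse(ps > 0, ps, 1), 0.25)
        prob <- ifelse(pr > 0, pmin(1, px / pr), 0)
        nw <- rbinom(L, left, prob)
        left <- left - nw
        pr <- pr - px
        counts[, ind, ] <- counts[, ind, ] + .emit_counts(rep(w, L), nw, E)
      }
    }
  }

  inds <- sprintf("ind%02d", seq_len(nI))
  quartets <- data.frame(
    species = species,
    individual = rep(inds, each = L),
    contig = "cds1",
    pos = rep(seq_len(L), nI),
    nA = as.vector(counts[, , 1]), nC = as.vector(counts[, , 2]),
    nG = as.vector(counts[, , 3]), nT = as.vector(counts[, , 4]),
    stringsAsFactors = FALSE)

  gt_str <- matrix(paste0(
    BASES[ifelse(galt >= 1, altm, refm)],
    BASES[ifelse(galt == 2, altm, refm)]), L, nI,
    dimnames = list(NULL, inds))
  list(quartets = quartets,
       truth = list(cds = cds,
                    genotypes = gt_str,
                    alt_allele = ifelse(is.na(alt), NA_character_,
                                        BASES[ifelse(is.na(alt), 1, alt)]),
                    poly_pos = poly,
                    leaked = n_leak,
                    params = list(n_individuals = nI, n_positions = L,
                                  coverage = coverage, eps_ts = eps_ts,
                                  eps_tv = eps_tv, gamma = gamma,
                                  prop_polymorphic = prop_polymorphic,
                                  inbreeding_f = inbreeding_f),
                    seed = seed))
}

#' Simulate homo-quartet error records
#'
#' Draws `n` monoallelic-position homo-quartet records directly: the
#' major state from `base_freqs`, the minor (erroneous) state from the
#' corresponding row of `error_law` (default uniform over the three
#' alternative bases). Used to calibrate [error_matrix()] and
#' [error_class_summary()].
#'
#' @param n number of records.
#' @param base_freqs length-4 major-state frequencies.
#' @param error_law 4x4 matrix of minor-state probabilities given the
#'   major state (diagonal ignored); default uniform.
#' @param seed integer seed.
#' @return homo-quartet record data frame (all monoallelic).
#' @export
simulate_error_records <- function(n = 1e5,
                                   base_freqs = rep(0.25, 4),
                                   error_law = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(error_law)) {
    error_law <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
    diag(error_law) <- 0
  }
  maj <- sample.int(4, n, replace = TRUE, prob = base_freqs)
  minr <- integer(n)
  for (a in 1:4) {
    sel <- maj == a
    if (!any(sel)) next
    p <- error_law[a, ]
    p[a] <- 0
    minr[sel] <- sample.int(4, sum(sel), replace = TRUE, prob = p)
  }
  data.frame(species = "simsp", individual = "ind01", contig = "sim",
             pos = seq_len(n), major = BASES[maj], minor = BASES[minr],
             class = "monoallelic", z = NA_character_, r_z = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Simulate sample metadata with shipment / flowcell / lane structure
#'
#' Species are assigned one technician and one shipment date each; per
#' sample a flowcell (nested in the shipment) and a lane (nested in the
#' flowcell) are drawn; entry dates precede shipment dates.
#'
#' @param n_species number of species.
#' @param n_technicians number of technicians.
#' @param shipment_dates vector of `Date`s (shipments).
#' @param flowcells_per_shipment,lanes_per_flowcell nesting structure.
#' @param samples_per_species samples (individuals) per species.
#' @param center sequencing-center label (single center by default).
#' @param seed integer seed.
#' @return data frame: `species`, `individual`, `technician`,
#'   `entry_date`, `shipment_date`, `center`, `flowcell`, `lane`.
#' @export
simulate_metadata <- function(n_species = 30, n_technicians = 4,
                              shipment_dates =
                                as.Date("2011-01-15") + c(0, 90, 180, 270),
                              flowcells_per_shipment = 2,
                              lanes_per_flowcell = 2,
                              samples_per_species = 2,
                              center = "SC1", seed = 1) {
  stopifnot(n_species >= 1, n_technicians >= 1,
            length(shipment_dates) >= 1)
  set.seed(seed)
  sp <- sprintf("sp%03d", seq_len(n_species))
  tech <- sprintf("tech%02d", sample.int(n_technicians, n_species,
                                         replace = TRUE))
  ship <- sample(shipment_dates, n_species, replace = TRUE)
  entry <- ship - sample(30:250, n_species, replace = TRUE)
  rows <- lapply(seq_len(n_species), function(i) {
    fc <- sprintf("%s_FC%d", format(ship[i]),
                  sample.int(flowcells_per_shipment,
                             samples_per_species, replace = TRUE))
    data.frame(species = sp[i],
               individual = sprintf("%s_ind%02d", sp[i],
                                    seq_len(samples_per_species)),
               technician = tech[i],
               entry_date = entry[i], shipment_date = ship[i],
               center = center, flowcell = fc,
               lane = sample.int(lanes_per_flowcell,
                                 samples_per_species, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# mutate a sequence (integer-coded) at each site with probability d,
# to a uniformly chosen different base
.mutate_seq <- function(s, d) {
  hit <- runif(length(s)) < d
  if (any(hit))
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(1:4, b), 1), 0L)
  s
}

#' Simulate a barcode screening experiment
#'
#' Generates a panel of species barcode sequences with controlled
#' pairwise divergences (including `n_close_pairs` pairs below the 5%
#' diagnostic threshold, to exercise the mask), sample metadata, and
#' per-sample reads: own-species barcode reads plus contaminant reads
#' injected between species pairs linked by the scenario (by default,
#' pairs sharing a shipment). Read counts are interpreted against a
#' nominal `total_reads` per sample so that injection prevalences are
#' on the per-million scale.
#'
#' @param n_species number of species.
#' @param samples_per_species samples per species.
#' @param seq_length aligned barcode length (default 351).
#' @param read_length read length (default 50).
#' @param reads_per_sample expected number of own-species barcode reads.
#' @param total_reads nominal total read count per sample (denominator
#'   of per-million prevalences).
#' @param error_rate per-base sequencing error rate of the reads.
#' @param divergence per-site substitution probability from the common
#'   ancestor (controls between-species divergence, roughly twice this
#'   value).
#' @param n_close_pairs number of species pairs generated at ~3%
#'   divergence (non-diagnostic).
#' @param scenario list: `link` (metadata relation inducing
#'   contamination, `"same_shipment"` or `"none"`), `pair_prob`
#'   (probability that a linked ordered species pair contaminates a
#'   given sample), `mean_reads` (mean contaminant reads injected).
#' @param metadata optionally, a pre-built metadata table (must match
#'   `n_species` and `samples_per_species`).
#' @param seed integer seed.
#' @return list with `panel` (a `barcode_panel`), `samples` (list of
#'   per-sample lists: `species`, `individual`, `reads`, `total_reads`),
#'   `metadata`, `truth` (injected contamination events and parameters).
#' @export
simulate_barcode_experiment <- function(n_species = 30,
                                        samples_per_species = 2,
                                        seq_length = 351,
                                        read_length = 50,
                                        reads_per_sample = 150,
                                        total_reads = 1e6,
                                        error_rate = 0.001,
                                        divergence = 0.12,
                                        n_close_pairs = 3,
                                        scenario = list(
                                          link = "same_shipment",
                                          pair_prob = 0.5,
                                          mean_reads = 20),
                                        metadata = NULL, seed = 1) {
  if (2 * n_close_pairs > n_species)
    stop("n_close_pairs incompatible with n_species")
  set.seed(seed)
  sp <- sprintf("sp%03d", seq_len(n_species))
  anc <- sample.int(4, seq_length, replace = TRUE)
  seqs <- matrix(0L, n_species, seq_length)
  i <- 1
  while (i <= n_species) {
    seqs[i, ] <- .mutate_seq(anc, divergence)
    if (i %% 2 == 0 && (i / 2) <= n_close_pairs)
      seqs[i, ] <- .mutate_seq(seqs[i - 1, ], 0.03)
    i <- i + 1
  }
  panel <- barcode_panel(
    sequences = apply(seqs, 1, function(s) paste(BASES[s], collapse = "")),
    id = paste0("ref_", sp), species = sp,
    component = rep("target", n_species))

  if (is.null(metadata))
    metadata <- simulate_metadata(n_species = n_species,
                                  samples_per_species = samples_per_species,
                                  seed = seed + 1)
  sp_ship <- tapply(as.character(metadata$shipment_date), metadata$species,
                    function(x) x[1])

  draw_reads <- function(sp_idx, n) {
    if (n == 0) return(character())
    offs <- sample.int(seq_length - read_length + 1, n, replace = TRUE)
    vapply(offs, function(o) {
      r <- seqs[sp_idx, o:(o + read_length - 1)]
      r <- .mutate_seq(r, error_rate)
      paste(BASES[r], collapse = "")
    }, "")
  }

  events <- list()
  samples <- lapply(seq_len(nrow(metadata)), function(k) {
    j <- match(metadata$species[k], sp)
    reads <- draw_reads(j, rpois(1, reads_per_sample))
    if (!is.null(scenario$link) && scenario$link == "same_shipment") {
      linked <- which(sp_ship == sp_ship[[sp[j]]] & sp != sp[j])
      for (i2 in linked) {
        if (runif(1) < scenario$pair_prob) {
          nc <- rpois(1, scenario$mean_reads) + 1L
          reads <- c(reads, draw_reads(i2, nc))
          events[[length(events) + 1]] <<-
            data.frame(contaminant = sp[i2],
                       contaminated = sp[j],
                       sample = metadata$individual[k],
                       n_reads = nc, stringsAsFactors = FALSE)
        }
      }
    }
    list(species = metadata$species[k],
         individual = metadata$individual[k],
         reads = reads, total_reads = total_reads)
  })
  truth <- list(events = if (length(events)) do.call(rbind, events)
                         else NULL,
                params = list(n_species = n_species,
                              divergence = divergence,
                              n_close_pairs = n_close_pairs,
                              scenario = scenario,
                              error_rate = error_rate),
                seed = seed)
  list(panel = panel, samples = samples, metadata = metadata,
       truth = truth)
}
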