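#' Classify a quartet as a homo-quartet
#'
#' A quartet is the vector of A/C/G/T read counts for one individual at
#' one position. It is a *homo-quartet* when exactly two states carry
#' reads, the larger count is strictly greater than `major_threshold`,
#' and the smaller count is exactly one. Such quartets are interpreted as
#' homozygous genotypes carrying a single erroneous (or leaked) read.
#'
#' @param counts numeric vector of length 4 (A, C, G, T read counts).
#' @param major_threshold minimum (exclusive) read count for the major
#'   state; default 40.
#' @return a list with `is_homo` (logical), and when `TRUE` the `major`
#'   and `minor` base letters.
#' @examples
#' classify_quartet(c(45, 0, 0, 1))  # homo-quartet, major A, minor T
#' classify_quartet(c(40, 0, 0, 1))  # not: major must exceed 40
#' @export
classify_quartet <- function(counts, major_threshold = 40) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  nz <- which(counts > 0)
  if (length(nz) != 2L)
    return(list(is_homo = FALSE, major = NA_character_, minor = NA_character_))
  hi <- nz[which.max(counts[nz])]
  lo <- setdiff(nz, hi)
  ok <- counts[hi] > major_threshold && counts[lo] == 1
  list(is_homo = ok,
       major = if (ok) BASES[hi] else NA_character_,
       minor = if (ok) BASES[lo] else NA_character_)
}

# Vectorised homo-quartet flags over an N x 4 count matrix.
# Returns integer major/minor base indices (NA where not a homo-quartet).
.hq_flags <- function(m, major_threshold = 40) {
  nz <- rowSums(m > 0)
  hi <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), hi)]
  tot <- rowSums(m)
  is_hq <- nz == 2L & mx > major_threshold & (tot - mx) == 1
  lo <- rep(NA_integer_, nrow(m))
  if (any(is_hq)) {
    m2 <- m[is_hq, , drop = FALSE]
    m2[cbind(seq_len(nrow(m2)), hi[is_hq])] <- 0L
    lo[is_hq] <- max.col(m2, ties.method = "first")
  }
  list(is_hq = is_hq, major = ifelse(is_hq, hi, NA_integer_), minor = lo)
}

#' Classify a site column as monoallelic, biallelic or other
#'
#' Totals are read counts pooled across all genotyped individuals
#' (including the focal one). The site is *monoallelic* when the major
#' state exceeds `major_frac` of the grand total, otherwise *biallelic*
#' when the second-ranked state's total exceeds `biallelic_factor * n`,
#' and *other* otherwise. Ties for the second rank are broken by the
#' fixed base order A < C < G < T.
#'
#' @param totals numeric vector of length 4: pooled A, C, G, T counts.
#' @param n number of genotyped individuals.
#' @param major_frac monoallelic threshold on the major-state fraction
#'   (default 0.95, exclusive).
#' @param biallelic_factor multiplier of `n` for the biallelic rule
#'   (default 10, exclusive).
#' @return one of `"monoallelic"`, `"biallelic"`, `"other"`.
#' @examples
#' classify_position(c(960, 0, 0, 40), n = 4)  # monoallelic (96% > 95%)
#' classify_position(c(500, 0, 0, 41), n = 4)  # biallelic (41 > 40)
#' @export
classify_position <- function(totals, n, major_frac = 0.95,
                              biallelic_factor = 10) {
  stopifnot(length(totals) == 4, n >= 1)
  grand <- sum(totals)
  if (grand == 0) stop("zero-coverage column: no reads at this position")
  o1 <- which.max(totals)
  rest <- totals
  rest[o1] <- -Inf
  o2 <- which.max(rest)
  if (totals[o1] > major_frac * grand) return("monoallelic")
  if (totals[o2] > biallelic_factor * n) return("biallelic")
  "other"
}

# Vectorised position classification over a P x 4 totals matrix.
# Returns list(class, s1, s2): class strings plus the indices of the
# top-ranked and second-ranked states (base-order tie-break via
# max.col(ties.method = "first")).
.position_classes <- function(tot, n, major_frac = 0.95,
                              biallelic_factor = 10) {
  grand <- rowSums(tot)
  s1 <- max.col(tot, ties.method = "first")
  t2 <- tot
  t2[cbind(seq_len(nrow(tot)), s1)] <- -Inf
  s2 <- max.col(t2, ties.method = "first")
  second <- tot[cbind(seq_len(nrow(tot)), s2)]
  cls <- rep("other", nrow(tot))
  cls[second > biallelic_factor * n] <- "biallelic"
  cls[tot[cbind(seq_len(nrow(tot)), s1)] > major_frac * grand] <- "monoallelic"
  list(class = cls, s1 = s1, s2 = s2, grand = grand)
}

#' Extract homo-quartet records from a quartet table
#'
#' Scans every (individual, position) quartet of a quartet table, keeps
#' the homo-quartets, annotates each with the class of its position
#' (monoallelic / biallelic; records at "other" positions are dropped)
#' and, at biallelic positions, with `z` — the segregating allele
#' different from the record's major state — and `r_z`, the indicator
#' that the minor state equals `z`. Homo-quartets at biallelic positions
#' whose major state is neither of the two segregating alleles are
#' excluded (their `z` would be ambiguous); the count of such exclusions
#' is returned as the attribute `n_excluded_ambiguous`.
#'
#' When a `species` column is present the table is processed per species
#' (position totals and `n` are species-specific).
#'
#' @param quartets data frame with columns `individual`, `contig`, `pos`,
#'   `nA`, `nC`, `nG`, `nT`, and optionally `species`.
#' @param major_threshold,major_frac,biallelic_factor thresholds passed
#'   to [classify_quartet()] and [classify_position()].
#' @return data frame with columns `species`, `individual`, `contig`,
#'   `pos`, `major`, `minor`, `class`, `z`, `r_z`, ordered by
#'   (species, contig, pos, individual).
#' @export
extract_homo_quartets <- function(quartets, major_threshold = 40,
                                  major_frac = 0.95, biallelic_factor = 10) {
  quartets <- .check_quartets(quartets)
  parts <- split(quartets, quartets$species)
  out <- lapply(parts, .extract_hq_species,
                major_threshold = major_threshold,
                major_frac = major_frac,
                biallelic_factor = biallelic_factor)
  res <- do.call(rbind, lapply(out, `[[`, "records"))
  rownames(res) <- NULL
  structure(res,
            n_excluded_ambiguous = sum(vapply(out, `[[`, 0L, "n_excluded")))
}

.extract_hq_species <- function(q, major_threshold, major_frac,
                                biallelic_factor) {
  m <- as.matrix(q[, c("nA", "nC", "nG", "nT")])
  n <- length(unique(q$individual))
  poskey <- paste(q$contig, q$pos, sep = "\r")
  tot <- rowsum(m, poskey)
  pc <- .position_classes(tot, n, major_frac, biallelic_factor)
  names(pc$class) <- rownames(tot)
  s1 <- setNames(pc$s1, rownames(tot))
  s2 <- setNames(pc$s2, rownames(tot))

  hq <- .hq_flags(m, major_threshold)
  keep <- which(hq$is_hq & pc$class[poskey] != "other")
  if (length(keep) == 0L) {
    rec <- data.frame(species = character(), individual = character(),
                      contig = character(), pos = integer(),
                      major = character(), minor = character(),
                      class = character(), z = character(),
                      r_z = integer(), stringsAsFactors = FALSE)
    return(list(records = rec, n_excluded = 0L))
  }
  k <- poskey[keep]
  cls <- unname(pc$class[k])
  maj <- hq$major[keep]
  min_ <- hq$minor[keep]
  a1 <- unname(s1[k]); a2 <- unname(s2[k])
  z <- rep(NA_integer_, length(keep))
  bi <- cls == "biallelic"
  z[bi & maj == a1] <- a2[bi & maj == a1]
  z[bi & maj == a2] <- a1[bi & maj == a2]
  ambiguous <- bi & maj != a1 & maj != a2
  rec <- data.frame(
    species = q$species[keep], individual = q$individual[keep],
    contig = q$contig[keep], pos = q$pos[keep],
    major = BASES[maj], minor = BASES[min_], class = cls,
    z = ifelse(is.na(z), NA_character_, BASES[z]),
    r_z = ifelse(bi & !ambiguous, as.integer(BASES[min_] == BASES[z]),
                 NA_integer_),
    stringsAsFactors = FALSE)
  rec <- rec[!ambiguous, , drop = FALSE]
  rec <- rec[order(rec$contig, rec$pos, rec$individual), , drop = FALSE]
  list(records = rec, n_excluded = sum(ambiguous))
}

# Validate a quartet table; adds a species column when absent.
.check_quartets <- function(q) {
  need <- c("individual", "contig", "pos", "nA", "nC", "nG", "nT")
  miss <- setdiff(need, names(q))
  if (length(miss))
    stop("quartet table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"species" %in% names(q)) q$species <- "unspecified"
  cnt <- as.matrix(q[, c("nA", "nC", "nG", "nT")])
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("quartet counts must be non-negative and non-missing")
  q
}
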