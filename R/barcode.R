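#' Construct a barcode reference panel
#'
#' An aligned panel of equal-length barcode (cox1) sequences with a
#' species label and a component tag (`target`, `companion` or `model`)
#' per sequence.
#'
#' @param sequences character vector of aligned sequences (equal
#'   length).
#' @param id sequence identifiers.
#' @param species species labels (non-empty).
#' @param component component tags; default `"target"`.
#' @return an object of class `barcode_panel`.
#' @export
barcode_panel <- function(sequences, id = NULL, species, component = NULL) {
  sequences <- toupper(sequences)
  n <- length(sequences)
  if (n == 0) stop("empty panel")
  L <- nchar(sequences)
  if (length(unique(L)) != 1) {
    bad <- which(L != L[1])[1]
    stop("aligned panel has unequal lengths: record ",
         (id %||% seq_len(n))[bad], " has length ", L[bad],
         " (expected ", L[1], ")")
  }
  if (any(!nzchar(species))) stop("species labels must be non-empty")
  structure(list(sequences = sequences,
                 id = as.character(id %||% sprintf("seq%d", seq_len(n))),
                 species = as.character(species),
                 component = as.character(component %||%
                                            rep("target", n)),
                 length = L[1]),
            class = "barcode_panel")
}

#' @export
print.barcode_panel <- function(x, ...) {
  cat("Barcode panel:", length(x$sequences), "aligned sequences x",
      x$length, "bp;", length(unique(x$species)), "species\n")
  invisible(x)
}

#' Pairwise species divergence over an aligned panel
#'
#' p-distance per sequence pair over positions where both sequences
#' carry unambiguous bases (pairwise deletion); the species-pair value
#' is the *minimum* over their sequence pairs. Sequence pairs with fewer
#' than 50% comparable positions are flagged unreliable.
#'
#' @param panel a [barcode_panel()].
#' @return object of class `divergence_table`: list with `D` (symmetric
#'   species x species minimum p-distance matrix, zero on the diagonal),
#'   `unreliable` (logical matrix), `species`.
#' @export
pairwise_divergence <- function(panel) {
  chm <- do.call(rbind, strsplit(panel$sequences, ""))
  code <- matrix(match(chm, BASES), nrow(chm), ncol(chm))
  sp <- unique(panel$species)
  n <- length(panel$sequences)
  d <- matrix(NA_real_, n, n)
  unrel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) next
      ok <- !is.na(code[i, ]) & !is.na(code[j, ])
      nc <- sum(ok)
      if (nc == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        unrel[i, j] <- unrel[j, i] <- TRUE
        next
      }
      d[i, j] <- d[j, i] <- sum(code[i, ok] != code[j, ok]) / nc
      if (nc < 0.5 * panel$length)
        unrel[i, j] <- unrel[j, i] <- TRUE
    }
  }
  D <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  U <- matrix(FALSE, length(sp), length(sp), dimnames = list(sp, sp))
  for (a in seq_along(sp)) {
    for (b in seq_len(a)) {
      ia <- which(panel$species == sp[a])
      ib <- which(panel$species == sp[b])
      block <- d[ia, ib, drop = FALSE]
      D[a, b] <- D[b, a] <- if (all(is.na(block))) NA_real_
                            else min(block, na.rm = TRUE)
      U[a, b] <- U[b, a] <- any(unrel[ia, ib])
    }
  }
  diag(D) <- 0
  structure(list(D = D, unreliable = U, species = sp),
            class = "divergence_table")
}

#' Diagnostic flags for species pairs
#'
#' A species pair is *non-diagnostic* when its minimum barcode
#' divergence is strictly below `threshold` (default 5%): cross-hits
#' between such species cannot attest contamination.
#'
#' @param divt a [pairwise_divergence()] table.
#' @param threshold divergence threshold (default 0.05; the 10% variant
#'   is a robustness setting).
#' @return logical species x species matrix, `TRUE` = diagnostic.
#' @export
diagnostic_mask <- function(divt, threshold = 0.05) {
  m <- !(divt$D < threshold)
  m[is.na(divt$D)] <- NA
  diag(m) <- FALSE
  m
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "")[[1]])
    paste(ifelse(ch %in% BASES, REVCOMP[ch], "N"), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Map a read to a barcode panel
#'
#' Ungapped scan of every offset on both strands of every reference;
#' the best hit is the placement with the fewest mismatches, within the
#' tolerance (`max_mismatch`: 1 for reads of length <= 50, else 2, when
#' not given). Ambiguous bases count as mismatches. When several
#' references tie for the best score one is chosen uniformly with R's
#' RNG (seed it for reproducibility); the full tie set is returned.
#'
#' @param read a read sequence (character).
#' @param panel a [barcode_panel()].
#' @param max_mismatch mismatch tolerance; `NULL` = length rule.
#' @param min_read_length reads shorter than this are skipped (default
#'   30).
#' @return `NULL` when no placement is within tolerance (or the read is
#'   too short), else a list with `ref` (index), `id`, `species`,
#'   `mismatches`, `strand`, `tie_set` (indices of tied references).
#' @export
map_read <- function(read, panel, max_mismatch = NULL,
                     min_read_length = 30) {
  read <- toupper(read)
  if (nchar(read) < min_read_length) return(NULL)
  if (is.null(max_mismatch))
    max_mismatch <- if (nchar(read) <= 50) 1L else 2L
  fwd <- cpp_scan_read(read, panel$sequences, max_mismatch)
  rev_ <- cpp_scan_read(revcomp(read), panel$sequences, max_mismatch)
  mm <- pmin(fwd$mismatches, rev_$mismatches, na.rm = TRUE)
  mm[is.na(fwd$mismatches) & is.na(rev_$mismatches)] <- NA
  if (all(is.na(mm))) return(NULL)
  best <- min(mm, na.rm = TRUE)
  ties <- which(mm == best)
  hit <- if (length(ties) > 1) ties[sample.int(length(ties), 1)] else ties
  strand <- if (!is.na(fwd$mismatches[hit]) &&
                fwd$mismatches[hit] == best) "+" else "-"
  list(ref = hit, id = panel$id[hit], species = panel$species[hit],
       mismatches = best, strand = strand, tie_set = ties)
}

#' Screen one sample against the panel
#'
#' Maps every read, tallies hits per reference and per species, and
#' accounts prevalences per million reads. Hits to the expected species
#' are "expected"; hits to species diagnostic with respect to the
#' expected species are "unexpected"; hits to species non-diagnostic
#' w.r.t. the expected species are counted separately and attest
#' nothing. A sample is flagged dubious when the unexpected:expected
#' prevalence ratio exceeds 1.
#'
#' @param reads character vector of read sequences.
#' @param panel a [barcode_panel()].
#' @param expected_species the species the sample is supposed to be.
#' @param mask diagnostic mask from [diagnostic_mask()].
#' @param total_reads total reads of the sample (prevalence
#'   denominator); defaults to `length(reads)`.
#' @param max_mismatch,min_read_length see [map_read()].
#' @return object of class `hit_table`: list with `species_hits` (named
#'   vector), `prevalence_per_million`, `expected_hits`,
#'   `unexpected_hits`, `nondiagnostic_hits`, `expected_prevalence`,
#'   `unexpected_prevalence`, `dubious`, `expected_in_panel`,
#'   `total_reads`, `expected_species`.
#' @export
screen_sample <- function(reads, panel, expected_species, mask,
                          total_reads = length(reads),
                          max_mismatch = NULL, min_read_length = 30) {
  if (total_reads <= 0) stop("sample has zero total reads")
  hits <- integer(length(panel$sequences))
  for (r in reads) {
    h <- map_read(r, panel, max_mismatch, min_read_length)
    if (!is.null(h)) hits[h$ref] <- hits[h$ref] + 1L
  }
  sp_hits <- tapply(hits, panel$species, sum)
  sp_hits <- setNames(as.integer(sp_hits), names(sp_hits))
  in_panel <- expected_species %in% panel$species
  expected <- if (in_panel) sum(sp_hits[expected_species]) else 0L
  other <- setdiff(names(sp_hits), expected_species)
  if (in_panel) {
    diag_ok <- mask[expected_species, other]
    unexpected <- sum(sp_hits[other][diag_ok %in% TRUE])
    nondiag <- sum(sp_hits[other][!(diag_ok %in% TRUE)])
  } else {
    unexpected <- sum(sp_hits[other])  # flagged: expected absent
    nondiag <- 0L
  }
  prev <- sp_hits * 1e6 / total_reads
  ep <- expected * 1e6 / total_reads
  up <- unexpected * 1e6 / total_reads
  structure(list(species_hits = sp_hits,
                 prevalence_per_million = prev,
                 expected_hits = expected,
                 unexpected_hits = unexpected,
                 nondiagnostic_hits = nondiag,
                 expected_prevalence = ep,
                 unexpected_prevalence = up,
                 dubious = up > ep,
                 expected_in_panel = in_panel,
                 total_reads = total_reads,
                 expected_species = expected_species),
            class = "hit_table")
}

#' Build the between-species contamination matrix M
#'
#' Aggregates unexpected hits over samples: a read from a sample of
#' species `j` hitting a reference of species `i` attests contamination
#' of `j` by `i`. Cell `m[i, j]` is 1 when the summed unexpected reads
#' reach `min_reads` (default 1: a single read suffices; 10 is the
#' robustness variant), 0 otherwise, and missing (NA) when the pair is
#' non-diagnostic. Rows cover every panel species (potential
#' contaminants); columns cover species with screened samples. `p` is
#' the proportion of ones among non-missing cells.
#'
#' @param hit_tables list of [screen_sample()] results; each must carry
#'   its sample's species in `expected_species`.
#' @param mask diagnostic mask.
#' @param min_reads minimum summed unexpected reads to set a cell to 1.
#' @return object of class `contamination_matrix`: list with `m`
#'   (contaminant x contaminated), `reads` (underlying read counts),
#'   `p`, `min_reads`.
#' @export
build_contamination_matrix <- function(hit_tables, mask, min_reads = 1) {
  contaminants <- rownames(mask)
  screened <- unique(vapply(hit_tables, `[[`, "", "expected_species"))
  screened <- intersect(contaminants, screened)
  reads <- matrix(0L, length(contaminants), length(screened),
                  dimnames = list(contaminants, screened))
  for (ht in hit_tables) {
    j <- ht$expected_species
    if (!j %in% screened) next
    src <- setdiff(names(ht$species_hits), j)
    src <- intersect(src, contaminants)
    reads[src, j] <- reads[src, j] + ht$species_hits[src]
  }
  m <- (reads >= min_reads) * 1L
  for (j in screened) {
    nd <- rownames(mask)[!(mask[, j] %in% TRUE)]
    m[intersect(nd, contaminants), j] <- NA_integer_
  }
  if (all(screened %in% rownames(m)))
    m[cbind(screened, screened)] <- NA_integer_
  nm <- sum(!is.na(m))
  structure(list(m = m, reads = reads,
                 p = if (nm > 0) sum(m == 1, na.rm = TRUE) / nm
                     else NA_real_,
                 min_reads = min_reads),
            class = "contamination_matrix")
}

#' @export
print.contamination_matrix <- function(x, ...) {
  cat("Contamination matrix:", nrow(x$m), "potential contaminants x",
      ncol(x$m), "screened species;",
      sum(x$m == 1, na.rm = TRUE), "attested events; p =",
      signif(x$p, 3), "\n")
  invisible(x)
}
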