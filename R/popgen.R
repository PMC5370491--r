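# Population-genomic summaries computed from called genotypes.
# Estimator conventions: unbiased per-site heterozygosity, ratio-of-sums
# across sites for pi and F_IT, Nei-Gojobori fractional site counts for
# the synonymous/non-synonymous partition.

# memoised 64-codon translation table (standard genetic code, seqinr)
.codon_env <- new.env(parent = emptyenv())
.codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    codons <- apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1, paste,
                    collapse = "")
    aa <- vapply(codons, function(cd)
      seqinr::translate(strsplit(cd, "")[[1]]), "")
    .codon_env$tab <- setNames(aa, codons)
  }
  .codon_env$tab
}

#' Per-site nucleotide diversity
#'
#' Unbiased heterozygosity `(m / (m - 1)) * (1 - sum p_i^2)` from the
#' called allele copies at one site; equals the mean pairwise difference
#' among the `m` copies.
#'
#' @param alleles character vector of called allele copies at the site
#'   (two per called diploid), or a vector of two-letter genotype
#'   strings.
#' @return the per-site diversity; `NA` when fewer than 2 copies are
#'   called.
#' @examples
#' site_pi(c("AA", "CC"))  # p = 0.5, m = 4 -> 2/3
#' @export
site_pi <- function(alleles) {
  a <- unlist(strsplit(alleles, ""))
  a <- a[!is.na(a)]
  m <- length(a)
  if (m < 2) return(NA_real_)
  p <- table(a) / m
  (m / (m - 1)) * (1 - sum(p^2))
}

#' Synonymous and non-synonymous site counts of a coding sequence
#'
#' Nei–Gojobori fractional counting under the standard genetic code:
#' for each codon, each of the nine single-base changes contributes 1/3
#' of a site to the synonymous or non-synonymous total according to
#' whether it preserves the amino acid. Stop codons and codons with
#' ambiguous bases are skipped (counted in the `n_skipped` attribute).
#' S + N = 3 for every counted codon.
#'
#' @param cds in-frame coding sequence (character string, length a
#'   multiple of 3).
#' @return named vector `c(L_S = ..., L_N = ...)` with attribute
#'   `n_skipped`.
#' @examples
#' count_syn_nonsyn_sites("TTT")  # S = 1/3, N = 8/3
#' @export
count_syn_nonsyn_sites <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length must be a multiple of 3")
  tab <- .codon_table()
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  Ls <- 0; Ln <- 0; skipped <- 0L
  for (cd in codons) {
    aa <- tab[cd]
    if (is.na(aa) || aa == "*") { skipped <- skipped + 1L; next }
    ch <- strsplit(cd, "")[[1]]
    for (k in 1:3) {
      for (b in setdiff(BASES, ch[k])) {
        mut <- ch
        mut[k] <- b
        if (tab[paste(mut, collapse = "")] == aa) Ls <- Ls + 1 / 3
        else Ln <- Ln + 1 / 3
      }
    }
  }
  structure(c(L_S = Ls, L_N = Ln), n_skipped = skipped)
}

#' Classify a SNP as synonymous or non-synonymous
#'
#' A biallelic change at one codon position is synonymous iff both
#' codons translate to the same amino acid. A change creating a stop is
#' classified non-synonymous and flagged.
#'
#' @param codon reference codon (3 letters).
#' @param pos_in_codon 1, 2 or 3.
#' @param alleles the two alleles at the site.
#' @return list with `effect` (`"synonymous"`/`"non-synonymous"`) and
#'   `stop_flag`.
#' @examples
#' classify_snp_effect("TTT", 3, c("T", "C"))  # synonymous
#' @export
classify_snp_effect <- function(codon, pos_in_codon, alleles) {
  stopifnot(pos_in_codon %in% 1:3, length(alleles) == 2)
  tab <- .codon_table()
  mk <- function(b) {
    ch <- strsplit(toupper(codon), "")[[1]]
    ch[pos_in_codon] <- toupper(b)
    paste(ch, collapse = "")
  }
  aa <- tab[c(mk(alleles[1]), mk(alleles[2]))]
  if (anyNA(aa)) stop("ambiguous base in codon")
  stop_flag <- any(aa == "*")
  list(effect = if (!stop_flag && aa[1] == aa[2]) "synonymous"
                else "non-synonymous",
       stop_flag = stop_flag)
}

#' F_IT: homozygosity excess over Hardy–Weinberg expectations
#'
#' `1 - sum(H_obs) / sum(H_exp)` across SNPs (ratio of sums), with
#' `H_obs` the fraction of heterozygous called individuals and `H_exp`
#' the unbiased expected heterozygosity at each site.
#'
#' @param sites list of character vectors of genotype strings (one
#'   vector per SNP; one two-letter genotype per called individual).
#' @return F_IT; errors when the summed expected heterozygosity is 0.
#' @export
f_it <- function(sites) {
  hobs <- 0; hexp <- 0
  for (g in sites) {
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    a <- unlist(strsplit(g, ""))
    m <- length(a)
    if (m < 2) next
    p <- table(a) / m
    hobs <- hobs + mean(substr(g, 1, 1) != substr(g, 2, 2))
    hexp <- hexp + (m / (m - 1)) * (1 - sum(p^2))
  }
  if (hexp == 0) stop("F_IT undefined: zero expected heterozygosity")
  1 - hobs / hexp
}

#' Tajima's D from folded allele counts
#'
#' Standard `D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1))` with the
#' canonical constants for `m` sequences; `pi` is the summed mean
#' pairwise difference and `theta_W = S / a1`.
#'
#' @param minor_counts integer vector: minor-allele copy count per
#'   segregating site.
#' @param m number of allele copies (sequences); must be >= 4.
#' @return Tajima's D; errors when there are no segregating sites.
#' @export
tajimas_d <- function(minor_counts, m) {
  stopifnot(m >= 4)
  S <- length(minor_counts)
  if (S == 0) stop("Tajima's D undefined: no segregating sites")
  pi <- sum(minor_counts * (m - minor_counts)) / choose(m, 2)
  a1 <- sum(1 / seq_len(m - 1))
  a2 <- sum(1 / seq_len(m - 1)^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Population-genomic summary from genotype calls
#'
#' Computes, from a [call_genotypes()] result and the coding sequences
#' it was called on, the number of SNPs, piS and piN (ratio of summed
#' per-site diversities over Nei–Gojobori site counts), piN/piS, F_IT
#' over all SNPs, and synonymous / non-synonymous Tajima's D. Tajima's D
#' uses the called allele-copy count at the median site as `m`.
#' Tri-allelic SNPs are classified per minor allele against the major
#' allele and flagged.
#'
#' @param calls the `calls` data frame from [call_genotypes()].
#' @param cds named character vector of in-frame coding sequences, one
#'   per contig (names = contig ids); position 1 of a contig is codon 1,
#'   position 1 of the codon.
#' @return data frame (one row) of class `popgen_summary`: `n_snps`,
#'   `pi_S`, `pi_N`, `pi_N_over_pi_S`, `f_it`, `tajimas_d_syn`,
#'   `tajimas_d_nonsyn`, `L_S`, `L_N`.
#' @export
diversity_summary <- function(calls, cds) {
  cc <- calls[calls$called, , drop = FALSE]
  Lsn <- Reduce(`+`, lapply(cds, count_syn_nonsyn_sites))
  if (Lsn[["L_S"]] == 0) stop("pi_S undefined: no synonymous sites")
  tab <- .codon_table()

  key <- paste(cc$contig, cc$pos, sep = "\r")
  idx <- split(seq_len(nrow(cc)), key)
  pi_s <- 0; pi_n <- 0
  syn_minor <- integer(); nonsyn_minor <- integer()
  het_sites <- list()
  m_per_site <- integer()
  n_snps <- 0L
  for (k in names(idx)) {
    rows <- cc[idx[[k]], , drop = FALSE]
    g <- paste0(rows$allele1, rows$allele2)
    a <- unlist(strsplit(g, ""))
    als <- sort(unique(a))
    if (length(als) < 2) next
    n_snps <- n_snps + 1L
    m <- length(a)
    m_per_site <- c(m_per_site, m)
    contig <- rows$contig[1]; pos <- rows$pos[1]
    cstart <- 3 * ((pos - 1) %/% 3) + 1
    codon <- substr(cds[[contig]], cstart, cstart + 2)
    pic <- pos - cstart + 1
    major <- names(sort(table(a), decreasing = TRUE))[1]
    spi <- site_pi(g)
    het_sites[[length(het_sites) + 1]] <- g
    # per minor allele against the major allele (tri-allelic flagged)
    minors <- setdiff(als, major)
    for (mn in minors) {
      eff <- classify_snp_effect(codon, pic, c(major, mn))$effect
      cnt <- sum(a == mn)
      w <- spi * if (length(minors) > 1) cnt * (m - cnt) /
        sum(vapply(minors, function(x) sum(a == x) *
                     (m - sum(a == x)), 0)) else 1
      if (eff == "synonymous") {
        pi_s <- pi_s + w
        syn_minor <- c(syn_minor, min(cnt, m - cnt))
      } else {
        pi_n <- pi_n + w
        nonsyn_minor <- c(nonsyn_minor, min(cnt, m - cnt))
      }
    }
  }
  piS <- pi_s / Lsn[["L_S"]]
  piN <- pi_n / Lsn[["L_N"]]
  fit <- if (length(het_sites)) tryCatch(f_it(het_sites),
                                         error = function(e) NA_real_)
         else NA_real_
  m_d <- if (length(m_per_site)) as.integer(median(m_per_site)) else NA
  td_s <- if (length(syn_minor) && !is.na(m_d) && m_d >= 4)
    tajimas_d(syn_minor, m_d) else NA_real_
  td_n <- if (length(nonsyn_minor) && !is.na(m_d) && m_d >= 4)
    tajimas_d(nonsyn_minor, m_d) else NA_real_
  structure(
    data.frame(n_snps = n_snps, pi_S = piS, pi_N = piN,
               pi_N_over_pi_S = if (piS > 0) piN / piS else NA_real_,
               f_it = fit, tajimas_d_syn = td_s, tajimas_d_nonsyn = td_n,
               L_S = Lsn[["L_S"]], L_N = Lsn[["L_N"]]),
    class = c("popgen_summary", "data.frame"))
}
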