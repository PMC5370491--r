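#' Per-read emission matrix of the error channel
#'
#' `E[w, x]` is the probability that a read whose true state is `w` is
#' called `x`: the genuine state with probability
#' `1 - (eps_ts + 2 eps_tv)`, the transition partner with probability
#' `eps_ts`, and each transversion partner with probability `eps_tv`.
#' With `eps_ts = eps_tv = eps` this reduces to the single-rate channel
#' (genuine state with probability `1 - 3 eps`).
#'
#' @param eps_ts,eps_tv transition / transversion per-read error rates.
#' @return 4x4 matrix with dimnames A, C, G, T.
#' @export
error_emission_matrix <- function(eps_ts, eps_tv) {
  s <- 1 - (eps_ts + 2 * eps_tv)
  if (s <= 0) stop("error rates too large: 1 - (eps_ts + 2 eps_tv) <= 0")
  E <- matrix(eps_tv, 4, 4, dimnames = list(BASES, BASES))
  E[cbind(c(1, 3, 2, 4), c(3, 1, 4, 2))] <- eps_ts  # A<->G, C<->T
  diag(E) <- s
  E
}

#' Read-state probabilities for a diploid genotype
#'
#' The probability that a read from an individual of genotype `{y, z}`
#' is called A, C, G or T under the contamination-aware model: with
#' probability `1 - gamma` the read comes from the individual's own
#' genotype (one of the two gametic alleles, then the error channel);
#' with probability `gamma` it is a contaminant whose state is drawn
#' from `fprime`, the read frequencies at the position excluding the
#' focal individual, and then passed through the same error channel.
#' At `gamma = 0` this reduces exactly to the contamination-free model.
#'
#' @param genotype two base letters, e.g. `c("A", "C")`, or a two-letter
#'   string `"AC"`.
#' @param eps_ts,eps_tv error rates by substitution class.
#' @param gamma contamination probability in `[0, 1]`.
#' @param fprime length-4 read-frequency vector excluding the focal
#'   individual; required when `gamma > 0`. If it carries no reads
#'   (all zero) the quartet falls back to `gamma = 0`.
#' @return named length-4 probability vector (sums to 1).
#' @examples
#' read_state_probs("AA", eps_ts = 0.01, eps_tv = 0.01)    # (0.97, ...)
#' read_state_probs("AC", eps_ts = 0.01, eps_tv = 0.01)    # (0.49, 0.49, ...)
#' @export
read_state_probs <- function(genotype, eps_ts, eps_tv, gamma = 0,
                             fprime = NULL) {
  g <- .parse_genotype(genotype)
  E <- error_emission_matrix(eps_ts, eps_tv)
  own <- 0.5 * (E[g[1], ] + E[g[2], ])
  if (gamma == 0) return(own)
  if (is.null(fprime) || sum(fprime) <= 0) {
    warning("gamma > 0 but no non-focal reads: falling back to gamma = 0")
    return(own)
  }
  fprime <- fprime / sum(fprime)
  contam <- as.vector(fprime %*% E)
  setNames((1 - gamma) * own + gamma * contam, BASES)
}

.parse_genotype <- function(genotype) {
  if (is.character(genotype) && length(genotype) == 1 &&
      nchar(genotype) == 2)
    genotype <- strsplit(genotype, "")[[1]]
  g <- base_index(genotype)
  if (length(g) != 2 || any(is.na(g))) stop("invalid genotype")
  g
}

#' Likelihood of a quartet under the read-count mixture model
#'
#' Sums, over the ten possible diploid genotypes weighted by their
#' Hardy–Weinberg priors from the population allele frequencies `f`, the
#' multinomial probability of the observed read counts with per-read
#' state probabilities from [read_state_probs()]. The heterozygote prior
#' is `2 f_a f_b` by default (`het_factor2 = FALSE` drops the factor 2).
#'
#' @param counts length-4 read counts (A, C, G, T).
#' @param f length-4 population allele frequencies at the position.
#' @param eps_ts,eps_tv,gamma,fprime model parameters, see
#'   [read_state_probs()].
#' @param het_factor2 include the Hardy–Weinberg factor 2 on
#'   heterozygote priors (default TRUE).
#' @return the probability of the quartet.
#' @export
quartet_likelihood <- function(counts, f, eps_ts, eps_tv, gamma = 0,
                               fprime = NULL, het_factor2 = TRUE) {
  stopifnot(length(counts) == 4, length(f) == 4)
  tot <- 0
  for (g in seq_len(10)) {
    y <- GT_PAIRS[g, 1]; z <- GT_PAIRS[g, 2]
    w <- f[y] * f[z] * if (het_factor2 && y != z) 2 else 1
    if (w == 0) next
    p <- suppressWarnings(
      read_state_probs(BASES[c(y, z)], eps_ts, eps_tv, gamma, fprime))
    tot <- tot + w * stats::dmultinom(counts, prob = p)
  }
  tot
}

# Assemble the per-quartet matrices the C++ kernel needs: read counts R,
# per-position pooled allele frequencies F ("estimated from observed
# read counts"), and the leave-one-out read frequencies Fp.
.site_data <- function(quartets) {
  quartets <- .check_quartets(quartets)
  m <- as.matrix(quartets[, c("nA", "nC", "nG", "nT")])
  storage.mode(m) <- "integer"
  poskey <- paste(quartets$species, quartets$contig, quartets$pos,
                  sep = "\r")
  tot <- rowsum(m, poskey)
  idx <- match(poskey, rownames(tot))
  ptot <- tot[idx, , drop = FALSE]
  gs <- rowSums(ptot)
  fmat <- ptot / ifelse(gs > 0, gs, 1)
  other <- ptot - m
  os <- rowSums(other)
  Fp <- other / ifelse(os > 0, os, 1)
  Fp[os == 0, ] <- 0  # flags "no non-focal reads" to the kernel
  list(q = quartets, R = m, F = unname(fmat), Fp = unname(Fp),
       poskey = poskey)
}

#' Maximum-likelihood estimation of the error rates
#'
#' Maximises the summed log quartet likelihood over `(eps_ts, eps_tv)`
#' at a fixed contamination rate `gamma`, with allele frequencies per
#' position taken from pooled observed read counts. Bounded two-parameter
#' optimisation with fixed multi-start; deterministic.
#'
#' @param quartets quartet table.
#' @param gamma fixed contamination rate.
#' @param het_factor2 see [quartet_likelihood()].
#' @param starts matrix of starting values (rows = starts, columns =
#'   `eps_ts`, `eps_tv`); defaults to three fixed starts.
#' @param upper upper bound on each rate (default 0.2).
#' @return list with `eps_ts`, `eps_tv`, `loglik` (full, including the
#'   multinomial coefficient), `boundary` (TRUE when an estimate sits at
#'   the zero bound), `convergence`.
#' @export
estimate_error_rates <- function(quartets, gamma = 0, het_factor2 = TRUE,
                                 starts = NULL, upper = 0.2) {
  sd_ <- if (is.list(quartets) && !is.data.frame(quartets)) quartets
         else .site_data(quartets)
  if (is.null(starts))
    starts <- rbind(c(1e-3, 1e-3), c(1e-2, 3e-3), c(1e-4, 1e-4))
  nll <- function(par) {
    ll <- sum(cpp_quartet_loglik(sd_$R, sd_$F, sd_$Fp, par[1], par[2],
                                 gamma, het_factor2, FALSE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::nlminb(starts[i, ], nll, lower = c(0, 0),
                         upper = c(upper, upper),
                         control = list(abs.tol = 1e-8, rel.tol = 1e-10))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  coef_const <- sum(lgamma(rowSums(sd_$R) + 1)) -
    sum(lgamma(sd_$R + 1))
  list(eps_ts = best$par[1], eps_tv = best$par[2],
       loglik = -best$objective + coef_const,
       boundary = any(best$par < 1e-7),
       convergence = best$convergence)
}

#' Profile the contamination rate gamma over a grid
#'
#' Refits the error rates at every grid value of gamma and returns the
#' maximally likely gamma (`gamma_star`) together with the likelihood
#' profile. Exact ties are broken toward the smaller gamma (parsimony).
#' Each refit is warm-started from the previous grid point's estimate.
#'
#' @param quartets quartet table.
#' @param grid gamma values to profile; default `c(0, 0.05, 0.1, 0.2)`.
#' @param het_factor2 see [quartet_likelihood()].
#' @return list with `gamma_star`, `profile` (data frame: gamma, loglik,
#'   eps_ts, eps_tv), `fits`.
#' @export
select_gamma <- function(quartets, grid = c(0, 0.05, 0.1, 0.2),
                         het_factor2 = TRUE) {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  sd_ <- .site_data(quartets)
  fits <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    starts <- rbind(if (!is.null(prev)) c(prev$eps_ts, prev$eps_tv),
                    c(1e-3, 1e-3))
    fits[[i]] <- estimate_error_rates(sd_, gamma = grid[i],
                                      het_factor2 = het_factor2,
                                      starts = starts)
    prev <- fits[[i]]
  }
  ll <- vapply(fits, `[[`, 0, "loglik")
  gamma_star <- grid[which(ll == max(ll))[1]]  # ties -> smaller gamma
  list(gamma_star = gamma_star,
       profile = data.frame(gamma = grid, loglik = ll,
                            eps_ts = vapply(fits, `[[`, 0, "eps_ts"),
                            eps_tv = vapply(fits, `[[`, 0, "eps_tv")),
       fits = fits)
}

#' Contamination-aware genotype and SNP calling
#'
#' Computes, per individual and position, the posterior over the ten
#' diploid genotypes (Hardy–Weinberg prior from pooled read-count allele
#' frequencies times the multinomial read-count term), calls the
#' maximum-a-posteriori genotype when its posterior reaches
#' `posterior_threshold`, and flags as SNPs the positions at which at
#' least two distinct alleles occur among called genotypes.
#'
#' @param quartets quartet table.
#' @param gamma contamination rate used for calling.
#' @param eps_ts,eps_tv error rates; when `NULL` they are estimated by
#'   [estimate_error_rates()] at the given gamma.
#' @param posterior_threshold minimum posterior for a call (default
#'   0.95); zero-coverage quartets are never called.
#' @param het_factor2 see [quartet_likelihood()].
#' @return list with `calls` (data frame: species, contig, pos,
#'   individual, allele1, allele2, posterior, called), `snps` (data
#'   frame: species, contig, pos, alleles, n_alleles), `eps_ts`,
#'   `eps_tv`, `gamma`.
#' @export
call_genotypes <- function(quartets, gamma = 0, eps_ts = NULL,
                           eps_tv = NULL, posterior_threshold = 0.95,
                           het_factor2 = TRUE) {
  sd_ <- .site_data(quartets)
  if (is.null(eps_ts) || is.null(eps_tv)) {
    est <- estimate_error_rates(sd_, gamma = gamma,
                                het_factor2 = het_factor2)
    eps_ts <- est$eps_ts; eps_tv <- est$eps_tv
  }
  lp <- cpp_genotype_logpost(sd_$R, sd_$F, sd_$Fp, eps_ts, eps_tv, gamma,
                             het_factor2)
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  gbest <- max.col(post, ties.method = "first")
  pbest <- post[cbind(seq_len(nrow(post)), gbest)]
  cov <- rowSums(sd_$R)
  called <- is.finite(mx) & pbest >= posterior_threshold & cov > 0
  calls <- data.frame(
    species = sd_$q$species, contig = sd_$q$contig, pos = sd_$q$pos,
    individual = sd_$q$individual,
    allele1 = ifelse(called, BASES[GT_PAIRS[gbest, 1]], NA_character_),
    allele2 = ifelse(called, BASES[GT_PAIRS[gbest, 2]], NA_character_),
    posterior = pbest, called = called, stringsAsFactors = FALSE)
  snps <- .snp_table(calls)
  list(calls = calls, snps = snps, eps_ts = eps_ts, eps_tv = eps_tv,
       gamma = gamma)
}

.snp_table <- function(calls) {
  cc <- calls[calls$called, , drop = FALSE]
  if (nrow(cc) == 0L)
    return(data.frame(species = character(), contig = character(),
                      pos = integer(), alleles = character(),
                      n_alleles = integer(), stringsAsFactors = FALSE))
  key <- paste(cc$species, cc$contig, cc$pos, sep = "\r")
  al <- tapply(paste0(cc$allele1, cc$allele2), key, function(x) {
    sort(unique(unlist(strsplit(x, ""))))
  })
  n_alleles <- lengths(al)
  parts <- do.call(rbind, strsplit(names(al), "\r"))
  snp <- data.frame(species = parts[, 1], contig = parts[, 2],
                    pos = as.integer(parts[, 3]),
                    alleles = vapply(al, paste, "", collapse = ","),
                    n_alleles = as.integer(n_alleles),
                    stringsAsFactors = FALSE)
  snp <- snp[snp$n_alleles >= 2, , drop = FALSE]
  rownames(snp) <- NULL
  snp
}

#' Full genotyping pipeline with gamma model selection
#'
#' Profiles gamma over the grid, calls genotypes at the maximally likely
#' gamma, and returns a JSON-serialisable model report.
#'
#' @inheritParams select_gamma
#' @inheritParams call_genotypes
#' @return list with `selection` ([select_gamma()] result), `genotypes`
#'   ([call_genotypes()] result at `gamma_star`).
#' @export
genotype_pipeline <- function(quartets, grid = c(0, 0.05, 0.1, 0.2),
                              posterior_threshold = 0.95,
                              het_factor2 = TRUE) {
  sel <- select_gamma(quartets, grid = grid, het_factor2 = het_factor2)
  i <- match(sel$gamma_star, sel$profile$gamma)
  gt <- call_genotypes(quartets, gamma = sel$gamma_star,
                       eps_ts = sel$profile$eps_ts[i],
                       eps_tv = sel$profile$eps_tv[i],
                       posterior_threshold = posterior_threshold,
                       het_factor2 = het_factor2)
  list(selection = sel, genotypes = gt)
}
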