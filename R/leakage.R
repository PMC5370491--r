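#' Estimate the contamination-free error matrix P
#'
#' From homo-quartet records at monoallelic positions, tabulates
#' `h_mono(a, b)` — the number of homo-quartets with major state `a` and
#' minor state `b` — and row-normalises it into `P(a, b)`, the
#' probability that an error from major state `a` is called `b`. Rows
#' with no observations are flagged undefined (NA).
#'
#' @param records homo-quartet records from [extract_homo_quartets()];
#'   only rows with `class == "monoallelic"` are used.
#' @return an object of class `error_matrix`: list with `P` (4x4, rows =
#'   major state), `h_mono` (counts), `row_totals`, `undefined` (logical
#'   per row).
#' @export
error_matrix <- function(records) {
  rec <- records[records$class == "monoallelic", , drop = FALSE]
  h <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  if (nrow(rec)) {
    tab <- table(factor(rec$major, BASES), factor(rec$minor, BASES))
    h <- h + unclass(tab)
  }
  diag(h) <- 0L
  rt <- rowSums(h)
  if (all(rt == 0))
    stop("all rows of the error matrix are undefined: no monoallelic ",
         "homo-quartets")
  P <- h / ifelse(rt > 0, rt, NA_real_)
  diag(P) <- 0
  P[rt == 0, ] <- NA_real_
  structure(list(P = P, h_mono = h, row_totals = rt, undefined = rt == 0),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("Homo-quartet error matrix P (rows = major state),",
      sum(x$row_totals), "records\n")
  print(round(x$P, 4))
  invisible(x)
}

#' Observed prevalence of the other segregating allele
#'
#' Over homo-quartets at biallelic positions, the fraction whose minor
#' state equals `z`, the allele different from the major state
#' segregating at the position.
#'
#' @param records homo-quartet records; only biallelic rows are used.
#' @return list with `q_obs` and `h_bi` (number of records used).
#' @export
q_observed <- function(records) {
  rec <- records[records$class == "biallelic" & !is.na(records$r_z), ,
                 drop = FALSE]
  if (nrow(rec) == 0L)
    stop("q_obs undefined: no homo-quartets at biallelic positions")
  list(q_obs = mean(rec$r_z), h_bi = nrow(rec))
}

#' Expected prevalence of the other segregating allele under P
#'
#' The error-matrix expectation of [q_observed()]: sum of `P(a, z)` over
#' biallelic homo-quartets divided by the sum of full rows `P(a, .)`.
#' Because each defined row of P sums to one, this equals the mean of
#' `P(a, z)` over the retained records; both forms are computed and must
#' agree. Records whose major state has an undefined P row are skipped
#' from numerator and denominator (counted in `n_skipped`).
#'
#' @param records homo-quartet records; only biallelic rows are used.
#' @param em an [error_matrix()].
#' @return list with `q_exp`, `n_used`, `n_skipped`.
#' @export
q_expected <- function(records, em) {
  rec <- records[records$class == "biallelic" & !is.na(records$z), ,
                 drop = FALSE]
  if (nrow(rec) == 0L)
    stop("q_exp undefined: no homo-quartets at biallelic positions")
  defined <- !em$undefined[base_index(rec$major)]
  rec <- rec[defined, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("q_exp undefined: all records have undefined P rows")
  num <- sum(em$P[cbind(base_index(rec$major), base_index(rec$z))])
  den <- sum(rowSums(em$P, na.rm = TRUE)[base_index(rec$major)])
  list(q_exp = num / den, n_used = nrow(rec), n_skipped = sum(!defined))
}

#' Allele-leakage index lambda
#'
#' `lambda = (q_obs - q_exp) / q_exp`: the relative excess, over the
#' error-matrix expectation, of homo-quartet minor states matching the
#' other segregating allele. Zero is expected in the absence of
#' contamination.
#'
#' @param q_obs,q_exp observed and expected prevalences.
#' @return numeric lambda.
#' @export
lambda_index <- function(q_obs, q_exp) {
  if (!is.finite(q_exp) || q_exp <= 0)
    stop("lambda undefined: q_exp must be positive")
  (q_obs - q_exp) / q_exp
}

#' Per-species allele-leakage report
#'
#' Runs the full leakage pipeline per species: homo-quartet extraction,
#' error matrix, q_obs, q_exp and lambda. Species with fewer than
#' `min_hbi` biallelic homo-quartets are reported with `lambda = NA`
#' (too few records for a stable index).
#'
#' @param quartets quartet table (see [extract_homo_quartets()]).
#' @param min_hbi minimum number of biallelic homo-quartets required to
#'   report lambda for a species; default 50.
#' @param ... thresholds passed to [extract_homo_quartets()].
#' @return data frame, one row per species: `species`, `h_mono`, `h_bi`,
#'   `q_obs`, `q_exp`, `lambda`. The per-species [error_matrix()] objects
#'   are attached as the attribute `error_matrices`.
#' @export
leakage_report <- function(quartets, min_hbi = 50, ...) {
  records <- extract_homo_quartets(quartets, ...)
  sp <- unique(records$species)
  ems <- list()
  rows <- lapply(sp, function(s) {
    rec <- records[records$species == s, , drop = FALSE]
    em <- error_matrix(rec)
    ems[[s]] <<- em
    hb <- sum(rec$class == "biallelic" & !is.na(rec$r_z))
    if (hb == 0) {
      return(data.frame(species = s, h_mono = sum(em$row_totals), h_bi = 0L,
                        q_obs = NA_real_, q_exp = NA_real_,
                        lambda = NA_real_))
    }
    qo <- q_observed(rec)
    qe <- q_expected(rec, em)
    lam <- if (hb >= min_hbi) lambda_index(qo$q_obs, qe$q_exp) else NA_real_
    data.frame(species = s, h_mono = sum(em$row_totals), h_bi = hb,
               q_obs = qo$q_obs, q_exp = qe$q_exp, lambda = lam)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, error_matrices = ems)
}

#' Between-group allele-leakage index lambda-prime
#'
#' Restricts the leakage statistic to contamination *between* groups of
#' individuals (e.g. shipment batches): only homo-quartets at positions
#' that are biallelic across the whole species sample but monoallelic
#' (by the `major_frac` rule applied to group-restricted totals) within
#' the focal individual's group are retained. Numerators and
#' denominators of q_obs / q_exp are pooled across species, each record
#' scored against its own species' error matrix.
#'
#' @param quartets quartet table covering one or more species.
#' @param groups named character vector mapping individual id to group
#'   label.
#' @param min_hbi unused per species (pooling is the point); kept for
#'   symmetry with [leakage_report()].
#' @param major_threshold,major_frac,biallelic_factor thresholds as in
#'   [extract_homo_quartets()].
#' @return list with `lambda_prime`, `q_obs`, `q_exp`, `h` (pooled record
#'   count), `groups` (the grouping used) and `per_species` counts.
#' @export
lambda_between_groups <- function(quartets, groups, min_hbi = 0,
                                  major_threshold = 40, major_frac = 0.95,
                                  biallelic_factor = 10) {
  quartets <- .check_quartets(quartets)
  if (any(!quartets$individual %in% names(groups)))
    stop("every individual needs a group assignment")
  if (length(unique(groups[unique(quartets$individual)])) < 2)
    stop("lambda_prime undefined: all individuals are in a single group")

  num_obs <- 0; den_obs <- 0; num_exp <- 0; den_exp <- 0
  per_species <- list()
  for (s in unique(quartets$species)) {
    q <- quartets[quartets$species == s, , drop = FALSE]
    rec <- extract_homo_quartets(q, major_threshold, major_frac,
                                 biallelic_factor)
    em <- tryCatch(error_matrix(rec), error = function(e) NULL)
    if (is.null(em)) next
    bi <- rec[rec$class == "biallelic" & !is.na(rec$z), , drop = FALSE]
    if (nrow(bi) == 0L) next
    # group-restricted totals at each position
    m <- as.matrix(q[, c("nA", "nC", "nG", "nT")])
    gkey <- paste(q$contig, q$pos, groups[q$individual], sep = "\r")
    gt <- rowsum(m, gkey)
    gmax <- apply(gt, 1, max)
    gsum <- rowSums(gt)
    mono_in_group <- gmax > major_frac * gsum
    names(mono_in_group) <- rownames(gt)
    bk <- paste(bi$contig, bi$pos, groups[bi$individual], sep = "\r")
    keep <- bi[mono_in_group[bk] %in% TRUE, , drop = FALSE]
    keep <- keep[!em$undefined[base_index(keep$major)], , drop = FALSE]
    if (nrow(keep) == 0L) next
    num_obs <- num_obs + sum(keep$r_z)
    den_obs <- den_obs + nrow(keep)
    num_exp <- num_exp +
      sum(em$P[cbind(base_index(keep$major), base_index(keep$z))])
    den_exp <- den_exp +
      sum(rowSums(em$P, na.rm = TRUE)[base_index(keep$major)])
    per_species[[s]] <- nrow(keep)
  }
  if (den_obs == 0)
    stop("lambda_prime undefined: no qualifying homo-quartets ",
         "(biallelic overall, monoallelic within-group)")
  q_obs <- num_obs / den_obs
  q_exp <- num_exp / den_exp
  lp <- if (is.finite(q_exp) && q_exp > 0) lambda_index(q_obs, q_exp)
        else {
          warning("lambda_prime undefined: pooled q_exp is zero")
          NA_real_
        }
  list(lambda_prime = lp, q_obs = q_obs,
       q_exp = q_exp, h = den_obs, groups = groups,
       per_species = unlist(per_species))
}

#' Pooled error-class summary of an error matrix
#'
#' Without strand information an X->Y error cannot be told apart from
#' its complement X*->Y*, so counts are pooled into six strand-ambiguous
#' classes: two transition classes (A->G/T->C and G->A/C->T) and four
#' transversion classes (A->C/T->G, A->T/T->A, C->A/G->T, C->G/G->C).
#'
#' Two composition-corrected ratios are reported. The transition:
#' transversion ratio is corrected against its expectation under errors
#' uniform over the three alternative bases — that expectation is 1/3 of
#' errors being transitions *for any* base composition (every base has
#' exactly one transition target), so the corrected ratio equals the raw
#' count ratio and equals 0.5 under random error. The share of the
#' A->C/T->G class among transversions does depend on composition
#' (expected class weight proportional to the frequencies of the source
#' major states); it is reported as observed/expected ratio relative to
#' the other transversion classes, with 1/3 being the random-error value
#' at equal base composition.
#'
#' @param em an [error_matrix()].
#' @return list with `class_counts` (named, pooled), `ts_tv_ratio`
#'   (composition-corrected; `Inf` flagged when no transversions),
#'   `actg_vs_other_tv` (observed ratio), `actg_vs_other_tv_expected`
#'   (composition expectation), `base_composition` (major-state
#'   frequencies among homo-quartets).
#' @export
error_class_summary <- function(em) {
  h <- em$h_mono
  cls <- c(
    AG_TC = h["A", "G"] + h["T", "C"],
    GA_CT = h["G", "A"] + h["C", "T"],
    AC_TG = h["A", "C"] + h["T", "G"],
    AT_TA = h["A", "T"] + h["T", "A"],
    CA_GT = h["C", "A"] + h["G", "T"],
    CG_GC = h["C", "G"] + h["G", "C"])
  ts <- cls[["AG_TC"]] + cls[["GA_CT"]]
  tv <- sum(cls) - ts
  comp <- em$row_totals / sum(em$row_totals)
  # uniform-error expectation: 1/3 transitions regardless of composition,
  # so corrected ts/tv is the raw ratio (random error -> 0.5)
  ts_tv <- if (tv == 0) Inf else ts / tv
  # transversion class masses under uniform error given composition
  w_actg <- (comp[["A"]] + comp[["T"]]) / 2
  w_other <- (comp[["A"]] + comp[["T"]]) / 2 + (comp[["C"]] + comp[["G"]])
  exp_actg <- if (w_other > 0) w_actg / w_other else NA_real_
  other_tv <- tv - cls[["AC_TG"]]
  obs_actg <- if (other_tv == 0) Inf else cls[["AC_TG"]] / other_tv
  list(class_counts = cls,
       ts_tv_ratio = ts_tv,
       ts_tv_infinite = !is.finite(ts_tv),
       actg_vs_other_tv = obs_actg,
       actg_vs_other_tv_expected = exp_actg,
       base_composition = comp)
}

#' Write a per-species leakage report as JSON
#'
#' @param report result of [leakage_report()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_leakage_json <- function(report, path) {
  ems <- attr(report, "error_matrices")
  obj <- lapply(seq_len(nrow(report)), function(i) {
    s <- report$species[i]
    em <- ems[[s]]
    list(species = s,
         h_mono = unname(em$row_totals),
         P = unname(em$P),
         h_bi = report$h_bi[i],
         q_obs = report$q_obs[i],
         q_exp = report$q_exp[i],
         lambda = report$lambda[i])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
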