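#' Per-species-pair metadata predictors
#'
#' Derives, for every unordered species pair, the five predictors of
#' contamination probability: `lab_overlap` (days of intersection of the
#' two species' laboratory processing periods, where a species' period
#' runs from its first entry date to its last shipment date),
#' `same_technician`, `same_shipment` (same day *and* same center),
#' `same_flowcell`, `same_lane` (booleans; the latter two are NA for
#' pairs involving a species with missing flowcell/lane information),
#' plus the synthetic `lab` (+/-) and `center` tier (-, +, ++, +++).
#'
#' `lab` is positive when `same_technician` and `lab_overlap` exceeds
#' `lab_overlap_days`; `lab_overlap_greater = FALSE` flips the reading
#' to "overlap below the threshold".
#'
#' @param metadata per-sample metadata: columns `species`, `individual`,
#'   `technician`, `entry_date`, `shipment_date`, `center`, and
#'   optionally `flowcell`, `lane`.
#' @param lab_overlap_days threshold for the `lab` coding (default 200).
#' @param lab_overlap_greater direction of the threshold (default TRUE:
#'   overlap must exceed the threshold).
#' @return data frame, one row per unordered pair: `species1`,
#'   `species2`, `lab_overlap`, `same_technician`, `same_shipment`,
#'   `same_flowcell`, `same_lane`, `lab`, `center`.
#' @export
pair_predictors <- function(metadata, lab_overlap_days = 200,
                            lab_overlap_greater = TRUE) {
  md <- metadata
  md$entry_date <- as.Date(md$entry_date)
  md$shipment_date <- as.Date(md$shipment_date)
  if (any(md$entry_date > md$shipment_date, na.rm = TRUE))
    stop("entry dates must precede shipment dates")
  sp <- sort(unique(md$species))
  per <- lapply(sp, function(s) {
    r <- md[md$species == s, , drop = FALSE]
    has_fc <- "flowcell" %in% names(r) && !anyNA(r$flowcell)
    has_lane <- has_fc && "lane" %in% names(r) && !anyNA(r$lane)
    list(start = min(r$entry_date), end = max(r$shipment_date),
         tech = unique(r$technician),
         ship = unique(paste(r$shipment_date, r$center)),
         fc = if (has_fc) unique(paste(r$shipment_date, r$center,
                                       r$flowcell)) else NULL,
         lane = if (has_lane) unique(paste(r$shipment_date, r$center,
                                           r$flowcell, r$lane)) else NULL)
  })
  names(per) <- sp
  pairs <- utils::combn(sp, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- per[[pr[1]]]; b <- per[[pr[2]]]
    ov <- max(0, as.numeric(min(a$end, b$end) - max(a$start, b$start)))
    st <- length(intersect(a$tech, b$tech)) > 0
    ss <- length(intersect(a$ship, b$ship)) > 0
    sf <- if (is.null(a$fc) || is.null(b$fc)) NA
          else length(intersect(a$fc, b$fc)) > 0
    sl <- if (is.null(a$lane) || is.null(b$lane)) NA
          else length(intersect(a$lane, b$lane)) > 0
    data.frame(species1 = pr[1], species2 = pr[2], lab_overlap = ov,
               same_technician = st, same_shipment = ss,
               same_flowcell = sf, same_lane = sl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ovpass <- if (lab_overlap_greater) out$lab_overlap > lab_overlap_days
            else out$lab_overlap < lab_overlap_days
  out$lab <- ifelse(out$same_technician & ovpass, "+", "-")
  out$center <- ifelse(!out$same_shipment, "-",
                ifelse(out$same_lane %in% TRUE, "+++",
                ifelse(out$same_flowcell %in% TRUE, "++", "+")))
  out$center[out$same_shipment &
               (is.na(out$same_flowcell) | is.na(out$same_lane))] <- NA
  out
}

# value of a pair predictor for every directed cell of M, as a vector
# aligned with the non-missing cells; predictors are symmetric, so a
# directed cell inherits its unordered pair's value
.cell_values <- function(M, pred, predictor) {
  key <- paste(pred$species1, pred$species2, sep = "\r")
  val <- setNames(as.numeric(pred[[predictor]]), key)
  cells <- which(!is.na(M$m), arr.ind = TRUE)
  i <- rownames(M$m)[cells[, 1]]
  j <- colnames(M$m)[cells[, 2]]
  k <- ifelse(i < j, paste(i, j, sep = "\r"), paste(j, i, sep = "\r"))
  list(cells = cells, value = unname(val[k]))
}

#' Observed metadata statistic over contaminated pairs
#'
#' The mean of a pair predictor over the non-missing cells of the
#' contamination matrix that equal one.
#'
#' @param M a [build_contamination_matrix()] result.
#' @param pred a [pair_predictors()] table.
#' @param predictor predictor column name.
#' @return list with `observed` (mean), `n_ones`, `n_dropped` (cells
#'   whose pair has an NA predictor value).
#' @export
observed_statistic <- function(M, pred, predictor) {
  cv <- .cell_values(M, pred, predictor)
  ones <- M$m[cv$cells] == 1
  if (!any(ones)) stop("no contaminated pairs: statistic undefined")
  v <- cv$value[ones]
  list(observed = mean(v, na.rm = TRUE), n_ones = sum(ones),
       n_dropped = sum(is.na(v)))
}

#' Unconditional randomisation null for a metadata statistic
#'
#' Every non-missing cell of the contamination matrix is redrawn as one
#' with probability `p` (the matrix's overall proportion of ones) and
#' zero otherwise; missing cells are left unchanged. Returns the
#' distribution of the mean-predictor statistic over replicates.
#'
#' @param M contamination matrix.
#' @param pred predictor table.
#' @param predictor predictor column name.
#' @param reps replicates (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `reps` replicate statistics (NA for
#'   replicates with zero ones).
#' @export
randomize_unconditional <- function(M, pred, predictor, reps = 1000,
                                    seed = 1) {
  cv <- .cell_values(M, pred, predictor)
  set.seed(seed)
  n <- nrow(cv$cells)
  draws <- matrix(rbinom(reps * n, 1, M$p), reps, n)
  .null_stats(draws, cv$value)
}

.null_stats <- function(draws, value) {
  ok <- !is.na(value)
  num <- draws[, ok, drop = FALSE] %*% value[ok]
  den <- rowSums(draws[, ok, drop = FALSE])
  as.vector(ifelse(den > 0, num / den, NA))
}

#' Conditional randomisation null
#'
#' As [randomize_unconditional()], but each cell's probability of one is
#' the observed proportion of ones in its conditioning stratum, so the
#' null preserves the dependence of contamination on the conditioning
#' predictors. Boolean conditioners stratify by value; `lab_overlap` is
#' binned into quartiles. Empty strata (no observed ones) keep
#' probability 0.
#'
#' @param M contamination matrix.
#' @param pred predictor table.
#' @param predictor predictor whose null distribution is wanted.
#' @param condition_on character vector of conditioning predictors.
#' @param reps,seed as in [randomize_unconditional()].
#' @return numeric vector of replicate statistics; stratum probabilities
#'   attached as attribute `stratum_probs`.
#' @export
randomize_conditional <- function(M, pred, predictor, condition_on,
                                  reps = 1000, seed = 1) {
  cv <- .cell_values(M, pred, predictor)
  strat <- rep("", nrow(cv$cells))
  for (cond in condition_on) {
    v <- .cell_values(M, pred, cond)$value
    if (cond == "lab_overlap") {
      qs <- unique(stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE))
      v <- as.integer(cut(v, c(-Inf, qs, Inf)))
    }
    strat <- paste(strat, v, sep = "|")
  }
  obs <- M$m[cv$cells]
  ps <- tapply(obs, strat, mean)
  pcell <- unname(ps[strat])
  pcell[is.na(pcell)] <- 0
  set.seed(seed)
  n <- nrow(cv$cells)
  draws <- matrix(rbinom(reps * n, 1, rep(pcell, each = reps)), reps, n)
  structure(.null_stats(draws, cv$value), stratum_probs = ps)
}

#' Add-one empirical p-value
#'
#' `(number of null values at least as extreme as the observed + 1) /
#' (replicates + 1)`.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of null replicates (NAs dropped).
#' @param tail `"upper"` (default) or `"lower"`.
#' @return the p-value.
#' @export
empirical_pvalue <- function(observed, nulls,
                             tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  nulls <- nulls[!is.na(nulls)]
  if (length(nulls) == 0) stop("empty null sample")
  k <- if (tail == "upper") sum(nulls >= observed)
       else sum(nulls <= observed)
  (k + 1) / (length(nulls) + 1)
}

#' Contamination probability grid by laboratory and center variables
#'
#' Tabulates, for each center tier crossed with the lab coding, the
#' number of connected (contaminated, in either direction) unordered
#' species pairs over the total, with the probability as their ratio.
#' Center rows are cumulative by default (same shipment includes same
#' flowcell includes same lane, matching the nesting of the variables);
#' `cumulative = FALSE` reports disjoint tiers.
#'
#' @param M contamination matrix.
#' @param pred predictor table (with `lab` and `center` columns).
#' @param cumulative report cumulative center rows (default TRUE).
#' @return data frame: `center`, `lab`, `n_connected`, `n_pairs`,
#'   `probability`.
#' @export
stratified_probabilities <- function(M, pred, cumulative = TRUE) {
  pairs <- .connected_pairs(M, pred)
  pair_probability_table(pairs, cumulative = cumulative)
}

# unordered pairs with both species in M, at least one non-missing
# directed cell and a defined center tier
.connected_pairs <- function(M, pred) {
  keep <- pred$species1 %in% c(rownames(M$m), colnames(M$m)) &
    pred$species2 %in% c(rownames(M$m), colnames(M$m))
  pr <- pred[keep, , drop = FALSE]
  get <- function(i, j) {
    if (i %in% rownames(M$m) && j %in% colnames(M$m)) M$m[i, j]
    else NA_integer_
  }
  con <- mapply(function(a, b) {
    v <- c(get(a, b), get(b, a))
    if (all(is.na(v))) NA else any(v == 1, na.rm = TRUE)
  }, pr$species1, pr$species2)
  pr$connected <- as.logical(con)
  pr[!is.na(pr$connected), , drop = FALSE]
}

#' Probability grid from a pair table
#'
#' Lower-level worker behind [stratified_probabilities()]: takes a data
#' frame of unordered pairs with `connected` (logical), `center` tier
#' (`-`, `+`, `++`, `+++`) and `lab` (`-`/`+`) and returns the
#' probability grid.
#'
#' @param pairs data frame as described.
#' @param cumulative cumulative center rows (default TRUE).
#' @return data frame: `center`, `lab`, `n_connected`, `n_pairs`,
#'   `probability` (NA for empty cells).
#' @export
pair_probability_table <- function(pairs, cumulative = TRUE) {
  pairs <- pairs[!is.na(pairs$center) & !is.na(pairs$lab), , drop = FALSE]
  tiers <- if (cumulative)
    list("-" = "-", "+" = c("+", "++", "+++"),
         "++" = c("++", "+++"), "+++" = "+++")
  else list("-" = "-", "+" = "+", "++" = "++", "+++" = "+++")
  rows <- list()
  for (tn in names(tiers)) {
    for (lb in c("-", "+")) {
      sel <- pairs$center %in% tiers[[tn]] & pairs$lab == lb
      n <- sum(sel)
      k <- sum(pairs$connected[sel])
      rows[[length(rows) + 1]] <-
        data.frame(center = tn, lab = lb, n_connected = k, n_pairs = n,
                   probability = if (n > 0) k / n else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Subsample one species per technician-by-shipment stratum
#'
#' Control analysis removing the induced correlation between technician
#' and shipment: keeps a single randomly chosen species per (technician,
#' shipment) stratum. Species spanning several strata are assigned to
#' their earliest stratum by shipment date (`multi = "earliest"`), or
#' entered in all their strata (`multi = "all"`).
#'
#' @param metadata per-sample metadata.
#' @param seed integer seed.
#' @param multi how species spanning several strata are assigned.
#' @return character vector of retained species.
#' @export
subsample_one_per_stratum <- function(metadata, seed = 1,
                                      multi = c("earliest", "all")) {
  multi <- match.arg(multi)
  md <- metadata
  md$shipment_date <- as.Date(md$shipment_date)
  st <- unique(md[, c("species", "technician", "shipment_date")])
  if (multi == "earliest") {
    st <- st[order(st$species, st$shipment_date), , drop = FALSE]
    st <- st[!duplicated(st$species), , drop = FALSE]
  }
  st$stratum <- paste(st$technician, st$shipment_date)
  set.seed(seed)
  picks <- tapply(st$species, st$stratum, function(x)
    if (length(x) == 1) x else x[sample.int(length(x), 1)])
  sort(unique(unname(picks)))
}

#' Metadata significance report
#'
#' Convenience wrapper producing, for each predictor, the observed
#' statistic, the null mean/sd and the add-one empirical p-value, under
#' the unconditional null or conditioning on other predictors.
#'
#' @param M contamination matrix.
#' @param pred predictor table.
#' @param predictors predictors to test.
#' @param condition_on optional conditioning predictors.
#' @param reps,seed randomisation settings.
#' @return data frame: `predictor`, `observed`, `null_mean`, `null_sd`,
#'   `p`.
#' @export
metadata_test <- function(M, pred,
                          predictors = c("lab_overlap",
                                         "same_technician",
                                         "same_shipment",
                                         "same_flowcell", "same_lane"),
                          condition_on = NULL, reps = 1000, seed = 1) {
  rows <- lapply(predictors, function(pn) {
    obs <- observed_statistic(M, pred, pn)$observed
    nulls <- if (is.null(condition_on))
      randomize_unconditional(M, pred, pn, reps, seed)
    else randomize_conditional(M, pred, pn, condition_on, reps, seed)
    data.frame(predictor = pn, observed = obs,
               null_mean = mean(nulls, na.rm = TRUE),
               null_sd = stats::sd(nulls, na.rm = TRUE),
               p = empirical_pvalue(obs, nulls),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
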