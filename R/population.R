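#' S-phase fraction from EdU counts
#'
#' @param nEduPositive count of EdU-positive nuclei.
#' @param nNuclei total nuclei counted (> 0).
#' @return fraction in `[0, 1]` (vectorized).
#' @export
sphaseFraction <- function(nEduPositive, nNuclei) {
  if (any(nNuclei <= 0)) stop("nNuclei must be > 0")
  if (any(nEduPositive < 0 | nEduPositive > nNuclei))
    stop("nEduPositive must lie in [0, nNuclei]")
  nEduPositive / nNuclei
}

#' Proliferation fold change with parental normalization
#'
#' Per observation, the S-phase fraction with doxycycline divided by that
#' without; each fold is then divided by the mean fold of the parental
#' cells, so the parental normalized mean is exactly 1 (the dashed line of
#' the condition plots).
#'
#' @param doxFraction,nodoxFraction S-phase fractions of paired +Dox /
#'   -Dox observations (vectorized).
#' @param parentalFolds numeric vector of raw +Dox/-Dox folds of parental
#'   observations, non-empty.
#' @return list with `fold` (raw folds, `NA` where the no-dox fraction is
#'   zero) and `normalized` (folds divided by the parental mean).
#' @export
proliferationFoldChange <- function(doxFraction, nodoxFraction,
                                    parentalFolds) {
  if (!length(parentalFolds)) stop("parental set must be non-empty")
  fold <- ifelse(nodoxFraction > 0, doxFraction / nodoxFraction, NA_real_)
  list(fold = fold,
       normalized = fold / mean(parentalFolds, na.rm = TRUE))
}

#' Fold changes from an EdU count table
#'
#' Pairs +Dox and -Dox observations by position and population, computes
#' raw S-phase fold changes, and normalizes by the mean parental fold.
#'
#' @param edu EdU count table (columns `position`, `population`, `dox`,
#'   `n_nuclei`, `n_edu_positive`).
#' @param parentalPopulation population label used as the normalization
#'   baseline.
#' @return data.frame with `position`, `population`, `fold`,
#'   `normalized_fold`.
#' @export
eduFoldTable <- function(edu, parentalPopulation = "parental") {
  doxT <- edu[edu$dox, , drop = FALSE]
  doxF <- edu[!edu$dox, , drop = FALSE]
  key <- function(d) paste(d$position, d$population)
  m <- match(key(doxT), key(doxF))
  if (any(is.na(m))) stop("unpaired +Dox observation")
  fracD <- sphaseFraction(doxT$n_edu_positive, doxT$n_nuclei)
  fracN <- sphaseFraction(doxF$n_edu_positive[m], doxF$n_nuclei[m])
  fold <- ifelse(fracN > 0, fracD / fracN, NA_real_)
  isPar <- doxT$population == parentalPopulation
  if (!any(isPar)) stop("no parental observations to normalize against")
  parMean <- mean(fold[isPar], na.rm = TRUE)
  data.frame(position = doxT$position, population = doxT$population,
             fold = fold, normalized_fold = fold / parMean,
             stringsAsFactors = FALSE)
}

#' Proportion-response relation across coculture compositions
#'
#' One row per imaging position: the percent of inducible nuclei and the
#' S-phase fold change of the neighboring population at that position —
#' the raw material of the coculture proportion-response curve.
#'
#' @param edu EdU count table covering `inducible` and `neighbor`
#'   populations with paired dox arms per position.
#' @return data.frame with `position`, `percent_inducible`, `fold`.
#' @export
proportionResponseCurve <- function(edu) {
  positions <- unique(edu$position)
  out <- lapply(positions, function(p) {
    sub <- edu[edu$position == p, , drop = FALSE]
    dox <- sub[sub$dox, , drop = FALSE]
    tot <- sum(dox$n_nuclei)
    nInd <- sum(dox$n_nuclei[dox$population == "inducible"])
    nb <- sub[sub$population == "neighbor", , drop = FALSE]
    fd <- sphaseFraction(nb$n_edu_positive[nb$dox], nb$n_nuclei[nb$dox])
    fn <- sphaseFraction(nb$n_edu_positive[!nb$dox], nb$n_nuclei[!nb$dox])
    data.frame(position = p,
               percent_inducible = 100 * nInd / tot,
               fold = if (length(fd) && length(fn) && fn > 0) fd / fn
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Filter shed-protein records by significance and fold change
#'
#' Implements the supernatant-proteomics filter: retain proteins
#' statistically significant (raw p below `pMax`) in both the +Dox vs -Dox
#' and the WT vs sheddase-KO comparisons, and classify retained proteins
#' as in-box when both natural-log fold changes exceed `log(fcMin)` —
#' induction-dependent, sheddase-dependent release.  Output is ranked by
#' `ln_fc_dox` descending.  The filter is monotone: relaxing `pMax` or
#' `fcMin` never removes a retained record.
#'
#' @param records data.frame with columns `protein`, `ln_fc_dox`,
#'   `ln_fc_ko`, `p_dox`, `p_ko`.
#' @param pMax significance cutoff on both raw p-values.
#' @param fcMin fold-change cutoff (natural scale) for the in-box call.
#' @return the retained records, ranked, with added logical column
#'   `in_box`.
#' @export
filterShedProteins <- function(records, pMax = 0.05, fcMin = 1.5) {
  need <- c("protein", "ln_fc_dox", "ln_fc_ko", "p_dox", "p_ko")
  if (!all(need %in% names(records)))
    stop("records must contain ", paste(need, collapse = ", "))
  keep <- records$p_dox < pMax & records$p_ko < pMax
  out <- records[keep, , drop = FALSE]
  out$in_box <- out$ln_fc_dox > log(fcMin) & out$ln_fc_ko > log(fcMin)
  out[order(-out$ln_fc_dox), , drop = FALSE]
}

#' Per-protein fold changes and p-values from a shed-protein table
#'
#' Reduces a replicate-level abundance table (see [simulateShedTable()])
#' to one record per protein: natural-log fold changes of WT +Dox over WT
#' -Dox (`ln_fc_dox`) and of WT +Dox over KO +Dox (`ln_fc_ko`), with
#' unpaired t-test p-values across replicates on the log scale.
#'
#' @param table data.frame with `protein`, `genotype`, `dox`, `replicate`,
#'   `abundance`.
#' @return data.frame with the [filterShedProteins()] input schema.
#' @export
shedRecords <- function(table) {
  proteins <- unique(table$protein)
  grab <- function(p, g, d)
    log(table$abundance[table$protein == p & table$genotype == g &
                          table$dox == d])
  out <- lapply(proteins, function(p) {
    wtD <- grab(p, "WT", TRUE); wtN <- grab(p, "WT", FALSE)
    koD <- grab(p, "KO", TRUE)
    tDox <- stats::t.test(wtD, wtN)
    tKo <- stats::t.test(wtD, koD)
    data.frame(protein = p,
               ln_fc_dox = mean(wtD) - mean(wtN),
               ln_fc_ko = mean(wtD) - mean(koD),
               p_dox = tDox$p.value, p_ko = tKo$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
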