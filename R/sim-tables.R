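#' Simulate an EdU incorporation count table
#'
#' Emulates image-based S-phase scoring of fixed monolayers: for each
#' imaging position and population, the number of EdU-positive nuclei is a
#' binomial draw at that population's true S-phase fraction.  Positions are
#' generated in +Dox / -Dox pairs so that fold changes over the no-dox
#' control can be formed per position.
#'
#' @param nPositions number of imaging positions per dox arm.
#' @param fractions named list giving, per population (e.g. `inducible`,
#'   `neighbor`, `parental`), a length-2 numeric `c(nodox =, dox =)` of
#'   true S-phase fractions in `[0, 1]`.
#' @param nNucleiPerPosition expected nuclei counted per population and
#'   position (Poisson-distributed around this); either a single number or
#'   a named vector keyed by population, so coculture compositions (e.g. a
#'   1% inducible fraction) can be emulated.
#' @param condition condition label stored in the table.
#' @param seed integer seed or `NULL`.
#' @return list with `table` (data.frame: position, condition, population,
#'   dox, n_nuclei, n_edu_positive) and `truth` (the input fractions).
#' @export
#' @examples
#' sim <- simulateEduTable(4, list(neighbor = c(nodox = 0.1, dox = 0.3)),
#'                         seed = 1)
#' sim$table
simulateEduTable <- function(nPositions,
                             fractions = list(
                               inducible = c(nodox = 0.15, dox = 0.15),
                               neighbor = c(nodox = 0.10, dox = 0.30),
                               parental = c(nodox = 0.15, dox = 0.15)),
                             nNucleiPerPosition = 500,
                             condition = "sim", seed = NULL) {
  fr <- unlist(fractions)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  withSeed(seed, {
    rows <- list()
    for (popn in names(fractions)) {
      f <- fractions[[popn]]
      if (is.null(names(f))) names(f) <- c("nodox", "dox")
      nExp <- if (length(nNucleiPerPosition) > 1)
        nNucleiPerPosition[[popn]] else nNucleiPerPosition
      for (dox in c(FALSE, TRUE)) {
        p <- unname(f[[if (dox) "dox" else "nodox"]])
        n <- pmax(1L, stats::rpois(nPositions, nExp))
        k <- stats::rbinom(nPositions, n, p)
        rows[[length(rows) + 1L]] <- data.frame(
          position = sprintf("pos_%02d", seq_len(nPositions)),
          condition = condition, population = popn, dox = dox,
          n_nuclei = n, n_edu_positive = k, stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows),
         truth = list(fractions = fractions,
                      nNucleiPerPosition = nNucleiPerPosition))
  })
}

#' Simulate a shed-protein (supernatant proteomics) abundance table
#'
#' Emulates triplicate relative-abundance measurements of supernatant
#' proteins across four conditions (WT and sheddase-KO cells, each with and
#' without oncogene induction).  Designated "hit" proteins are elevated in
#' the induced wild-type condition only — the signature of
#' induction-dependent, sheddase-dependent release; all other proteins and
#' conditions share a common baseline.  Replicate measurements are
#' log-normal with coefficient of variation `replicateCv`.
#'
#' @param nProteins total proteins.
#' @param nHits number of designated hits (`<= nProteins`).
#' @param effectLnfc natural-log fold change of hits in the WT +Dox
#'   condition.
#' @param replicateCv replicate coefficient of variation on the natural
#'   scale.
#' @param nReplicates replicates per condition.
#' @param seed integer seed or `NULL`.
#' @return list with `table` (data.frame: protein, genotype in
#'   `{WT, KO}`, dox, replicate, abundance) and `truth` (hit ids and
#'   per-protein true ln fold changes).
#' @export
simulateShedTable <- function(nProteins = 200, nHits = 10, effectLnfc = 1,
                              replicateCv = 0.2, nReplicates = 3,
                              seed = NULL) {
  if (nHits > nProteins) stop("nHits must be <= nProteins")
  withSeed(seed, {
    prot <- sprintf("prot_%04d", seq_len(nProteins))
    isHit <- seq_len(nProteins) <= nHits
    baseAbund <- stats::rlnorm(nProteins, meanlog = log(1000), sdlog = 0.5)
    sdlog <- sqrt(log(1 + replicateCv^2))
    conds <- expand.grid(genotype = c("WT", "KO"), dox = c(FALSE, TRUE),
                         replicate = seq_len(nReplicates),
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(conds)), function(j) {
      g <- conds$genotype[j]; d <- conds$dox[j]
      mu <- log(baseAbund)
      if (g == "WT" && d) mu <- mu + ifelse(isHit, effectLnfc, 0)
      data.frame(protein = prot, genotype = g, dox = d,
                 replicate = conds$replicate[j],
                 abundance = stats::rlnorm(nProteins, mu, sdlog),
                 stringsAsFactors = FALSE)
    })
    truth <- list(hits = prot[isHit],
                  lnFc = stats::setNames(ifelse(isHit, effectLnfc, 0), prot))
    list(table = do.call(rbind, rows), truth = truth)
  })
}
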