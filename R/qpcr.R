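## qPCR: Ct simulation, input-amount correction, S/N ratio and
## titration recovery. Cycle efficiency is fixed at perfect doubling
## (2 per cycle), which is what the correction and S/N formulas assume.

#' Simulate qPCR Ct values
#'
#' Ct model: `Ct = intercept - log2(concentration) + N(0, sd)`. A zero
#' concentration never amplifies and is reported censored (`Ct = NA`,
#' `censored = TRUE`); censored values propagate as missing downstream, they
#' are never imputed to a pseudo-cycle.
#'
#' @param concentrations data.frame with columns `sample`, `target`,
#'   `assay` (`"IP"`/`"input"`), `concentration` (arbitrary linear units,
#'   >= 0) and optionally `inputFraction`.
#' @param cfg a [SimConfig-class] supplying `qpcrIntercept` and the default
#'   noise `qpcrCtSd`.
#' @param sd Ct noise standard deviation in cycles; 0 gives the closed-form
#'   Ct exactly.
#' @return the input data.frame plus `Ct` and `censored` columns.
#' @examples
#' conc <- data.frame(sample = c("a", "b"), target = "GLuc", assay = "IP",
#'                    concentration = c(2, 1))
#' qt <- simulateQpcr(conc, simConfig(), sd = 0)
#' diff(qt$Ct)  # 2:1 concentration ratio -> delta Ct of exactly +1 cycle
#' @export
simulateQpcr <- function(concentrations, cfg, sd = cfg@qpcrCtSd) {
  stopifnot(is.data.frame(concentrations),
            all(c("sample", "target", "assay", "concentration") %in%
                  names(concentrations)))
  if (any(concentrations$concentration < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  withSubstream(cfg@seed, "qpcr", {
    conc <- concentrations$concentration
    n <- length(conc)
    noise <- if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
    ct <- cfg@qpcrIntercept - log2(conc) + noise
    censored <- conc == 0
    ct[censored] <- NA_real_
    out <- concentrations
    out$Ct <- ct
    out$censored <- censored
    out
  })
}

#' Input-amount-corrected Ct
#'
#' When the input library is made from a fraction of the material used for
#' the IP, its Ct is corrected by subtracting `log2(1/inputFraction)`:
#' an input from 1/10 of the IP amount is corrected by `-log2(10)`, and at
#' `inputFraction = 1` no correction is applied.
#'
#' @param ct input Ct (cycles).
#' @param inputFraction fraction of the IP starting amount used for the
#'   input, in (0, 1].
#' @return corrected Ct.
#' @examples
#' correctedInputCt(20, 0.1)  # 20 - log2(10) = 16.678
#' @export
correctedInputCt <- function(ct, inputFraction) {
  if (any(is.na(ct)))
    stop("censored Ct cannot be corrected", call. = FALSE)
  if (any(inputFraction <= 0 | inputFraction > 1))
    stop("inputFraction must be in (0, 1]", call. = FALSE)
  ct - log2(1 / inputFraction)
}

#' qPCR signal-to-noise ratio
#'
#' Enrichment of a known m6A-positive target over a known negative target:
#' `S/N = 2^(corrCt_input(pos) - Ct_IP(pos)) / 2^(corrCt_input(neg) -
#' Ct_IP(neg))`, with input Cts corrected for the input amount via
#' [correctedInputCt()].
#'
#' @param posInputCt,posIpCt input/IP Ct of the positive target.
#' @param negInputCt,negIpCt input/IP Ct of the negative target.
#' @param posInputFraction,negInputFraction input material fractions.
#' @return the S/N ratio (dimensionless).
#' @examples
#' # equal inputs; IP Cts 18 vs 22 -> 2^(22 - 18) = 16
#' snRatio(20, 18, 20, 22, posInputFraction = 0.1)
#' @export
snRatio <- function(posInputCt, posIpCt, negInputCt, negIpCt,
                    posInputFraction = 1, negInputFraction = posInputFraction) {
  cts <- c(posInputCt, posIpCt, negInputCt, negIpCt)
  if (any(is.na(cts)))
    stop("censored Ct in S/N computation", call. = FALSE)
  2^(correctedInputCt(posInputCt, posInputFraction) - posIpCt) /
    2^(correctedInputCt(negInputCt, negInputFraction) - negIpCt)
}

#' Titration recovery from IP Ct values
#'
#' Converts IP Cts of a titration series into percent methylation relative
#' to the fully methylated normaliser mix:
#' `observed_i = 100 * 2^(Ct_norm - Ct_i)`. Censored Cts (no amplification)
#' recover as 0%. When the expected levels are supplied the Pearson
#' correlation between expected and observed is returned as well.
#'
#' @param ct numeric IP Ct per mix (NA = censored).
#' @param normalizer index of the 100% mix in `ct`.
#' @param expected optional numeric expected percent levels.
#' @return list with `observed` (percent) and `r` (Pearson, or NA when
#'   `expected` is missing).
#' @examples
#' lv <- titrationLevels(c(30, 30 - log2(0.8), 31, NA),
#'                       expected = c(100, 80, 50, 0))
#' round(lv$observed, 10)
#' @export
titrationLevels <- function(ct, normalizer = 1L, expected = NULL) {
  if (is.na(ct[normalizer]))
    stop("normaliser Ct is censored/missing", call. = FALSE)
  observed <- 100 * 2^(ct[normalizer] - ct)
  observed[is.na(ct)] <- 0
  r <- if (!is.null(expected)) stats::cor(expected, observed) else NA_real_
  list(observed = observed, r = r)
}
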