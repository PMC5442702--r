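#' @include utils.R
NULL

#' Catalytic efficiency kcat/Km
#'
#' @param kcat turnover number, 1/s.
#' @param Km Michaelis constant, uM (must be positive).
#' @return kcat/Km in 1/s/uM.
#' @examples
#' round(catalyticEfficiency(125, 0.22), 2)   # 568.18
#' @export
catalyticEfficiency <- function(kcat, Km) {
  if (any(Km <= 0)) stop("Km must be positive")
  kcat / Km
}

#' Fold change a/b
#'
#' @param a,b positive values (b > 0).
#' @return the ratio a/b.
#' @export
foldChange <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be positive")
  a / b
}

#' Estimate Vmax and Km from a Lineweaver-Burk plot
#'
#' Ordinary least squares on the double-reciprocal transform
#' 1/v = (Km/Vmax) (1/S) + 1/Vmax, the classical linearization of the
#' Michaelis-Menten law. Then Vmax = 1/intercept and
#' Km = slope/intercept. The fit is unweighted; for data with
#' multiplicative error a direct nonlinear fit
#' (\code{\link{michaelisMentenFit}}) is provided for comparison.
#'
#' @param conc substrate concentrations (strictly positive, at least 2
#'   distinct values).
#' @param velocity initial velocities, same length, no zeros.
#' @return list with \code{Vmax}, \code{Km}, \code{slope},
#'   \code{intercept}, \code{r2}, and \code{warning} (character or
#'   NULL; set when the intercept is non-positive, which makes the
#'   estimates meaningless).
#' @export
lineweaverBurkFit <- function(conc, velocity) {
  stopifnot(length(conc) == length(velocity), length(conc) >= 3)
  if (any(conc <= 0)) stop("substrate concentrations must be positive")
  if (any(velocity == 0)) stop("zero velocity cannot be reciprocated")
  if (length(unique(conc)) < 2)
    stop("singular design: need at least two distinct concentrations")
  x <- 1 / conc
  y <- 1 / velocity
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  intercept <- unname(co[1])
  slope <- unname(co[2])
  warn <- NULL
  if (intercept <= 0)
    warn <- "non-positive intercept: Vmax/Km estimates are unreliable"
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::resid(fit)^2) / sstot else 1
  list(Vmax = 1 / intercept, Km = slope / intercept,
       slope = slope, intercept = intercept,
       r2 = r2, warning = warn)
}

#' Direct nonlinear Michaelis-Menten fit
#'
#' Least-squares fit of v = Vmax S / (Km + S) by \code{stats::nls},
#' started from the Lineweaver-Burk estimates.
#'
#' @inheritParams lineweaverBurkFit
#' @return list with \code{Vmax} and \code{Km}.
#' @export
michaelisMentenFit <- function(conc, velocity) {
  lb <- lineweaverBurkFit(conc, velocity)
  start <- list(Vmax = max(abs(lb$Vmax), max(velocity)),
                Km = max(abs(lb$Km), min(conc)))
  # scaleOffset makes convergence well defined on (near-)zero-residual data
  fit <- stats::nls(velocity ~ Vmax * conc / (Km + conc), start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  co <- stats::coef(fit)
  list(Vmax = unname(co["Vmax"]), Km = unname(co["Km"]))
}

#' Consistency of Vmax and kcat via the molecular mass
#'
#' For a specific activity Vmax in umol/min/mg and a molecular mass mw
#' in kDa (= g/mmol), Vmax * mw / 60 is the implied turnover number in
#' 1/s. The relative deviation |Vmax mw / 60 - kcat| / kcat audits the
#' unit coherence of a reported kinetics row.
#'
#' @param Vmax specific activity, umol/min/mg.
#' @param mw molecular mass, kDa.
#' @param kcat reported turnover number, 1/s.
#' @return relative deviation (dimensionless, >= 0).
#' @examples
#' kcatConsistency(277.78, 27.37, 125)   # ~0.014
#' @export
kcatConsistency <- function(Vmax, mw, kcat) {
  if (missing(Vmax) || missing(mw) || missing(kcat) ||
      is.na(Vmax) || is.na(mw) || is.na(kcat))
    stop("Vmax, mw and kcat must all be present")
  stopifnot(Vmax > 0, mw > 0, kcat > 0)
  abs(Vmax * mw / 60 - kcat) / kcat
}

#' Assemble a kinetics record
#'
#' Collects the kinetic constants of one enzyme and validates their
#' internal consistency: when kcat, Km and efficiency are all given,
#' efficiency must equal kcat/Km within 0.5% (matching the precision
#' at which such tables are printed).
#'
#' @param enzymeId identifier.
#' @param Vmax specific activity, umol/min/mg (optional).
#' @param Km Michaelis constant, uM.
#' @param kcat turnover number, 1/s.
#' @param efficiency kcat/Km; computed from kcat and Km when omitted.
#'   Stored with an explicit unit tag ("1/s/uM").
#' @param mw molecular mass, kDa (optional).
#' @return A one-row data.frame with an \code{efficiencyUnit} column.
#' @export
kineticsRecord <- function(enzymeId, Vmax = NA_real_, Km = NA_real_,
                           kcat = NA_real_, efficiency = NULL,
                           mw = NA_real_) {
  vals <- c(Vmax = Vmax, Km = Km, kcat = kcat, mw = mw)
  if (any(!is.na(vals) & vals <= 0))
    stop("kinetic constants must be positive where present")
  if (is.null(efficiency)) {
    efficiency <- if (!is.na(kcat) && !is.na(Km))
      catalyticEfficiency(kcat, Km) else NA_real_
  } else if (!is.na(kcat) && !is.na(Km)) {
    expected <- kcat / Km
    if (abs(efficiency - expected) / expected > 0.005)
      stop("efficiency ", efficiency, " disagrees with kcat/Km = ",
           signif(expected, 6), " by more than 0.5%")
  }
  data.frame(enzymeId = enzymeId, Vmax = Vmax, Km = Km, kcat = kcat,
             efficiency = efficiency, efficiencyUnit = "1/s/uM",
             mw = mw, stringsAsFactors = FALSE)
}

#' Two-enzyme kinetics comparison report
#'
#' Computes catalytic efficiencies and their fold change for two
#' kinetics records, with values rounded half-up to 2 decimals as in
#' standard kinetics tables.
#'
#' @param recA,recB one-row data.frames from
#'   \code{\link{kineticsRecord}} (A is the mutant / numerator).
#' @return data.frame with rows for each enzyme's efficiency and the
#'   fold change A/B.
#' @export
kineticsReport <- function(recA, recB) {
  effA <- catalyticEfficiency(recA$kcat, recA$Km)
  effB <- catalyticEfficiency(recB$kcat, recB$Km)
  data.frame(
    quantity = c(paste0("efficiency.", recA$enzymeId),
                 paste0("efficiency.", recB$enzymeId),
                 "foldChange"),
    value = .round2(c(effA, effB, foldChange(effA, effB))),
    unit = c("1/s/uM", "1/s/uM", ""),
    stringsAsFactors = FALSE)
}

# round half-up to 2 decimals (R's round() is half-to-even)
.round2 <- function(x) floor(x * 100 + 0.5) / 100
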