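## Linking dynamic surface areas to lipophilicity: Pearson correlations
## and the linear logD ~ NPSA + PSA model.

#' Pearson correlation with input validation
#'
#' Thin wrapper over `stats::cor` that enforces equal lengths (at least
#' 3) and nonzero variance in both variables.
#'
#' @param x,y numeric vectors.
#' @return sample Pearson correlation coefficient.
#' @export
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 5))  # 0.8
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Fit the linear lipophilicity model logD ~ NPSA + PSA
#'
#' Ordinary least squares of measured logD on ensemble-averaged
#' nonpolar and polar surface-area descriptors:
#' `logD = coefNpsa * NPSA + coefPsa * PSA + intercept`.
#' Descriptors are used on whatever scale the caller supplies; the
#' scale is recorded in the model, never altered.
#'
#' @param psa,npsa numeric descriptor vectors.
#' @param logd measured logD values.
#' @param descriptorScale free-text note on the descriptor units
#'   (recorded in the model).
#' @return a [LipoModel-class]. `pearsonRFit` is the correlation of
#'   fitted vs. measured logD, `NA` when the response is constant.
#' @export
#' @examples
#' npsa <- c(6, 7, 8, 9); psa <- c(5, 4.5, 4, 3.2)
#' logd <- 0.27 * npsa - 0.82 * psa + 2.22
#' fitLogdModel(psa, npsa, logd)
fitLogdModel <- function(psa, npsa, logd,
                         descriptorScale = "as supplied") {
  n <- length(logd)
  if (length(psa) != n || length(npsa) != n)
    stop("psa, npsa and logd must have equal length")
  if (n < 4L) stop("need at least 4 observations to fit 3 parameters")
  X <- cbind(npsa = npsa, psa = psa)
  if (qr(cbind(1, X))$rank < 3L)
    stop("rank-deficient design: PSA and NPSA are collinear")
  fit <- lm(logd ~ npsa + psa)
  fitted <- unname(fitted(fit))
  r <- if (sd(logd) == 0 || sd(fitted) == 0) NA_real_ else cor(fitted, logd)
  cf <- coef(fit)
  new("LipoModel",
      coefNpsa = unname(cf["npsa"]), coefPsa = unname(cf["psa"]),
      intercept = unname(cf["(Intercept)"]),
      pearsonRFit = r, n = as.integer(n),
      descriptorScale = descriptorScale, fit = fit)
}

#' Predict logD from surface-area descriptors
#'
#' @param model a [LipoModel-class].
#' @param psa,npsa descriptor values on the scale the model was fitted
#'   on.
#' @return predicted logD values.
#' @export
#' @examples
#' m <- new("LipoModel", coefNpsa = 0.27, coefPsa = -0.82,
#'          intercept = 2.22, pearsonRFit = NA_real_, n = 4L,
#'          descriptorScale = "example", fit = NULL)
#' predictLogd(m, psa = 0, npsa = 0)  # intercept
predictLogd <- function(model, psa, npsa) {
  stopifnot(is(model, "LipoModel"))
  model@coefNpsa * npsa + model@coefPsa * psa + model@intercept
}

#' Difference of measured logD between two ligands
#'
#' @param a,b either numbers (logD values) or lists/data.frame rows with
#'   a `logD` field.
#' @return `logD(a) - logD(b)`.
#' @export
#' @examples
#' logdDifference(1.26, 0.63)  # 0.63
logdDifference <- function(a, b) {
  pick <- function(z) {
    if (is.numeric(z) && length(z) == 1L) return(z)
    v <- z[["logD"]]
    if (is.null(v) || is.na(v)) stop("missing logD value")
    as.numeric(v)
  }
  pick(a) - pick(b)
}
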