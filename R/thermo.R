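## Affinity algebra: apparent binding constants under a conformational
## pre-equilibrium, free energy <-> pKd conversion, the direct-vs-
## conformational dissection, binding efficiency, Cheng-Prusoff.
##
## Model: a ligand binds only from its bioactive conformation, populated
## with fraction p in the free state. The apparent dissociation constant
## is then Kd_app = Kd/p, i.e. pKd_app = pKd + log10(p), where Kd is the
## binding constant the compound would have if the transition into
## non-bioactive conformations were not permitted.

# Gas constant in kcal/(mol K).
.Rgas <- 1.98720425864083e-3

#' Apparent pKd under a conformational pre-equilibrium
#'
#' `pKd_app = pKd_intrinsic + log10(p)`: a ligand that spends only a
#' fraction `p` of its free-state time in the bioactive conformation pays
#' a `log10(p)` penalty on its apparent affinity.
#'
#' @param pkdIntrinsic intrinsic pKd (binding from the bioactive
#'   conformation only).
#' @param p bioactive population fraction, in (0, 1].
#' @return apparent pKd.
#' @export
#' @examples
#' apparentPkd(7, 0.1)  # 6
apparentPkd <- function(pkdIntrinsic, p) {
  if (any(p <= 0)) stop("population fraction must be > 0")
  if (any(p > 1)) stop("population fraction must be <= 1")
  pkdIntrinsic + log10(p)
}

#' Conformational contribution to a relative binding affinity
#'
#' The pKd difference between two ligands attributable purely to their
#' bioactive-population fractions: `log10(pA / pB)`. Antisymmetric under
#' argument swap and path-independent (differences chain).
#'
#' @param pA,pB bioactive population fractions in (0, 1].
#' @return conformational Delta-pKd (pKd units), ligand A minus ligand B.
#' @export
#' @examples
#' conformationalDpkd(0.40, 0.06)  # ~0.82: the "larger substituent" gain
conformationalDpkd <- function(pA, pB) {
  if (any(c(pA, pB) <= 0)) stop("population fractions must be > 0")
  if (any(c(pA, pB) > 1)) stop("population fractions must be <= 1")
  log10(pA / pB)
}

#' Convert a binding free energy difference to a pKd difference
#'
#' `dpKd = -ddG / (ln(10) R T)` with R = 1.98720425864083e-3
#' kcal/(mol K). A negative ddG (more favourable binding) gives a
#' positive dpKd.
#'
#' @param ddG free energy difference in kcal/mol.
#' @param temperature absolute temperature in K (default 298.15).
#' @return pKd difference.
#' @export
#' @examples
#' ddgToDpkd(-1.3642)  # ~1
ddgToDpkd <- function(ddG, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be > 0")
  -ddG / (log(10) * .Rgas * temperature)
}

#' Dissect a relative affinity into direct and conformational terms
#'
#' Combines a direct interaction/solvation term (typically from a
#' restrained FEP network) with a conformational term (from free-ligand
#' population ratios) into the total predicted pKd difference, and
#' reports the fraction of the total magnitude carried by the
#' conformational term.
#'
#' @param direct direct-interaction Delta-pKd (pKd units).
#' @param conformational conformational Delta-pKd (pKd units).
#' @param ligandPair optional character(2) naming the pair (A, B).
#' @return list with `ligandPair`, `dpkdDirect`, `dpkdConformational`,
#'   `dpkdTotal` and `fractionConformational`
#'   (`|conf| / (|direct| + |conf|)`; `NA` when both terms are 0).
#' @export
#' @examples
#' dissectAffinity(2.0, 0.8)$fractionConformational  # ~0.286, "ca. 1/3"
dissectAffinity <- function(direct, conformational, ligandPair = c("A", "B")) {
  denom <- abs(direct) + abs(conformational)
  list(
    ligandPair = ligandPair,
    dpkdDirect = direct,
    dpkdConformational = conformational,
    dpkdTotal = direct + conformational,
    fractionConformational = if (denom > 0) abs(conformational) / denom
                             else NA_real_)
}

#' Binding efficiency index
#'
#' `BEI = pKd / (MW x 10^-3)`: potency normalized by molecular weight in
#' kDa, used to compare structurally related compounds of different size.
#'
#' @param pkd pKd (or pKi).
#' @param mw molecular weight in g/mol, > 0.
#' @return BEI.
#' @export
#' @examples
#' bei(6.0, 1500)  # 4
bei <- function(pkd, mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0")
  pkd / (mw * 1e-3)
}

#' Ki from a competition IC50 (Cheng-Prusoff)
#'
#' Classical Cheng-Prusoff correction for a competition assay with a
#' labelled tracer: `Ki = IC50 / (1 + [tracer]/Kd_tracer)`. An
#' alternative mode implements the correction of Nikolovska-Coleska et
#' al. for fluorescence polarization competition, which also accounts for
#' the free protein concentration at the IC50:
#' `Ki = IC50 / (1 + L50/Kd_tracer + P0/Kd_tracer)` with
#' `L50` the free tracer and `P0` the free protein concentration at 50%
#' inhibition (supplied by the caller).
#'
#' @param ic50 IC50 in M.
#' @param tracerConc tracer concentration in M (classical mode) or free
#'   tracer at IC50 (fp mode).
#' @param tracerKd tracer dissociation constant in M.
#' @param mode "cheng-prusoff" (default) or "fp".
#' @param freeProteinConc free protein concentration at 50% inhibition
#'   (M); required for `mode = "fp"`.
#' @return Ki in M. Use `-log10()` for pKi.
#' @export
#' @examples
#' kiFromIC50(1e-6, 1e-8, 1e-8)  # 5e-7: denominator 2
kiFromIC50 <- function(ic50, tracerConc, tracerKd,
                       mode = c("cheng-prusoff", "fp"),
                       freeProteinConc = NULL) {
  mode <- match.arg(mode)
  if (any(c(ic50, tracerConc, tracerKd) <= 0))
    stop("ic50, tracerConc and tracerKd must all be > 0")
  if (mode == "cheng-prusoff")
    return(ic50 / (1 + tracerConc / tracerKd))
  if (is.null(freeProteinConc) || any(freeProteinConc < 0))
    stop("mode 'fp' needs a non-negative freeProteinConc")
  ic50 / (1 + tracerConc / tracerKd + freeProteinConc / tracerKd)
}

#' Read an affinity table
#'
#' Reads a TSV/CSV of per-ligand affinity bookkeeping (columns among:
#' `ligand_id`, `pKd`, `pKi`, `IC50_M`, `tracer_conc_M`, `tracer_Kd_M`,
#' `MW`, `BEI`, `logD`, `XlogP`), filling in BEI from pKd and MW where
#' both are present and BEI is not.
#'
#' @param path path to the table.
#' @param sep field separator; default tab, use "," for CSV.
#' @return data.frame, one row per ligand.
#' @export
readAffinityTable <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!"ligand_id" %in% names(tab))
    stop("affinity table needs a ligand_id column")
  if (all(c("pKd", "MW") %in% names(tab))) {
    if (!"BEI" %in% names(tab)) tab$BEI <- NA_real_
    fill <- is.na(tab$BEI) & !is.na(tab$pKd) & !is.na(tab$MW)
    tab$BEI[fill] <- bei(tab$pKd[fill], tab$MW[fill])
  }
  tab
}
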