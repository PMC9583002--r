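# Correlation statistics: Pearson (delegated to stats::cor.test) and the
# Dunn-Clark z test for comparing two dependent, overlapping correlation
# coefficients (e.g. released waters vs affinity against buried area vs
# affinity, measured on the same complexes).

#' Pearson correlation with a two-sided t test
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient,
#' p-value and sample size.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list `rho`, `p_value`, `n`.
#' @examples
#' pearsonCor(1:10, (1:10) * 2 + 1)$rho   # exactly 1
#' @export
pearsonCor <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("x and y must have equal length >= 3", call. = FALSE)
    if (anyNA(x) || anyNA(y))
        stop("missing values are not allowed", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance: correlation undefined", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson")
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Dunn-Clark test for two dependent overlapping correlations
#'
#' Tests H0: rho12 = rho13 when both correlations are measured on the same
#' n subjects and share variable 1 (overlapping dependent groups). The
#' statistic is the difference of the Fisher z-transforms of r12 and r13,
#' standardised with the Dunn-Clark (1969) covariance correction, which
#' requires the intercorrelation r23 between the two non-shared variables:
#'
#' z = (atanh(r12) - atanh(r13)) * sqrt(n - 3) / sqrt(2 - 2 c), with
#' c = \{ r23 (1 - r12^2 - r13^2) - r12 r13 (1 - r12^2 - r13^2 - r23^2)/2 \}
#'     / \{ (1 - r12^2)(1 - r13^2) \}.
#'
#' @param r12,r13 the two correlations being compared (share variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (>= 4).
#' @return list `z`, `p_value` (two-sided normal), `n`.
#' @examples
#' dunnClarkTest(0.5, 0.5, 0.3, 50)$z   # symmetric null: 0
#' @export
dunnClarkTest <- function(r12, r13, r23, n) {
    if (any(abs(c(r12, r13, r23)) > 1))
        stop("correlations must lie in [-1, 1]", call. = FALSE)
    if (any(abs(c(r12, r13)) == 1))
        stop("degenerate correlation (|r| = 1): test undefined",
             call. = FALSE)
    if (n < 4) stop("n must be >= 4", call. = FALSE)
    cnum <- r23 * (1 - r12^2 - r13^2) -
        0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
    cc <- cnum / ((1 - r12^2) * (1 - r13^2))
    z <- (atanh(r12) - atanh(r13)) * sqrt(n - 3) / sqrt(2 - 2 * cc)
    list(z = z, p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Correlate released waters and buried area with binding affinity
#'
#' Given a per-complex table, computes the Pearson correlation of the
#' number of released waters with the binding free energy, the correlation
#' of the buried area with the binding free energy, and the Dunn-Clark
#' comparison of the two (they share the affinity variable and are measured
#' on the same complexes).
#'
#' @param dataset data.frame with columns `dg_bind` (kcal/mol),
#'   `delta_asa` (Angstrom^2) and `n_released`.
#' @param p_adjust optional multiple-testing method passed to
#'   [stats::p.adjust()] and applied to the two correlation p-values
#'   (default: none; raw p-values reported).
#' @return list `cor_released` and `cor_dasa` (each as [pearsonCor()]),
#'   `comparison` (as [dunnClarkTest()]).
#' @export
affinityCorrelations <- function(dataset, p_adjust = "none") {
    need <- c("dg_bind", "delta_asa", "n_released")
    if (!all(need %in% names(dataset)))
        stop("dataset needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (anyNA(dataset[need]))
        stop("missing values in tested variables", call. = FALSE)
    c1 <- pearsonCor(dataset$n_released, dataset$dg_bind)
    c2 <- pearsonCor(dataset$delta_asa, dataset$dg_bind)
    r23 <- pearsonCor(dataset$n_released, dataset$delta_asa)$rho
    cmp <- dunnClarkTest(c1$rho, c2$rho, r23, nrow(dataset))
    padj <- stats::p.adjust(c(c1$p_value, c2$p_value), method = p_adjust)
    c1$p_value <- padj[1]
    c2$p_value <- padj[2]
    list(cor_released = c1, cor_dasa = c2, comparison = cmp)
}
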