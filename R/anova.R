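# Repeated-measures ANOVA with Greenhouse-Geisser correction, wrapping a
# multivariate linear model fit (car::Anova) behind a small stable contract.

#' Within-subject ANOVA with Greenhouse-Geisser correction
#'
#' Fits a repeated-measures ANOVA over one or two fully-crossed within
#' factors. For every effect whose factor part has more than two levels,
#' Mauchly's sphericity test is run; when it rejects at 0.05, the
#' Greenhouse-Geisser epsilon corrects the degrees of freedom and the
#' p-value. Two-level effects have epsilon 1 by construction.
#'
#' @param y subjects x cells numeric matrix, complete and balanced. Cell
#'   order must match the rows of `within`.
#' @param within data.frame with one row per cell and one or two factor
#'   columns naming the within-subject design.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p_uncorrected`, `epsilon`, `df1_gg`, `df2_gg`, `p` (corrected when the
#'   sphericity rule fires, otherwise uncorrected), `sphericity_p`,
#'   `corrected`.
#' @export
rm_anova_gg <- function(y, within) {
  y <- as.matrix(y)
  stopifnot(nrow(within) == ncol(y), ncol(within) %in% c(1L, 2L))
  if (anyNA(y)) stop("missing cells: the design must be complete")
  within <- as.data.frame(lapply(within, factor))
  effects <- names(within)
  idesign <- stats::as.formula(paste("~", paste(effects, collapse = "*")))

  # degenerate data (all cells identical within subject) have no within-cell
  # variance anywhere: report F = 0, p = 1 for every effect
  if (all(abs(sweep(y, 1, y[, 1])) < 1e-12)) {
    eff_names <- c(effects, if (length(effects) == 2L)
      paste(effects, collapse = ":"))
    return(data.frame(effect = eff_names, df1 = NA, df2 = NA, F = 0,
                      p_uncorrected = 1, epsilon = 1, df1_gg = NA,
                      df2_gg = NA, p = 1, sphericity_p = NA,
                      corrected = FALSE))
  }

  fit <- stats::lm(y ~ 1)
  av <- car::Anova(fit, idata = within, idesign = idesign, type = 3)
  # car prints a harmless note when the Huynh-Feldt epsilon exceeds 1; only
  # the Greenhouse-Geisser branch is consumed here
  sm <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  uni <- sm$univariate.tests
  eff_rows <- setdiff(rownames(uni), "(Intercept)")
  sph <- sm$sphericity.tests
  adj <- sm$pval.adjustments

  out <- lapply(eff_rows, function(e) {
    df1 <- uni[e, "num Df"]
    df2 <- uni[e, "den Df"]
    Fv <- uni[e, "F value"]
    p_unc <- uni[e, "Pr(>F)"]
    eps <- 1
    sph_p <- NA_real_
    corrected <- FALSE
    p <- p_unc
    if (!is.null(sph) && e %in% rownames(sph)) {
      sph_p <- sph[e, "p-value"]
      eps_gg <- adj[e, "GG eps"]
      if (is.finite(sph_p) && sph_p < 0.05) {
        eps <- eps_gg
        p <- adj[e, "Pr(>F[GG])"]
        corrected <- TRUE
      } else {
        eps <- 1
      }
    }
    data.frame(effect = e, df1 = df1, df2 = df2, F = Fv,
               p_uncorrected = p_unc, epsilon = eps,
               df1_gg = df1 * eps, df2_gg = df2 * eps, p = p,
               sphericity_p = sph_p, corrected = corrected)
  })
  res <- do.call(rbind, out)
  # zero-variance effects (identical condition means, no error variance)
  bad <- !is.finite(res$F)
  res$F[bad] <- 0
  res$p[bad] <- 1
  res$p_uncorrected[bad] <- 1
  rownames(res) <- NULL
  res
}
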