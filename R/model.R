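#' @importFrom lme4 lmerControl
#' @importFrom stats as.formula lm pt qt coef vcov
NULL

## Random-effect structure cascades. "sample" in the nested intercepts is
## read as the excision pair (lesion); sampleUnit = "specimen" switches
## to individual-specimen intercepts.
.structures <- function(proteinIntercept, sampleUnit) {
  unit <- if (sampleUnit == "specimen") "sample_id" else "lesion_id"
  prot <- if (proteinIntercept) "(1 | protein_id) + " else ""
  if (proteinIntercept) {
    list(full = paste0(prot, "(1 | patient_id) + (1 | ", unit, ")"),
         no_patient = paste0(prot, "(1 | ", unit, ")"),
         minimal = "(1 | protein_id)")
  } else {
    list(full = paste0("(1 | patient_id) + (1 | ", unit, ")"),
         no_patient = paste0("(1 | ", unit, ")"),
         minimal = NA_character_)   # plain linear regression
  }
}

.fitOne <- function(tab, re) {
  if (is.na(re)) {
    fit <- lm(log_quantity ~ tissue, data = tab)
    sm <- summary(fit)$coefficients
    return(list(coef = sm["tissuecNF", "Estimate"],
                se = sm["tissuecNF", "Std. Error"],
                df = fit$df.residual,
                p = sm["tissuecNF", "Pr(>|t|)"],
                converged = TRUE, singular = FALSE))
  }
  form <- as.formula(paste("log_quantity ~ tissue +", re))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lmerTest::lmer(
      form, data = tab, REML = TRUE,
      control = lmerControl(check.conv.singular = "ignore")))),
    error = function(e) e)
  if (inherits(fit, "error")) return(NULL)
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  failed <- any(grepl("failed to converge", conv_msgs, ignore.case = TRUE)) ||
    !is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(sm) || !"tissuecNF" %in% rownames(sm)) return(NULL)
  est <- sm["tissuecNF", "Estimate"]
  se <- sm["tissuecNF", "Std. Error"]
  df <- sm["tissuecNF", "df"]
  p <- sm["tissuecNF", "Pr(>|t|)"]
  if (!is.finite(se) || se <= 0) return(NULL)
  if (!is.finite(df) || df <= 0) {  # Satterthwaite df unavailable
    df <- Inf
    p <- 2 * pt(-abs(est / se), df = Inf)
  }
  if (failed) return(NULL)
  list(coef = est, se = se, df = df, p = p, converged = TRUE,
       singular = lme4::isSingular(fit))
}

#' Fit the tissue mixed model for one observation table
#'
#' Fits `log_quantity ~ tissue + <random intercepts>` by REML with the
#' cNF/skin indicator as the fixed effect (skin = baseline, so the
#' coefficient is the log cNF/skin ratio). The random-intercept cascade
#' is `full` (protein + patient + excision pair), then `no_patient`
#' (drop the patient intercept), then `minimal` (protein only; for
#' single-protein models the minimal level is ordinary linear
#' regression). A level is abandoned — and the next one tried — when the
#' optimizer fails, reports non-convergence, or yields a non-finite
#' standard error; a boundary (singular, zero-variance) fit counts as
#' converged. Two-sided P values and the CI critical value use the
#' Satterthwaite degrees of freedom; `df_method` records this. Exactly
#' noiseless tables (zero residual variance) have a degenerate
#' likelihood; the tissue contrast is then returned directly from the
#' fixed-effects fit with `structure = "degenerate"`.
#'
#' @param tab a [buildTermTable()]-style `data.frame`.
#' @param proteinIntercept include a per-protein random intercept (GO
#'   models `TRUE`, single-protein models `FALSE`).
#' @param structure starting structure, normally `"full"`.
#' @param sampleUnit `"lesion"` (excision pair, default) or
#'   `"specimen"` for the nested sample intercept.
#' @param failLevels character vector of structure levels to treat as
#'   failed, for testing the fallback cascade.
#' @return list with `coef`, `se`, `df`, `p`, `structure` (the level that
#'   converged), `singular`, `df_method`.
#' @export
fitTissueModel <- function(tab, proteinIntercept = TRUE,
                           structure = c("full", "no_patient", "minimal"),
                           sampleUnit = c("lesion", "specimen"),
                           failLevels = character()) {
  structure <- match.arg(structure)
  sampleUnit <- match.arg(sampleUnit)
  if (nlevels(droplevels(tab$tissue)) < 2L)
    stop("both tissues must be represented")
  if (nrow(tab) < 3L)
    stop("too few observations to fit the tissue model")
  ## noiseless data (zero residual after protein + tissue means) makes
  ## the mixed-model likelihood degenerate; the tissue contrast is then
  ## exact and is returned directly from the fixed-effects fit
  fixed_form <- if (proteinIntercept && length(unique(tab$protein_id)) > 1L)
    log_quantity ~ protein_id + tissue else log_quantity ~ tissue
  lm0 <- lm(fixed_form, data = tab)
  scale_y <- max(stats::sd(tab$log_quantity), 1)
  if (stats::sigma(lm0) < 1e-10 * scale_y) {
    est <- coef(lm0)[["tissuecNF"]]
    return(list(coef = est, se = 0, df = lm0$df.residual,
                p = if (abs(est) < 1e-12) 1 else 0,
                converged = TRUE, singular = TRUE,
                structure = "degenerate", df_method = "exact"))
  }
  cascade <- .structures(proteinIntercept, sampleUnit)
  levels_try <- names(cascade)[match(structure, names(cascade)):
                                 length(cascade)]
  for (lev in levels_try) {
    if (lev %in% failLevels) next
    res <- .fitOne(tab, cascade[[lev]])
    if (!is.null(res)) {
      res$structure <- lev
      res$df_method <- if (is.na(cascade[[lev]])) "residual"
        else "satterthwaite"
      return(res)
    }
  }
  stop("no model structure converged")
}

.effectRow <- function(target, fit, n_proteins, n_obs, familySize) {
  crit <- qt(0.975, df = fit$df)
  data.frame(
    target = target,
    ratio = exp(fit$coef),
    ci_low = exp(fit$coef - crit * fit$se),
    ci_high = exp(fit$coef + crit * fit$se),
    p_plain = fit$p,
    p_corrected = bonferroniAdjust(fit$p, familySize),
    n_proteins = n_proteins,
    n_observations = n_obs,
    model_structure_used = fit$structure,
    df = fit$df,
    df_method = fit$df_method,
    stringsAsFactors = FALSE)
}

#' Differential abundance of one GO term
#'
#' Rolls the term's proteins into one mixed model (see
#' [fitTissueModel()]) and returns the exponentiated tissue effect: the
#' cNF/skin ratio with its 95% CI, the plain two-sided P value and the
#' Bonferroni-corrected P value.
#'
#' @param x an imputed [ProteinQuantMatrix-class] with design metadata.
#' @param annotations a [GOAnnotationMap-class].
#' @param termId a single eligible term.
#' @param familySize Bonferroni family size (number of terms tested in
#'   the run).
#' @param ... passed to [fitTissueModel()].
#' @return one-row `data.frame` (an effect estimate).
#' @export
testGOTerm <- function(x, annotations, termId, familySize = 1L, ...) {
  tab <- buildTermTable(x, annotations, termId)
  fit <- fitTissueModel(tab, proteinIntercept = TRUE, ...)
  .effectRow(termId, fit, length(unique(tab$protein_id)), nrow(tab),
             familySize)
}

#' Differential abundance of a single protein
#'
#' Identical to the GO-term analysis except that no per-protein random
#' intercept is included (a single protein has nothing to pool); the
#' fallback cascade ends in ordinary linear regression.
#'
#' @param x an imputed [ProteinQuantMatrix-class] with design metadata.
#' @param proteinId protein accession present in the matrix.
#' @param familySize Bonferroni family size.
#' @param ... passed to [fitTissueModel()].
#' @return one-row `data.frame`.
#' @export
testProtein <- function(x, proteinId, familySize = 1L, ...) {
  if (!proteinId %in% rownames(x))
    stop("protein not in matrix: ", proteinId)
  cd <- .sampleData(x)
  q <- quantities(x)[proteinId, ]
  keep <- !is.na(q)
  tab <- data.frame(protein_id = proteinId,
                    sample_id = colnames(x)[keep],
                    patient_id = cd$patient_id[keep],
                    lesion_id = cd$lesion_id[keep],
                    tissue = cd$tissue[keep],
                    log_quantity = log(q[keep]))
  fit <- fitTissueModel(tab, proteinIntercept = FALSE, ...)
  .effectRow(proteinId, fit, 1L, nrow(tab), familySize)
}

#' Bonferroni multiple-testing correction
#'
#' `min(1, p * m)` with an explicit family size `m`, preserving order.
#'
#' @param p numeric vector of P values.
#' @param m family size (>= 1).
#' @return numeric vector of corrected P values.
#' @export
bonferroniAdjust <- function(p, m) {
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop("family size m must be a single number >= 1")
  pmin(1, p * m)
}

#' Subset a study to specific lesions, keeping pairs intact
#'
#' Selects samples for sensitivity analyses. `which = "growing"` keeps
#' lesions recorded as growing; `which = "patient"` keeps one donor's
#' lesions; `which = "lesions"` an explicit lesion set. The matched skin
#' sample of every selected lesion is always retained, so the paired
#' structure survives subsetting.
#'
#' @param x a [ProteinQuantMatrix-class] with design metadata.
#' @param which subset rule.
#' @param patient patient identifier (for `which = "patient"`).
#' @param lesions lesion identifiers (for `which = "lesions"`).
#' @return the column-subset [ProteinQuantMatrix-class].
#' @export
subsetSamples <- function(x, which = c("all", "growing", "patient",
                                       "lesions"),
                          patient = NULL, lesions = NULL) {
  which <- match.arg(which)
  cd <- .sampleData(x)
  keep_lesions <- switch(which,
    all = unique(cd$lesion_id),
    growing = unique(cd$lesion_id[cd$growing == "yes"]),
    patient = {
      if (is.null(patient)) stop("'patient' required")
      unique(cd$lesion_id[cd$patient_id == patient])
    },
    lesions = {
      if (is.null(lesions)) stop("'lesions' required")
      lesions
    })
  sel <- cd$lesion_id %in% keep_lesions
  sub <- x[, sel]
  if (nlevels(droplevels(.sampleData(sub)$tissue)) < 2L)
    stop("subset removes a whole tissue")
  sub
}

#' Rerun an analysis on a sample subset
#'
#' Convenience wrapper: subsets the study via [subsetSamples()] and
#' applies `analysis`, a function of the subset matrix.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @param analysis `function(x_subset) -> result`.
#' @inheritParams subsetSamples
#' @return the `analysis` result.
#' @export
runSensitivity <- function(x, analysis, which = "all", patient = NULL,
                           lesions = NULL) {
  analysis(subsetSamples(x, which = which, patient = patient,
                         lesions = lesions))
}
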