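# Feature selection: univariate screening of component scores against
# peak velocity, and forward/backward stepwise multivariate linear
# regression over the retained scores plus the sex, age and height
# covariates.

#' Univariate screening of PC scores against the outcome
#'
#' Pearson correlation and two-sided p-value of each score column
#' against peak velocity (simple linear regression per component).
#'
#' @param scores subjects x components score matrix.
#' @param outcome per-subject peak velocity, m/s.
#' @return data.frame with columns \code{term}, \code{r}, \code{p}.
#' @export
univariateScreen <- function(scores, outcome) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L) stop("at least 3 subjects are required")
  if (length(outcome) != nrow(scores))
    stop("outcome length must match the number of subjects")
  if (sd(outcome) == 0) stop("outcome is constant; correlations are undefined")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  res <- lapply(seq_len(ncol(scores)), function(j) {
    if (sd(scores[, j]) == 0)
      stop("score column ", colnames(scores)[j],
           " has zero variance; correlation is undefined")
    ct <- cor.test(scores[, j], outcome)
    data.frame(term = colnames(scores)[j], r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, res)
}

# p-value of the partial F test for adding `cand` to the model holding
# `included` (equals the squared-t test of cand's coefficient in the
# extended fit).
.entryP <- function(y, X, included, cand) {
  fit <- suppressWarnings(
    lm(y ~ ., data = as.data.frame(X[, c(included, cand), drop = FALSE])))
  cf <- suppressWarnings(summary(fit))$coefficients
  if (!cand %in% rownames(cf)) return(NA_real_)  # aliased / zero variance
  cf[cand, 4L]
}

#' Stepwise multivariate linear regression of peak velocity
#'
#' Forward/backward stepwise search: at each iteration the candidate
#' with the smallest partial-F p-value enters if it is below
#' \code{pEnter}; then the included term with the largest p-value leaves
#' if it exceeds the exit tolerance \code{pRemove}. Iteration stops when
#' neither step changes the model, and the final selection is refitted
#' by ordinary least squares with an intercept. Requiring
#' \code{pEnter <= pRemove} rules out add/remove cycling. If no
#' candidate ever enters, the intercept-only model is returned.
#'
#' @param candidates subjects x candidates matrix or data.frame
#'   (component scores and/or covariates), with column names.
#' @param outcome per-subject peak velocity, m/s.
#' @param pEnter entry threshold on the partial-F p-value.
#' @param pRemove exit tolerance: terms with p above it are removed.
#' @return a \linkS4class{StepwiseModel}.
#' @export
stepwiseRegress <- function(candidates, outcome, pEnter = 0.05,
                            pRemove = 0.10) {
  if (pRemove < pEnter)
    stop("pRemove (", pRemove, ") must be >= pEnter (", pEnter,
         "); a smaller exit tolerance allows add/remove cycling")
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) stop("candidates must have column names")
  if (anyDuplicated(colnames(X))) stop("candidate names must be unique")
  n <- nrow(X)
  if (n <= 3L) stop("more than 3 subjects are required")
  if (length(outcome) != n)
    stop("outcome length must match the number of subjects")
  y <- outcome
  pool <- colnames(X)
  included <- character(0)
  maxTerms <- n - 2L

  sst <- sum((y - mean(y))^2)
  repeat {
    changed <- FALSE
    # forward step; skipped once the current fit is numerically exact
    # (p-values computed on eps-scale residuals are meaningless)
    curSse <- if (length(included)) {
      sum(lm(y ~ ., data = as.data.frame(
        X[, included, drop = FALSE]))$residuals^2)
    } else sst
    out <- setdiff(pool, included)
    if (length(out) && length(included) < maxTerms &&
        curSse > 1e-20 * max(sst, .Machine$double.xmin)) {
      ps <- vapply(out, function(cand) .entryP(y, X, included, cand),
                   numeric(1L))
      ps[is.na(ps)] <- Inf
      best <- which.min(ps)
      if (ps[best] < pEnter) {
        included <- c(included, out[best])
        changed <- TRUE
      }
    }
    # backward step
    if (length(included)) {
      fit <- lm(y ~ ., data = as.data.frame(X[, included, drop = FALSE]))
      cf <- suppressWarnings(summary(fit))$coefficients
      pvals <- cf[match(included, rownames(cf)), 4L]
      pvals[is.na(pvals)] <- Inf  # aliased terms always leave
      worst <- which.max(pvals)
      if (pvals[worst] > pRemove) {
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # final OLS refit with intercept
  df <- as.data.frame(X[, included, drop = FALSE])
  fit <- if (length(included)) lm(y ~ ., data = df) else lm(y ~ 1)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  terms <- data.frame(term = c("(Intercept)", included),
                      estimate = unname(cf[, 1L]),
                      se = unname(cf[, 2L]),
                      t = unname(cf[, 3L]),
                      p = unname(cf[, 4L]),
                      row.names = NULL)
  modelP <- if (!is.null(sm$fstatistic)) {
    fs <- sm$fstatistic
    unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  } else NA_real_
  methods::new("StepwiseModel", terms = terms,
               r2 = if (length(included)) sm$r.squared else 0,
               rmse = sm$sigma, modelP = modelP, fit = fit,
               selected = included)
}

#' @rdname StepwiseModel-class
#' @param object a \linkS4class{StepwiseModel}.
#' @export
setMethod("modelTerms", "StepwiseModel", function(object) object@terms)

#' @rdname StepwiseModel-class
#' @export
setMethod("selectedTerms", "StepwiseModel", function(object) object@selected)

setMethod("show", "StepwiseModel", function(object) {
  cat("StepwiseModel:", length(object@selected), "selected terms\n")
  print(object@terms, digits = 4)
  cat(sprintf("R-squared = %.3f, RMSE = %.3f, model p = %s\n",
              object@r2, object@rmse, format.pval(object@modelP, digits = 3)))
})

#' Export a stepwise model report
#'
#' Writes the per-term table (Feature, Estimate, SE, t Statistic,
#' p-value) plus the model-level R-squared, RMSE and p-value as CSV.
#'
#' @param model a \linkS4class{StepwiseModel}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeModelReport <- function(model, path) {
  tab <- model@terms
  colnames(tab) <- c("Feature", "Estimate", "SE", "t Statistic", "p-value")
  tab$R2 <- c(model@r2, rep(NA, nrow(tab) - 1L))
  tab$RMSE <- c(model@rmse, rep(NA, nrow(tab) - 1L))
  tab$ModelP <- c(model@modelP, rep(NA, nrow(tab) - 1L))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
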