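#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Fits a linear model whose error covariance is a Pagel's-lambda transform
#' of the Brownian-motion covariance implied by a phylogeny:
#' `V(lambda) = lambda * C + (1 - lambda) * diag(C)`. By default lambda is
#' estimated by maximizing the profile Gaussian log-likelihood over \[0, 1\]
#' (golden-section search with parabolic refinement, tolerance 1e-6, ties at
#' a boundary resolved to the boundary). Coefficient standard errors use the
#' GLS estimator with `sigma^2 = RSS / (n - p)`; reported p-values are
#' two-sided t with `df = n - p`. `R^2` is `1 - RSS(model) / RSS(intercept)`
#' with both residual sums computed in the metric of the model's fitted
#' lambda.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data A data.frame containing the model variables and a species
#'   identifier column matching the tip labels of `tree` (or the dimnames of
#'   `cov`).
#' @param tree A `"phylo"` object (used to build the covariance); ignored if
#'   `cov` is given.
#' @param cov Optional precomputed covariance matrix with species dimnames.
#' @param lambda `"ML"` (default) or a fixed numeric value in \[0, 1\].
#' @param species_col Name of the species identifier column (default
#'   `"species"`).
#' @return An object of class `"pgls"` with components `coefficients`,
#'   `se`, `tstat`, `pvalue`, `vcov`, `lambda`, `lambda_ml` (logical),
#'   `logLik`, `AIC`, `R2`, `n`, `df.residual`, `fitted`, `residuals` (raw),
#'   `wresiduals` (whitened), plus the pieces needed for refitting.
#' @examples
#' tr <- ape::rphylo(30, 1, 0)
#' d <- data.frame(species = tr$tip.label, y = rnorm(30), x = rnorm(30))
#' fit <- fit_pgls(y ~ x, d, tree = tr)
#' summary(fit)
#' @export
fit_pgls <- function(formula, data, tree = NULL, cov = NULL, lambda = "ML",
                     species_col = "species") {
  if (is.null(cov)) {
    if (is.null(tree)) stop("supply either 'tree' or 'cov'")
    cov <- phylo_covariance(tree)
  }
  if (!species_col %in% names(data)) stop("no '", species_col, "' column in data")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  sp <- as.character(data[[species_col]])[keep]
  if (anyDuplicated(sp)) stop("duplicate species after subsetting")
  common <- intersect(sp, rownames(cov))
  if (length(common) < 3L) stop("fewer than 3 species shared with covariance")
  idx <- match(common, sp)
  mf <- mf[keep, , drop = FALSE][idx, , drop = FALSE]
  C <- cov[common, common]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("too few species for the design (n = ", n, ", p = ", p, ")")
  if (qr(X)$rank < p) {
    stop("singular design; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  }

  gls_at <- function(lam, Xm = X) {
    V <- lam * C
    diag(V) <- diag(C)
    L <- tryCatch(chol(V), error = function(e)
      stop("covariance not positive definite at lambda = ", lam))
    Xw <- backsolve(L, Xm, transpose = TRUE)
    yw <- backsolve(L, y, transpose = TRUE)
    qf <- qr(Xw)
    beta <- qr.coef(qf, yw)
    rw <- yw - Xw %*% beta
    rss <- sum(rw^2)
    logdet <- 2 * sum(log(diag(L)))
    ll <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + logdet + n)
    list(beta = beta, rss = rss, logLik = ll, L = L, qf = qf, rw = rw)
  }

  if (identical(lambda, "ML")) {
    prof <- function(l) gls_at(l)$logLik
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, 1, opt$maximum)
    vals <- c(prof(0), prof(1), opt$objective)
    # ties within tolerance resolve toward the boundary value
    best <- cand[which.max(vals - 1e-9 * (cand > 0 & cand < 1))]
    lam_hat <- best
    lambda_ml <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be 'ML' or a value in [0, 1]")
    lam_hat <- lambda
    lambda_ml <- FALSE
  }

  fit <- gls_at(lam_hat)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  sigma2 <- fit$rss / (n - p)
  XtXinv <- chol2inv(qr.R(fit$qf))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)

  null_fit <- gls_at(lam_hat, Xm = matrix(1, n, 1))
  R2 <- 1 - fit$rss / null_fit$rss
  ll <- fit$logLik
  aic <- -2 * ll + 2 * (p + 2)            # coefficients + sigma^2 + lambda
  fitted <- drop(X %*% beta)

  structure(list(
    coefficients = beta, se = se, tstat = tstat, pvalue = pval, vcov = vc,
    lambda = lam_hat, lambda_ml = lambda_ml, logLik = ll, AIC = aic, R2 = R2,
    n = n, df.residual = n - p, sigma2 = sigma2,
    fitted = fitted, residuals = drop(y - fitted),
    wresiduals = drop(fit$rw) / sqrt(sigma2),
    y = y, X = X, C = C, species = common,
    terms = attr(mf, "terms"), model = mf, call = match.call(),
    formula = formula
  ), class = "pgls")
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  cat("n =", x$n, "  lambda =", signif(x$lambda, 4),
      if (x$lambda_ml) "(ML)" else "(fixed)",
      "  R2 =", signif(x$R2, 3), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tstat, `Pr(>|t|)` = object$pvalue)
  structure(list(call = object$call, formula = object$formula,
                 coefficients = tab, lambda = object$lambda,
                 lambda_ml = object$lambda_ml, R2 = object$R2, n = object$n,
                 logLik = object$logLik, AIC = object$AIC),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nPagel's lambda:", signif(x$lambda, 4),
      if (x$lambda_ml) "(ML)" else "(fixed)", "\n")
  cat("R2:", signif(x$R2, 4), "  n:", x$n,
      "  logLik:", signif(x$logLik, 6), "  AIC:", signif(x$AIC, 6), "\n")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
residuals.pgls <- function(object, type = c("response", "whitened"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$wresiduals
}

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  drop(X %*% object$coefficients)
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' Simulate responses from a fitted PGLS model
#'
#' Draws `nsim` response vectors from the fitted multivariate normal
#' `N(X beta, sigma^2 V(lambda))`.
#'
#' @param object A `"pgls"` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, rows named by species.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- object$lambda * object$C
  diag(V) <- diag(object$C)
  L <- chol(V * object$sigma2)
  n <- object$n
  out <- as.data.frame(
    object$fitted + t(L) %*% matrix(stats::rnorm(n * nsim), n, nsim))
  rownames(out) <- object$species
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Type-3 (marginal) Wald F-tests for a PGLS fit
#'
#' Tests each term in the design given all other terms, using Wald
#' F-statistics `F = (L b)' (L V L')^{-1} (L b) / df_num` with denominator
#' degrees of freedom `n - p`, the convention of marginal ANOVA tables for
#' GLS fits. For single-coefficient terms `F = t^2`.
#'
#' @param fit A `"pgls"` object.
#' @return A data.frame with one row per term: `F`, `df_num`, `df_den`, `p`.
#' @export
anova_marginal <- function(fit) {
  stopifnot(inherits(fit, "pgls"))
  asgn <- attr(fit$X, "assign")
  labels <- c("(Intercept)", attr(fit$terms, "term.labels"))[unique(asgn) + 1L]
  out <- data.frame(term = labels, F = NA_real_, df_num = NA_integer_,
                    df_den = fit$df.residual, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(unique(asgn))) {
    a <- unique(asgn)[i]
    sel <- which(asgn == a)
    b <- fit$coefficients[sel]
    Vb <- fit$vcov[sel, sel, drop = FALSE]
    stat <- drop(t(b) %*% solve(Vb, b)) / length(sel)
    out$F[i] <- stat
    out$df_num[i] <- length(sel)
    out$p[i] <- stats::pf(stat, length(sel), fit$df.residual, lower.tail = FALSE)
  }
  out
}

#' Per-group trait slopes from an interaction PGLS fit
#'
#' For a design `response ~ trait * group`, returns the trait slope within
#' each group: the reference group's slope is the trait coefficient, the
#' other group's slope adds the interaction coefficient. Standard errors
#' follow from the coefficient covariance of the linear combination; 95%
#' confidence intervals are t-based with `df = n - p`.
#'
#' @param fit A `"pgls"` fit containing `trait`, `group`, and their
#'   interaction.
#' @param trait Name of the continuous trait in the formula.
#' @param group Name of the grouping factor in the formula.
#' @return A data.frame with one row per group level: `slope`, `se`,
#'   `lower`, `upper`.
#' @export
group_slopes <- function(fit, trait, group) {
  stopifnot(inherits(fit, "pgls"))
  cn <- names(fit$coefficients)
  if (!trait %in% cn) stop("trait coefficient '", trait, "' not in fit")
  gl <- fit$model[[group]]
  if (is.null(gl)) stop("group variable '", group, "' not in model frame")
  levels_g <- levels(factor(gl))
  out <- data.frame(group = levels_g, slope = NA_real_, se = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  tq <- stats::qt(0.975, fit$df.residual)
  for (i in seq_along(levels_g)) {
    lv <- levels_g[i]
    L <- stats::setNames(numeric(length(cn)), cn)
    L[trait] <- 1
    if (i > 1L) {
      inter <- cn[grepl(trait, cn, fixed = TRUE) &
                  grepl(paste0(group, lv), cn, fixed = TRUE) &
                  grepl(":", cn, fixed = TRUE)]
      if (length(inter) != 1L)
        stop("no unique interaction coefficient for group '", lv, "'")
      L[inter] <- 1
    }
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    out$slope[i] <- est; out$se[i] <- se
    out$lower[i] <- est - tq * se; out$upper[i] <- est + tq * se
  }
  out
}

#' Compare linear and quadratic PGLS fits of a bivariate relationship
#'
#' Fits `response ~ predictor` and `response ~ predictor + predictor^2`,
#' each with its own ML lambda, and reports `dAIC = AIC(quadratic) -
#' AIC(linear)` (positive values favour the model without the quadratic
#' term) together with a 1-df likelihood-ratio test.
#'
#' @param response,predictor Column names in `data`.
#' @param data Trait data.frame with a species column.
#' @param tree,cov Phylogeny or covariance (as in [fit_pgls()]).
#' @param species_col Species identifier column.
#' @return A list with `dAIC`, `chisq`, `p`, and the two fits.
#' @export
compare_quadratic <- function(response, predictor, data, tree = NULL,
                              cov = NULL, species_col = "species") {
  f_lin <- stats::reformulate(predictor, response)
  f_quad <- stats::reformulate(c(predictor, sprintf("I(%s^2)", predictor)),
                               response)
  fl <- fit_pgls(f_lin, data, tree, cov, species_col = species_col)
  fq <- fit_pgls(f_quad, data, tree, cov, species_col = species_col)
  chisq <- max(0, 2 * (fq$logLik - fl$logLik))
  list(dAIC = fq$AIC - fl$AIC,
       chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       linear = fl, quadratic = fq)
}

#' Simulation power analysis for a (phylogenetically transformed) predictor
#'
#' Simulates responses with a known standardized effect of `x`, fits an
#' ordinary linear model to each replicate, and reports the fraction of
#' replicates whose slope p-value falls below `alpha`. For
#' `type = "correlation"` the predictor is z-scored and noise has
#' `sd = sqrt(1 - effect^2)` so the standardized slope equals `effect`
#' (requires `|effect| < 1`); for `type = "difference"` the predictor is a
#' 0/1 group indicator and noise has unit SD so `effect` is a Cohen's d.
#'
#' @param x Numeric predictor (typically phylogenetically transformed), or a
#'   two-level factor / 0-1 vector for `type = "difference"`.
#' @param effect True standardized effect size.
#' @param n_reps Number of simulation replicates (>= 100).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param type `"correlation"` or `"difference"`.
#' @return A list with `power`, `se` (binomial), `n`, `n_reps`, `alpha`.
#' @export
power_simulation <- function(x, effect, n_reps = 1000, alpha = 0.05,
                             seed = 1, type = c("correlation", "difference")) {
  type <- match.arg(type)
  if (n_reps < 100) stop("n_reps must be >= 100")
  if (is.factor(x) || is.character(x)) {
    x <- as.numeric(factor(x)) - 1
    type <- "difference"
  }
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance")
  n <- length(x)
  set.seed(seed)
  if (type == "correlation") {
    if (abs(effect) >= 1) stop("correlation-type effect must satisfy |effect| < 1")
    xs <- (x - mean(x)) / stats::sd(x)
    sd_noise <- sqrt(1 - effect^2)
  } else {
    xs <- x
    sd_noise <- 1
  }
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    yy <- effect * xs + stats::rnorm(n, 0, sd_noise)
    sm <- summary(stats::lm(yy ~ xs))
    hits[r] <- sm$coefficients[2, 4] < alpha
  }
  pw <- mean(hits)
  list(power = pw, se = sqrt(pw * (1 - pw) / n_reps), n = n,
       n_reps = n_reps, alpha = alpha)
}
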