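#' The candidate path-model set linking sex determination to adult sex ratio
#'
#' Eight directed acyclic graphs over the vertices GSD (sex-determination
#' system), JMB and AMB (juvenile and adult mortality bias), MAT (maturation
#' bias), and ASR (adult sex ratio). All models contain AMB -> ASR,
#' JMB -> ASR, MAT -> ASR and GSD -> AMB. The ".b" variants add a direct
#' GSD -> ASR link; models 2, 3, and 4 add GSD -> JMB, GSD -> MAT, or both.
#' Model 1.a is nested in 1.b, and both are nested in their expanded
#' versions.
#'
#' @return A named list of `"path_model"` objects (`m1.a` ... `m4.b`), each
#'   with `id`, `vertices`, and an `edges` two-column character matrix
#'   (from, to).
#' @export
build_model_set <- function() {
  V <- c("GSD", "JMB", "AMB", "MAT", "ASR")
  base <- rbind(c("GSD", "AMB"), c("AMB", "ASR"), c("JMB", "ASR"), c("MAT", "ASR"))
  direct <- c("GSD", "ASR")
  extras <- list(m1 = NULL, m2 = rbind(c("GSD", "JMB")),
                 m3 = rbind(c("GSD", "MAT")),
                 m4 = rbind(c("GSD", "JMB"), c("GSD", "MAT")))
  out <- list()
  for (m in names(extras)) {
    for (v in c("a", "b")) {
      e <- base
      if (!is.null(extras[[m]])) e <- rbind(e, extras[[m]])
      if (v == "b") e <- rbind(e, direct)
      id <- paste0(m, ".", v)
      colnames(e) <- c("from", "to")
      out[[id]] <- structure(list(id = id, vertices = V, edges = e),
                             class = "path_model")
    }
  }
  out
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model", x$id, "-", nrow(x$edges), "edges:\n")
  cat(paste(x$edges[, 1], "->", x$edges[, 2]), sep = "\n")
  invisible(x)
}

path_parents <- function(model, v) model$edges[model$edges[, "to"] == v, "from"]

path_is_acyclic <- function(model) {
  !is.null(tryCatch(topological_order(model), error = function(e) NULL))
}

topological_order <- function(model) {
  V <- model$vertices
  e <- model$edges
  order <- character(0)
  remaining <- sort(V)
  while (length(remaining)) {
    indeg0 <- remaining[vapply(remaining, function(v)
      !any(e[, "to"] == v & e[, "from"] %in% remaining), logical(1))]
    if (!length(indeg0)) stop("cycle detected in path model ", model$id)
    nxt <- sort(indeg0)[1]               # alphabetical tie-break
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  order
}

#' d-separation basis set of a path model
#'
#' Enumerates the testable independence claims of a DAG: one claim per
#' non-adjacent vertex pair, conditioned on the union of the pair's parents.
#' Two conventions are supported. `"hardenberg"` (the phylopath/pairwise-PGLS
#' convention) tests every non-adjacent pair, so `k = choose(V, 2) - edges`.
#' `"santos"` (the per-variable-contrasts / piecewiseSEM convention) treats
#' exogenous variables as freely correlated and therefore drops pairs whose
#' members both lack parents. Within each claim, the vertex later in the
#' topological order (ties broken alphabetically) is the response.
#'
#' @param model A `"path_model"`.
#' @param style `"santos"` or `"hardenberg"`.
#' @return A list of claims, each a list with `response`, `predictor`, and
#'   `conditioning` (character vector, possibly empty).
#' @export
basis_set <- function(model, style = c("santos", "hardenberg")) {
  style <- match.arg(style)
  V <- model$vertices
  adj <- paste(model$edges[, 1], model$edges[, 2])
  topo <- topological_order(model)
  pairs <- utils::combn(sort(V), 2)
  claims <- list()
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
    if (style == "santos" &&
        length(path_parents(model, a)) == 0L &&
        length(path_parents(model, b)) == 0L) next
    later <- if (match(a, topo) > match(b, topo)) a else b
    earlier <- setdiff(c(a, b), later)
    cond <- setdiff(unique(c(path_parents(model, a), path_parents(model, b))),
                    c(a, b))
    claims[[length(claims) + 1L]] <- list(response = later,
                                          predictor = earlier,
                                          conditioning = cond)
  }
  claims
}

#' Per-variable lambda-rescaled independent contrasts
#'
#' The data transformation of the per-variable-contrasts path-analysis
#' flavour: for each variable, Pagel's lambda is estimated by ML from an
#' intercept-only PGLS fit, the tree is rescaled by that lambda, and
#' Felsenstein contrasts are computed on the rescaled tree. Rescaling does
#' not change the topology, so contrasts of all variables are aligned by
#' internal node.
#'
#' @param table Complete-case data.frame with a `species` column and the
#'   numeric columns in `variables` (a binary sex-determination system
#'   should already be coded 0/1 and standardized).
#' @param tree A `"phylo"` object covering the species.
#' @param variables Columns to transform (default: all numeric columns).
#' @return A data.frame of contrasts (one row per internal node) with
#'   attributes `lambdas` (named vector of per-variable ML lambda) and
#'   `node_ids`.
#' @export
santos_transform <- function(table, tree,
                             variables = setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                                                 "species")) {
  if (any(!stats::complete.cases(table[variables])))
    stop("complete-case table required")
  for (v in variables) {
    if (stats::sd(table[[v]]) == 0) stop("variable '", v, "' is constant")
  }
  tree <- prune_to(tree, table$species)
  table <- table[match(tree$tip.label, table$species), , drop = FALSE]
  lambdas <- numeric(0)
  out <- NULL
  node_ids <- NULL
  for (v in variables) {
    f0 <- fit_pgls(stats::reformulate("1", v), table, tree = tree)
    lam <- f0$lambda
    if (lam %in% c(0, 1))
      message("lambda for '", v, "' estimated at the boundary (", lam, ")")
    lambdas[v] <- lam
    tr_l <- lambda_rescale_tree(tree, lam)
    vals <- stats::setNames(table[[v]], table$species)
    cs <- independent_contrasts(tr_l, vals)
    if (is.null(out)) {
      out <- data.frame(row.names = as.character(cs$node_ids))
      node_ids <- cs$node_ids
    }
    out[[v]] <- cs$contrasts
  }
  attr(out, "lambdas") <- lambdas
  attr(out, "node_ids") <- node_ids
  out
}

#' Test a single independence claim
#'
#' Regresses the claim's response on the tested predictor plus the
#' conditioning set and returns the two-sided p-value of the tested
#' coefficient. In the `"santos"` flavour the data are pre-transformed
#' contrasts and the regression is an ordinary linear model (with intercept
#' by default); in the `"hardenberg"` flavour the regression is a PGLS with
#' its own ML lambda on the raw (standardized) trait data.
#'
#' @param claim A claim from [basis_set()].
#' @param data Contrast table (`santos`) or trait table (`hardenberg`).
#' @param style `"santos"` or `"hardenberg"`.
#' @param tree Required for `"hardenberg"`.
#' @param intercept Include an intercept in santos-style regressions
#'   (default `TRUE`; set `FALSE` for through-origin contrast regressions).
#' @return The claim p-value.
#' @export
test_claim <- function(claim, data, style = c("santos", "hardenberg"),
                       tree = NULL, intercept = TRUE) {
  style <- match.arg(style)
  if (claim$predictor %in% claim$conditioning ||
      claim$response %in% claim$conditioning)
    stop("tested variable appears in its own conditioning set")
  rhs <- c(claim$predictor, claim$conditioning)
  if (style == "santos") {
    f <- stats::reformulate(rhs, claim$response, intercept = intercept)
    sm <- summary(stats::lm(f, data = data))
    cf <- sm$coefficients
    cf[claim$predictor, 4]
  } else {
    if (is.null(tree)) stop("hardenberg-style claims need a tree")
    f <- stats::reformulate(rhs, claim$response)
    fit <- fit_pgls(f, data, tree = tree)
    fit$pvalue[claim$predictor]
  }
}

#' Fisher's C statistic from independence-claim p-values
#'
#' `C = -2 * sum(log(p_i))`, chi-squared distributed with `2k` degrees of
#' freedom when all k claims hold.
#'
#' @param claim_pvalues Numeric vector of p-values in (0, 1\].
#' @return A list with `C`, `df`, and `p`. A claim p-value of exactly zero
#'   gives `C = Inf`, `p = 0`, and a `degenerate = TRUE` flag.
#' @export
fisher_c <- function(claim_pvalues) {
  k <- length(claim_pvalues)
  if (k < 1L) stop("need at least one claim p-value")
  if (any(claim_pvalues < 0 | claim_pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (any(claim_pvalues == 0)) {
    return(list(C = Inf, df = 2 * k, p = 0, degenerate = TRUE))
  }
  C <- -2 * sum(log(claim_pvalues))
  list(C = C, df = 2 * k, p = stats::pchisq(C, df = 2 * k, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Small-sample information criterion for d-separation models
#'
#' `IC = C + 2 q n / (n - 1 - q)`, the small-sample (AICc-style) correction
#' applied to Fisher's C. With `q` counted as edges + vertices this is the
#' CICc of the pairwise-PGLS flavour; with `q` counted as regression
#' coefficients plus residual variances it is the AICc of the
#' per-variable-contrasts flavour.
#'
#' @param C Fisher's C statistic.
#' @param q Parameter count.
#' @param n Sample size; must exceed `q + 1`.
#' @return The criterion value.
#' @export
information_criterion <- function(C, q, n) {
  if (n <= q + 1) stop("n must exceed q + 1")
  C + 2 * q * n / (n - 1 - q)
}

#' Parameter count of a path model
#'
#' @param model A `"path_model"`.
#' @param style `"hardenberg"` counts edges + vertices; `"santos"` counts
#'   per-regression coefficients (including intercepts) plus one residual
#'   variance per endogenous vertex.
#' @return Integer parameter count.
#' @export
path_q <- function(model, style = c("santos", "hardenberg")) {
  style <- match.arg(style)
  if (style == "hardenberg") return(nrow(model$edges) + length(model$vertices))
  endo <- unique(model$edges[, "to"])
  sum(vapply(endo, function(v) length(path_parents(model, v)) + 1L, integer(1))) +
    length(endo)
}

#' Confirmatory d-separation analysis of a path-model set
#'
#' Runs the full d-separation test for one or more candidate models: basis
#' set, claim p-values, Fisher's C with its chi-squared p, parameter count,
#' and the small-sample information criterion (AICc for the santos flavour,
#' CICc for the hardenberg flavour), plus delta-IC against the best model.
#'
#' @param models A `"path_model"` or list of them (default the full set from
#'   [build_model_set()]).
#' @param data Trait table (complete cases over the model variables) with a
#'   `species` column; variables standardized, GSD coded 0/1 standardized.
#' @param tree Phylogeny covering the species.
#' @param style `"santos"` or `"hardenberg"`.
#' @return An object of class `"dsep"`: a data.frame with one row per model
#'   (`model`, `k`, `df`, `C`, `p`, `q`, `IC`, `dIC`), ordered by IC, with
#'   the per-model claim p-values in `attr(, "claims")`.
#' @export
dsep <- function(models = build_model_set(), data, tree,
                 style = c("santos", "hardenberg")) {
  style <- match.arg(style)
  if (inherits(models, "path_model")) models <- stats::setNames(list(models), models$id)
  n <- nrow(data)
  if (style == "santos") {
    vars <- unique(c(models[[1]]$vertices))
    contr <- santos_transform(data, tree, variables = intersect(vars, names(data)))
  }
  rows <- list(); claims_all <- list()
  for (id in names(models)) {
    m <- models[[id]]
    bs <- basis_set(m, style)
    ps <- vapply(bs, function(cl) {
      if (style == "santos") test_claim(cl, contr, "santos")
      else test_claim(cl, data, "hardenberg", tree = tree)
    }, numeric(1))
    fc <- fisher_c(ps)
    q <- path_q(m, style)
    rows[[id]] <- data.frame(model = id, k = length(bs), df = fc$df,
                             C = fc$C, p = fc$p, q = q,
                             IC = information_criterion(fc$C, q, n),
                             stringsAsFactors = FALSE)
    claims_all[[id]] <- ps
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$IC), ]
  out$dIC <- out$IC - min(out$IC)
  rownames(out) <- NULL
  structure(out, class = c("dsep", "data.frame"), style = style, n = n,
            claims = claims_all)
}

#' @export
print.dsep <- function(x, digits = 3, ...) {
  cat("d-separation model comparison (", attr(x, "style"), " flavour, n = ",
      attr(x, "n"), ")\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Standardized path coefficients with bootstrap confidence intervals
#'
#' Fits each endogenous variable on its parents with the style-appropriate
#' engine (ordinary regression on the per-variable contrasts for `"santos"`;
#' PGLS with ML lambda on the raw standardized traits for `"hardenberg"`,
#' with lambda held at its fitted value during bootstrapping) and reports
#' standardized coefficients with 95% confidence intervals from a seeded
#' residual bootstrap: each replicate resamples a regression's
#' variance-rescaled residuals with replacement, adds them to the fitted
#' values, and refits. The default interval is the bootstrap-SE t-interval
#' (`coef +/- t[0.975, n - p] * sd(boot)`), which is well calibrated at the
#' sample sizes of comparative path analyses; percentile intervals are
#' available via `ci = "percentile"`.
#'
#' @param model A `"path_model"`.
#' @param data Complete-case trait table with `species` column.
#' @param tree Phylogeny.
#' @param style `"santos"` or `"hardenberg"`.
#' @param n_boot Number of bootstrap replicates (>= 100; default 500).
#' @param seed Integer seed.
#' @param ci Interval type, `"normal"` (default) or `"percentile"`.
#' @return A data.frame with one row per edge: `from`, `to`, `coef`,
#'   `lower`, `upper`, `n_boot_used`.
#' @export
fit_path_coefficients <- function(model, data, tree,
                                  style = c("santos", "hardenberg"),
                                  n_boot = 500, seed = 1,
                                  ci = c("normal", "percentile")) {
  style <- match.arg(style)
  ci <- match.arg(ci)
  if (n_boot < 100) stop("n_boot must be >= 100")
  vars <- intersect(model$vertices, names(data))
  if (style == "santos") {
    reg_data <- santos_transform(data, tree, variables = vars)
  } else {
    # whiten each equation at its own ML lambda; bootstrap at fixed lambda
    reg_data <- NULL
  }
  set.seed(seed)
  endo <- unique(model$edges[, "to"])
  rows <- list()
  for (v in endo) {
    pars <- path_parents(model, v)
    if (style == "santos") {
      X <- cbind(`(Intercept)` = 1, as.matrix(reg_data[pars]))
      y <- reg_data[[v]]
    } else {
      fit0 <- fit_pgls(stats::reformulate(pars, v), data, tree = tree)
      V <- fit0$lambda * fit0$C; diag(V) <- diag(fit0$C)
      L <- chol(V)
      X <- backsolve(L, fit0$X, transpose = TRUE)
      colnames(X) <- colnames(fit0$X)
      y <- drop(backsolve(L, fit0$y, transpose = TRUE))
    }
    qf <- qr(X)
    b <- qr.coef(qf, y)
    fitted <- drop(X %*% b)
    # variance-rescaled residuals so bootstrap draws carry the full error
    # variance despite the p fitted coefficients
    res <- (y - fitted) * sqrt(length(y) / (length(y) - ncol(X)))
    # inputs are standardized at the species level, and slopes are invariant
    # under the linear contrast/whitening transforms, so the raw slope is
    # already the standardized path coefficient
    std <- function(bb) bb[pars]
    boot <- matrix(NA_real_, n_boot, length(pars),
                   dimnames = list(NULL, pars))
    used <- 0L
    for (r in seq_len(n_boot)) {
      ystar <- fitted + sample(res, replace = TRUE)
      bb <- tryCatch(qr.coef(qf, ystar), error = function(e) NULL)
      if (is.null(bb) || any(is.na(bb))) next
      used <- used + 1L
      boot[used, ] <- std(bb)
    }
    if (used < n_boot)
      message(n_boot - used, " bootstrap replicate(s) dropped for ", v)
    bmat <- boot[seq_len(used), , drop = FALSE]
    if (ci == "percentile") {
      lims <- apply(bmat, 2, stats::quantile, probs = c(0.025, 0.975))
    } else {
      tq <- stats::qt(0.975, length(y) - ncol(X))
      se_b <- apply(bmat, 2, stats::sd)
      lims <- rbind(std(b) - tq * se_b, std(b) + tq * se_b)
      colnames(lims) <- pars
    }
    for (p_ in pars) {
      rows[[paste(p_, v)]] <- data.frame(
        from = p_, to = v, coef = unname(std(b)[p_]),
        lower = lims[1, p_], upper = lims[2, p_], n_boot_used = used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test between nested path models
#'
#' Computes the Gaussian maximum likelihood of each recursive path model as
#' the sum of per-equation regression likelihoods (each endogenous variable
#' on its parents, ML error variance `RSS / n`; a variable endogenous only in
#' the larger model contributes an intercept-only equation in the smaller
#' one) on the supplied (typically contrast-transformed) data, and reports
#' the chi-squared likelihood-ratio statistic with degrees of freedom equal
#' to the edge-count difference.
#'
#' @param model_small,model_large Nested `"path_model"` objects
#'   (`model_small$edges` must be a subset of `model_large$edges`).
#' @param data Data.frame of the model variables (e.g. from
#'   [santos_transform()]).
#' @return A list with `chisq`, `df`, and `p`.
#' @export
lrt_nested <- function(model_small, model_large, data) {
  es <- paste(model_small$edges[, 1], model_small$edges[, 2])
  el <- paste(model_large$edges[, 1], model_large$edges[, 2])
  if (!all(es %in% el)) stop("models are not nested")
  eq_loglik <- function(v, parents) {
    f <- if (length(parents)) stats::reformulate(parents, v)
         else stats::as.formula(paste(v, "~ 1"))
    fit <- stats::lm(f, data = data)
    n <- length(fit$residuals)
    rss <- sum(fit$residuals^2)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  endo <- unique(c(model_small$edges[, "to"], model_large$edges[, "to"]))
  ll_s <- sum(vapply(endo, function(v) eq_loglik(v, path_parents(model_small, v)),
                     numeric(1)))
  ll_l <- sum(vapply(endo, function(v) eq_loglik(v, path_parents(model_large, v)),
                     numeric(1)))
  chisq <- max(0, 2 * (ll_l - ll_s))
  df <- length(el) - length(es)
  list(chisq = chisq, df = df,
       p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1)
}
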