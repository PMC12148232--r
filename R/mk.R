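#' Two-state Mk transition probability matrix
#'
#' Closed form for the binary continuous-time Markov chain with rates
#' `q12` (state 1 -> 2) and `q21`: with `s = q12 + q21`,
#' `P11(t) = q21/s + q12/s * exp(-s t)` and so on. `s = 0` gives the
#' identity.
#'
#' @param q12,q21 Non-negative rates.
#' @param t Branch length.
#' @return A 2x2 transition probability matrix (rows = starting state).
#' @keywords internal
mk_prob <- function(q12, q21, t) {
  s <- q12 + q21
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c(q21 / s + q12 / s * e, q12 / s - q12 / s * e,
           q21 / s - q21 / s * e, q12 / s + q21 / s * e),
         2, 2, byrow = TRUE)
}

mk_conditionals <- function(tree, states01, q12, q21) {
  # Felsenstein pruning: conditional likelihoods L[node, state]
  n_tip <- length(tree$tip.label)
  L <- matrix(0, n_tip + tree$Nnode, 2)
  L[cbind(seq_len(n_tip), states01[tree$tip.label] + 1L)] <- 1
  eo <- ape::reorder.phylo(tree, "postorder")
  for (nd in unique(eo$edge[, 1])) {
    idx <- which(eo$edge[, 1] == nd)
    prod_ <- c(1, 1)
    for (i in idx) {
      ch <- eo$edge[i, 2]
      P <- mk_prob(q12, q21, eo$edge.length[i])
      prod_ <- prod_ * (P %*% L[ch, ])
    }
    L[nd, ] <- prod_
  }
  L
}

mk_loglik <- function(tree, states01, q12, q21, root_prior = c(0.5, 0.5)) {
  L <- mk_conditionals(tree, states01, q12, q21)
  root <- length(tree$tip.label) + 1L
  log(sum(root_prior * L[root, ]))
}

#' Fit a binary Mk model of character evolution
#'
#' Maximum-likelihood estimation of transition rates for a two-state
#' character (XY/ZW sex-determination systems) under the equal-rates (ER) or
#' all-rates-different (ARD) Mk model, using the pruning algorithm with an
#' equal (0.5/0.5) root prior by default. Rates are optimized on the log
#' scale by bounded search.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param states Named character vector of tip states (`"XY"`/`"ZW"`, or any
#'   two labels; the first sorted label is state 1).
#' @param model `"ER"` or `"ARD"`.
#' @param root_prior `"equal"` (default) or `"stationary"`.
#' @return An object of class `"mk_fit"` with `rates` (named
#'   `q_<s1>-><s2>`), `logLik`, `AIC`, `model`, `states` (level labels),
#'   `root_prior`, `tree`, and `tip_states`.
#' @export
fit_mk <- function(tree, states, model = c("ER", "ARD"),
                   root_prior = c("equal", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  tree <- validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0) stop("tree has zero total depth")
  if (!all(tree$tip.label %in% names(states)))
    stop("states missing for some tips")
  states <- states[tree$tip.label]
  lev <- sort(unique(as.character(states)))
  if (length(lev) > 2L) stop("more than two states")
  s01 <- stats::setNames(match(as.character(states), lev) - 1L, names(states))

  if (length(lev) == 1L) {
    warning("single-state data; rates at the zero boundary")
    lev <- if (lev == "XY") c("XY", "ZW") else c(lev, paste0(lev, "_alt"))
    rates <- c(0, 0)
    ll <- log(0.5)                        # equal prior on the constant state
    k <- if (model == "ER") 1 else 2
    return(structure(list(model = model, rates = stats::setNames(rates,
             paste0("q_", lev[1], "->", lev[2], c("", "_rev"))),
             logLik = ll, AIC = -2 * ll + 2 * k, states = lev,
             root_prior = root_prior, tree = tree, tip_states = states),
             class = "mk_fit"))
  }

  prior_fun <- function(q12, q21) {
    if (root_prior == "equal") c(0.5, 0.5)
    else { s <- q12 + q21; if (s == 0) c(0.5, 0.5) else c(q21 / s, q12 / s) }
  }
  nll <- function(logq) {
    q <- exp(logq)
    q12 <- q[1]; q21 <- if (model == "ER") q[1] else q[2]
    -mk_loglik(tree, s01, q12, q21, prior_fun(q12, q21))
  }
  # initial rate: parsimony-informed guess (changes per unit tree length)
  init <- log(max(length(lev) / sum(tree$edge.length), 1e-4))
  if (model == "ER") {
    opt <- stats::optim(init, nll, method = "Brent",
                        lower = log(1e-9), upper = log(1e4))
    q12 <- q21 <- exp(opt$par)
  } else {
    opt <- stats::optim(c(init, init), nll, method = "L-BFGS-B",
                        lower = log(1e-9), upper = log(1e4),
                        control = list(factr = 1e4))
    q12 <- exp(opt$par[1]); q21 <- exp(opt$par[2])
  }
  ll <- -opt$value
  k <- if (model == "ER") 1 else 2
  structure(list(
    model = model,
    rates = stats::setNames(c(q12, q21),
                            c(paste0("q_", lev[1], "->", lev[2]),
                              paste0("q_", lev[2], "->", lev[1]))),
    logLik = ll, AIC = -2 * ll + 2 * k, states = lev,
    root_prior = root_prior, tree = tree, tip_states = states,
    tip_states01 = s01
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model (", x$model, "), states ", paste(x$states, collapse = "/"),
      "\n", sep = "")
  print(signif(x$rates, 4))
  cat("logLik:", signif(x$logLik, 6), "  AIC:", signif(x$AIC, 6), "\n")
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik, df = if (object$model == "ER") 1 else 2,
            nobs = length(object$tip_states), class = "logLik")
}

#' @export
AIC.mk_fit <- function(object, ...) object$AIC

#' Likelihood of a binary Mk model at given rates
#'
#' Evaluates the pruning-algorithm log-likelihood without optimizing; used
#' to profile the ARD surface and to cross-check against enumeration.
#'
#' @inheritParams fit_mk
#' @param q12,q21 Transition rates (state order = sorted state labels).
#' @return Log-likelihood.
#' @export
mk_loglik_at <- function(tree, states, q12, q21, root_prior = c(0.5, 0.5)) {
  lev <- sort(unique(as.character(states)))
  s01 <- stats::setNames(match(as.character(states), lev) - 1L, names(states))
  mk_loglik(tree, s01, q12, q21, root_prior)
}

sample_branch_history <- function(a, b, t, q12, q21) {
  # uniformization: exact sampling of a CTMC path conditional on endpoints.
  # Returns the number of real state changes on the branch.
  Q <- matrix(c(-q12, q12, q21, -q21), 2, 2, byrow = TRUE)
  omega <- max(q12, q21)
  if (omega == 0) return(0L)
  R <- diag(2) + Q / omega
  P <- mk_prob(q12, q21, t)
  pab <- P[a, b]
  # jump-count distribution: P(N = n | a, b) ~ Pois(omega t)(n) R^n[a,b] / pab
  nmax <- max(10L, stats::qpois(1 - 1e-12, omega * t) + 10L)
  Rp <- vector("list", nmax + 1L)
  Rp[[1]] <- diag(2)
  for (i in seq_len(nmax)) Rp[[i + 1L]] <- Rp[[i]] %*% R
  wts <- vapply(0:nmax, function(n)
    stats::dpois(n, omega * t) * Rp[[n + 1L]][a, b], numeric(1))
  wts <- wts / sum(wts)
  N <- sample.int(nmax + 1L, 1L, prob = wts) - 1L
  if (N == 0L) return(0L)
  # sample the uniformized chain states by backward conditioning
  changes <- 0L
  cur <- a
  for (j in seq_len(N)) {
    # P(state_j = s | cur, b) ~ R[cur, s] * R^(N-j)[s, b]
    w <- R[cur, ] * Rp[[N - j + 1L]][, b]
    s_new <- sample.int(2L, 1L, prob = w)
    if (s_new != cur) changes <- changes + 1L
    cur <- s_new
  }
  changes
}

#' Stochastic character maps and transition counts
#'
#' Samples full character histories conditional on the tip states and the
#' fitted rates: ancestral node states are drawn from their conditional
#' distributions (pruning pass plus root draw and preorder sampling), then
#' each branch history is sampled by uniformization conditional on its
#' endpoint states, and directional transitions are counted.
#'
#' @param fit An `"mk_fit"` object.
#' @param n_maps Number of maps (>= 1).
#' @param seed Integer seed.
#' @return An object of class `"simmap_summary"`: a list with `n_maps`,
#'   `mean_total`, `mean_12`, `mean_21` (direction labels in
#'   `$directions`), and the per-map count matrix `counts`.
#' @export
stochastic_maps <- function(fit, n_maps = 100, seed = 1) {
  stopifnot(inherits(fit, "mk_fit"), n_maps >= 1)
  set.seed(seed)
  tree <- fit$tree
  q <- unname(fit$rates)
  q12 <- q[1]; q21 <- q[2]
  lev <- fit$states
  s01 <- fit$tip_states01
  if (is.null(s01))
    s01 <- stats::setNames(match(as.character(fit$tip_states), lev) - 1L,
                           names(fit$tip_states))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  prior <- if (fit$root_prior == "equal") c(0.5, 0.5) else {
    s <- q12 + q21; if (s == 0) c(0.5, 0.5) else c(q21 / s, q12 / s)
  }
  L <- mk_conditionals(tree, s01, q12, q21)
  eo <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(eo$edge)))     # preorder traversal
  counts <- matrix(0L, n_maps, 2, dimnames = list(NULL,
              c(paste0(lev[1], "->", lev[2]), paste0(lev[2], "->", lev[1]))))
  for (m in seq_len(n_maps)) {
    state <- integer(n_tip + tree$Nnode)
    state[seq_len(n_tip)] <- s01[tree$tip.label] + 1L
    w_root <- prior * L[root, ]
    state[root] <- sample.int(2L, 1L, prob = w_root)
    c12 <- 0L; c21 <- 0L
    for (i in pre_edges) {
      par <- eo$edge[i, 1]; ch <- eo$edge[i, 2]; t <- eo$edge.length[i]
      P <- mk_prob(q12, q21, t)
      if (ch <= n_tip) {
        # tip state fixed; just sample the branch history
      } else {
        w <- P[state[par], ] * L[ch, ]
        state[ch] <- sample.int(2L, 1L, prob = w)
      }
      nc <- sample_branch_history(state[par], state[ch], t, q12, q21)
      # distribute changes between directions given endpoints
      a <- state[par]; b <- state[ch]
      if (nc > 0L) {
        # alternating path starting at a with nc changes
        dir1 <- if (a == 1L) ceiling(nc / 2) else floor(nc / 2)
        c12 <- c12 + dir1
        c21 <- c21 + (nc - dir1)
      }
    }
    counts[m, 1] <- c12; counts[m, 2] <- c21
  }
  structure(list(n_maps = n_maps,
                 mean_total = mean(rowSums(counts)),
                 mean_12 = mean(counts[, 1]), mean_21 = mean(counts[, 2]),
                 directions = colnames(counts), counts = counts),
            class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat("Stochastic character maps:", x$n_maps, "maps\n")
  cat("mean transitions:", signif(x$mean_total, 4),
      sprintf("(%s: %.3g, %s: %.3g)\n", x$directions[1], x$mean_12,
              x$directions[2], x$mean_21))
  invisible(x)
}

#' Fitch parsimony count for a binary character
#'
#' Minimum number of state changes on the tree consistent with the tip
#' states; used as a lower reference for stochastic-map transition counts.
#'
#' @param tree A `"phylo"` object.
#' @param states Named tip states (two levels).
#' @return Integer parsimony score.
#' @export
fitch_count <- function(tree, states) {
  tree <- validate_phylo(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  lev <- sort(unique(as.character(states)))
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip))
    sets[[i]] <- match(as.character(states[tree$tip.label[i]]), lev)
  eo <- ape::reorder.phylo(tree, "postorder")
  score <- 0L
  for (nd in unique(eo$edge[, 1])) {
    ch <- eo$edge[eo$edge[, 1] == nd, 2]
    s <- Reduce(intersect, sets[ch])
    if (length(s) == 0L) {
      s <- Reduce(union, sets[ch])
      score <- score + 1L
    }
    sets[[nd]] <- s
  }
  score
}
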