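## Proportional-odds (cumulative-logit) regression of ordinal fibrosis stage
## on a single gene's expression, fit by Newton-Raphson with step halving.
## A lean native fitter is used because the signature pipeline fits one model
## per gene (thousands of fits); formula-interface fitters spend most of
## their time building model frames.

## Model: P(Y <= k | x) = plogis(zeta_k - beta * x), k = 1..K-1, zeta increasing.

## Negative log-likelihood pieces for one parameter vector.
polr_loglik <- function(zeta, beta, x, y, K) {
  eta_hi <- ifelse(y == K, Inf, zeta[pmin(y, K - 1)] - beta * x)
  eta_lo <- ifelse(y == 1, -Inf, zeta[pmax(y - 1, 1)] - beta * x)
  p <- stats::plogis(eta_hi) - stats::plogis(eta_lo)
  sum(log(pmax(p, 1e-300)))
}

#' Fit a proportional-odds model for one predictor
#'
#' Newton-Raphson with analytic gradient/Hessian and step halving;
#' convergence when the gradient max-norm falls below `tol`. Genes with
#' quasi-separated or degenerate likelihoods are flagged non-converged
#' rather than erroring.
#'
#' @param x numeric predictor (one gene's expression across samples).
#' @param y ordered factor or integer codes 1..K.
#' @param tol gradient max-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return list: `beta`, `zeta` (K-1 thresholds), `converged`, `loglik`,
#'   `n_iter`, `levels`.
#' @export
fit_ordinal <- function(x, y, tol = 1e-8, max_iter = 100) {
  if (is.factor(y)) {
    y <- droplevels(as.factor(y))
    lev <- levels(y)
    y <- as.integer(y)
  } else {
    lev <- as.character(sort(unique(y)))
    y <- match(y, sort(unique(y)))
  }
  K <- length(lev)
  if (K < 2) stop("need >= 2 outcome levels")
  n <- length(y)
  ## start at the zero-slope solution: empirical cumulative logits
  cum <- cumsum(tabulate(y, K))[seq_len(K - 1)] / n
  zeta <- stats::qlogis(pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n)))
  beta <- 0
  if (stats::sd(x) == 0) {
    ## slope unidentifiable for a constant predictor
    return(list(beta = 0, zeta = zeta, converged = FALSE,
                loglik = polr_loglik(zeta, 0, x, y, K), n_iter = 0L,
                levels = lev))
  }
  ll <- polr_loglik(zeta, beta, x, y, K)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta_hi <- ifelse(y == K, Inf, zeta[pmin(y, K - 1)] - beta * x)
    eta_lo <- ifelse(y == 1, -Inf, zeta[pmax(y - 1, 1)] - beta * x)
    Fh <- stats::plogis(eta_hi); Fl <- stats::plogis(eta_lo)
    p <- pmax(Fh - Fl, 1e-12)
    fh <- ifelse(is.finite(eta_hi), Fh * (1 - Fh), 0)
    fl <- ifelse(is.finite(eta_lo), Fl * (1 - Fl), 0)
    fph <- ifelse(is.finite(eta_hi), fh * (1 - 2 * Fh), 0)
    fpl <- ifelse(is.finite(eta_lo), fl * (1 - 2 * Fl), 0)
    u <- fh / p          # dll/d eta_hi
    w <- -fl / p         # dll/d eta_lo
    Haa <- fph / p - (fh / p)^2
    Hbb <- -fpl / p - (fl / p)^2
    Hab <- fh * fl / p^2
    np <- K              # K-1 thresholds + slope
    grad <- numeric(np)
    H <- matrix(0, np, np)
    for (k in seq_len(K - 1)) {
      hi <- y == k        # obs whose upper threshold is zeta_k
      lo <- y == k + 1    # obs whose lower threshold is zeta_k
      grad[k] <- sum(u[hi]) + sum(w[lo])
      H[k, k] <- sum(Haa[hi]) + sum(Hbb[lo])
      if (k < K - 1) {
        ## obs in category k+1 couple zeta_k (lower) with zeta_{k+1} (upper)
        H[k, k + 1] <- H[k + 1, k] <- sum(Hab[lo & (y < K)])
      }
      H[k, np] <- H[np, k] <- -sum(x[hi] * (Haa[hi] + Hab[hi] * (y[hi] > 1))) -
        sum(x[lo] * (Hbb[lo] + Hab[lo] * (y[lo] < K)))
    }
    grad[np] <- -sum(x * (u + w))
    H[np, np] <- sum(x^2 * (Haa + Hbb + 2 * Hab * (y > 1 & y < K)))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    ## Newton ascent: H is (near) negative definite, so move -H^{-1} grad
    lam <- 1
    repeat {
      zeta_new <- zeta - lam * step[seq_len(K - 1)]
      beta_new <- beta - lam * step[np]
      ok <- all(diff(zeta_new) > 0) || K == 2
      if (ok) {
        ll_new <- polr_loglik(zeta_new, beta_new, x, y, K)
        if (ll_new >= ll - 1e-10) break
      }
      lam <- lam / 2
      if (lam < 1e-10) { ll_new <- ll; zeta_new <- zeta; beta_new <- beta; break }
    }
    zeta <- zeta_new; beta <- beta_new; ll <- ll_new
    if (abs(beta) > 50) break   # quasi-separation guard
  }
  list(beta = beta, zeta = zeta, converged = converged, loglik = ll,
       n_iter = it, levels = lev)
}

#' Fit per-gene proportional-odds models of stage on expression
#'
#' Fits one cumulative-logit model per gene (stage on transformed
#' expression). Genes whose fit does not converge (flat expression, quasi-
#' separation) are flagged and excluded by downstream scoring. Non-coding
#' genes are handled the same as coding genes (no annotation filter).
#'
#' @param expr genes x samples matrix of variance-stabilized expression (see
#'   [transform_expression()]).
#' @param stages per-sample stage labels (coerced to the ordered scale).
#' @param tol,max_iter passed to [fit_ordinal()].
#' @return an `ordinal_fit_set`: list with `beta` (named vector), `zeta`
#'   (genes x K-1), `converged`, `loglik`, `levels`.
#' @export
fit_ordinal_per_gene <- function(expr, stages, tol = 1e-8, max_iter = 100) {
  expr <- as.matrix(expr)
  y <- droplevels(stage_factor(stages))
  if (nlevels(y) < 2) stop("need >= 2 stage levels")
  if (any(table(y) < 2)) stop("each stage level needs >= 2 samples")
  if (length(y) != ncol(expr)) stop("stages do not align with expr columns")
  K <- nlevels(y)
  g <- nrow(expr)
  beta <- numeric(g); conv <- logical(g); ll <- numeric(g)
  zeta <- matrix(NA_real_, g, K - 1,
                 dimnames = list(rownames(expr), paste0("zeta", seq_len(K - 1))))
  for (j in seq_len(g)) {
    f <- tryCatch(fit_ordinal(expr[j, ], y, tol = tol, max_iter = max_iter),
                  error = function(e) NULL)
    if (is.null(f)) { conv[j] <- FALSE; next }
    beta[j] <- f$beta; conv[j] <- f$converged
    zeta[j, ] <- f$zeta; ll[j] <- f$loglik
  }
  names(beta) <- names(conv) <- names(ll) <- rownames(expr)
  structure(list(beta = beta, zeta = zeta, converged = conv, loglik = ll,
                 levels = levels(y)),
            class = "ordinal_fit_set")
}

## Category probabilities P(Y = k | x) for one fitted gene, k = 1..K.
ordinal_probs <- function(zeta, beta, x) {
  K <- length(zeta) + 1
  cum <- rbind(matrix(stats::plogis(outer(zeta, x, function(z, xx) z - beta * xx)),
                      nrow = K - 1),
               rep(1, length(x)))
  rbind(cum[1, , drop = FALSE], diff(cum))
}
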